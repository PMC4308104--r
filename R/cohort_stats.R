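# round half away from zero, the convention used for printed percentages
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarise a genotyped cohort
#'
#' Computes genotype counts, activity-score phenotype frequencies, the
#' number of homozygous samples and of *5 deletion carriers, and per-SNP
#' Hardy-Weinberg tests from a cohort of diplotypes.
#'
#' Founder haplotypes are counted at each panel SNP for the HWE tests
#' (two founders per sample, ignoring copy number); *5 founders carry no
#' sequence and are counted as reference at every site.  When population
#' labels are supplied the HWE test is computed per label.
#'
#' @param genotypes Diplotypes: a character vector of star strings, a
#'   list of `cyp_config` objects, or a list of `diplotype_call`s.
#' @param counts Optional integer vector of per-genotype sample counts
#'   (for frequency-table input); defaults to 1 each.
#' @param population_labels Optional per-entry labels for stratified HWE.
#' @param model Allele model.
#' @return Object of class `cohort_summary`: list with `n`,
#'   `genotype_table` (data frame: genotype, n, activity_score,
#'   phenotype, percent), `phenotype_table` (data frame: phenotype,
#'   n, percent), `n_homozygous`, `n_deletion_carriers` and
#'   `hwe` (data frame per SNP (and population): chi-squared statistic,
#'   p-value, monomorphic flag).
#' @examples
#' s <- summarize_cohort(c("*1/*1", "*1/*4", "*4/*4"), counts = c(2, 2, 1))
#' s$phenotype_table
#' @export
summarize_cohort <- function(genotypes, counts = NULL,
                             population_labels = NULL,
                             model = default_allele_model()) {
  configs <- lapply(genotypes, function(g) {
    if (inherits(g, "diplotype_call")) {
      if (is.null(g$best)) return(NULL)
      return(g$best)
    }
    if (inherits(g, "cyp_config")) return(g)
    parse_diplotype(g, model)
  })
  drop <- vapply(configs, is.null, logical(1))
  if (any(drop)) {
    warning(sum(drop), " unresolved call(s) excluded from cohort summary")
    configs <- configs[!drop]
    if (!is.null(counts)) counts <- counts[!drop]
    if (!is.null(population_labels)) population_labels <-
        population_labels[!drop]
  }
  if (length(configs) == 0L) stop("empty cohort")
  if (is.null(counts)) counts <- rep(1L, length(configs))
  stopifnot(length(counts) == length(configs))

  strings <- vapply(configs, format, character(1))
  scores <- vapply(configs, activity_score, numeric(1), model = model)
  phenos <- vapply(scores, phenotype_from_score, character(1), model = model)
  n_total <- sum(counts)

  genotype_table <- data.frame(
    genotype = strings, n = as.integer(counts), activity_score = scores,
    phenotype = phenos,
    percent = round_half_up(100 * counts / n_total, 2),
    stringsAsFactors = FALSE, row.names = NULL)

  ph_levels <- c("PM", "IM", "EM", "UM")
  ph_n <- vapply(ph_levels, function(p) sum(counts[phenos == p]), numeric(1))
  phenotype_table <- data.frame(
    phenotype = ph_levels, n = as.integer(ph_n),
    percent = round_half_up(100 * ph_n / n_total, 1),
    stringsAsFactors = FALSE, row.names = NULL)

  hom <- vapply(configs, function(cf) cf$allele_a == cf$allele_b, logical(1))
  del <- vapply(configs, function(cf)
    model$alleles[[cf$allele_a]]$is_deletion ||
      model$alleles[[cf$allele_b]]$is_deletion, logical(1))

  hwe <- .cohort_hwe(configs, counts, population_labels, model)

  structure(list(n = n_total, genotype_table = genotype_table,
                 phenotype_table = phenotype_table,
                 n_homozygous = as.integer(sum(counts[hom])),
                 n_deletion_carriers = as.integer(sum(counts[del])),
                 hwe = hwe),
            class = "cohort_summary")
}

.cohort_hwe <- function(configs, counts, population_labels, model) {
  if (is.null(population_labels))
    population_labels <- rep("all", length(configs))
  out <- list()
  for (pop in unique(population_labels)) {
    idx <- population_labels == pop
    for (snp in model$panel$snp_id) {
      carries <- function(name) snp %in% model$alleles[[name]]$variant_snps
      g <- vapply(configs[idx], function(cf)
        carries(cf$allele_a) + carries(cf$allele_b), numeric(1))
      n_hom_ref <- sum(counts[idx][g == 0])
      n_het <- sum(counts[idx][g == 1])
      n_hom_var <- sum(counts[idx][g == 2])
      h <- hwe_chi2(n_hom_ref, n_het, n_hom_var)
      out[[length(out) + 1L]] <- data.frame(
        population = pop, snp_id = snp, n_hom_ref = n_hom_ref,
        n_het = n_het, n_hom_var = n_hom_var,
        statistic = h$statistic, p_value = h$p_value,
        monomorphic = h$monomorphic, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort summary> n =", x$n, "samples;",
      x$n_homozygous, "homozygous;",
      x$n_deletion_carriers, "*5 carriers\n")
  print(x$phenotype_table, row.names = FALSE)
  invisible(x)
}

#' Hardy-Weinberg chi-squared test from genotype counts at one SNP
#'
#' Pearson chi-squared test (1 degree of freedom) of observed genotype
#' counts against the p^2 / 2pq / q^2 expectation computed from the
#' sample allele frequencies.
#'
#' @param n_hom_ref,n_het,n_hom_var Genotype counts.
#' @return List with `statistic`, `p_value` and `monomorphic` (when one
#'   allele is absent the test is undefined; statistic 0, p 1).
#' @examples
#' hwe_chi2(25, 50, 25)   # exact HWE proportions: statistic 0
#' hwe_chi2(50, 0, 50)    # maximal departure: statistic 100
#' @export
hwe_chi2 <- function(n_hom_ref, n_het, n_hom_var) {
  n <- n_hom_ref + n_het + n_hom_var
  if (n <= 0) stop("no observations")
  p <- (2 * n_hom_ref + n_het) / (2 * n)
  q <- 1 - p
  if (p == 0 || q == 0)
    return(list(statistic = 0, p_value = 1, monomorphic = TRUE))
  expd <- n * c(p^2, 2 * p * q, q^2)
  obs <- c(n_hom_ref, n_het, n_hom_var)
  stat <- sum((obs - expd)^2 / expd)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       monomorphic = FALSE)
}

#' Allelic-ratio statistics by copy-number class
#'
#' Descriptive statistics of the allelic ratio per total-copy-number
#' class, a one-way ANOVA across classes, Tukey HSD post-hoc pairwise
#' comparisons (alpha 0.05), and the Pearson correlation between copy
#' number and ratio over all samples.
#'
#' @param copies Integer vector of total gene copy numbers.
#' @param ratios Numeric vector of allelic ratios (same length).
#' @param conf_level Confidence level for the Tukey intervals.
#' @return Object of class `ratio_stats`: list with `by_class` (data
#'   frame: copies, n, mean, sd, min, max), `anova_f`, `anova_p`,
#'   `tukey` (data frame: comparison, diff, p_adj, significant) and
#'   `pearson_r`.  With fewer than two classes of at least two
#'   observations the tests are skipped (`NA`).
#' @examples
#' set.seed(1)
#' st <- ratio_stats(rep(2:4, each = 20),
#'                   rnorm(60, rep(c(0.97, 1.83, 2.76), each = 20),
#'                         rep(c(0.07, 0.16, 0.39), each = 20)))
#' st$by_class
#' @export
ratio_stats <- function(copies, ratios, conf_level = 0.95) {
  stopifnot(length(copies) == length(ratios), length(ratios) > 0)
  cls <- sort(unique(copies))
  by_class <- do.call(rbind, lapply(cls, function(k) {
    r <- ratios[copies == k]
    data.frame(copies = k, n = length(r), mean = mean(r),
               sd = stats::sd(r), min = min(r), max = max(r))
  }))
  out <- list(by_class = by_class, anova_f = NA_real_, anova_p = NA_real_,
              tukey = NULL, pearson_r = NA_real_)
  if (length(cls) >= 2) {
    out$pearson_r <- stats::cor(copies, ratios, method = "pearson")
    if (sum(by_class$n >= 2) >= 2 && stats::var(ratios) > 0) {
      grp <- factor(copies)
      fit <- stats::aov(ratios ~ grp)
      tab <- summary(fit)[[1]]
      out$anova_f <- tab[["F value"]][1]
      out$anova_p <- tab[["Pr(>F)"]][1]
      tk <- stats::TukeyHSD(fit, conf.level = conf_level)$grp
      out$tukey <- data.frame(
        comparison = rownames(tk), diff = tk[, "diff"],
        p_adj = tk[, "p adj"],
        significant = tk[, "p adj"] < 1 - conf_level,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  structure(out, class = "ratio_stats")
}

#' @export
print.ratio_stats <- function(x, ...) {
  cat("<allelic-ratio statistics>\n")
  print(x$by_class, row.names = FALSE)
  if (!is.na(x$anova_p))
    cat("ANOVA F =", signif(x$anova_f, 4), ", p =", format.pval(x$anova_p),
        "; Pearson r =", signif(x$pearson_r, 3), "\n")
  invisible(x)
}
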