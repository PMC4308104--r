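#' Read an allele-quantification sample sheet
#'
#' The sample sheet is a TSV with one row per (sample, panel SNP) and
#' columns `sample_id`, `snp_id`, `percent_var`, plus optional
#' `percent_ref` (imputed as 100 - percent_var when absent),
#' `total_copies` and `population_label`.  Rows whose percentages do not
#' sum to 100 within the tolerance are rejected with their line numbers.
#'
#' @param path Path to the TSV file.
#' @param model Allele model used to validate SNP identifiers.
#' @param sum_tolerance Passed to [snp_quant_call()].
#' @return List of [sample_input()] objects, ordered by sample_id.
#' @export
read_sample_sheet <- function(path, model = default_allele_model(),
                              sum_tolerance = 2) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty sample sheet: ", path)
  need <- c("sample_id", "snp_id", "percent_var")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  if (!"percent_ref" %in% names(df)) df$percent_ref <- NA_real_
  bad <- setdiff(unique(df$snp_id), model$panel$snp_id)
  if (length(bad))
    stop("unknown snp_id in sample sheet: ", paste(bad, collapse = ", "),
         "; panel is ", paste(model$panel$snp_id, collapse = " "))
  dup <- duplicated(df[, c("sample_id", "snp_id")])
  if (any(dup))
    stop("duplicate (sample, SNP) rows at line(s) ",
         paste(which(dup) + 1L, collapse = ", "))
  df$.line <- seq_len(nrow(df)) + 1L   # header is line 1
  out <- lapply(split(df, df$sample_id), function(d) {
    calls <- lapply(seq_len(nrow(d)), function(i) {
      tryCatch(
        snp_quant_call(d$snp_id[i], percent_var = d$percent_var[i],
                       percent_ref = d$percent_ref[i],
                       sum_tolerance = sum_tolerance),
        error = function(e) stop("line ", d$.line[i], ": ",
                                 conditionMessage(e), call. = FALSE))
    })
    tot <- if ("total_copies" %in% names(d) && !all(is.na(d$total_copies)))
      unique(stats::na.omit(d$total_copies))[1] else NULL
    pop <- if ("population_label" %in% names(d) &&
               !all(is.na(d$population_label)))
      unique(stats::na.omit(d$population_label))[1] else NULL
    sample_input(d$sample_id[1], calls, total_copies = tot,
                 population_label = pop, model = model)
  })
  out[order(names(out))]
}

#' Write samples back to a sample-sheet TSV
#'
#' Inverse of [read_sample_sheet()]: one row per (sample, SNP), tab
#' separated, '.' decimal separator, no quoting.
#'
#' @param samples List of [sample_input()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  if (length(samples) == 0L) stop("no samples to write")
  rows <- do.call(rbind, lapply(samples, function(s) {
    do.call(rbind, lapply(s$quant_calls, function(q) data.frame(
      sample_id = s$sample_id, snp_id = q$snp_id,
      percent_var = q$percent_var, percent_ref = q$percent_ref,
      total_copies = if (is.null(s$total_copies)) NA_integer_
                     else s$total_copies,
      population_label = if (is.null(s$population_label)) NA_character_
                         else s$population_label,
      stringsAsFactors = FALSE)))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.call_row <- function(call, model) {
  ph <- phenotype_for_sample(call, model)
  data.frame(
    sample_id = call$sample_id,
    diplotype = format(call$best),
    total_copies = if (is.na(total_copies(call$best))) NA_integer_
                   else total_copies(call$best),
    duplicated_allele = if (is.na(call$duplicated_allele)) ""
                        else call$duplicated_allele,
    activity_score = if (ph$ambiguous)
      paste(ph$candidate_scores, collapse = "|")
      else as.character(ph$activity_score),
    phenotype = if (ph$ambiguous)
      paste(ph$candidate_phenotypes, collapse = "|")
      else ph$phenotype,
    flags = paste(call$flags, collapse = ","),
    residual = call$residual,
    stringsAsFactors = FALSE)
}

#' Write diplotype calls to TSV or JSON
#'
#' @param calls List of `diplotype_call` objects (no-calls are skipped
#'   with a warning).
#' @param path Output path.
#' @param format `"tsv"` (default) or `"json"`.
#' @param model Allele model used for phenotyping.
#' @return `path`, invisibly.  Rows are ordered by sample_id; ambiguous
#'   phenotypes are rendered like `"EM|UM"`.
#' @export
write_calls <- function(calls, path, format = c("tsv", "json"),
                        model = default_allele_model()) {
  format <- match.arg(format)
  if (length(calls) == 0L) stop("no calls to write")
  ok <- !vapply(calls, function(cl) is.null(cl$best), logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " no-call(s) skipped")
    calls <- calls[ok]
  }
  if (length(calls) == 0L) stop("all calls were no-calls")
  tab <- do.call(rbind, lapply(calls, .call_row, model = model))
  tab <- tab[order(tab$sample_id), , drop = FALSE]
  if (format == "tsv") {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(tab, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Export one sample's panel genotypes as a minimal VCF
#'
#' Writes a small VCF 4.2 file with one record per panel SNP on a
#' gene-relative `CYP2D6` contig, a single sample column with `GT` and a
#' `VF` (variant-allele fraction, percent) FORMAT field carrying the
#' quantification signal.  Intended as an interoperability convenience;
#' allele-quantification percentages have no canonical VCF home.
#'
#' @param sample A [sample_input()].
#' @param call The corresponding `diplotype_call` (for genotypes).
#' @param path Output path.
#' @param model Allele model.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(sample, call, path,
                            model = default_allele_model()) {
  stopifnot(inherits(sample, "sample_input"), inherits(call, "diplotype_call"))
  if (is.null(call$best)) stop("cannot export a no-call")
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=CYP2D6>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("##FORMAT=<ID=VF,Number=1,Type=Float,Description=",
                  "\"Variant allele fraction, percent\">"),
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample$sample_id, sep = "\t"))
  b <- call$best
  recs <- vapply(seq_len(nrow(model$panel)), function(i) {
    snp <- model$panel[i, ]
    pos <- as.integer(sub("^([0-9]+).*$", "\\1", snp$label))
    in_a <- snp$snp_id %in% model$alleles[[b$allele_a]]$variant_snps
    in_b <- snp$snp_id %in% model$alleles[[b$allele_b]]$variant_snps
    gt <- paste0(as.integer(in_a), "/", as.integer(in_b))
    q <- sample$quant_calls[[snp$snp_id]]
    vf <- if (is.null(q)) "." else sprintf("%.2f", q$percent_var)
    ref <- snp$ref_base
    alt <- if (snp$var_base == "-") paste0("<DEL>") else snp$var_base
    paste(c("CYP2D6", pos, snp$snp_id, ref, alt, ".", ".", ".",
            "GT:VF", paste0(gt, ":", vf)), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Packaged genotype-frequency tables
#'
#' Accessors for the plain-text tables shipped with the package:
#' `reference_cohort_genotypes()` returns the 39-genotype frequency table
#' of a 218-sample clinical cohort (columns `genotype`, `n`);
#' `coriell_genotypes()` the Coriell repository validation samples with
#' known copy numbers (`sample_id`, `genotype`); and
#' `cnv_resolution_genotypes()` the duplication/multiplication-bearing
#' subset with orthogonal total copy numbers used to illustrate
#' pre- versus post-quantification phenotype prediction
#' (`resolved_genotype`, `n`, `total_copies`).
#'
#' @return A data frame.
#' @export
reference_cohort_genotypes <- function() {
  utils::read.delim(system.file("extdata", "reference_cohort_genotypes.tsv",
                                package = "cypquant", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' @rdname reference_cohort_genotypes
#' @export
coriell_genotypes <- function() {
  utils::read.delim(system.file("extdata", "coriell_validation_genotypes.tsv",
                                package = "cypquant", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' @rdname reference_cohort_genotypes
#' @export
cnv_resolution_genotypes <- function() {
  utils::read.delim(system.file("extdata", "cnv_resolution_genotypes.tsv",
                                package = "cypquant", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}
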