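#' Bundle one sample's quantification calls for diplotype calling
#'
#' @param sample_id Sample identifier.
#' @param quant_calls List of [snp_quant_call()] objects, at most one per
#'   panel SNP.
#' @param total_copies Optional total gene copy number from an orthogonal
#'   assay (e.g. TaqMan real-time PCR); when supplied it constrains the
#'   search and overrides ratio-implied totals.
#' @param population_label Optional population / ethnicity label used for
#'   stratified Hardy-Weinberg testing.
#' @param model Allele model used to validate SNP identifiers.
#' @return Object of class `sample_input`.
#' @export
sample_input <- function(sample_id, quant_calls, total_copies = NULL,
                         population_label = NULL,
                         model = default_allele_model()) {
  if (length(quant_calls) == 0L)
    stop("sample ", sample_id, ": empty quantification call list")
  ids <- vapply(quant_calls, function(q) q$snp_id, character(1))
  bad <- setdiff(ids, model$panel$snp_id)
  if (length(bad))
    stop("sample ", sample_id, ": unknown snp_id ",
         paste(bad, collapse = ", "), "; panel is ",
         paste(model$panel$snp_id, collapse = " "))
  if (anyDuplicated(ids))
    stop("sample ", sample_id, ": duplicate quantification call for ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!is.null(total_copies)) {
    total_copies <- as.integer(total_copies)
    if (is.na(total_copies) || total_copies < 1L)
      stop("sample ", sample_id, ": total_copies must be a positive integer")
  }
  names(quant_calls) <- ids
  structure(list(sample_id = sample_id, quant_calls = quant_calls,
                 total_copies = total_copies,
                 population_label = population_label),
            class = "sample_input")
}

# enumerate every founder-pair / copy-split configuration reaching the
# given total of sequence-contributing copies
.enumerate_configs <- function(total, model, max_copies = 3L) {
  alleles <- names(model$alleles)
  out <- list()
  for (i in seq_along(alleles)) for (j in i:length(alleles)) {
    a <- alleles[i]; b <- alleles[j]
    del_a <- model$alleles[[a]]$is_deletion
    del_b <- model$alleles[[b]]$is_deletion
    if (del_a && del_b) next                    # no sequence at all
    if (del_a || del_b) {
      if (total >= 1L && total <= max_copies) {
        ca <- if (del_a) 0L else total
        cb <- if (del_b) 0L else total
        out[[length(out) + 1L]] <- allele_config(a, ca, b, cb, model = model)
      }
      next
    }
    for (ca in seq_len(min(max_copies, total - 1L))) {
      cb <- total - ca
      if (cb < 1L || cb > max_copies) next
      if (a == b && ca > cb) next               # homozygous: split unordered
      out[[length(out) + 1L]] <- allele_config(a, ca, b, cb, model = model)
    }
  }
  out
}

.config_residual <- function(config, obs_frac, model) {
  exp_frac <- vapply(names(obs_frac), function(s)
    expected_variant_fraction(config, s, model), numeric(1))
  mean(abs(obs_frac - exp_frac))
}

# tie-break key: fewer distinct non-reference founders, fewer total
# copies, then star-number order
.config_order_key <- function(config) {
  founders <- unique(c(config$allele_a, config$allele_b))
  c(length(setdiff(founders, "*1")),
    config$copies_a + config$copies_b,
    star_number(config$allele_a), star_number(config$allele_b),
    config$copies_a)
}

#' Call a CYP2D6 diplotype with allele-specific copy number
#'
#' The core dosage-fit search.  Every candidate configuration — a founder
#' pair from the allele model (including *1 and the *5 deletion) with a
#' copy-count split of each candidate total — is scored by the mean
#' absolute deviation between the observed variant-allele fractions and
#' the fractions expected under the forward dosage model; the minimiser is
#' returned.  Candidate totals come from an orthogonal copy-number assay
#' when supplied, otherwise from the allelic-ratio classifier applied to
#' each heterozygous panel SNP (plus the default of 2).
#'
#' Samples with no heterozygous panel SNP read "about 100%" at every
#' position regardless of copy number, so quantification alone cannot
#' size them; they are flagged `homozygous_unquantifiable` and are only
#' resolved when a total is supplied.  Calls containing *5 are flagged
#' `deletion_carrier`; calls containing *10 are flagged `star10_or_36`
#' because the panel cannot discriminate *36 from *10.
#'
#' @param sample A [sample_input()].
#' @param model Allele model.
#' @param bins Ratio calibration, a [ratio_bin_table()].
#' @param residual_margin Alternatives within this residual of the best
#'   fit are reported; the call is flagged `ambiguous` when any of them
#'   disagrees with the best fit on phenotype.
#' @param max_copies Maximum per-founder copy count searched (default 3,
#'   supporting x3 multiplications).
#' @param hom_threshold Minor-allele percentage below which a SNP is
#'   treated as homozygous.
#' @return Object of class `diplotype_call`: list with `sample_id`,
#'   `best` (a `cyp_config`, or `NULL` for a no-call), `residual`,
#'   `total_copies`, `duplicated_allele`, `alternatives`, `flags` and
#'   `diagnostics`.
#' @examples
#' m <- default_allele_model()
#' s <- sample_input("ex", list(
#'   snp_quant_call("rs28371706", 65.3), snp_quant_call("rs16947", 65.3),
#'   snp_quant_call("rs35742686", 0), snp_quant_call("rs3892097", 0),
#'   snp_quant_call("rs5030655", 0), snp_quant_call("rs1065852", 0),
#'   snp_quant_call("rs28371725", 0)))
#' call <- call_diplotype(s)
#' format(call$best)            # "*1/*17x2": the *17 allele is duplicated
#' call$duplicated_allele
#' @export
call_diplotype <- function(sample, model = default_allele_model(),
                           bins = ratio_bin_table(),
                           residual_margin = 0.03, max_copies = 3L,
                           hom_threshold = 5) {
  stopifnot(inherits(sample, "sample_input"))
  obs_frac <- vapply(sample$quant_calls,
                     function(q) q$percent_var / 100, numeric(1))
  ratios <- lapply(sample$quant_calls, allelic_ratio,
                   hom_threshold = hom_threshold)
  het <- !vapply(ratios, function(r) r$homozygous_signal, logical(1))
  flags <- character(0)
  diagnostics <- character(0)

  implied <- integer(0)
  if (any(het)) {
    implied <- unique(unlist(lapply(ratios[het], function(r) {
      rc <- classify_ratio(r$ratio, bins)
      rc$implied_total_copies
    })))
    implied <- implied[!is.na(implied)]
  } else {
    flags <- c(flags, "homozygous_unquantifiable")
  }

  if (!is.null(sample$total_copies)) {
    totals <- sample$total_copies
    if (any(het) && length(implied) && !sample$total_copies %in% implied) {
      diagnostics <- c(diagnostics, paste0(
        "orthogonal-assay total (", sample$total_copies,
        ") conflicts with ratio-implied total(s) ",
        paste(implied, collapse = "/"), "; using the orthogonal assay"))
      flags <- c(flags, "total_copies_conflict")
    }
  } else {
    totals <- sort(unique(c(2L, implied)))
  }

  cands <- list()
  for (t in totals) cands <- c(cands, .enumerate_configs(t, model, max_copies))
  if (length(cands) == 0L) {
    return(structure(list(sample_id = sample$sample_id, best = NULL,
                          residual = NA_real_, total_copies = NULL,
                          duplicated_allele = NA_character_,
                          alternatives = list(),
                          flags = c(flags, "no_call"),
                          diagnostics = c(diagnostics, paste0(
                            "no feasible configuration for total(s) ",
                            paste(totals, collapse = "/")))),
                     class = "diplotype_call"))
  }

  res <- vapply(cands, .config_residual, numeric(1),
                obs_frac = obs_frac, model = model)
  keys <- t(vapply(cands, .config_order_key, numeric(5)))
  ord <- do.call(order, c(list(res), lapply(seq_len(ncol(keys)),
                                            function(k) keys[, k])))
  best <- cands[[ord[1]]]
  best_res <- res[ord[1]]
  alt_idx <- ord[-1][res[ord[-1]] <= best_res + residual_margin]
  alternatives <- cands[alt_idx]

  # unresolved homozygous split: annotate so rendering shows "(A/A)xN"
  if (!any(het) && best$allele_a == best$allele_b &&
      total_copies(best) > 2L) {
    tot <- total_copies(best)
    best <- allele_config(best$allele_a, tot %/% 2L, best$allele_b,
                          tot - tot %/% 2L, homozygous_total = tot,
                          model = model)
  }

  if (model$alleles[[best$allele_a]]$is_deletion ||
      model$alleles[[best$allele_b]]$is_deletion)
    flags <- c(flags, "deletion_carrier")
  if ("*10" %in% c(best$allele_a, best$allele_b))
    flags <- c(flags, "star10_or_36")

  call <- structure(list(sample_id = sample$sample_id, best = best,
                         residual = best_res,
                         total_copies = total_copies(best),
                         duplicated_allele = NA_character_,
                         alternatives = alternatives, flags = flags,
                         diagnostics = diagnostics),
                    class = "diplotype_call")

  # phenotype ambiguity across near-equivalent fits
  if (length(alternatives)) {
    ph_best <- phenotype_from_score(activity_score(best, model), model)
    ph_alt <- vapply(alternatives, function(cfg)
      phenotype_from_score(activity_score(cfg, model), model), character(1))
    if (any(ph_alt != ph_best))
      call$flags <- c(call$flags, "ambiguous")
  }
  # balanced duplications (e.g. 2+2) have no single duplicated founder;
  # the quantification signal alone cannot orient them
  if (best$copies_a > 1L && best$copies_b > 1L &&
      best$copies_a == best$copies_b && best$allele_a != best$allele_b)
    call$flags <- unique(c(call$flags, "ambiguous"))
  call$duplicated_allele <- identify_duplicated_allele(call)
  call
}

#' Identify the duplicated/multiplicated founder allele of a call
#'
#' @param call A `diplotype_call`.
#' @return The star name of the founder whose copy count exceeds one, or
#'   `NA` when neither (1:1 configurations), when both founders carry the
#'   same elevated copy count (indistinguishable balanced duplication,
#'   flagged upstream), or when the call is homozygous-unquantifiable.
#' @examples
#' # *1/*17x2 -> "*17"; *1/*2 -> NA
#' @export
identify_duplicated_allele <- function(call) {
  stopifnot(inherits(call, "diplotype_call"))
  if (is.null(call$best)) return(NA_character_)
  b <- call$best
  if ("homozygous_unquantifiable" %in% call$flags) return(NA_character_)
  if (b$copies_a > 1L && b$copies_b > 1L) {
    return(NA_character_)  # balanced duplication: no single duplicated allele
  }
  if (b$copies_a > 1L) return(b$allele_a)
  if (b$copies_b > 1L) return(b$allele_b)
  NA_character_
}

#' Phenotype a resolved diplotype call
#'
#' Composes [activity_score()] and [phenotype_from_score()] on the best
#' configuration.  When the call is flagged ambiguous (near-equivalent
#' fits with different phenotypes), the candidate phenotypes and scores
#' across the best fit and its alternatives are reported.
#'
#' @param call A `diplotype_call`.
#' @param model Allele model.
#' @return Object of class `phenotype_call`: list with `activity_score`,
#'   `phenotype`, `ambiguous`, `candidate_phenotypes` and
#'   `candidate_scores`.
#' @export
phenotype_for_sample <- function(call, model = default_allele_model()) {
  stopifnot(inherits(call, "diplotype_call"))
  if (is.null(call$best))
    stop("cannot phenotype a no-call (sample ", call$sample_id, ")")
  score <- activity_score(call$best, model)
  ph <- phenotype_from_score(score, model)
  ambiguous <- "ambiguous" %in% call$flags
  cand_ph <- ph; cand_sc <- score
  if (ambiguous && length(call$alternatives)) {
    alt_sc <- vapply(call$alternatives, function(cfg)
      activity_score(cfg, model), numeric(1))
    cand_sc <- sort(unique(c(score, alt_sc)))
    cand_ph <- unique(vapply(cand_sc, phenotype_from_score, character(1),
                             model = model))
  }
  structure(list(activity_score = score, phenotype = ph,
                 ambiguous = ambiguous,
                 candidate_phenotypes = cand_ph,
                 candidate_scores = cand_sc),
            class = "phenotype_call")
}

#' Pre-resolution phenotype candidates from genotype plus total copy number
#'
#' Reproduces what a copy-number assay alone can say: given an unphased
#' founder pair and a total gene copy number — but no allele
#' quantification to say which allele carries the extra copies — the
#' possible activity scores are enumerated under the assumption that a
#' single allele carries the whole duplication/multiplication (splits
#' 1 + (T-1) and (T-1) + 1).  A heterozygote such as *1/*17 with 3 total
#' copies is "EM or UM" (score 2 or 2.5) until quantification resolves
#' which allele is duplicated.
#'
#' @param allele_a,allele_b Founder star-allele names.
#' @param total Total gene copy number (deletion founders contribute 0).
#' @param model Allele model.
#' @return A `phenotype_call` whose `candidate_scores` and
#'   `candidate_phenotypes` enumerate the possibilities; `ambiguous` is
#'   `TRUE` when the phenotype depends on the unassigned duplication, and
#'   `phenotype`/`activity_score` are then `NA`.
#' @examples
#' phenotype_before_quant("*1", "*17", 3)$candidate_phenotypes  # EM, UM
#' phenotype_before_quant("*1", "*1", 3)$phenotype              # "UM"
#' @export
phenotype_before_quant <- function(allele_a, allele_b, total,
                                   model = default_allele_model()) {
  .check_allele(allele_a, model); .check_allele(allele_b, model)
  del_a <- model$alleles[[allele_a]]$is_deletion
  del_b <- model$alleles[[allele_b]]$is_deletion
  total <- as.integer(total)
  if (del_a && del_b) stop("both founders are deletions")
  if (del_a || del_b) {
    splits <- list(c(if (del_a) 0L else total, if (del_b) 0L else total))
  } else if (total <= 2L) {
    splits <- list(c(1L, total - 1L))
  } else {
    splits <- list(c(1L, total - 1L), c(total - 1L, 1L))
  }
  scores <- sort(unique(vapply(splits, function(sp)
    activity_score(allele_config(allele_a, sp[1], allele_b, sp[2],
                                 model = model), model), numeric(1))))
  phs <- unique(vapply(scores, phenotype_from_score, character(1),
                       model = model))
  ambiguous <- length(phs) > 1L
  structure(list(
    activity_score = if (length(scores) == 1L) scores else NA_real_,
    phenotype = if (!ambiguous) phs else NA_character_,
    ambiguous = ambiguous,
    candidate_phenotypes = phs,
    candidate_scores = scores),
    class = "phenotype_call")
}

#' @export
print.diplotype_call <- function(x, ...) {
  cat("<diplotype call> ", x$sample_id, ": ",
      if (is.null(x$best)) "NO CALL" else format(x$best), sep = "")
  if (!is.null(x$best))
    cat("  residual ", signif(x$residual, 3),
        if (!is.na(x$duplicated_allele))
          paste0("  duplicated ", x$duplicated_allele), sep = "")
  if (length(x$flags)) cat("  [", paste(x$flags, collapse = ","), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
print.phenotype_call <- function(x, ...) {
  if (x$ambiguous) {
    cat("<phenotype> ", paste(x$candidate_phenotypes, collapse = " or "),
        " (score ", paste(x$candidate_scores, collapse = " or "),
        ", ambiguous)\n", sep = "")
  } else {
    cat("<phenotype> ", x$phenotype, " (activity score ", x$activity_score,
        ")\n", sep = "")
  }
  invisible(x)
}
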