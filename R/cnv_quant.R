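#' A single-SNP allele-quantification measurement
#'
#' Holds the measured reference and variant percentages at one panel
#' position for one sample.  Percentages must sum to 100 within a
#' tolerance (default +/- 2 percentage points, matching typical
#' pyrosequencing software rounding) and are renormalised to sum to
#' exactly 100.
#'
#' @param snp_id Panel SNP identifier (rs number).
#' @param percent_ref,percent_var Measured percentages in \[0, 100\].
#'   If `percent_ref` is missing it is imputed as `100 - percent_var`.
#' @param sum_tolerance Maximum allowed deviation of the raw sum from 100.
#' @return Object of class `snp_quant_call` with normalised percentages.
#' @examples
#' snp_quant_call("rs28371706", percent_var = 65.3)  # ref imputed as 34.7
#' @export
snp_quant_call <- function(snp_id, percent_var, percent_ref = NULL,
                           sum_tolerance = 2) {
  if (is.null(percent_ref) || is.na(percent_ref))
    percent_ref <- 100 - percent_var
  if (any(!is.finite(c(percent_ref, percent_var))) ||
      percent_ref < 0 || percent_var < 0 ||
      percent_ref > 100 || percent_var > 100)
    stop("percentages must lie in [0, 100] for ", snp_id)
  s <- percent_ref + percent_var
  if (abs(s - 100) > sum_tolerance)
    stop("percentages at ", snp_id, " sum to ", s,
         ", outside 100 +/- ", sum_tolerance)
  structure(list(snp_id = snp_id,
                 percent_ref = percent_ref * 100 / s,
                 percent_var = percent_var * 100 / s),
            class = "snp_quant_call")
}

#' Allelic ratio of a single-SNP quantification call
#'
#' The major/minor allelic ratio is the larger of the two allele
#' percentages divided by the smaller; it is about 1 for a balanced 1:1
#' heterozygote, about 2 for a 2:1 copy split (one allele duplicated) and
#' about 3 for 3:1.  When the minor allele falls below the homozygosity
#' threshold the site carries no quantifiable two-allele signal (the assay
#' reads "about 100%" for homozygotes, deletion carriers and homozygous
#' multiplications alike) and no numeric ratio is returned.
#'
#' @param call A `snp_quant_call`.
#' @param oriented If `TRUE` return the raw variant/reference quotient
#'   without folding (useful for reproducing oriented calibration
#'   statistics whose balanced-heterozygote mean falls slightly below 1);
#'   classification always uses the folded ratio.
#' @param hom_threshold Minor-allele percentage below which the signal is
#'   considered homozygous (default 5).
#' @return A list with `ratio` (`NA` when homozygous), `homozygous_signal`
#'   (logical) and `snp_id`.
#' @examples
#' allelic_ratio(snp_quant_call("rs28371706", 65.3))$ratio  # 1.882
#' allelic_ratio(snp_quant_call("rs1065852", 100))          # homozygous
#' @export
allelic_ratio <- function(call, oriented = FALSE, hom_threshold = 5) {
  stopifnot(inherits(call, "snp_quant_call"))
  minor <- min(call$percent_ref, call$percent_var)
  if (minor < hom_threshold)
    return(list(snp_id = call$snp_id, ratio = NA_real_,
                homozygous_signal = TRUE))
  r <- if (oriented) call$percent_var / call$percent_ref
       else max(call$percent_ref, call$percent_var) / minor
  list(snp_id = call$snp_id, ratio = r, homozygous_signal = FALSE)
}

#' Calibration table for allelic-ratio copy-split classification
#'
#' Default calibration (per-class mean, SD, minimum, maximum of the
#' allelic ratio) for heterozygous samples with total gene copy numbers
#' 2, 3 and 4: means 0.97, 1.83 and 2.76 with SDs 0.07, 0.16 and 0.39 and
#' ranges 0.85-1.06, 1.6-2.2 and 2.42-3.2.  Decision boundaries between
#' classes default to the midpoints of the gaps between the class ranges
#' ((1.06+1.6)/2 = 1.33 and (2.2+2.42)/2 = 2.31); the upper acceptance
#' bound defaults to 3.7, about one within-class SD above the 4-copy
#' maximum.
#'
#' @param calibration Data frame with columns `copies`, `mean`, `sd`,
#'   `min`, `max` (one row per copy class, increasing).
#' @param boundaries Strictly increasing numeric vector of decision
#'   boundaries between successive classes.
#' @param upper_bound Ratio above which calls are flagged out of range.
#' @return Object of class `ratio_bin_table`.
#' @export
ratio_bin_table <- function(calibration = NULL, boundaries = NULL,
                            upper_bound = NULL) {
  if (is.null(calibration))
    calibration <- data.frame(
      copies = c(2L, 3L, 4L),
      split  = c("1:1", "2:1", "3:1"),
      mean   = c(0.97, 1.83, 2.76),
      sd     = c(0.07, 0.16, 0.39),
      min    = c(0.85, 1.60, 2.42),
      max    = c(1.06, 2.20, 3.20),
      stringsAsFactors = FALSE)
  if (is.null(boundaries)) {
    k <- nrow(calibration)
    boundaries <- (calibration$max[-k] + calibration$min[-1]) / 2
  }
  if (is.null(upper_bound))
    upper_bound <- 3.7
  if (is.unsorted(boundaries, strictly = TRUE))
    stop("decision boundaries must be strictly increasing")
  structure(list(calibration = calibration, boundaries = boundaries,
                 upper_bound = upper_bound),
            class = "ratio_bin_table")
}

#' Classify an allelic ratio into a copy-number split
#'
#' Assigns a folded (major/minor) allelic ratio to a 1:1, 2:1 or 3:1 copy
#' split, implying total gene copy numbers 2, 3 and 4 respectively.
#' Oriented ratios below 1 are folded to their reciprocal before
#' classification.  Ratios within `near_margin` of a decision boundary are
#' flagged `near_boundary`; ratios above the table's upper acceptance
#' bound are returned unclassified with the `out_of_range` flag.
#'
#' @param ratio Positive allelic ratio.
#' @param bins A `ratio_bin_table`.
#' @param near_margin Width of the near-boundary warning zone.
#' @return Object of class `ratio_call`: list with `ratio` (folded),
#'   `copy_split` (`"1:1"`, `"2:1"`, `"3:1"` or `"unclassified"`),
#'   `implied_total_copies` (integer or `NA`) and `flags` (character).
#' @examples
#' classify_ratio(1.83)$implied_total_copies   # 3
#' classify_ratio(0.97)$copy_split             # "1:1"
#' classify_ratio(65.3 / 34.7)$copy_split      # "2:1"
#' @export
classify_ratio <- function(ratio, bins = ratio_bin_table(),
                           near_margin = 0.1) {
  if (!is.finite(ratio) || ratio <= 0)
    stop("allelic ratio must be a positive finite number")
  if (ratio < 1) ratio <- 1 / ratio
  flags <- character(0)
  if (any(abs(ratio - bins$boundaries) < near_margin))
    flags <- c(flags, "near_boundary")
  if (ratio > bins$upper_bound) {
    return(structure(list(ratio = ratio, copy_split = "unclassified",
                          implied_total_copies = NA_integer_,
                          flags = c(flags, "out_of_range")),
                     class = "ratio_call"))
  }
  cls <- findInterval(ratio, bins$boundaries) + 1L
  structure(list(ratio = ratio,
                 copy_split = bins$calibration$split[cls],
                 implied_total_copies = bins$calibration$copies[cls],
                 flags = flags),
            class = "ratio_call")
}

#' @export
print.ratio_call <- function(x, ...) {
  cat("<ratio call> ratio ", signif(x$ratio, 4), " -> split ", x$copy_split,
      if (!is.na(x$implied_total_copies))
        paste0(" (", x$implied_total_copies, " total copies)"),
      if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Convert a comparative delta-delta-Ct value to gene copy number
#'
#' Real-time PCR relative quantification: copy number equals the
#' reference copy number times 2^(-ddCt).  The raw value is rounded to
#' the nearest integer; raw values farther than `confidence_margin` from
#' any integer are flagged low-confidence.
#'
#' @param ddct Delta-delta-Ct value (any real number).
#' @param reference_copies Copy number of the calibrator (default 2).
#' @param confidence_margin Maximum |raw - rounded| treated as confident.
#' @return List with `raw`, `rounded` (integer) and `low_confidence`.
#' @examples
#' copies_from_ddct(0)        # reference: 2 copies
#' copies_from_ddct(1)        # half: 1 copy (deletion carrier)
#' copies_from_ddct(-0.585)   # 3 copies
#' @export
copies_from_ddct <- function(ddct, reference_copies = 2L,
                             confidence_margin = 0.35) {
  stopifnot(is.finite(ddct), reference_copies >= 1)
  raw <- reference_copies * 2^(-ddct)
  rounded <- as.integer(round(raw))
  list(raw = raw, rounded = rounded,
       low_confidence = abs(raw - rounded) > confidence_margin)
}
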