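#' Default star-allele frequencies for cohort simulation
#'
#' Founder haplotype frequencies observed in a 218-sample US hypertensive
#' cohort genotyped on this panel (163 *1, 109 *2, 8 *3, 65 *4, 18 *5,
#' 3 *6, 18 *10, 27 *17 and 25 *41 founder alleles out of 436).
#'
#' @return Named numeric vector summing to 1.
#' @export
default_allele_frequencies <- function() {
  n <- c("*1" = 163, "*2" = 109, "*3" = 8, "*4" = 65, "*5" = 18,
         "*6" = 3, "*10" = 18, "*17" = 27, "*41" = 25)
  n / sum(n)
}

#' Configuration for the allele-quantification cohort simulator
#'
#' @param allele_frequencies Named vector of founder star-allele
#'   frequencies summing to 1.
#' @param duplication_rate Per-founder probability of carrying 2 copies.
#' @param multiplication_rate Per-founder probability of carrying 3
#'   copies (x3 multiplication).
#' @param percent_noise_sd Gaussian noise SD applied to each simulated
#'   allele percentage, in percentage points.  The default of 2.0 induces
#'   an allelic-ratio dispersion bracketing the published per-class ratio
#'   SDs (0.07 / 0.16 / 0.39 for 2 / 3 / 4 copies): by the delta method
#'   the ratio r = p/(100-p) has dr/dp = 100/(100-p)^2, i.e. about 0.04,
#'   0.09 and 0.16 at the 50%, 67% and 75% class centres, giving ratio
#'   SDs of roughly 0.08, 0.18 and 0.32.
#' @param taqman_raw_sd SD of the raw (pre-rounding) simulated
#'   orthogonal-assay copy number.
#' @param n_samples Number of samples for [simulate_cohort()].
#' @param seed Integer seed; fixed seeds give bit-identical cohorts.
#' @return Object of class `sim_config`.
#' @export
simulation_config <- function(allele_frequencies = default_allele_frequencies(),
                              duplication_rate = 0.03,
                              multiplication_rate = 0.002,
                              percent_noise_sd = 2.0,
                              taqman_raw_sd = 0.15,
                              n_samples = 100L,
                              seed = NULL) {
  if (abs(sum(allele_frequencies) - 1) > 1e-9)
    stop("allele frequencies must sum to 1")
  if (any(allele_frequencies < 0))
    stop("allele frequencies must be non-negative")
  stopifnot(duplication_rate >= 0, duplication_rate <= 1,
            multiplication_rate >= 0, multiplication_rate <= 1,
            duplication_rate + multiplication_rate <= 1,
            percent_noise_sd >= 0, taqman_raw_sd >= 0, n_samples >= 1)
  structure(list(allele_frequencies = allele_frequencies,
                 duplication_rate = duplication_rate,
                 multiplication_rate = multiplication_rate,
                 percent_noise_sd = percent_noise_sd,
                 taqman_raw_sd = taqman_raw_sd,
                 n_samples = as.integer(n_samples), seed = seed),
            class = "sim_config")
}

#' Simulate one sample's allele-quantification measurements
#'
#' Applies the forward dosage model to a true allele configuration:
#' at each panel SNP the variant percentage is 100 times the expected
#' variant fraction plus truncated Gaussian noise, with the ref/var pair
#' renormalised to 100.  An orthogonal-assay total copy number is drawn
#' as the rounded true total plus Gaussian noise on the raw scale.
#'
#' Uses the current RNG state; seed control belongs to the caller (or to
#' [simulate_cohort()], which seeds from its configuration).
#'
#' @param truth A `cyp_config`, the true configuration.
#' @param cfg A [simulation_config()].
#' @param include_total Attach the simulated orthogonal total copy
#'   number to the returned sample (default `TRUE`).
#' @param sample_id Identifier for the simulated sample.
#' @param model Allele model.
#' @return A [sample_input()].
#' @examples
#' cfg <- simulation_config(percent_noise_sd = 0)
#' s <- simulate_sample(parse_diplotype("*1/*17x2"), cfg)
#' s$quant_calls[["rs28371706"]]$percent_var  # exactly 66.67
#' @export
simulate_sample <- function(truth, cfg = simulation_config(),
                            include_total = TRUE, sample_id = "sim",
                            model = default_allele_model()) {
  stopifnot(inherits(truth, "cyp_config"))
  true_total <- truth$copies_a + truth$copies_b
  calls <- lapply(model$panel$snp_id, function(snp) {
    pv <- 100 * expected_variant_fraction(truth, snp, model)
    pv <- pv + stats::rnorm(1, 0, cfg$percent_noise_sd)
    pv <- min(100, max(0, pv))
    snp_quant_call(snp, percent_var = pv, percent_ref = 100 - pv)
  })
  tot <- NULL
  if (include_total) {
    raw <- true_total + stats::rnorm(1, 0, cfg$taqman_raw_sd)
    tot <- max(1L, as.integer(round(raw)))
  }
  sample_input(sample_id, calls, total_copies = tot, model = model)
}

# draw per-founder copy count: 1, 2 (duplication) or 3 (multiplication)
.draw_copies <- function(n, cfg) {
  u <- stats::runif(n)
  ifelse(u < cfg$multiplication_rate, 3L,
         ifelse(u < cfg$multiplication_rate + cfg$duplication_rate, 2L, 1L))
}

#' Simulate a Hardy-Weinberg-structured cohort
#'
#' Founder pairs are drawn independently from the configured allele
#' frequencies (Hardy-Weinberg by construction); each non-deletion
#' founder is then independently duplicated or multiplicated at the
#' configured rates.  Every sample is passed through
#' [simulate_sample()], and the hidden truths are returned alongside the
#' measurements for recovery scoring.
#'
#' @param cfg A [simulation_config()]; its `seed`, when non-`NULL`,
#'   makes the cohort fully reproducible.
#' @param include_total Attach simulated orthogonal totals.
#' @param model Allele model.
#' @return List with `samples` (list of `sample_input`), `truths` (list
#'   of `cyp_config`) and `truth_table` (data frame: sample_id, genotype,
#'   total_copies).
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_samples = 5, seed = 42))
#' cohort$truth_table
#' @export
simulate_cohort <- function(cfg = simulation_config(), include_total = TRUE,
                            model = default_allele_model()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  freqs <- cfg$allele_frequencies
  bad <- setdiff(names(freqs), names(model$alleles))
  if (length(bad))
    stop("frequencies given for alleles absent from the model: ",
         paste(bad, collapse = ", "))
  n <- cfg$n_samples
  a <- sample(names(freqs), n, replace = TRUE, prob = freqs)
  b <- sample(names(freqs), n, replace = TRUE, prob = freqs)
  # a double-deletion individual has no CYP2D6 sequence to assay; the
  # simulated cohort is conditioned on at least one sequence-bearing
  # founder (redrawn, preserving HWE among the retained pairs)
  is_del <- function(x) vapply(x, function(nm)
    model$alleles[[nm]]$is_deletion, logical(1))
  while (any(both <- is_del(a) & is_del(b))) {
    a[both] <- sample(names(freqs), sum(both), replace = TRUE, prob = freqs)
    b[both] <- sample(names(freqs), sum(both), replace = TRUE, prob = freqs)
  }
  ca <- .draw_copies(n, cfg)
  cb <- .draw_copies(n, cfg)
  truths <- vector("list", n)
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    truths[[i]] <- allele_config(a[i], ca[i], b[i], cb[i], model = model)
    samples[[i]] <- simulate_sample(truths[[i]], cfg,
                                    include_total = include_total,
                                    sample_id = sprintf("sim%04d", i),
                                    model = model)
  }
  truth_table <- data.frame(
    sample_id = vapply(samples, function(s) s$sample_id, character(1)),
    genotype = vapply(truths, format, character(1)),
    total_copies = vapply(truths, function(t) t$copies_a + t$copies_b,
                          integer(1)),
    stringsAsFactors = FALSE)
  list(samples = samples, truths = truths, truth_table = truth_table)
}

#' Simulate calibrated allelic ratios by copy-number class
#'
#' Draws allelic ratios directly from per-class Gaussian distributions
#' with the calibration table's means and SDs — the distributional
#' summary of heterozygous 2-, 3- and 4-copy samples — for studying the
#' copy-number/ratio relationship (e.g. its Pearson correlation) without
#' simulating full quantification profiles.
#'
#' @param n_per_class Samples per copy-number class.
#' @param bins A [ratio_bin_table()] supplying means and SDs.
#' @param seed Optional integer seed.
#' @return Data frame with columns `copies` and `ratio`.
#' @examples
#' d <- simulate_calibrated_ratios(100, seed = 7)
#' ratio_stats(d$copies, d$ratio)$pearson_r
#' @export
simulate_calibrated_ratios <- function(n_per_class = 500,
                                       bins = ratio_bin_table(),
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cal <- bins$calibration
  do.call(rbind, lapply(seq_len(nrow(cal)), function(i) {
    data.frame(copies = cal$copies[i],
               ratio = stats::rnorm(n_per_class, cal$mean[i], cal$sd[i]))
  }))
}
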