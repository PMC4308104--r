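# Independent re-statement of the panel haplotype/dosage model, used as
# an oracle against the package implementation.  Kept deliberately free
# of package internals: plain named lists and loops.

oracle_panel <- c("rs16947", "rs35742686", "rs3892097", "rs5030655",
                  "rs1065852", "rs28371706", "rs28371725")

oracle_haplotypes <- list(
  "*1"  = character(0),
  "*2"  = "rs16947",
  "*3"  = "rs35742686",
  "*4"  = c("rs1065852", "rs3892097"),
  "*5"  = character(0),          # whole-gene deletion, no sequence
  "*6"  = "rs5030655",
  "*10" = "rs1065852",
  "*17" = c("rs28371706", "rs16947"),
  "*41" = c("rs16947", "rs28371725"))

oracle_activity <- c("*1" = 1, "*2" = 1, "*3" = 0, "*4" = 0, "*5" = 0,
                     "*6" = 0, "*10" = 0.5, "*17" = 0.5, "*41" = 0.5)

oracle_fraction <- function(a, ca, b, cb, snp) {
  nv <- ca * (snp %in% oracle_haplotypes[[a]]) +
        cb * (snp %in% oracle_haplotypes[[b]])
  nv / (ca + cb)
}

# exhaustive search over founder pairs and copy splits for the given
# candidate totals; same scoring (mean |obs - expected|) and tie-break
# (fewer non-*1 founders, fewer copies, star order) as the documented
# method, independently re-implemented
oracle_best_fit <- function(obs_frac, totals, max_copies = 3) {
  alleles <- names(oracle_haplotypes)
  starnum <- function(x) as.numeric(sub("\\*", "", x))
  best <- NULL
  for (t in totals) {
    for (i in seq_along(alleles)) for (j in i:length(alleles)) {
      a <- alleles[i]; b <- alleles[j]
      if (a == "*5" && b == "*5") next
      splits <- if (a == "*5" || b == "*5") {
        if (t >= 1 && t <= max_copies)
          list(c(if (a == "*5") 0 else t, if (b == "*5") 0 else t))
        else list()
      } else {
        sp <- list()
        for (ca in seq_len(min(max_copies, t - 1))) {
          cb <- t - ca
          if (cb >= 1 && cb <= max_copies && !(a == b && ca > cb))
            sp[[length(sp) + 1]] <- c(ca, cb)
        }
        sp
      }
      for (sp in splits) {
        res <- mean(abs(obs_frac - vapply(names(obs_frac), function(s)
          oracle_fraction(a, sp[1], b, sp[2], s), numeric(1))))
        # lexicographic key: residual, then the documented tie-breaks
        key <- c(res, length(setdiff(unique(c(a, b)), "*1")),
                 sp[1] + sp[2], starnum(a), starnum(b), sp[1])
        if (is.null(best)) {
          best <- list(key = key, a = a, ca = sp[1], b = b, cb = sp[2])
        } else {
          d <- key - best$key
          nz <- which(abs(d) > 1e-12)
          if (length(nz) && d[nz[1]] < 0)
            best <- list(key = key, a = a, ca = sp[1], b = b, cb = sp[2])
        }
      }
    }
  }
  best
}

# noiseless sample_input for a diplotype string, using the package
# forward model (the round-trip property under test)
noiseless_sample <- function(genotype, with_total = TRUE, id = genotype) {
  cfg <- parse_diplotype(genotype)
  calls <- lapply(panel_snps(), function(s)
    snp_quant_call(s, percent_var = 100 * expected_variant_fraction(cfg, s)))
  sample_input(id, calls,
               total_copies = if (with_total) total_copies(cfg) else NULL)
}

# a full 7-SNP sample from a named variant-percent vector (others ref)
panel_sample <- function(id, percents = c(), total_copies = NULL) {
  calls <- lapply(panel_snps(), function(s)
    snp_quant_call(s, percent_var = if (s %in% names(percents))
      percents[[s]] else 0))
  sample_input(id, calls, total_copies = total_copies)
}

fixture_genotype_strings <- function() {
  c(reference_cohort_genotypes()$genotype,
    coriell_genotypes()$genotype,
    cnv_resolution_genotypes()$resolved_genotype)
}
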