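test_that("dosage fit resolves the canonical worked cases", {
  # balanced heterozygote: 50% at the *2 key SNP, 2 copies
  cl <- call_diplotype(panel_sample("a", c(rs16947 = 50), total_copies = 2))
  expect_identical(format(cl$best), "*1/*2")
  expect_true(is.na(cl$duplicated_allele))
  expect_equal(cl$residual, 0)

  # duplicated variant allele: 65.3% at the *17-defining sites, 3 copies
  cl <- call_diplotype(panel_sample("b", c(rs28371706 = 65.3, rs16947 = 65.3),
                                    total_copies = 3))
  expect_identical(format(cl$best), "*1/*17x2")
  expect_identical(cl$duplicated_allele, "*17")
  ph <- phenotype_for_sample(cl)
  expect_identical(ph$phenotype, "EM")
  expect_equal(ph$activity_score, 2)

  # homozygous 100C>T with an orthogonal total of 4: split unresolvable
  cl <- call_diplotype(panel_sample("c", c(rs1065852 = 100), total_copies = 4))
  expect_identical(format(cl$best), "(*10/*10)x4")
  expect_true("homozygous_unquantifiable" %in% cl$flags)
  expect_true("star10_or_36" %in% cl$flags)
  expect_equal(phenotype_for_sample(cl)$activity_score, 2)

  # all-reference with a single gene copy: deletion carrier
  cl <- call_diplotype(panel_sample("d", c(), total_copies = 1))
  expect_identical(format(cl$best), "*1/*5")
  expect_true("deletion_carrier" %in% cl$flags)
  expect_equal(phenotype_for_sample(cl)$activity_score, 1)
})

test_that("duplicated-allele identification handles 1:1, n:1 and balanced cases", {
  cl <- call_diplotype(panel_sample("um", c(rs16947 = 66.7, rs1065852 = 33.3),
                                    total_copies = 3))
  expect_identical(format(cl$best), "*2x2/*10")
  expect_identical(cl$duplicated_allele, "*2")
  # balanced 2:2 duplication: indistinguishable orientation, flagged
  cl <- call_diplotype(panel_sample("bal", c(rs16947 = 50), total_copies = 4))
  expect_identical(format(cl$best), "*1x2/*2x2")
  expect_true(is.na(cl$duplicated_allele))
  expect_true("ambiguous" %in% cl$flags)
})

test_that("candidate totals come from het-SNP ratios when no assay total is given", {
  # 66.7% at the *10 site implies a 2:1 split, total 3, without TaqMan
  cl <- call_diplotype(panel_sample("noassay", c(rs1065852 = 66.7)))
  expect_identical(format(cl$best), "*1/*10x2")
  expect_identical(cl$duplicated_allele, "*10")
  # conflicting orthogonal total wins but is flagged
  cl <- call_diplotype(panel_sample("conflict", c(rs1065852 = 66.7),
                                    total_copies = 2))
  expect_true("total_copies_conflict" %in% cl$flags)
  expect_equal(total_copies(cl$best), 2L)
})

test_that("noiseless simulate-then-call is the identity on the printed genotypes", {
  strings <- setdiff(unique(fixture_genotype_strings()),
                     c("(*1/*1)xN", "(*2/*2)xN"))  # unknown totals: no signal
  for (g in strings) {
    truth <- parse_diplotype(g)
    cl <- call_diplotype(noiseless_sample(g))
    expect_equal(cl$residual, 0, info = g)
    expect_equal(activity_score(cl$best), activity_score(truth), info = g)
    expect_identical(phenotype_for_sample(cl)$phenotype,
                     phenotype_from_score(activity_score(truth)), info = g)
    if (truth$allele_a != truth$allele_b) {
      truth_dup <- if (truth$copies_a > 1L) truth$allele_a
                   else if (truth$copies_b > 1L) truth$allele_b
                   else NA_character_
      expect_identical(cl$duplicated_allele, truth_dup, info = g)
    }
  }
})

test_that("heterozygous duplications are recovered without an orthogonal total", {
  for (g in c("*1/*17x2", "*1/*10x2", "*2/*10x2", "*2/*4x3", "*10x2/*41")) {
    cl <- call_diplotype(noiseless_sample(g, with_total = FALSE))
    expect_identical(format(cl$best), g, info = g)
  }
})

test_that("production search agrees with the independent exhaustive oracle", {
  set.seed(202)
  alleles <- names(oracle_haplotypes)
  cfg <- simulation_config(seed = NULL)
  n_agree <- 0L
  n_cases <- 300L
  for (i in seq_len(n_cases)) {
    a <- sample(alleles, 1)
    b <- sample(setdiff(alleles, if (a == "*5") "*5" else character(0)), 1)
    ca <- if (a == "*5") 0L else sample(1:3, 1)
    cb <- if (b == "*5") 0L else sample(1:3, 1)
    truth <- allele_config(a, ca, b, cb)
    s <- simulate_sample(truth, cfg, sample_id = paste0("case", i))
    cl <- call_diplotype(s)
    obs <- vapply(s$quant_calls, function(q) q$percent_var / 100, numeric(1))
    totals <- if (!is.null(s$total_copies)) s$total_copies else {
      het <- vapply(s$quant_calls, function(q)
        !allelic_ratio(q)$homozygous_signal, logical(1))
      imp <- unlist(lapply(s$quant_calls[het], function(q) {
        classify_ratio(allelic_ratio(q)$ratio)$implied_total_copies
      }))
      sort(unique(c(2L, imp[!is.na(imp)])))
    }
    orc <- oracle_best_fit(obs, totals)
    if (!is.null(cl$best$homozygous_total)) {
      same <- setequal(c(cl$best$allele_a, cl$best$allele_b),
                       c(orc$a, orc$b)) &&
        total_copies(cl$best) == orc$ca + orc$cb
    } else {
      prod_key <- paste(cl$best$allele_a, cl$best$copies_a,
                        cl$best$allele_b, cl$best$copies_b)
      oc <- allele_config(orc$a, orc$ca, orc$b, orc$cb)
      orc_key <- paste(oc$allele_a, oc$copies_a, oc$allele_b, oc$copies_b)
      same <- prod_key == orc_key
    }
    n_agree <- n_agree + same
    if (!same) {
      fail(sprintf("case %d: production %s vs oracle %s/%s (%d+%d)",
                   i, format(cl$best), orc$a, orc$b, orc$ca, orc$cb))
      break
    }
  }
  expect_identical(n_agree, n_cases)
})

test_that("degenerate inputs produce informative errors and no-calls", {
  expect_error(sample_input("x", list()), "empty")
  expect_error(sample_input("x", list(snp_quant_call("rs000", 50))),
               "unknown snp_id")
  expect_error(sample_input("x", list(snp_quant_call("rs16947", 50),
                                      snp_quant_call("rs16947", 40))),
               "duplicate")
  expect_error(sample_input("x", list(snp_quant_call("rs16947", 50)),
                            total_copies = 0), "positive integer")
  # infeasible total: 7 copies cannot be split with max 3 per founder
  cl <- call_diplotype(panel_sample("big", c(rs16947 = 50), total_copies = 7))
  expect_null(cl$best)
  expect_true("no_call" %in% cl$flags)
  expect_error(phenotype_for_sample(cl), "no-call")
})

test_that("pre-resolution candidates mirror what a total-copy assay alone can say", {
  pb <- phenotype_before_quant("*1", "*17", 3)
  expect_true(pb$ambiguous)
  expect_identical(sort(pb$candidate_phenotypes), c("EM", "UM"))
  expect_equal(pb$candidate_scores, c(2, 2.5))
  # homozygous duplications are never ambiguous
  pb <- phenotype_before_quant("*1", "*1", 3)
  expect_false(pb$ambiguous)
  expect_identical(pb$phenotype, "UM")
  expect_equal(pb$activity_score, 3)
  # single-event assumption: a x3 multiplication sits on one allele
  pb <- phenotype_before_quant("*1", "*10", 4)
  expect_equal(pb$candidate_scores, c(2.5, 3.5))
  expect_identical(pb$candidate_phenotypes, "UM")
  expect_false(pb$ambiguous)
  # deletion carrier: the surviving allele carries all copies
  pb <- phenotype_before_quant("*2", "*5", 1)
  expect_identical(pb$phenotype, "EM")
  expect_equal(pb$activity_score, 1)
})
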