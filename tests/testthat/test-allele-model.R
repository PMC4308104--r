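test_that("diplotype strings from the printed tables round-trip through parse/render", {
  for (s in fixture_genotype_strings()) {
    cfg <- parse_diplotype(s)
    rendered <- format(cfg)
    expect_identical(format(parse_diplotype(rendered)), rendered,
                     info = paste("not canonical-stable:", s))
    # canonical form preserves founders and copy counts
    cfg2 <- parse_diplotype(rendered)
    expect_identical(sort(c(cfg$allele_a, cfg$allele_b)),
                     sort(c(cfg2$allele_a, cfg2$allele_b)), info = s)
    expect_identical(sort(c(cfg$copies_a, cfg$copies_b)),
                     sort(c(cfg2$copies_a, cfg2$copies_b)), info = s)
  }
})

test_that("parser handles copy annotations, unresolved homozygotes and errors", {
  cfg <- parse_diplotype("*1/*17x2")
  expect_identical(cfg$allele_a, "*1")
  expect_identical(cfg$copies_b, 2L)
  cfg <- parse_diplotype("*1x2/*4")
  expect_identical(cfg$copies_a, 2L)
  expect_identical(cfg$allele_b, "*4")
  # multiplication sign variant and canonical reordering
  expect_identical(format(parse_diplotype("*4/*1×2")), "*1x2/*4")
  # unresolved homozygous total
  cfg <- parse_diplotype("(*10/*10)x4")
  expect_identical(total_copies(cfg), 4L)
  expect_identical(cfg$copies_a + cfg$copies_b, 4L)
  expect_identical(format(cfg), "(*10/*10)x4")
  # unknown total: parses and renders, but cannot be scored
  cfg <- parse_diplotype("(*1/*1)xN")
  expect_true(is.na(total_copies(cfg)))
  expect_identical(format(cfg), "(*1/*1)xN")
  expect_error(activity_score(cfg), "unknown total")
  # deletion founder keeps zero copies
  cfg <- parse_diplotype("*1/*5")
  expect_identical(cfg$copies_b, 0L)
  expect_identical(format(cfg), "*1/*5")
  expect_error(parse_diplotype("*1/*17xx2"), "position")
  expect_error(parse_diplotype("(*1/*2)x3"), "homozygous")
  expect_error(parse_diplotype("*1/*99"), "unknown star allele")
})

test_that("activity scores reproduce every genotype row of the reference cohort", {
  expected <- c(
    "*3/*4" = 0, "*4/*4" = 0, "*4/*5" = 0, "*4/*6" = 0,
    "*3/*17" = 0.5, "*4/*10" = 0.5, "*4/*17" = 0.5, "*4/*41" = 0.5,
    "*5/*10" = 0.5, "*5/*17" = 0.5,
    "*1/*1" = 2, "*1/*2" = 2, "*1/*3" = 1, "*1/*4" = 1, "*1/*5" = 1,
    "*1/*6" = 1, "*1/*10" = 1.5, "*1/*17" = 1.5, "*1/*41" = 1.5,
    "*1x2/*4" = 2, "*1/*10x2" = 2, "*1/*17x2" = 2,
    "*2/*2" = 2, "*2/*4" = 1, "*2/*4x3" = 1, "*2/*5" = 1,
    "*2/*10" = 1.5, "*2/*17" = 1.5, "*2/*41" = 1.5,
    "*10/*17" = 1, "*10x2/*41" = 1.5, "*17/*17" = 1, "*17/*41" = 1,
    "*41/*41" = 1,
    "*1/*1x2" = 3, "*1x2/*2" = 3, "*1/*2x2" = 3, "*2x2/*10" = 2.5,
    "*2x2/*2" = 3)
  for (g in names(expected)) {
    expect_equal(activity_score(parse_diplotype(g)), expected[[g]],
                 info = g)
  }
  expect_error(activity_score(structure(
    list(allele_a = "*99", copies_a = 1L, allele_b = "*1", copies_b = 1L,
         homozygous_total = NULL), class = "cyp_config")), "unknown")
})

test_that("score-to-phenotype mapping follows the CPIC bins and is monotone", {
  expect_identical(phenotype_from_score(0), "PM")
  expect_identical(phenotype_from_score(0.5), "IM")
  expect_identical(phenotype_from_score(1), "EM")
  expect_identical(phenotype_from_score(2), "EM")    # 2 is still EM
  expect_identical(phenotype_from_score(2.5), "UM")  # strictly above 2 is UM
  expect_error(phenotype_from_score(-0.5), "non-negative")
  expect_error(phenotype_from_score(0.75), "multiple of 0.5")
  ord <- c(PM = 1, IM = 2, EM = 3, UM = 4)
  ranks <- ord[vapply(seq(0, 4, by = 0.5), phenotype_from_score,
                      character(1))]
  expect_true(all(diff(ranks) >= 0))
})

test_that("expected variant fractions follow copy-number dosage and are symmetric", {
  expect_equal(expected_variant_fraction(parse_diplotype("*1/*17x2"),
                                         "rs28371706"), 2 / 3)
  expect_equal(expected_variant_fraction(parse_diplotype("*1/*2"),
                                         "rs16947"), 0.5)
  expect_equal(expected_variant_fraction(parse_diplotype("(*10/*10)x4"),
                                         "rs1065852"), 1)
  # symmetry under founder swap, against the independent oracle
  alleles <- names(oracle_haplotypes)
  set.seed(11)
  for (rep in 1:60) {
    a <- sample(alleles, 1); b <- sample(alleles, 1)
    if (a == "*5" && b == "*5") next
    ca <- if (a == "*5") 0L else sample(1:3, 1)
    cb <- if (b == "*5") 0L else sample(1:3, 1)
    if (ca + cb == 0L) next
    snp <- sample(oracle_panel, 1)
    f1 <- expected_variant_fraction(allele_config(a, ca, b, cb), snp)
    f2 <- expected_variant_fraction(allele_config(b, cb, a, ca), snp)
    expect_equal(f1, f2)
    expect_equal(f1, oracle_fraction(a, ca, b, cb, snp))
  }
  expect_error(
    expected_variant_fraction(parse_diplotype("*1/*17x2"), "rs000"),
    "unknown panel SNP")
})

test_that("the allele model validates its definition file", {
  m <- default_allele_model()
  expect_length(panel_snps(m), 7L)
  expect_true(all(m$panel$ref_base != m$panel$var_base))
  expect_identical(m$alleles[["*1"]]$variant_snps, character(0))
  expect_true(m$alleles[["*5"]]$is_deletion)
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("panel:",
               "  - {snp_id: rs1, label: 1C>T, ref_base: C, var_base: T}",
               "alleles:",
               "  - {name: '*9', variant_snps: [rs_absent], activity: 1}"),
             bad)
  expect_error(load_allele_model(bad), "unknown snp_id")
})
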