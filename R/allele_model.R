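.model_cache <- new.env(parent = emptyenv())

#' Load a star-allele model from a YAML definition file
#'
#' The model bundles the SNP panel (the seven CYP2D6 allele-defining
#' positions), the star-allele haplotype definitions restricted to that
#' panel, the CPIC per-copy activity values, and the activity-score to
#' metabolizer-phenotype bins.  The default definition shipped with the
#' package covers *1, *2, *3, *4, *5 (deletion), *6, *10 (= *10-or-*36 on
#' this panel), *17 and *41.
#'
#' @param path Path to a YAML file with `panel`, `alleles` and
#'   `phenotype_bins` sections; defaults to the packaged definition.
#' @return An object of class `cyp_allele_model`: a list with elements
#'   `panel` (data frame: `snp_id`, `label`, `ref_base`, `var_base`),
#'   `alleles` (named list of allele definitions with `variant_snps`,
#'   `activity`, `is_deletion`) and `phenotype_bins`.
#' @examples
#' m <- default_allele_model()
#' m$panel$snp_id
#' m$alleles[["*17"]]$activity
#' @export
load_allele_model <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$panel) || is.null(raw$alleles))
    stop("allele model file must define 'panel' and 'alleles'")
  panel <- do.call(rbind, lapply(raw$panel, function(s)
    data.frame(snp_id = s$snp_id, label = s$label,
               ref_base = s$ref_base, var_base = s$var_base,
               stringsAsFactors = FALSE)))
  if (anyDuplicated(panel$snp_id))
    stop("duplicate snp_id in panel definition")
  if (any(panel$ref_base == panel$var_base))
    stop("panel SNP with identical ref and var base")
  alleles <- list()
  for (a in raw$alleles) {
    bad <- setdiff(unlist(a$variant_snps), panel$snp_id)
    if (length(bad))
      stop("allele ", a$name, " references unknown snp_id: ",
           paste(bad, collapse = ", "))
    alleles[[a$name]] <- list(
      name = a$name,
      variant_snps = as.character(unlist(a$variant_snps)),
      activity = as.numeric(a$activity),
      is_deletion = isTRUE(a$is_deletion))
  }
  bins <- lapply(raw$phenotype_bins, function(b) as.numeric(unlist(b)))
  structure(list(panel = panel, alleles = alleles, phenotype_bins = bins),
            class = "cyp_allele_model")
}

#' @rdname load_allele_model
#' @export
default_allele_model <- function() {
  if (is.null(.model_cache$default)) {
    path <- system.file("extdata", "allele_definitions.yaml",
                        package = "cypquant", mustWork = TRUE)
    .model_cache$default <- load_allele_model(path)
  }
  .model_cache$default
}

#' Panel SNP identifiers of a star-allele model
#' @param model A `cyp_allele_model`; defaults to the packaged one.
#' @return Character vector of rs identifiers in panel order.
#' @export
panel_snps <- function(model = default_allele_model()) model$panel$snp_id

star_number <- function(name) as.numeric(sub("^\\*", "", name))

.check_allele <- function(name, model) {
  if (!name %in% names(model$alleles))
    stop("unknown star allele '", name, "'; model defines: ",
         paste(names(model$alleles), collapse = " "))
  invisible(name)
}

#' Construct an allele configuration (diplotype with per-allele copy number)
#'
#' An allele configuration is an ordered pair of founder star alleles with
#' per-allele copy counts, e.g. *1 with 1 copy plus *17 with 2 copies for
#' the diplotype written `*1/*17x2`.  The deletion allele *5 always has 0
#' sequence-contributing copies.  Founders are stored in canonical order
#' (lower star number first; for homozygous pairs, fewer copies first) so
#' that the string rendering is unique.
#'
#' @param allele_a,allele_b Star-allele names (e.g. `"*1"`, `"*17"`).
#' @param copies_a,copies_b Non-negative integer copy counts.
#' @param homozygous_total For homozygous configurations whose split the
#'   assay cannot resolve, the total copy number rendered as `(A/A)xN`;
#'   `NA` for an unknown total (`(A/A)xN` with literal N); `NULL` (default)
#'   for ordinary resolved configurations.
#' @param model Allele model used to validate names.
#' @return Object of class `cyp_config`.
#' @examples
#' allele_config("*17", 2, "*1", 1)       # canonicalised to *1/*17x2
#' allele_config("*1", 1, "*5", 0)        # deletion carrier, total 1 copy
#' @export
allele_config <- function(allele_a, copies_a, allele_b, copies_b,
                          homozygous_total = NULL,
                          model = default_allele_model()) {
  .check_allele(allele_a, model); .check_allele(allele_b, model)
  if (model$alleles[[allele_a]]$is_deletion) copies_a <- 0L
  if (model$alleles[[allele_b]]$is_deletion) copies_b <- 0L
  copies_a <- as.integer(copies_a); copies_b <- as.integer(copies_b)
  if (any(c(copies_a, copies_b) < 0L))
    stop("copy counts must be non-negative")
  if (copies_a + copies_b < 1L && is.null(homozygous_total))
    stop("configuration must contribute at least one gene copy")
  # canonical order: lower star number first; within homozygous, fewer
  # copies first so *1x2/*1 renders as *1/*1x2
  swap <- star_number(allele_a) > star_number(allele_b) ||
    (allele_a == allele_b && copies_a > copies_b)
  if (swap) {
    tmp <- allele_a; allele_a <- allele_b; allele_b <- tmp
    tmp <- copies_a; copies_a <- copies_b; copies_b <- tmp
  }
  structure(list(allele_a = allele_a, copies_a = copies_a,
                 allele_b = allele_b, copies_b = copies_b,
                 homozygous_total = homozygous_total),
            class = "cyp_config")
}

#' Total sequence-contributing gene copies of a configuration
#' @param config A `cyp_config`.
#' @return Integer total copy number (deletion founders contribute 0).
#' @export
total_copies <- function(config) {
  if (!is.null(config$homozygous_total)) {
    if (is.na(config$homozygous_total)) return(NA_integer_)
    return(as.integer(config$homozygous_total))
  }
  config$copies_a + config$copies_b
}

.render_side <- function(name, copies) {
  if (copies > 1L) paste0(name, "x", copies) else name
}

#' @export
format.cyp_config <- function(x, ...) {
  if (!is.null(x$homozygous_total)) {
    n <- if (is.na(x$homozygous_total)) "N" else as.character(x$homozygous_total)
    return(sprintf("(%s/%s)x%s", x$allele_a, x$allele_b, n))
  }
  paste0(.render_side(x$allele_a, x$copies_a), "/",
         .render_side(x$allele_b, x$copies_b))
}

#' @export
print.cyp_config <- function(x, ...) {
  cat("<diplotype> ", format(x), "  (", x$copies_a, "+", x$copies_b,
      " copies)\n", sep = "")
  invisible(x)
}

#' @export
as.character.cyp_config <- function(x, ...) format(x)

#' Parse a star-nomenclature diplotype string
#'
#' Accepts the notation `allele[xN]/allele[xN]` (e.g. `*1/*17x2`,
#' `*1x2/*4`) and the unresolved-homozygote form `(A/A)xN` where N is the
#' total copy number the quantification assay cannot split (e.g.
#' `(*10/*10)x4`), or a literal `N` when even the total is unknown.  Both
#' `x` and the multiplication sign are accepted as the copy marker;
#' rendering always uses lowercase `x`.
#'
#' @param text A diplotype string.
#' @param model Allele model used to validate names.
#' @return A `cyp_config`.
#' @examples
#' parse_diplotype("*1/*17x2")
#' parse_diplotype("(*10/*10)x4")
#' format(parse_diplotype("*4/*1x2"))   # canonicalised: "*1x2/*4"
#' @export
parse_diplotype <- function(text, model = default_allele_model()) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("×", "x", trimws(text))
  m <- regexec("^\\((\\*\\d+)/(\\*\\d+)\\)x(\\d+|N)$", s)[[1]]
  if (m[1] != -1L) {
    g <- regmatches(s, list(m))[[1]]
    if (g[2] != g[3])
      stop("unresolved-total form requires a homozygous pair, got '",
           text, "'")
    tot <- if (g[4] == "N") NA_integer_ else as.integer(g[4])
    if (!is.na(tot) && tot < 2L)
      stop("homozygous total must be at least 2 in '", text, "'")
    ca <- if (is.na(tot)) 1L else tot %/% 2L
    cb <- if (is.na(tot)) 1L else tot - ca
    return(allele_config(g[2], ca, g[3], cb, homozygous_total = tot,
                         model = model))
  }
  m <- regexec("^(\\*\\d+)(?:x(\\d+))?/(\\*\\d+)(?:x(\\d+))?$", s)[[1]]
  if (m[1] == -1L) {
    # locate first offending character for the error message
    ok <- regexpr("^\\(?(\\*\\d+)(x\\d+)?(/|\\))?(\\*\\d+)?(x\\d+)?", s)
    pos <- max(1L, attr(ok, "match.length") + 1L)
    stop("malformed diplotype string '", text, "' (near position ", pos, ")")
  }
  g <- regmatches(s, list(m))[[1]]
  ca <- if (g[3] == "") 1L else as.integer(g[3])
  cb <- if (g[5] == "") 1L else as.integer(g[5])
  allele_config(g[2], ca, g[4], cb, model = model)
}

#' CPIC activity score of an allele configuration
#'
#' The activity score sums the per-copy activity value of every gene copy:
#' fully functional alleles (*1, *2) contribute 1 per copy, reduced-function
#' alleles (*10, *17, *41) contribute 0.5, and non-functional alleles
#' (*3, *4, *5, *6) contribute 0.  A duplicated functional allele therefore
#' raises the score, e.g. *2x2/*17 scores 2.5.
#'
#' @param config A `cyp_config`.
#' @param model Allele model providing activity values.
#' @return Numeric activity score (non-negative, in steps of 0.5).
#' @examples
#' activity_score(parse_diplotype("*1/*17x2"))  # 2
#' activity_score(parse_diplotype("*2x2/*17"))  # 2.5
#' activity_score(parse_diplotype("*4/*4"))     # 0
#' @export
activity_score <- function(config, model = default_allele_model()) {
  stopifnot(inherits(config, "cyp_config"))
  .check_allele(config$allele_a, model)
  .check_allele(config$allele_b, model)
  if (!is.null(config$homozygous_total) && is.na(config$homozygous_total))
    stop("cannot score a configuration with unknown total copy number")
  config$copies_a * model$alleles[[config$allele_a]]$activity +
    config$copies_b * model$alleles[[config$allele_b]]$activity
}

#' Map a CPIC activity score to a metabolizer phenotype
#'
#' Bins follow the activity-score system: 0 is a poor metabolizer (PM),
#' 0.5 an intermediate metabolizer (IM), scores from 1 up to and including
#' 2 an extensive metabolizer (EM), and anything strictly above 2 an
#' ultrarapid metabolizer (UM).
#'
#' @param score Non-negative activity score in steps of 0.5.
#' @param model Allele model providing the phenotype bins.
#' @return One of `"PM"`, `"IM"`, `"EM"`, `"UM"`.
#' @examples
#' phenotype_from_score(0)    # "PM"
#' phenotype_from_score(2)    # "EM"
#' phenotype_from_score(2.5)  # "UM"
#' @export
phenotype_from_score <- function(score, model = default_allele_model()) {
  if (length(score) != 1L || !is.finite(score) || score < 0)
    stop("activity score must be a single non-negative number")
  if (abs(score * 2 - round(score * 2)) > 1e-9)
    stop("activity score must be a multiple of 0.5, got ", score)
  bins <- model$phenotype_bins
  for (ph in names(bins)) {
    if (score >= bins[[ph]][1] - 1e-9 && score <= bins[[ph]][2] + 1e-9)
      return(ph)
  }
  # unreachable with the default allele set (no score falls between the
  # IM and EM bins in half steps), but a custom activity table could
  warning("activity score ", score, " falls outside all phenotype bins")
  NA_character_
}

#' Expected variant-allele fraction at a panel SNP under a configuration
#'
#' The forward dosage model of allele quantification: with every gene copy
#' amplifying equally, the variant percentage at a position equals the
#' number of copies carrying the variant divided by the total number of
#' sequence-contributing copies.  A duplicated variant allele in a
#' heterozygote therefore shifts the fraction from 1/2 to 2/3 (about 67%),
#' and a triplicated one to 3/4.
#'
#' @param config A `cyp_config`.
#' @param snp_id A panel SNP identifier.
#' @param model Allele model.
#' @return Fraction in \[0, 1\].
#' @examples
#' expected_variant_fraction(parse_diplotype("*1/*17x2"), "rs28371706")  # 2/3
#' expected_variant_fraction(parse_diplotype("*1/*2"), "rs16947")        # 1/2
#' @export
expected_variant_fraction <- function(config, snp_id,
                                      model = default_allele_model()) {
  stopifnot(inherits(config, "cyp_config"))
  if (!snp_id %in% model$panel$snp_id)
    stop("unknown panel SNP '", snp_id, "'")
  tot <- config$copies_a + config$copies_b
  if (tot < 1L)
    stop("configuration has no sequence-contributing copies; ",
         "variant fraction undefined")
  nv <- config$copies_a *
    (snp_id %in% model$alleles[[config$allele_a]]$variant_snps) +
    config$copies_b *
    (snp_id %in% model$alleles[[config$allele_b]]$variant_snps)
  nv / tot
}
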