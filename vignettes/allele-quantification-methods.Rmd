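---
title: "Allele quantification-based CYP2D6 diplotype and copy-number calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele quantification-based CYP2D6 diplotype and copy-number calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypquant)
```

## The problem

CYP2D6 metabolizes a large fraction of commonly prescribed drugs, and its
gene is both highly polymorphic and copy-number variable: whole-gene
deletions (*5), duplications and multiplications all occur at appreciable
frequency.  Routine copy-number assays (e.g. TaqMan real-time PCR) report
*how many* gene copies a sample carries but not *which* allele carries the
extra copies.  That distinction decides the phenotype: a *1/*17 genotype
with three total copies is an extensive metabolizer if the
reduced-function *17 allele is duplicated (activity score 2) but an
ultrarapid metabolizer if the fully functional *1 allele is (score 2.5).

Allele quantification resolves this.  When a SNP assay reports the
*percentage* of each nucleotide at an allele-defining position rather
than just a genotype call, every gene copy contributes equally to the
signal, so a duplicated allele's nucleotide rises above 50% in proportion
to its copy count.  `cypquant` implements the computational half of this
idea: a forward dosage model, an allelic-ratio copy-number classifier, an
exhaustive diplotype search, CPIC activity-score phenotyping, cohort
statistics and a calibrated simulator.

## The forward dosage model

The panel covers the seven defining positions of *2 (2850C>T, rs16947),
*3 (2549delA), *4 (1846G>A), *6 (1707delT), *10 (100C>T), *17 (1023C>T)
and *41 (2988G>A).  Each star allele is modelled as the subset of panel
positions it carries in variant state.  Within the panel, haplotype
contents follow standard CYP2D6 nomenclature rather than just each
allele's single key SNP — *4 carries 100T alongside its defining 1846A,
*17 carries 2850T alongside 1023T, and *41 carries 2850T alongside
2988A.  This matters for the fit: without it, a *1/*41 sample's 50%
2850T signal would be misattributed to *2.

For a configuration with founders $(h_a, h_b)$ at copy numbers
$(c_a, c_b)$, the expected variant fraction at position $s$ is

$$f_s = \frac{c_a\,[s \in h_a] + c_b\,[s \in h_b]}{c_a + c_b},$$

the proportion of sequence-contributing copies carrying the variant.
The *5 deletion contributes zero copies, so a *1/*5 carrier reads 100%
reference everywhere — indistinguishable from *1/*1 by quantification
alone, which is why an orthogonal total is needed for such samples.

Two panel limitations are inherited from the assay, flagged rather than
solved: *36 shares 100C>T with *10 and cannot be discriminated
(`star10_or_36`), and samples with no heterozygous panel SNP
(homozygotes, *5 carriers, homozygous multiplications) read "about 100%"
at every site regardless of copy number
(`homozygous_unquantifiable`).

## The allelic-ratio classifier

At a heterozygous position the major/minor ratio of the two percentages
is ≈1 for a 1:1 copy split, ≈2 for 2:1 and ≈3 for 3:1.  The default
calibration is the published per-class distribution of this ratio:

| total copies | mean | SD | min | max |
|---|---|---|---|---|
| 2 | 0.97 | 0.07 | 0.85 | 1.06 |
| 3 | 1.83 | 0.16 | 1.60 | 2.20 |
| 4 | 2.76 | 0.39 | 2.42 | 3.20 |

The calibration publishes ranges, not decision rules, so boundaries had
to be chosen: `ratio_bin_table()` uses the midpoints of the gaps between
adjacent class ranges — 1.33 between 1:1 and 2:1, 2.31 between 2:1 and
3:1 — which are symmetric in the ratio scale and configurable.  Ratios
above 3.7 (about one within-class SD above the largest calibrated
maximum) are flagged `out_of_range` rather than assigned to the 3:1
class; ratios within 0.1 of a boundary carry a `near_boundary` warning.
The sub-1 calibrated mean for balanced heterozygotes (0.97) shows the
source statistics used an oriented quotient; `allelic_ratio()` keeps an
`oriented` mode for reproducing such statistics, but classification
always folds ratios to major/minor (≥ 1) so it cannot depend on which
allele happens to be called "first".

Percent pairs must sum to 100 within ±2 percentage points (typical
report rounding) and are renormalised; a minor allele below 5% is
treated as a homozygous signal rather than an enormous ratio.  The 5%
cut-off is far below the smallest informative minor fraction the model
produces (1/6 ≈ 16.7%, a 5:1 split beyond the supported range) and far
above realistic baseline noise, so its exact value is uncritical.

## The diplotype search

`call_diplotype()` scores every candidate configuration — each founder
pair from the allele table (including *1 and *5) combined with every
split of each candidate total, at most 3 copies per founder — by the
mean absolute deviation between observed and expected variant fractions
over the panel, and returns the minimiser.  Candidate totals are the
orthogonal-assay value when supplied (it wins on conflict, with a
`total_copies_conflict` diagnostic), otherwise the ratio-implied totals
of the heterozygous positions plus the CNV-free default of 2.  The
search space is small (a few hundred configurations), so exhaustive
enumeration is exact and fast; a property test keeps it equivalent to an
independently written brute-force enumeration.

Ties and near-ties are handled explicitly:

* equal-residual fits are broken by parsimony — fewer non-*1 founders,
  then fewer total copies, then star-number order;
* alternatives within 0.03 of the best residual are reported, and the
  call is `ambiguous` when any of them would change the phenotype.  The
  0.03 margin is roughly one per-SNP noise SD (2 percentage points)
  spread over the seven-site mean, i.e. alternatives the data cannot
  firmly exclude;
* balanced duplications (e.g. *1x2/*2x2) have no single duplicated
  founder; they are only reachable when an orthogonal total demands
  them and are flagged `ambiguous`, since quantification alone cannot
  distinguish them from the 1:1 diplotype;
* the shared 100C>T of *4 and *10 is resolved by the joint fit — a *4
  haplotype must also explain the 1846A fraction, and excess 100T
  implies a separate *10 — with no ad-hoc subtraction rules.

`phenotype_before_quant()` reproduces what a copy-number assay alone
supports: all activity scores consistent with the unphased founder pair
and the total, assuming a *single* allele carries the whole
duplication/multiplication event (splits $1 + (T-1)$ and $(T-1) + 1$).
The single-event assumption mirrors how such tables are reported in
practice — a four-copy *1/*10 heterozygote is listed as score 2.5 or
3.5, not the three-way split including 2+2 — and matches the biology of
tandem duplication arising on one chromosome.

## Activity scores and phenotypes

Per-copy activity values are 1 for *1 and *2, 0.5 for *10, *17 and *41,
and 0 for *3, *4, *5 and *6; a configuration's score is the
copy-weighted sum.  Scores map to metabolizer phenotypes as 0 → PM,
0.5 → IM, 1–2 → EM, and strictly greater than 2 → UM; a score of
exactly 2 is EM (the UM cut-off is *above* 2, which is what makes the
*1/*17x2 vs *1x2/*17 distinction clinically meaningful).  Both tables
live in a YAML configuration shipped with the package
(`inst/extdata/allele_definitions.yaml`), so other guideline versions
can be loaded without code changes; scores that fall between the IM and
EM bins cannot arise from the default table and trigger a warning if a
custom table produces them.

## Cohort statistics

`summarize_cohort()` computes genotype counts, phenotype frequencies
(percentages rounded half-away-from-zero to one decimal, two for
genotype frequencies), homozygote and *5-carrier counts, and per-SNP
Hardy-Weinberg chi-squared tests (1 df) from founder haplotype counts.
*5 founders carry no sequence and are counted as reference at every
site, the same convention the assay's genotype calls would produce.
HWE is stratified by `population_label` when labels are available;
pooled testing across structured cohorts can show a mild Wahlund
departure (visible at the *17 site in the packaged reference cohort,
whose source tested each ancestry group separately).

`ratio_stats()` delegates the standard machinery: one-way ANOVA
(`stats::aov`) across copy-number classes, Tukey HSD post-hoc pairs
(`stats::TukeyHSD`, α = 0.05) and the Pearson correlation between copy
number and ratio.  With the default calibration and equal class sizes
the analytic correlation is 0.948, reproducing the published 0.95.

## The simulator

`simulate_cohort()` draws founder pairs independently from configured
allele frequencies (Hardy-Weinberg by construction, conditioned on at
least one sequence-bearing founder, since a *5/*5 individual presents
no signal), duplicates each founder independently, and passes each
truth through the forward model with truncated Gaussian noise on the
percent scale.  Defaults are matched to the packaged 218-sample
reference cohort: its observed founder frequencies
(`default_allele_frequencies()`), a per-founder duplication rate of
0.03 and ×3 multiplication rate of 0.002 (the cohort's 14 duplicated
and 1 triplicated founders out of 436).

The noise default of 2.0 percentage points is a delta-method
calibration: for ratio $r = p/(100-p)$, $\mathrm{d}r/\mathrm{d}p =
100/(100-p)^2$ ≈ 0.04, 0.09 and 0.16 at the 50%, 67% and 75% class
centres, so a 2-point percent SD induces ratio SDs of roughly 0.08,
0.18 and 0.32 — bracketing the calibrated 0.07/0.16/0.39.  Gaussian
noise truncated to [0, 100] is the minimal symmetric choice; no
published error model exists to justify anything richer, and the real
per-assay noise is likely heteroscedastic across the seven primer sets,
which the simulator does not attempt to capture.  A simulated
orthogonal total is drawn with SD 0.15 on the raw copy scale and
rounded, mirroring `copies_from_ddct()`'s low-confidence margin of
0.35.

What passing simulation-based tests shows, therefore, is that the
*method* is sound under its own assumptions — equal amplification of
all copies, symmetric percent noise, a two-founder model.  It does not
show robustness to assay-specific biases (allele-specific amplification
efficiency, pyrogram baseline drift) or to hybrid gene structures,
none of which the panel can express.

## Problem sizes and numerical choices

The test suite and acceptance analyses use sizes chosen to make the
statistical checks stable: 1000 random samples for search-equivalence,
300 for duplication recovery, 500 ratios per copy class (analytic
Pearson r 0.948 ± ~0.005 at that size), 4000–6000 samples for HWE
convergence checks.  The whole suite runs in well under a minute.
Residual comparisons use exact arithmetic on rational expected
fractions, so noiseless inputs genuinely reach residual 0; tie-breaks
only ever decide between configurations with *identical* residuals.

## Known limitations

* No *36/*10 discrimination and no detection of *5 or homozygous
  multiplications from quantification alone (flagged, not solved).
* The allele universe is the seven-SNP panel: no full haplotype
  catalogue, no hybrid tandem arrangements, no more than two founder
  haplotypes per sample.
* Copy counts above 3 per founder are outside the calibrated range and
  the default search (`max_copies` is configurable, but the ratio
  classifier has no class above 3:1).
* Pre-resolution candidate enumeration assumes a single CNV event per
  sample; samples with independent duplications on both alleles would
  be mis-enumerated before quantification (and flagged `ambiguous`
  after it).
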