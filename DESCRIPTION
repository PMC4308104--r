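Package: cypquant
Title: CYP2D6 Diplotype and Copy-Number Calling from Allele Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Calls CYP2D6 star-allele diplotypes with allele-specific copy
    number from per-SNP variant-allele percentages, such as those produced by
    pyrosequencing allele quantification over the *2, *3, *4, *6, *10, *17
    and *41 defining positions.  Classifies major/minor allelic ratios into
    copy-number splits against a published calibration, identifies which
    allele carries a duplication or multiplication, assigns CPIC activity
    scores and metabolizer phenotypes (PM/IM/EM/UM), converts TaqMan delta-
    delta-Ct values to total gene copy number, summarises cohorts
    (genotype/phenotype frequencies, Hardy-Weinberg tests, allelic-ratio
    statistics by copy class), and simulates noisy allele-quantification
    cohorts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
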