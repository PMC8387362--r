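Package: hrdtwohit
Title: Two-Hit and Homologous Recombination Deficiency Analysis of
    Tumor/Normal Cohorts
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decides whether unsolved familial breast-cancer tumors are
    explained by homologous-recombination-deficiency (HRD) genes.
    Implements germline candidate-variant selection (quality, population
    frequency, gene category and in-silico predictor consensus routing),
    somatic variant filtering tuned for FFPE artifacts, somatic second-hit
    detection via a chi-squared allelic-imbalance test with
    loss-of-heterozygosity typing from allele-specific copy number,
    per-tumor HRD calling by consensus of mutational Signature-3
    attribution and genomic scar scores (HRD-LOH + LST + TAI, threshold
    42), and final candidate-gene nomination under the two-hit
    tumor-suppressor model. Ships a synthetic tumor/normal cohort
    generator (beta-binomial read counts, purity- and copy-number-aware
    tumor allele fractions, strand-biased FFPE artifacts, allele-specific
    segment profiles with controllable scar scores, and trinucleotide
    mutation catalogs with controllable signature exposures) so the whole
    pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
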