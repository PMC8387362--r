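# hrdtwohit

Tools for deciding whether unsolved familial breast-cancer cases are
explained by homologous-recombination-deficiency (HRD) genes, from paired
tumor/normal exome data.

Clinical gene panels leave many multiple-case breast-cancer families
unexplained. Under the two-hit tumor-suppressor model, a causal germline
variant in an HRD gene should leave three independent footprints in the
patient's tumor: a somatic second hit inactivating the wild-type allele
(usually loss of heterozygosity, LOH), the COSMIC Signature-3 mutational
spectrum of failed homologous recombination, and genome-wide "scars"
(copy-number abnormalities). `hrdtwohit` implements the full decision
pipeline that integrates these signals, plus a synthetic tumor/normal
cohort generator so every stage is testable without patient data.

## The analysis

1. **Germline candidate selection.** Variants pass quality rules (depth ≥ 5,
   ALT reads ≥ 2, allelic fraction in [0.35, 0.5], mapping quality ≥ 30)
   and a strict population-frequency cutoff (max AF < 0.01). Candidates are
   routed by ClinVar/ACMG class, gene category (20 clinical BCSG, 147 CSG,
   103 DNA-repair, 594 candidate-HR genes) and an in-silico consensus
   (deleterious by ≥ 4 of 8 predictors for non-BCSG missense).
2. **Somatic filtering (FFPE-aware).** Calls are removed for strand bias
   (exact binomial test of the ALT forward/reverse split, p < 0.01 with
   ≥ 6 ALT reads), germline origin, presence in a panel of normals, or
   tumor depth < 10.
3. **Second-hit detection.** For each candidate, Pearson's chi-squared test
   (1 df, no continuity correction) on the 2×2 table of germline vs tumor
   REF/ALT read counts detects allelic imbalance (p ≤ 0.05); combined with
   the allele-specific copy state at the locus (minor copy number 0 and
   the variant allele retained) this yields the LOH type: DEL-LOH (total
   CN 1), CN-LOH (2) or DUP-LOH (≥ 3). Somatic second point mutations and
   purely somatic biallelic hits are also reported.
4. **HRD calling.** Signature 3 presence is decided by a likelihood-ratio
   test of the NNLS refit of the tumor's 96-channel trinucleotide catalog
   with versus without the Signature 3 column, with a
   simulation-calibrated threshold (5% false-positive rate). Genomic scars
   are scored as HRD-LOH (LOH segments > 15 Mb, sub-chromosomal) + LST
   (breakpoints between ≥ 10 Mb segments after 3 Mb smoothing) + TAI
   (telomeric allelic imbalance not crossing the centromere); a sum ≥ 42
   is scar-positive. A tumor is HRD by **consensus** of both calls.
5. **Nomination.** A gene is `hrd-candidate-pathogenic` only when the same
   patient carries the germline candidate, the second hit, and a
   consensus-HRD tumor (CHEK2-like genes are exempt: their biallelic loss
   does not produce Signature 3).

## Worked example

```r
library(hrdtwohit)

# a 20-patient synthetic cohort, 10% of patients given a causal scenario
coh <- simulate_cohort(simulation_config(n_patients = 20, seed = 7))
cal <- calibrate_sig3(n_snvs = 100, n_null = 500, seed = 1)
res <- run_pipeline(coh, calibration = cal)
res
```

```
Two-hit HRD cohort analysis
  patients: 20
  germline candidates on master list: 28
  somatic variants kept/removed: 1988/683
  Sig3-positive: 2; scar-positive: 2; consensus HRD: 2
  nominated HRD candidate gene(s):
    BRCA2 in P010 (CN-LOH, p = 3.56e-12)
    RAD51D in P019 (CN-LOH, p = 1.73e-13)
```

The two spiked patients (ground truth: `coh$truth$patients`) are exactly
the two consensus-HRD tumors, and their causal genes are recovered with a
copy-neutral LOH second hit; the chi-squared p-values are the
allelic-imbalance evidence at the two loci. The single-locus test is also
available directly, e.g. for a germline 80/64 vs tumor 134/177 REF/ALT
table:

```r
allelic_imbalance_test(80, 64, 134, 177)
#> [1] 0.01319671
```

## Scope

Segments, annotations and read counts are *inputs*: alignment, variant
calling, annotation and copy-number segmentation (BWA/GATK/VEP/FACETS and
friends) are out of scope. The signature reference shipped with the
package is a synthetic six-signature matrix with COSMIC-like structure,
not the published COSMIC matrix; see the methods vignette
(`vignettes/methods.Rmd`) for this and the other modelling choices.
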