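---
title: "Two-hit HRD analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-hit HRD analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdtwohit)
```

`hrdtwohit` asks a single clinical question of a tumor/normal exome
cohort: does any gene behave like a homologous-recombination-deficiency
(HRD) breast-cancer susceptibility gene — that is, does a patient carry a
rare germline variant whose wild-type allele was somatically lost in a
tumor that shows the genome-wide footprints of failed homologous
recombination? This vignette explains the statistical machinery behind
each stage, the tunable parameters and why their defaults are what they
are, what the synthetic cohorts do and do not emulate, and the design
decisions that were genuinely open.

## The two-hit decision structure

A nomination requires the conjunction of three independent pieces of
evidence in the same patient and gene:

* a **germline candidate** surviving quality, frequency and
  interpretation filters;
* a **somatic second hit** — loss of heterozygosity (LOH) retaining the
  variant allele, or a somatic truncating mutation in the same gene;
* a **consensus-HRD tumor** — positive by both the Signature-3 caller and
  the genomic scar score.

The conjunction is deliberately strict: each leg alone has substantial
false-positive pressure (rare benign variants, passenger LOH in unstable
genomes, noisy exome-scale signature fits), while their intersection under
the null of "no causal HRD gene" is rare. The `require_consensus = FALSE`
flag relaxes the third leg to the Signature-3 call alone.

## Germline candidate selection

Quality rules are applied in a fixed order and every removal is tagged
with the first failing rule: (i) depth < 5 reads, (ii) fewer than 2 ALT
reads, (iii) allelic fraction outside [0.35, 0.5], (iv) mapping quality
< 30. The allelic-fraction window deserves comment: its source statement
is ambiguous about endpoint inclusion, and we read it as *keep AF in
[0.35, 0.5] inclusive*, the minimal reading; both endpoints are
configurable (`germline_af_range`). Note the window is asymmetric around
0.5 — a genuinely heterozygous site at high depth falls above 0.5 about
half the time, so roughly half of true heterozygotes are discarded. This
is a property of the published rule, not of our implementation; its
consequence for power is handled in the generator (below).

The population-frequency cutoff is strict (`max AF < 0.01`), and a
*missing* frequency is treated as 0: novel variants are precisely the
search target. Routing then follows interpretation and gene category:
ClinVar benign/likely-benign (ACMG when ClinVar is silent) is dropped;
truncating and splice variants go straight to the master list; missense
variants in clinical breast-cancer susceptibility genes (BCSG) are kept
regardless of predictor scores, because expert review is assumed
downstream; other missense variants need agreement of at least 4 of the 8
standard deleteriousness predictors, with absent calls counting against
(conservative). Gene categories are resolved with precedence BCSG > CSG >
DNA-repair > C-HRG. The 594-gene candidate-HR list is not public; the
package ships a deterministic placeholder table with the documented
category sizes and real exemplar symbols, which is a fixture format, not
a claim about the true list.

## Somatic filtering for FFPE material

Formalin fixation deaminates cytosines and yields low-allele-fraction
C>T/G>A calls whose supporting reads sit almost entirely on one strand.
The filter bank applies, in order: (i) a two-sided exact binomial test of
the ALT forward/reverse split against 0.5, applied once at least 6 ALT
reads are present, removing at p < 0.01 (the named filter had no published
statistic; this is the standard choice, and both constants are exposed);
(ii) removal of calls present in the matched germline; (iii) removal of
panel-of-normals sites; (iv) a tumor depth floor of 10 reads. On synthetic
cohorts with the default artifact model, more than 95% of injected
artifacts are removed while more than 95% of true somatic SNVs at VAF
≥ 0.2 and depth ≥ 30 survive.

## The allelic-imbalance test

Second hits by LOH shift the variant allele fraction between germline and
tumor. We test the 2×2 table of paired REF/ALT counts with Pearson's
chi-squared statistic (1 df), computed in determinant form
$\chi^2 = N(ad-bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$, **without**
continuity correction. The choice is empirical: of the printed worked
examples, eight reproduce exactly under the uncorrected test while only a
minority match a Yates-corrected value, so the uncorrected test is the
default and `continuity = TRUE` (the `--continuity` CLI flag) restores the
corrected one. Significance is p ≤ 0.05 inclusive; per the published
procedure, no multiple-testing correction is applied across candidates and
raw p-values are reported. Tables with a zero margin leave the test
undefined; they are returned as `NA` and treated as no evidence
downstream.

An LOH call additionally requires the variant to be the *retained* allele
(tumor VAF above germline VAF) and minor copy number 0 at the locus; the
total copy number then gives the type: 1 = DEL-LOH, 2 = CN-LOH, ≥ 3 =
DUP-LOH. Segment lookup uses 1-based inclusive coordinates and demands
exactly one covering segment.

## Signature 3 from exome-scale catalogs

Somatic SNVs are binned into the standard 96 trinucleotide channels
(purine references reverse-complemented). Exposures are fitted by
non-negative least squares (Lawson–Hanson, via `pracma::lsqnonneg`)
against a fixed signature matrix, on catalog frequencies; the fit is
returned both as weights and normalized fractions.

The presence call is a likelihood-ratio test: the multinomial
log-likelihood of the catalog under the full refit minus the refit without
the Signature 3 column. Because the null distribution of this score
depends on the signature set and the mutation count, the threshold is
*calibrated by simulation*: null catalogs are drawn from Dirichlet-random
mixtures of the non-Signature-3 columns at the working mutation count, and
the threshold is the 95th percentile of their scores (target 5%
false-positive rate; `sig3_fpr`). Catalogs below `sig3_min_snvs = 5`
mutations are a no-call, which propagates to a consensus no-call rather
than a negative. This caller is a fully specified, reproducible stand-in
for the proprietary-complex exome HRD classifiers used in practice; it
preserves their decision structure (a binary Signature-3 presence call
tuned for exome counts) without claiming to replicate any particular tool.

The shipped reference (`synthetic_signatures()`, also at
`inst/extdata/synthetic_signature_matrix.tsv`) is a **synthetic**
six-column matrix with the qualitative shapes of the COSMIC v2 exome set
most used for HRD refitting: clock-like NpCpG C>T ("Signature 1"), APOBEC
TpC ("2" and "13"), a flat HRD-like column ("Signature 3"), broad T>C
("5") and broad C>A ("8"). The flat Signature-3 column is the hardest of
these to detect against mixtures of the others, so power numbers are, if
anything, conservative relative to more peaked references. Simulation and
refitting use the same matrix, so all signature analyses are internally
consistent; users with a licensed COSMIC matrix can drop it in via
`read_signature_matrix()`. Catalog frequencies are not renormalized for
genome trinucleotide composition — generator and fitter share the
convention, so no bias enters at this scale; a normalization hook exists
at the matrix level.

## Genomic scar scores

The scar sum is HRD-LOH + LST + TAI, with the canonical component
definitions from the scar literature, since the source states only the
sum and its threshold:

* **HRD-LOH** — number of LOH regions (maximal runs of segments with
  minor copy number 0) longer than 15 Mb but shorter than the whole
  chromosome;
* **LST** — after smoothing away segments shorter than 3 Mb, the number
  of breakpoints whose flanking segments are each ≥ 10 Mb and differ in
  allele-specific copy number (counted per chromosome; no arm splitting,
  as no arm rule is stated);
* **TAI** — number of allelic-imbalance regions (2·minor ≠ total) that
  reach a telomere without crossing the centromere.

All three length constants are configuration values. A sum ≥ 42 (raw, not
ploidy-adjusted — the adjustment status is unstated in the source, and raw
is the simpler reading) is scar-positive. The scores are invariant under
splitting a segment into adjacent pieces with identical states, and the
smoothing step makes LST insensitive to sub-3-Mb interruptions.

## The synthetic cohort generator

The patient-level data behind this analysis are not publicly available,
so the generator reproduces the *statistical structure* the pipeline
assumes, at the study's stated scale:

* **Read counts** are beta-binomial with a single overdispersion
  parameter ρ (variance $np(1-p)(1+(n-1)\rho)$, ρ = 0 binomial). Default
  depths are 141× in both tissues, matching the reported mean exome
  coverage; ρ = 0.01 adds mild FFPE/exome noise. Tumor VAF at a germline
  site follows the purity/copy-number mixture
  $(p\,v + (1-p)\,2g)\,/\,(p\,t + (1-p)\,2)$ for purity $p$, variant and
  total copies $v, t$, germline fraction $g$.
* **Tumor purity** defaults to 0.6, a typical value for archival breast
  FFPE; the source states no purity distribution, so this is an
  order-of-magnitude choice, not a calibration.
* **FFPE artifacts** are injected at 1/Mb over a 30 Mb target: C>T (or
  G>A) calls with 12–18 supporting reads, at least 90% of them on one
  strand by construction, 30% at recurrent panel-of-normals sites.
* **Segment profiles** are built deterministically to hit requested
  (HRD-LOH, LST, TAI) targets *exactly*, using insulated building blocks
  (interior 16 Mb LOH segments between sub-10-Mb spacers; alternating
  balanced ≥ 12 Mb states for LST; 8 Mb telomeric imbalance caps for TAI)
  whose scores are verified against the scoring functions at run time.
  Spiked tumors get targets (20, 15, 8) — sum 43, just over threshold, so
  recovery is not an artifact of extreme profiles; background tumors get
  small random targets (sums ≤ 8).
* **Catalogs** are multinomial draws from the signature matrix; spiked
  tumors receive Signature-3 exposure 0.5 of 100 SNVs, background tumors
  exposure 0. Trinucleotide contexts come from the signature-implied
  channel rather than a reference FASTA, which removes the FASTA
  dependency while preserving catalog statistics exactly.
* **The causal scenario** plants a rare heterozygous missense BCSG
  variant, a 16 Mb copy-neutral-LOH segment covering the locus (adding
  exactly +1 to HRD-LOH and nothing else, by insulation), and the
  Signature-3-positive catalog. The spiked germline read counts are drawn
  from the beta-binomial *truncated to the detectable allelic-fraction
  window* [0.36, 0.495]: the scenario models a variant that was, by
  definition, ascertained by germline screening. Without this
  conditioning the asymmetric [0.35, 0.5] quality window would discard
  about half of all true heterozygotes at depth 141 and cap end-to-end
  sensitivity near 50% — a property of the published filter, not of the
  biology being emulated.
* **Determinism.** Patient *i*'s seed is
  `(master · 1000003 + i) mod (2³¹ − 1)` (`derive_seed()`), so identical
  configs give byte-identical cohorts and any patient can be regenerated
  alone. Ground truth (spiked genes, artifact keys, true exposures and
  scar targets) is returned separately and never written into the emitted
  tables.

What the generator does **not** emulate: subclonal copy-number states and
mixtures beyond a single purity value, indel/structural-variant artifacts,
mappability- or GC-driven depth waves, sequence context at real genomic
coordinates, and germline variants in linkage. Passing tests therefore
demonstrate that the decision logic is correct under the stated
statistical model, not that the thresholds are optimal for any particular
real cohort.

## End-to-end performance, and the problem sizes used

With defaults (20 patients, 10% spiked, depth 141, purity 0.6, 100 SNVs,
Signature-3 exposure 0.5), the acceptance script measures, over 100
simulated cohorts: spike-in sensitivity ≈ 0.91–0.96, mean false
nominations ≈ 0.05–0.12 per cohort, Signature-3 false-positive rate 0.049
at the calibrated threshold and power ≈ 0.83–0.87 at 50% exposure with 50
SNVs, and exposure recovery within ±0.005 at 50,000 mutations. The
exhaustive 2×2 sweep (both row margins ≤ 50, about 1.75 million tables)
agrees with the closed-form Pearson statistic to ~3×10⁻¹⁴ relative error.
These sizes (100 cohorts, 500–1000 replicate catalogs, 50-margin sweep)
were chosen as the smallest that make the binomial error of each rate
estimate comfortably smaller than its acceptance margin.

## Numerical and edge-case choices

* Zero-margin 2×2 tables: `NA` with a warning, treated as no evidence.
* Homozygous-deletion loci (total copy number 0) never type as LOH
  retention; they surface through the per-gene copy-number event calls.
* Ties: equal germline and tumor VAFs are `balanced` (no retention);
  the scar threshold, the AI p-cutoff and the AF window are inclusive.
* Multiple candidate variants in one gene and patient are tested
  independently and reported most-damaging-first — a convention, since
  the source does not state a resolution rule.
* NNLS exposures are floored at 0 and renormalized; empty catalogs return
  zero exposures flagged `zero`, and sub-5-SNV catalogs are Signature-3
  no-calls.

## Known limitations

The Signature-3 caller's absolute threshold is specific to the signature
matrix and mutation count it was calibrated with; calibrations are cheap
(~1 s) and should be recomputed when either changes. Scar scores assume
segments tile each chromosome contiguously from telomere to telomere, as
segmentation tools emit; sparse panels would need padding. The scar
threshold of 42 is taken as given — with 22 autosomes and desk-scale
profiles it is reachable, but nothing here validates it against outcome
data. Methylation silencing, complex rearrangement signatures and de novo
signature discovery are out of scope.
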