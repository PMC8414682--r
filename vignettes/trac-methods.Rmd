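---
title: "Models and methods behind tracseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tracseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracseq)
```

# Scope

`tracseq` analyses bulk RNA-seq of whole blood for coronary artery disease
(CAD) biomarkers. This vignette is the package's own account of the
statistical model behind each stage, the tunable parameters with their
defaults and units, what the synthetic cohort generator does and does not
emulate, the numerical conventions that were genuinely open choices, and
the known limitations. It states no empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

# Normalization model

Counts are converted to RPKM,

$$\mathrm{RPKM}_{ts} = \frac{R_{ts}}{(K_t/1000)\,(M_s/10^6)},$$

with $R$ the read count, $K_t$ the transcript length in bases and $M_s$
the sample's total mapped (informative) reads. $M_s$ defaults to the
column sum of the matrix but is overridden by the sample table's
`total_mapped_reads` when present, because aligned informative reads
generally differ from the post-filtering matrix sum. With column-sum
totals the transformation conserves reads exactly:
$\sum_t \mathrm{RPKM}_{ts} K_t/1000 = 10^6$ for every sample, which the
suite checks to $10^{-6}$ relative error. No further normalization
(size factors, quantile) is applied anywhere: the selection cascade is
defined on raw RPKM.

Group summaries use geometric means. Zeros make a bare geometric mean
degenerate, so means are computed on $x + \delta$ with a configurable
offset $\delta$ (default $10^{-6}$ RPKM, well below the 0.01 RPKM
expression floor so it never dominates a retained transcript); the
reported geometric mean subtracts $\delta$ back and floors at zero, while
folds are formed on the strictly positive offset scale. Signed folds
follow the convention that a decrease prints as a negative reciprocal
(fold 0.5 prints as −2.0), and the sign refers to the first (disease)
group relative to the second.

Percentile ranks use the "fraction strictly below" convention,
$100\,(\#\{x_j < x_i\})/(n-1)$, with ties sharing a rank, so the minimum
of a distinct list ranks 0 and the maximum 100. No convention is canonical
here; this one is frozen and tested.

# The selection cascade

Four nested stages, with every threshold in `analysisConfig()`:

1. *Expression floor* — keep transcripts with RPKM strictly above
   `min_rpkm` (0.01) in at least `min_fraction` (70 %) of the samples of
   at least one group.
2. *Differential test* — per-transcript Welch (unequal-variance) t-test of
   MID+ versus LOW on $\log_2(\mathrm{RPKM}+\delta)$, flagged at
   uncorrected `deg_p` (0.001). For exactly two groups the one-way ANOVA
   F statistic equals $t^2$ (checked against `oneway.test` to $10^{-9}$),
   so this stage is the two-group ANOVA. Testing on the log scale is the
   default because the volcano geometry assumes it; a raw-scale flag
   exists because the choice is not forced by the model. Welch was frozen
   rather than the pooled test because the summary-statistic checks on
   printed demographics reproduce under Welch. Benjamini–Hochberg q-values
   are reported alongside but never filtered on: the cascade is defined on
   uncorrected p.
3. *Percentile floor* — among flagged transcripts, require a geometric
   group mean above the `percentile_cut` (20th) percentile of expression
   in *both* groups.
4. *Parent list* — require a fold decrease greater than `parent_fc` (1.4)
   in the disease group.

Stage memberships are returned as nested flags, and monotone
non-increasing stage counts are a tested invariant. Covariate biomarker
lists (sex, age dichotomized at 60, BMI, smoking, aspirin, read depth,
...) reuse exactly this machinery at `covariate_fc` (3.0) and
`covariate_p` (0.05); age, sex and BMI lists are computed within LOW-CAD
samples only, to avoid confounding with CAD itself. A read-depth covariate
is expressed the same way (e.g. `total_mapped_reads` below 5 million) with
no separate code path.

`summaryTTest()` implements the Welch test from printed group summaries
(mean, SEM, n), since base R's `t.test` requires raw data. Note that a
minority of printed demographic rows in published cohort tables do not
reproduce from their summaries under any standard two-sample test; the
suite asserts only rows that do (age, BMI).

# Scoring and diagnostic evaluation

The composite score expresses each panel transcript as a ratio to its
cohort-mean expression and averages the ratios, so a highly expressed
transcript cannot dominate and the cohort-average sample scores 1. The
score is invariant to rescaling any transcript by a positive constant
(tested), which also makes it robust to the RPKM unit itself. Orientation
is explicit: for Treg-related panels the disease direction is a *lower*
score, and `cStatistic()`/`confusionAtThreshold()` orient scores before
evaluation.

The C-statistic is the empirical Mann–Whitney AUC with half-credit ties,
equal to brute-force pair counting (exact oracle test up to n = 200).
Fitted binormal ROC models would give slightly different values; the
empirical estimator is the standard choice and the difference is a
documented source of discrepancy when comparing against binormal-fitted
published values. Classification thresholds for confusion matrices default
to the cohort median score, a choice the evaluation exposes as a
parameter because published confusion matrices rarely print their
threshold; `confusionFromPredictiveValues()` inverts printed PPV/NPV over
known prediction counts instead, and round-trips with `confusionMetrics()`
to within the rounding granularity 1/n.

PLS-DA uses NIPALS PLS1: predictors standardized to unit variance, the
class coded ±1 and centred, components extracted by iterative deflation,
class assigned by the sign of the fitted response. Cross-validation folds
are stratified by class and driven by an explicit seed; the fold draw
restores the caller's RNG state so surrounding simulations are
undisturbed. Zero-variance predictors are dropped within each training
fold. Duplicating predictor columns leaves predictions unchanged (tested),
a property of the NIPALS weight normalization. Under a permutation null,
fold-wise CV accuracy is expected to sit at — in practice slightly below —
chance; the tested property is the absence of optimism.

The clinical risk model is purely additive integer points over factor
levels with ordinal cutpoints. No published point values are bundled: the
installed `toy_risk_points.yaml` is a synthetic table for tests and
examples, and real use requires supplying one.

# The synthetic cohort generator

The generator is a cell-mixture model, not a read simulator. Six cell
types (granulocyte, monocyte, B, NK, conventional T, Treg) have
per-transcript expression rates; a sample's expected transcript abundance
is the fraction-weighted sum of rates. Design choices:

- **Compartments.** Lymphocytes contribute `lymphFraction` (default 0.52)
  of whole-blood informative RNA — a deliberate choice reflecting that
  lymphocyte count is the dominant correlate of blood RNA yield even
  though granulocytes dominate cell counts; it is configurable, not a
  claim. Within lymphocytes, B and NK take fixed shares (15 %, 12 %) and
  conventional T absorbs whatever the Treg fraction leaves, so the
  lymphocyte total is identical across groups and the Treg/Tconv balance
  is the only planted compositional difference.
- **Treg depletion.** Treg fractions of lymphocytes default to 4.7 %
  (LOW), 3.2 % (MID), 2.8 % (HIGH), so Treg-exclusive markers carry an
  analytic fold of 0.047/0.032 = 1.46875 in the default two-group design.
- **Planted TRACs.** `nTrac` (40) non-marker transcripts are multiplied
  by 1/`tracFold` (1.7) in MID and HIGH samples. They are drawn from
  transcripts that are reliably quantified at the configured depth
  (expected count ≥ 25) and below the 92nd abundance percentile:
  biomarker-grade mid-to-high expressors, the population the percentile
  stage of the cascade is designed to retain. Planting effects in
  transcripts averaging a handful of reads would test counting noise, not
  the cascade.
- **Noise model.** Per-sample cell fractions are Dirichlet around the
  group means with precision `fractionDispersion` (200), putting
  realistic ~10 % CV on major compartments and ~45 % CV on the small Treg
  fraction. Counts are negative binomial (size `countDispersion` = 10,
  i.e. ~32 % biological CV at high expression) over expected counts
  formed from abundance × length mass shares scaled to a log-normal
  library size (`librarySizeMean` 2×10⁵ reads at desk scale, 5×10⁶ at
  full scale; CV 30 %). Transcript lengths are uniform on 500–10,000 bp
  so the length correction is genuinely exercised.
- **Anchors.** One hemoglobin-like transcript (600 bp, equal rate in all
  cell types so the anchor holds in every group) is calibrated to RPKM
  65,000 (≈ 16 in log₂); baseline rates are log-normal spanning ~23 log₂
  units.
- **Seeding.** One integer seed drives split streams (profiles,
  fractions, library sizes, counts, covariates), so regenerating one
  stage leaves the others untouched and everything is bit-reproducible.
- **Clinical covariates** are drawn per group from a plausible
  catheterization-cohort model (MID+ older, more often male, leaner, more
  medicated); they provide realistic inputs for the covariate-list and
  risk-model machinery, and carry no planted transcriptomic effect.

Desk scale is 2,000 transcripts and 2 × 48 samples; every contract the
package makes is testable at that size, and the full ~158,000-transcript
scale changes cost, not behaviour. What the generator does **not**
emulate: sequencing error, rRNA depletion artefacts, batch and RNA
stabilizer effects, between-cohort demographic shifts, alignment-reference
differences, and transcript-level redundancy of real annotations.
Consequently, passing recovery tests shows the *pipeline arithmetic* is
correct under its own assumptions — not that real cohorts will replicate.

The truth table records the analytic expected fold per transcript,
LOW over MID+ (sample-size-weighted when HIGH is present). The observed
count-ratio of a marker differs from the abundance fold by a small
denominator effect (depleting the TRAC mass slightly inflates every other
transcript's share in MID+, about 1–2 % at defaults); the Monte-Carlo
consistency checks therefore compare the pooled marker RPKM index across
1,000 samples per group at a 5 % tolerance that absorbs this plus shared
fraction noise.

The per-sample count total has expectation equal to the drawn library
size, but its sampling error is dominated by the heavy upper tail of the
abundance distribution (a single dominant transcript carries a material
share of the variance), so the conservation test uses the exact negative
binomial standard deviation $\sqrt{\sum_t(\mu_t + \mu_t^2/k)}$ per sample
rather than a homogeneous $CV/\sqrt{n}$ approximation, allowing the usual
small exceedance rate at 3σ.

# Enrichment conventions

Over-representation of two symbol sets in a universe of size $N$ uses the
upper-tail hypergeometric probability (the one-sided Fisher exact test;
two-sided by flag), with fold $kN/(|A||B|)$. $N$ is an explicit required
parameter (config default 20,000 symbols): published enrichment values are
only reproducible conditional on a universe, which is rarely printed.
Before overlap, transcript tables collapse to symbols; for correlation
panels the highest-expressed transcript represents its symbol. The
"close match" rule between cohort symbol lists is genuinely undefined in
the field; the frozen rules are (a) identity after stripping one trailing
alphanumeric character and (b) edit distance 1 with identical alphabetic
stem, and every reported pair carries its rule id so alternates can be
compared.

# Pipeline

`runPipeline()` executes simulate → normalize → deg → score → enrich from
one declarative config (R list or YAML), writes every table as TSV, logs
to stderr with stage prefixes, and emits a manifest with the config
snapshot, seed, md5 digests, stage timings and package version. Identical
config and seed give identical digests (tested). Pre-flight validation
rejects unknown stages and stage lists whose inputs cannot exist. The
functions themselves are the primary interface; a thin wrapper script at
`inst/scripts/run_pipeline.R` serves shell use.

# Known limitations

- The cascade tests transcripts independently (no variance moderation or
  shrinkage); that is faithful to the method it implements, not state of
  the art for small cohorts.
- Uncorrected p thresholds are part of the method's definition; BH
  q-values are reported for context only.
- The empirical AUC differs from binormal-fitted values on the same data.
- The generator's Dirichlet/negative-binomial noise cannot represent
  correlated technical batches; null-control tests calibrate type-I error
  only under the model's own noise.
- Symbol-level matching discards transcript-variant information by
  design, mirroring cross-cohort matching practice at the symbol level.
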