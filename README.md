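# tracseq

Whole-blood RNA-seq biomarker discovery for coronary artery disease (CAD),
built as an R/Bioconductor-style package. It implements the analysis chain
used to find and evaluate *transcripts associated with CAD* (TRACs) in bulk
RNA-seq of whole blood, together with a synthetic cell-mixture cohort
generator that lets every stage be tested end to end with known ground
truth.

## The problem and the method

Patients undergoing coronary angiography can be stratified by percent
luminal stenosis into LOW (≤ 20 %), MID (21–69 %) and HIGH (≥ 70 %) CAD.
Whole-blood RNA carries a signal of this status: regulatory T cells
(Tregs), whose abundance is reduced in CAD, contribute a small but
measurable share of blood mRNA, so Treg-associated transcripts fall in
proportion to Treg depletion. A drop of a Treg compartment from fraction
f₁ to f₂ of lymphocytes predicts a transcript-level fold of f₁/f₂ for
Treg-exclusive markers (e.g. 4.7 %/3.2 % ≈ 1.47), equivalently 1/(1−r) for
a fractional reduction r.

The package covers, as separate composable modules:

- **Normalization** — RPKM = R /(K·M): raw read counts corrected for
  transcript length (kb) and per-sample mapped reads (millions);
  log₂ transforms; geometric group means with signed fold changes
  (a decrease prints as a negative reciprocal). With column-sum totals,
  Σ RPKM·kb = 10⁶ in every sample.
- **TRAC selection cascade** — expression floor (RPKM > 0.01 in ≥ 70 % of
  one group's samples), per-transcript Welch t-test on log₂ RPKM
  (uncorrected p < 0.001; for two groups the one-way ANOVA F equals t²),
  volcano selection (p and fold combined), then an expression-percentile
  floor (> 20th percentile in both groups) and a > 1.4-fold-decrease
  filter yielding the parent biomarker list. The same machinery produces
  per-covariate biomarker lists (fold > 3, p < 0.05) and Welch tests from
  printed summary statistics (mean ± SEM).
- **Scoring and diagnostics** — a composite score averaging each panel
  transcript as a ratio to its cohort mean; empirical ROC C-statistic
  (Mann–Whitney with tie correction); confusion-matrix metrics and their
  reconstruction from published PPV/NPV; NIPALS PLS-DA with stratified
  N-fold internal validation; an additive clinical risk-point model;
  score-on-covariate regression.
- **Enrichment** — cell-type marker composite indices, hypergeometric
  gene-set over-representation (fold = kN/|A||B|), exact/close symbol
  matching across cohorts, marker correlation panels, and the Treg
  abundance↔fold arithmetic.
- **Synthetic cohorts** — six blood cell types with exclusive markers, a
  hemoglobin-like transcript anchored near RPKM 65,000 (≈16 in log₂),
  ~23 log₂ units of dynamic range, Dirichlet per-sample cell fractions,
  negative-binomial counts at configurable depth, a planted Treg depletion
  (4.7 % → 3.2 % of lymphocytes) and a planted TRAC set (1.7-fold down in
  MID+), with an analytic truth table for parameter-recovery tests.

## Worked example

```r
library(tracseq)

spec <- MixtureSpec()                  # 48 LOW / 48 MID, Treg 4.7% vs 3.2%
prof <- buildProfiles(2000, spec)
sim  <- simulateCohort(prof, spec)
r    <- rpkm(cohortExprs(sim))

cas <- degCascade(r)
colSums(cas[, c("pass_filter", "pass_p", "pass_percentile", "pass_parent")])
#>     pass_filter          pass_p pass_percentile     pass_parent
#>            1488              40              40              40

panel <- GeneSet("P7", members(tracGeneSet(prof))[1:7])
cs <- compositeScore(r, panel)         # lower score = disease direction
cStatistic(cs, isMidPlus(sampleInfo(r)$group))
#> [1] 0.9960938

tregFoldFromFractions(4.7, 3.2)        # expected Treg marker fold
#> [1] 1.46875
```

Of 2,000 simulated transcripts, 1,488 pass the expression floor; exactly
the 40 planted TRACs reach p < 0.001, all are expressed above the 20th
percentile in both groups, and all show a > 1.4-fold decrease, so the
parent list recovers the planted set in full. The 7-transcript composite
separates the groups almost perfectly on this synthetic cohort
(C-statistic 0.996) because the planted effect is uncontaminated by the
biological and technical variation of real patients.

One call runs everything (simulate → normalize → deg → score → enrich) and
writes every table plus a reproducibility manifest:

```r
runPipeline(list(seed = 1, out_dir = "demo_run"))
```

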