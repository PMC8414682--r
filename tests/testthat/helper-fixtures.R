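## Shared fixtures: cohorts are simulated once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

## the default study-scale cohort: 2,000 transcripts, 48 LOW / 48 MID,
## Treg 4.7% vs 3.2% of lymphocytes, 40 TRACs planted at fold 1.7
defaultCohort <- function() {
  if (is.null(.fixtures$default)) {
    spec <- MixtureSpec()
    prof <- buildProfiles(2000, spec)
    sim <- simulateCohort(prof, spec)
    .fixtures$default <- list(spec = spec, prof = prof, sim = sim,
                              rpkm = rpkm(cohortExprs(sim)))
  }
  .fixtures$default
}

## matched null cohort: identical fractions in every group, nothing planted
nullCohort <- function() {
  if (is.null(.fixtures$null)) {
    spec <- MixtureSpec(tregFracMid = 0.047, tregFracHigh = 0.047,
                        nTrac = 0L, seed = 3L)
    prof <- buildProfiles(2000, spec)
    sim <- simulateCohort(prof, spec)
    .fixtures$null <- list(spec = spec, prof = prof, sim = sim,
                           rpkm = rpkm(cohortExprs(sim)))
  }
  .fixtures$null
}

## tiny handmade expression object
makeBes <- function(values, symbols = NULL, lengths = 1000,
                    unit = "RPKM", groups = NULL, totals = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("t%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  if (is.null(symbols)) symbols <- toupper(rownames(values))
  tr <- data.frame(transcript_id = rownames(values), gene_symbol = symbols,
                   length_bp = rep_len(lengths, nrow(values)))
  sm <- NULL
  if (!is.null(groups) || !is.null(totals)) {
    sm <- data.frame(sample_id = colnames(values))
    if (!is.null(groups)) sm$group <- groups
    if (!is.null(totals)) sm$total_mapped_reads <- totals
  }
  BloodExprSet(values, transcripts = tr, samples = sm, unit = unit)
}

## brute-force AUC oracle: explicit pair counting with half-credit ties
pairCountAUC <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

## brute-force hypergeometric upper-tail oracle by enumeration of draws
enumHyperP <- function(N, sizeA, sizeB, k) {
  draws <- utils::combn(N, sizeA)
  hits <- apply(draws, 2L, function(d) sum(d <= sizeB) >= k)
  mean(hits)
}
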