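## The TRAC selection cascade: expression filter, per-transcript two-group
## Welch test, volcano selection, percentile + fold parent-list reduction,
## covariate biomarker lists, and Welch tests from printed summary
## statistics.

#' Low-expression filter
#'
#' Keeps a transcript iff, in at least one group, strictly more than
#' `minRpkm` RPKM is observed in at least `minFraction` of that group's
#' samples (defaults: RPKM > 0.01 in 70\% of samples of at least one
#' group).
#'
#' @param object a [BloodExprSet-class] with `unit == "RPKM"`.
#' @param groups factor/character of group membership per sample; default
#'   LOW vs MID+ from the sample annotation.
#' @param minRpkm expression floor (RPKM).
#' @param minFraction required fraction of a group's samples above the floor.
#' @return character vector of retained transcript ids.
#' @export
expressionFilter <- function(object, groups = NULL, minRpkm = 0.01,
                             minFraction = 0.70) {
  stopifnot(is(object, "BloodExprSet"))
  if (exprUnit(object) != "RPKM") stop("expressionFilter() expects unit 'RPKM'")
  x <- exprValues(object)
  if (nrow(x) == 0L || ncol(x) == 0L) stop("empty expression matrix")
  if (is.null(groups)) {
    labels <- sampleInfo(object)$group
    if (is.null(labels)) stop("no 'group' sample annotation")
    groups <- ifelse(isMidPlus(labels), "MID+", labels)
  }
  keep <- rep(FALSE, nrow(x))
  for (g in unique(groups)) {
    sel <- groups == g
    frac <- rowMeans(x[, sel, drop = FALSE] > minRpkm)
    keep <- keep | (frac >= minFraction)
  }
  rownames(x)[keep]
}

## row-wise Welch t on a numeric matrix split into two column sets
.rowWelch <- function(x, selA, selB) {
  nA <- sum(selA); nB <- sum(selB)
  xA <- x[, selA, drop = FALSE]; xB <- x[, selB, drop = FALSE]
  mA <- rowMeans(xA); mB <- rowMeans(xB)
  vA <- rowSums((xA - mA)^2) / (nA - 1)
  vB <- rowSums((xB - mB)^2) / (nB - 1)
  seA2 <- vA / nA; seB2 <- vB / nB
  se2 <- seA2 + seB2
  t <- ifelse(se2 == 0, 0, (mA - mB) / sqrt(se2))
  df <- ifelse(se2 == 0, nA + nB - 2,
               se2^2 / (seA2^2 / (nA - 1) + seB2^2 / (nB - 1)))
  p <- ifelse(se2 == 0, 1, 2 * stats::pt(-abs(t), df))
  list(t = t, df = df, p = p, mean_A = mA, mean_B = mB)
}

#' Per-transcript two-group differential expression test
#'
#' Welch (unequal-variance) two-sample t-test per transcript, by default on
#' `log2(RPKM + offset)`; for exactly two groups the one-way ANOVA F equals
#' the squared t, so this is the two-group ANOVA. The fold is the ratio of
#' geometric group means (group A over group B), signed so that a decrease
#' in group A prints as a negative reciprocal. BH-adjusted q-values are
#' reported alongside but nothing filters on them.
#'
#' @param object a [BloodExprSet-class] with `unit == "RPKM"`.
#' @param groupA,groupB sample id vectors or group labels (see
#'   [groupSummary()]); group A is the comparison (disease) group.
#' @param onLog test on log2 scale (default) or raw RPKM.
#' @param offset log/geometric-mean offset.
#' @return data.frame: `transcript_id`, `t`, `df`, `p`, `q`, `fold`
#'   (signed A over B), `mean_log2_A`, `mean_log2_B`, `pct_rank_A`,
#'   `pct_rank_B`.
#' @export
degTest <- function(object, groupA, groupB, onLog = TRUE, offset = 1e-6) {
  stopifnot(is(object, "BloodExprSet"))
  if (exprUnit(object) != "RPKM") stop("degTest() expects unit 'RPKM'")
  idsA <- .resolveSamples(object, groupA)
  idsB <- .resolveSamples(object, groupB)
  if (length(idsA) < 2L || length(idsB) < 2L)
    stop("each group needs at least 2 samples")
  x <- exprValues(object)
  xt <- if (onLog) log2(x + offset) else x
  w <- .rowWelch(xt, colnames(x) %in% idsA, colnames(x) %in% idsB)
  gs <- groupSummary(object, idsA, idsB, offset = offset)
  data.frame(
    transcript_id = rownames(x),
    t = w$t, df = w$df, p = w$p,
    q = stats::p.adjust(w$p, method = "BH"),
    fold = gs$signed_fold,
    mean_log2_A = if (onLog) w$mean_A else gs$log2_gm_A,
    mean_log2_B = if (onLog) w$mean_B else gs$log2_gm_B,
    pct_rank_A = gs$pct_rank_A, pct_rank_B = gs$pct_rank_B,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Volcano selection: combined p-value and fold-change filter
#'
#' @param deg data.frame from [degTest()].
#' @param pThresh uncorrected p threshold (default 0.001).
#' @param fcThresh absolute fold threshold (default 1.5).
#' @return data.frame of selected transcripts with a `direction` column
#'   (`"down"`/`"up"`, relative to group A).
#' @export
volcanoSelect <- function(deg, pThresh = 0.001, fcThresh = 1.5) {
  if (pThresh <= 0 || fcThresh <= 0) stop("thresholds must be > 0")
  sel <- deg$p < pThresh & abs(deg$fold) > fcThresh
  out <- deg[sel, c("transcript_id", "p", "fold"), drop = FALSE]
  out$direction <- ifelse(out$fold < 0, "down", "up")
  rownames(out) <- NULL
  out
}

#' Percentile + fold parent-list reduction
#'
#' Stage 1 keeps transcripts whose geometric group mean exceeds the
#' `percentileCut` percentile of expression within each group (both
#' groups); stage 2 keeps those with a fold decrease greater than
#' `parentFc` in group A (the disease group).
#'
#' @param deg data.frame from [degTest()] (which carries the within-group
#'   percentile ranks of the tested universe).
#' @param percentileCut percentile floor in \[0, 100) (default 20).
#' @param parentFc required fold decrease (default 1.4).
#' @return list with `percentile_ids` (stage-1 survivors) and `parent_ids`
#'   (stage-2 survivors, the parent list).
#' @export
parentList <- function(deg, percentileCut = 20, parentFc = 1.4) {
  if (percentileCut < 0 || percentileCut >= 100)
    stop("percentileCut must lie in [0, 100)")
  if (parentFc <= 0) stop("parentFc must be > 0")
  stage1 <- deg$pct_rank_A > percentileCut & deg$pct_rank_B > percentileCut
  stage2 <- stage1 & deg$fold < -parentFc
  list(percentile_ids = deg$transcript_id[stage1],
       parent_ids = deg$transcript_id[stage2])
}

#' Default analysis thresholds
#'
#' All printed cutoffs of the TRAC selection cascade in one list:
#' expression floor RPKM > 0.01 in 70\% of a group, uncorrected p < 0.001,
#' volcano fold > 1.5, percentile floor 20, parent fold decrease > 1.4,
#' covariate lists at fold > 3 and p < 0.05, log/geometric offset 1e-6.
#'
#' @return named list of thresholds.
#' @export
analysisConfig <- function() {
  list(min_rpkm = 0.01, min_fraction = 0.70, deg_p = 0.001, deg_fc = 1.5,
       percentile_cut = 20, parent_fc = 1.4, covariate_fc = 3.0,
       covariate_p = 0.05, log_offset = 1e-6)
}

#' The full TRAC selection cascade
#'
#' Expression filter, then the MID+ vs LOW Welch test on the filtered
#' universe (p < `deg_p` flags the differential set), then the
#' expression-percentile floor in both groups, then the fold-decrease
#' filter yielding the parent list. Stage memberships are returned as
#' nested pass flags (each stage implies the previous).
#'
#' @param object a [BloodExprSet-class] with `unit == "RPKM"` and a `group`
#'   sample annotation.
#' @param config threshold list, see [analysisConfig()].
#' @return data.frame over all transcripts with test columns from
#'   [degTest()] (NA for transcripts dropped by the expression filter) and
#'   logical flags `pass_filter`, `pass_p`, `pass_percentile`,
#'   `pass_parent`.
#' @examples
#' spec <- MixtureSpec(nLow = 6L, nMid = 6L, nTrac = 5L, markersPerType = 2L,
#'                     librarySizeMean = 2e4)
#' sim <- simulateCohort(buildProfiles(300, spec), spec)
#' cascade <- degCascade(rpkm(cohortExprs(sim)))
#' colSums(cascade[, c("pass_filter", "pass_p", "pass_percentile",
#'                     "pass_parent")])
#' @export
degCascade <- function(object, config = analysisConfig()) {
  stopifnot(is(object, "BloodExprSet"))
  keep <- expressionFilter(object, minRpkm = config$min_rpkm,
                           minFraction = config$min_fraction)
  sub <- object[keep, ]
  deg <- degTest(sub, "MID+", "LOW", onLog = TRUE,
                 offset = config$log_offset)
  pl <- parentList(deg, percentileCut = config$percentile_cut,
                   parentFc = config$parent_fc)
  deg$pass_filter <- TRUE
  deg$pass_p <- deg$p < config$deg_p
  deg$pass_percentile <- deg$pass_p &
    deg$transcript_id %in% pl$percentile_ids
  deg$pass_parent <- deg$pass_percentile &
    deg$transcript_id %in% pl$parent_ids
  dropped <- setdiff(rownames(object), keep)
  if (length(dropped)) {
    pad <- deg[rep(NA_integer_, length(dropped)), ]
    pad$transcript_id <- dropped
    pad$pass_filter <- FALSE
    pad$pass_p <- pad$pass_percentile <- pad$pass_parent <- FALSE
    deg <- rbind(deg, pad)
  }
  deg <- deg[match(rownames(object), deg$transcript_id), ]
  rownames(deg) <- NULL
  deg
}

#' Covariate biomarker list
#'
#' Dichotomizes a clinical covariate, runs the same volcano machinery at
#' the covariate thresholds (default fold > 3, p < 0.05 uncorrected) and
#' reports the biomarker set plus its overlap with a reference transcript
#' set. For `age`, `sex` and `bmi` only LOW-CAD samples are analyzed, to
#' prevent confounding with CAD; a read-depth covariate can be formed the
#' same way (e.g. `total_mapped_reads < 5e6`).
#'
#' @param object a [BloodExprSet-class] with `unit == "RPKM"`.
#' @param covariate covariate column name in the sample annotation.
#' @param cutoff for numeric covariates, the dichotomization cutpoint
#'   (level = value >= cutoff); default: age 60, otherwise the median.
#' @param restrictToLow restrict to LOW samples; default TRUE for
#'   age/sex/bmi, FALSE otherwise.
#' @param reference optional character vector of transcript ids (e.g. the
#'   TRAC list) to intersect with.
#' @param config threshold list, see [analysisConfig()].
#' @return list: `ids` (selected transcript ids), `selected` (the volcano
#'   table), `overlap` (ids shared with `reference`), `n_samples`, `levels`.
#' @export
covariateList <- function(object, covariate, cutoff = NULL,
                          restrictToLow = NULL, reference = NULL,
                          config = analysisConfig()) {
  stopifnot(is(object, "BloodExprSet"))
  info <- sampleInfo(object)
  if (!covariate %in% names(info))
    stop("unknown covariate: ", covariate)
  if (is.null(restrictToLow))
    restrictToLow <- tolower(covariate) %in% c("age", "sex", "bmi")
  if (restrictToLow) {
    if (is.null(info$group)) stop("no 'group' annotation to restrict on")
    object <- object[, info$group == "LOW"]
    info <- sampleInfo(object)
  }
  v <- info[[covariate]]
  ok <- !is.na(v)
  object <- object[, ok]
  v <- v[ok]
  if (is.numeric(v) && length(unique(v)) > 2L) {
    if (is.null(cutoff))
      cutoff <- if (tolower(covariate) == "age") 60 else stats::median(v)
    lv <- ifelse(v >= cutoff, paste0(">=", cutoff), paste0("<", cutoff))
  } else {
    lv <- as.character(v)
  }
  lev <- sort(unique(lv))
  if (length(lev) != 2L)
    stop("covariate '", covariate, "' does not dichotomize into two levels")
  idsA <- colnames(object)[lv == lev[2L]]
  idsB <- colnames(object)[lv == lev[1L]]
  deg <- degTest(object, idsA, idsB, offset = config$log_offset)
  sel <- volcanoSelect(deg, pThresh = config$covariate_p,
                       fcThresh = config$covariate_fc)
  list(ids = sel$transcript_id, selected = sel,
       overlap = intersect(sel$transcript_id, reference),
       n_samples = ncol(object), levels = lev)
}

#' Welch t-test from printed summary statistics
#'
#' Two-sided Welch test from group means, standard errors of the mean and
#' sizes, as used to compare printed demographic rows:
#' `t = (mean2 - mean1) / sqrt(sem1^2 + sem2^2)` with Welch-Satterthwaite
#' degrees of freedom.
#'
#' @param mean1,sem1,n1 first group summary (sem > 0, n >= 2).
#' @param mean2,sem2,n2 second group summary.
#' @return list with `t`, `df`, `p`.
#' @examples
#' summaryTTest(57.5, 1.49, 48, 62.5, 1.41, 48)$p  # ~0.017
#' @export
summaryTTest <- function(mean1, sem1, n1, mean2, sem2, n2) {
  if (sem1 <= 0 || sem2 <= 0) stop("standard errors must be > 0")
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  s1 <- sem1^2; s2 <- sem2^2
  t <- (mean2 - mean1) / sqrt(s1 + s2)
  df <- (s1 + s2)^2 / (s1^2 / (n1 - 1) + s2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
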