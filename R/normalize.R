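## RPKM normalization, log2 transforms and geometric group summaries.

#' RPKM normalization
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `RPKM = count / ((length_bp / 1000) * (total_mapped / 1e6))`. Transcript
#' lengths come from the object's transcript annotation (`length_bp`);
#' per-sample totals come from the sample annotation column
#' `total_mapped_reads` when present, else from the column sums. When the
#' column sums are used, `sum(RPKM * length_kb)` is exactly 1e6 in every
#' sample.
#'
#' @param object a [BloodExprSet-class] with `unit == "counts"`.
#' @param lengths optional numeric vector overriding `length_bp` (bases).
#' @param totals optional numeric vector overriding total mapped reads.
#' @return a [BloodExprSet-class] with `unit == "RPKM"`.
#' @examples
#' m <- matrix(c(10, 0), 2, 1, dimnames = list(c("t1", "t2"), "s1"))
#' tr <- data.frame(transcript_id = c("t1", "t2"), gene_symbol = c("A", "B"),
#'                  length_bp = c(1000, 2000))
#' bes <- BloodExprSet(m, transcripts = tr)
#' exprValues(rpkm(bes, totals = 1e6))  # count 10 / 1 kb / 1 M reads -> 10
#' @export
rpkm <- function(object, lengths = NULL, totals = NULL) {
  stopifnot(is(object, "BloodExprSet"))
  if (exprUnit(object) != "counts")
    stop("rpkm() expects unit 'counts', got '", exprUnit(object), "'")
  x <- exprValues(object)
  if (is.null(lengths)) {
    lengths <- transcriptInfo(object)$length_bp
    if (is.null(lengths))
      stop("no transcript lengths: supply 'lengths' or length_bp annotation")
  }
  if (length(lengths) != nrow(x)) stop("one length per transcript required")
  if (anyNA(lengths) || any(lengths < 1)) stop("invalid transcript lengths")
  if (is.null(totals)) {
    totals <- sampleInfo(object)$total_mapped_reads
    if (is.null(totals)) totals <- colSums(x)
  }
  if (length(totals) == 1L) totals <- rep(totals, ncol(x))
  if (length(totals) != ncol(x)) stop("one total per sample required")
  if (anyNA(totals) || any(totals <= 0))
    stop("total mapped reads must be positive in every sample")
  r <- sweep(x / (lengths / 1000), 2L, totals / 1e6, "/")
  out <- object
  SummarizedExperiment::assay(out, 1L) <- r
  out@unit <- "RPKM"
  validObject(out)
  out
}

#' log2 transform of an RPKM matrix
#'
#' @param object a [BloodExprSet-class] with `unit == "RPKM"`.
#' @param offset non-negative value added before taking log2; must be
#'   positive if the matrix contains zeros.
#' @return a [BloodExprSet-class] with `unit == "log2RPKM"`.
#' @export
log2Expr <- function(object, offset = 1e-6) {
  stopifnot(is(object, "BloodExprSet"))
  if (exprUnit(object) != "RPKM")
    stop("log2Expr() expects unit 'RPKM', got '", exprUnit(object), "'")
  if (offset < 0) stop("offset must be >= 0")
  x <- exprValues(object)
  if (offset == 0 && any(x == 0))
    stop("matrix contains zeros: use a positive offset")
  out <- object
  SummarizedExperiment::assay(out, 1L) <- log2(x + offset)
  out@unit <- "log2RPKM"
  validObject(out)
  out
}

## geometric mean of x on the offset scale: exp(mean(log(x + offset)));
## the reported geometric mean subtracts the offset back, floored at 0,
## while folds are taken on the (strictly positive) offset scale.
.geoMeanRows <- function(x, offset) {
  exp(rowMeans(log(x + offset)))
}

#' Percentile rank of values within their own distribution
#'
#' Rank of each value as `100 * (number strictly below) / (n - 1)`; ties
#' share a rank; the minimum of a distinct list ranks 0 and the maximum 100.
#'
#' @param values non-empty numeric vector.
#' @return numeric vector of ranks in \[0, 100\].
#' @examples
#' percentileRank(c(1, 2, 3, 4, 5))  # 0 25 50 75 100
#' @export
percentileRank <- function(values) {
  n <- length(values)
  if (n == 0L) stop("percentileRank needs a non-empty vector")
  if (n == 1L) return(0)
  below <- rank(values, ties.method = "min") - 1  # values strictly below
  100 * below / (n - 1)
}

#' Per-transcript geometric group summary
#'
#' For each transcript: geometric mean RPKM per group (computed on
#' `x + offset`, offset subtracted back and floored at 0), its log2, the
#' group A over group B fold on the offset scale, the signed fold (down
#' printed as a negative reciprocal: fold 0.5 prints as -2), and the
#' percentile rank of each transcript's group geometric mean within that
#' group's distribution across transcripts.
#'
#' @param object a [BloodExprSet-class] with `unit == "RPKM"`.
#' @param groupA,groupB character vectors of sample ids, or a single group
#'   label matched against the `group` sample annotation (`"MID+"` selects
#'   MID and HIGH).
#' @param offset geometric-mean offset (RPKM), default 1e-6.
#' @return data.frame with columns `transcript_id`, `geomean_A`,
#'   `geomean_B`, `log2_gm_A`, `log2_gm_B`, `fold`, `signed_fold`,
#'   `pct_rank_A`, `pct_rank_B`.
#' @export
groupSummary <- function(object, groupA, groupB, offset = 1e-6) {
  stopifnot(is(object, "BloodExprSet"))
  if (exprUnit(object) != "RPKM")
    stop("groupSummary() expects unit 'RPKM'")
  idsA <- .resolveSamples(object, groupA)
  idsB <- .resolveSamples(object, groupB)
  if (length(idsA) == 0L || length(idsB) == 0L)
    stop("both groups must contain at least one sample")
  x <- exprValues(object)
  gA <- .geoMeanRows(x[, idsA, drop = FALSE], offset)
  gB <- .geoMeanRows(x[, idsB, drop = FALSE], offset)
  fold <- gA / gB
  signed <- ifelse(fold >= 1, fold, -1 / fold)
  gmA <- pmax(gA - offset, 0)
  gmB <- pmax(gB - offset, 0)
  data.frame(
    transcript_id = rownames(x),
    geomean_A = gmA, geomean_B = gmB,
    log2_gm_A = log2(gA), log2_gm_B = log2(gB),
    fold = fold, signed_fold = signed,
    pct_rank_A = percentileRank(gmA),
    pct_rank_B = percentileRank(gmB),
    stringsAsFactors = FALSE, row.names = NULL)
}

## group argument: sample ids, or one of the group labels, or "MID+"
.resolveSamples <- function(object, group) {
  cn <- colnames(object)
  if (all(group %in% cn)) return(group)
  labels <- sampleInfo(object)$group
  if (is.null(labels))
    stop("no 'group' sample annotation and arguments are not sample ids")
  if (identical(group, "MID+")) return(cn[isMidPlus(labels)])
  if (length(group) == 1L && group %in% c("LOW", "MID", "HIGH"))
    return(cn[labels == group])
  stop("cannot resolve group: ", paste(utils::head(group, 3), collapse = ", "))
}
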