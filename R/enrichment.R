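## Cell-type composite indices, hypergeometric gene-set over-representation,
## cross-cohort symbol matching, marker correlation panels, and the
## Treg-abundance fold arithmetic.

#' Cell-type composite expression index
#'
#' For each marker set, the mean RPKM over the set's transcripts is the
#' per-sample index; indices are averaged within each CAD group (LOW / MID
#' / HIGH three-way).
#'
#' @param object a [BloodExprSet-class] with `unit == "RPKM"` and a `group`
#'   sample annotation.
#' @param markerSets list of [GeneSet-class]; each must overlap the matrix.
#' @param groups group labels to average within (default the three CAD
#'   groups present).
#' @return matrix, marker sets x groups, of mean indices.
#' @export
cellTypeIndex <- function(object, markerSets, groups = NULL) {
  stopifnot(is(object, "BloodExprSet"))
  if (exprUnit(object) != "RPKM") stop("cellTypeIndex() expects unit 'RPKM'")
  labels <- sampleInfo(object)$group
  if (is.null(labels)) stop("no 'group' sample annotation")
  if (is.null(groups))
    groups <- intersect(c("LOW", "MID", "HIGH"), unique(labels))
  info <- transcriptInfo(object)
  sym <- toupper(trimws(info$gene_symbol))
  x <- exprValues(object)
  out <- matrix(NA_real_, length(markerSets), length(groups),
                dimnames = list(vapply(markerSets, geneSetName, character(1)),
                                groups))
  for (i in seq_along(markerSets)) {
    rows <- which(sym %in% members(markerSets[[i]]))
    if (length(rows) == 0L)
      stop("marker set '", geneSetName(markerSets[[i]]),
           "' has no transcripts in the matrix")
    idx <- colMeans(x[rows, , drop = FALSE])
    for (g in groups) out[i, g] <- mean(idx[labels == g])
  }
  out
}

#' Gene-set overlap enrichment (hypergeometric / Fisher exact)
#'
#' Observed overlap `k = |A intersect B|` against the expectation
#' `|A||B|/N` in a universe of `N` symbols; fold over-representation is
#' `k N / (|A||B|)` and the p-value is the upper-tail hypergeometric
#' probability `P(X >= k)` (the one-sided Fisher exact test); a two-sided
#' variant is available.
#'
#' @param A,B [GeneSet-class] objects (or character vectors of symbols).
#' @param N universe size; must be at least `|A union B|`. The universe is
#'   an explicit analysis choice (e.g. 20,000 annotated symbols) on which
#'   all fold/p values are conditional.
#' @param alternative `"greater"` (upper tail, default) or `"two.sided"`
#'   (via [stats::fisher.test()]).
#' @return data.frame row: `set_a`, `set_b`, `universe`, `size_a`,
#'   `size_b`, `overlap`, `expected`, `fold`, `p`.
#' @examples
#' overlapEnrichment(GeneSet("A", letters[1:5]), GeneSet("B", letters[2:5]),
#'                   N = 10)  # k=4, fold 2, p = 5/210
#' @export
overlapEnrichment <- function(A, B, N,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  nameA <- if (is(A, "GeneSet")) geneSetName(A) else "A"
  nameB <- if (is(B, "GeneSet")) geneSetName(B) else "B"
  a <- if (is(A, "GeneSet")) members(A) else unique(toupper(trimws(A)))
  b <- if (is(B, "GeneSet")) members(B) else unique(toupper(trimws(B)))
  if (N < length(union(a, b)))
    stop("universe size N is smaller than |A union B|")
  k <- length(intersect(a, b))
  nA <- length(a); nB <- length(b)
  expected <- nA * nB / N
  p <- if (alternative == "greater") {
    stats::phyper(k - 1, nA, N - nA, nB, lower.tail = FALSE)
  } else {
    m <- matrix(c(k, nA - k, nB - k, N - nA - nB + k), 2L)
    stats::fisher.test(m, alternative = "two.sided")$p.value
  }
  data.frame(set_a = nameA, set_b = nameB, universe = N,
             size_a = nA, size_b = nB, overlap = k,
             expected = expected, fold = k / expected, p = p,
             stringsAsFactors = FALSE)
}

#' Exact and close symbol matching between transcript lists
#'
#' Exact matches are identical symbol strings. Close matches (for symbols
#' not matched exactly) follow two frozen rules, each recorded per pair:
#' `trail1` - identical after stripping a single trailing alphanumeric
#' character from either or both symbols (e.g. ELP3 vs ELP2); `edit1_stem` -
#' edit distance 1 with an identical alphabetic stem (letters only).
#'
#' @param listA,listB character vectors of symbols (normalized upper-case).
#' @param mode `"exact"` for exact only, `"close"` for both.
#' @return list: `exact` (character vector of shared symbols), `close`
#'   (data.frame `symbol_a`, `symbol_b`, `rule`); the two are disjoint.
#' @export
matchSymbols <- function(listA, listB, mode = c("close", "exact")) {
  mode <- match.arg(mode)
  a <- unique(toupper(trimws(listA)))
  b <- unique(toupper(trimws(listB)))
  exact <- intersect(a, b)
  close <- data.frame(symbol_a = character(0), symbol_b = character(0),
                      rule = character(0), stringsAsFactors = FALSE)
  if (mode == "close") {
    restA <- setdiff(a, exact)
    restB <- setdiff(b, exact)
    strip1 <- function(s) ifelse(nchar(s) > 1, substr(s, 1, nchar(s) - 1), s)
    stem <- function(s) gsub("[^A-Z]", "", s)
    for (sa in restA) {
      for (sb in restB) {
        rule <- NULL
        if (strip1(sa) == sb || sa == strip1(sb) ||
            (nchar(sa) > 1 && nchar(sb) > 1 && strip1(sa) == strip1(sb)))
          rule <- "trail1"
        else if (utils::adist(sa, sb) == 1 && stem(sa) == stem(sb))
          rule <- "edit1_stem"
        if (!is.null(rule))
          close <- rbind(close, data.frame(symbol_a = sa, symbol_b = sb,
                                           rule = rule,
                                           stringsAsFactors = FALSE))
      }
    }
  }
  list(exact = exact, close = close)
}

#' Correlation of a marker panel with an anchor transcript
#'
#' Pearson correlation of each panel symbol with the anchor symbol across
#' samples, on log2(RPKM + offset) by default, with the two-sided p-value
#' from the t transform of r. With several transcripts per symbol the
#' highest-expressed transcript represents the symbol.
#'
#' @param object a [BloodExprSet-class] with `unit == "RPKM"`.
#' @param anchor anchor gene symbol (e.g. `"FOXP3"`).
#' @param panel [GeneSet-class] of symbols to correlate with the anchor.
#' @param onLog correlate on log2 scale (default TRUE).
#' @param offset log offset.
#' @return data.frame: `symbol`, `r`, `p`, `n` (`r` is NA with a warning
#'   for zero-variance transcripts).
#' @export
markerCorrelations <- function(object, anchor, panel, onLog = TRUE,
                               offset = 1e-6) {
  stopifnot(is(object, "BloodExprSet"))
  if (exprUnit(object) != "RPKM")
    stop("markerCorrelations() expects unit 'RPKM'")
  if (ncol(object) < 3L) stop("need at least 3 samples")
  anchor <- toupper(trimws(anchor))
  aRow <- .rowsForSymbols(object, anchor)
  pRows <- .rowsForSymbols(object, members(panel))
  x <- exprValues(object)
  if (onLog) x <- log2(x + offset)
  av <- x[aRow, ]
  res <- lapply(seq_along(pRows), function(i) {
    pv <- x[pRows[i], ]
    if (stats::sd(av) == 0 || stats::sd(pv) == 0) {
      warning("zero-variance transcript: ", members(panel)[i])
      return(data.frame(symbol = members(panel)[i], r = NA_real_,
                        p = NA_real_, n = length(pv)))
    }
    ct <- stats::cor.test(av, pv, method = "pearson")
    data.frame(symbol = members(panel)[i], r = unname(ct$estimate),
               p = ct$p.value, n = length(pv), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Treg abundance arithmetic
#'
#' A fractional reduction `r` in Treg abundance translates to an expected
#' `1/(1-r)`-fold difference in Treg-exclusive transcript levels
#' (e.g. a 30.3\% reduction gives 1.43-fold); equivalently, normal and
#' disease Treg fractions give the fold directly as their ratio (4.7\% over
#' 3.2\% gives 1.47-fold).
#'
#' @param reduction fractional reduction in \[0, 1).
#' @return fold >= 1.
#' @examples
#' tregFoldFromReduction(0.303)      # 1.4347
#' tregFoldFromFractions(4.7, 3.2)   # 1.46875
#' @export
tregFoldFromReduction <- function(reduction) {
  if (any(reduction < 0 | reduction >= 1))
    stop("reduction must lie in [0, 1)")
  1 / (1 - reduction)
}

#' @param fNormal,fDisease Treg fractions (any common unit) in the normal
#'   and disease groups; both > 0.
#' @rdname tregFoldFromReduction
#' @export
tregFoldFromFractions <- function(fNormal, fDisease) {
  if (any(fNormal <= 0) || any(fDisease <= 0))
    stop("fractions must be > 0")
  fNormal / fDisease
}
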