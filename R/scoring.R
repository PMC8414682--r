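## Composite transcript scoring, diagnostic evaluation (empirical ROC
## C-statistic, confusion metrics), the additive clinical risk model,
## NIPALS PLS-DA with stratified cross-validation, and covariate regression.

## map gene symbols to matrix rows; with several transcripts per symbol,
## keep the one with the highest mean expression (symbol-level collapse)
.rowsForSymbols <- function(object, symbols) {
  info <- transcriptInfo(object)
  if (is.null(info$gene_symbol))
    stop("no gene_symbol transcript annotation")
  sym <- toupper(trimws(info$gene_symbol))
  rows <- integer(0)
  miss <- character(0)
  rm <- rowMeans(exprValues(object))
  for (s in symbols) {
    hit <- which(sym == s)
    if (length(hit) == 0L) { miss <- c(miss, s); next }
    rows <- c(rows, hit[which.max(rm[hit])])
  }
  if (length(miss))
    stop("panel symbols not in matrix: ", paste(miss, collapse = ", "))
  rows
}

#' Composite transcript score
#'
#' Each panel transcript is expressed as a ratio to the mean of its
#' expression in the entire cohort, and the per-sample score is the mean of
#' those ratios over the panel; this prevents highly expressed transcripts
#' from dominating the score, and the cohort-mean sample scores 1.
#'
#' @param object a [BloodExprSet-class] with `unit == "RPKM"`.
#' @param panel a [GeneSet-class] of gene symbols; each must be present.
#' @param orientation `"lower_is_disease"` (default: disease depresses the
#'   panel, as for Treg-related TRACs) or `"higher_is_disease"`.
#' @return A [CompositeScore-class].
#' @examples
#' m <- matrix(c(2, 4, 10, 30), 2, byrow = TRUE,
#'             dimnames = list(c("t1", "t2"), c("s1", "s2")))
#' tr <- data.frame(transcript_id = c("t1", "t2"),
#'                  gene_symbol = c("A", "B"), length_bp = c(1000, 1000))
#' bes <- BloodExprSet(m, transcripts = tr, unit = "RPKM")
#' scoreValues(compositeScore(bes, GeneSet("AB", c("A", "B"))))
#' # s1: (2/3 + 1/2)/2 = 0.5833, s2: (4/3 + 3/2)/2 = 1.4167
#' @export
compositeScore <- function(object, panel,
                           orientation = c("lower_is_disease",
                                           "higher_is_disease")) {
  orientation <- match.arg(orientation)
  stopifnot(is(object, "BloodExprSet"), is(panel, "GeneSet"))
  if (exprUnit(object) != "RPKM") stop("compositeScore() expects unit 'RPKM'")
  rows <- .rowsForSymbols(object, members(panel))
  x <- exprValues(object)[rows, , drop = FALSE]
  mu <- rowMeans(x)
  if (any(mu == 0))
    stop("panel transcripts with zero cohort mean: ",
         paste(members(panel)[mu == 0], collapse = ", "))
  score <- colMeans(x / mu)
  new("CompositeScore", score = score, panel = panel,
      orientation = orientation)
}

#' Empirical ROC C-statistic (area under the curve)
#'
#' Mann-Whitney AUC with ties counted one half, after orienting scores so
#' the disease direction is positive: the probability that a random
#' diseased sample scores in the disease direction relative to a random
#' non-diseased one.
#'
#' @param scores numeric scores or a [CompositeScore-class] (which supplies
#'   its own orientation).
#' @param labels logical/0-1 disease labels, both classes present.
#' @param orientation `"higher_is_disease"` or `"lower_is_disease"`.
#' @return AUC in \[0, 1\].
#' @export
cStatistic <- function(scores, labels,
                       orientation = c("higher_is_disease",
                                       "lower_is_disease")) {
  if (is(scores, "CompositeScore")) {
    orientation <- scoreOrientation(scores)
    scores <- scoreValues(scores)
  } else {
    orientation <- match.arg(orientation)
  }
  labels <- as.logical(labels)
  if (anyNA(labels) || anyNA(scores)) stop("missing scores or labels")
  if (length(labels) != length(scores)) stop("length mismatch")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  s <- if (orientation == "lower_is_disease") -scores else scores
  r <- rank(s)  # midranks handle ties as 1/2
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metrics
#'
#' Standard definitions; a metric with a zero denominator is reported as
#' `NA`, never as 0.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return named list: `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy` (proportions in \[0, 1\]).
#' @examples
#' unlist(confusionMetrics(ConfusionMatrix(41, 7, 12, 36)))
#' @export
confusionMetrics <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  with(list(tp = cm@tp, fp = cm@fp, fn = cm@fn, tn = cm@tn), list(
    sensitivity = frac(tp, tp + fn),
    specificity = frac(tn, tn + fp),
    ppv = frac(tp, tp + fp),
    npv = frac(tn, tn + fn),
    accuracy = frac(tp + tn, tp + fp + fn + tn)))
}

#' Reconstruct a confusion matrix from predictive values
#'
#' Inverts reported PPV/NPV over known numbers of positive and negative
#' predictions: `tp = round(ppv * nPredPos)`, `tn = round(npv * nPredNeg)`.
#'
#' @param ppv,npv predictive values in \[0, 1\].
#' @param nPredPos,nPredNeg number of positive/negative predictions.
#' @return A [ConfusionMatrix-class].
#' @examples
#' confusionFromPredictiveValues(0.854, 0.750, 48, 48)  # tp=41 fp=7 fn=12 tn=36
#' @export
confusionFromPredictiveValues <- function(ppv, npv, nPredPos, nPredNeg) {
  if (ppv < 0 || ppv > 1 || npv < 0 || npv > 1)
    stop("ppv and npv must lie in [0, 1]")
  if (nPredPos < 0 || nPredNeg < 0) stop("prediction counts must be >= 0")
  tp <- round(ppv * nPredPos)
  tn <- round(npv * nPredNeg)
  ConfusionMatrix(tp, nPredPos - tp, nPredNeg - tn, tn)
}

#' Classify scores at a threshold into a confusion matrix
#'
#' @param scores numeric scores or [CompositeScore-class].
#' @param labels logical disease labels.
#' @param threshold score threshold; default the cohort median. Samples on
#'   the disease side of the threshold (strictly, after orientation) are
#'   called positive.
#' @param orientation see [cStatistic()].
#' @return A [ConfusionMatrix-class].
#' @export
confusionAtThreshold <- function(scores, labels, threshold = NULL,
                                 orientation = c("higher_is_disease",
                                                 "lower_is_disease")) {
  if (is(scores, "CompositeScore")) {
    orientation <- scoreOrientation(scores)
    scores <- scoreValues(scores)
  } else {
    orientation <- match.arg(orientation)
  }
  labels <- as.logical(labels)
  s <- if (orientation == "lower_is_disease") -scores else scores
  if (is.null(threshold)) threshold <- stats::median(s)
  else if (orientation == "lower_is_disease") threshold <- -threshold
  pred <- s > threshold
  ConfusionMatrix(sum(pred & labels), sum(pred & !labels),
                  sum(!pred & labels), sum(!pred & !labels))
}

#' Additive clinical risk points
#'
#' Accumulates integer risk points over clinical factors (age band, sex,
#' symptom type, diabetes, hypertension, family history, smoking) and maps
#' the total through ordinal cutpoints to a risk class. The point table is
#' supplied as configuration (see the example table installed at
#' `system.file("extdata", "toy_risk_points.yaml", package = "tracseq")`,
#' a synthetic table for testing; no published point values are bundled).
#'
#' @param samples data.frame of sample records.
#' @param table risk point table: a list with `factors` (per factor, either
#'   `levels`: map level -> points, or `breaks`/`points` for numeric bands)
#'   and `cutpoints` (strictly increasing totals separating risk classes);
#'   or the path to a YAML file holding one.
#' @return data.frame: `sample_id`, `points`, `risk_class` (NA with a
#'   warning for patients missing a covariate).
#' @export
clinicalRisk <- function(samples, table) {
  if (is.character(table)) table <- yaml::read_yaml(table)
  if (is.null(table$factors)) stop("risk table needs a 'factors' entry")
  cut <- table$cutpoints
  if (!is.null(cut) && any(diff(as.numeric(cut)) <= 0))
    stop("cutpoints must be strictly increasing")
  pts <- rep(0, nrow(samples))
  missing <- rep(FALSE, nrow(samples))
  for (fname in names(table$factors)) {
    f <- table$factors[[fname]]
    v <- samples[[fname]]
    if (is.null(v)) stop("samples lack covariate '", fname, "'")
    missing <- missing | is.na(v)
    if (!is.null(f$breaks)) {
      band <- findInterval(as.numeric(v), as.numeric(unlist(f$breaks)))
      p <- as.numeric(unlist(f$points))[band + 1L]
    } else {
      lv <- unlist(f$levels)
      p <- as.numeric(lv[as.character(v)])
    }
    pts <- pts + ifelse(is.na(v), 0, p)
  }
  if (any(missing)) {
    warning(sum(missing), " patient(s) with missing covariates: risk set to NA")
    pts[missing] <- NA_real_
  }
  cls <- if (is.null(cut)) rep(NA_integer_, length(pts))
         else findInterval(pts, as.numeric(cut)) + 1L
  data.frame(sample_id = samples$sample_id, points = pts,
             risk_class = cls, stringsAsFactors = FALSE)
}

## NIPALS PLS1: standardized predictors, centered +/-1 response; returns
## the implied regression coefficients in standardized predictor space
.plsFit <- function(X, y, nComp) {
  E <- X; f <- y
  W <- P <- matrix(0, ncol(X), nComp)
  q <- numeric(nComp)
  for (k in seq_len(nComp)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { nComp <- k - 1L; break }
    w <- w / nw
    t <- drop(E %*% w)
    tt <- sum(t^2)
    p <- drop(crossprod(E, t)) / tt
    qk <- sum(f * t) / tt
    E <- E - tcrossprod(t, p)
    f <- f - t * qk
    W[, k] <- w; P[, k] <- p; q[k] <- qk
  }
  if (nComp == 0L) return(rep(0, ncol(X)))
  W <- W[, seq_len(nComp), drop = FALSE]
  P <- P[, seq_len(nComp), drop = FALSE]
  q <- q[seq_len(nComp)]
  drop(W %*% solve(crossprod(P, W), q))
}

.plsPredict <- function(Xnew, mu, sdev, beta, yBar) {
  Z <- sweep(sweep(Xnew, 2L, mu), 2L, sdev, "/")
  drop(Z %*% beta) + yBar
}

#' PLS discriminant analysis with stratified N-fold validation
#'
#' Partial least squares components are extracted by the iterative NIPALS
#' deflation procedure on standardized predictors against a +/-1 class
#' code; a sample is assigned the class whose sign its fitted response
#' takes. Cross-validation folds are stratified by class and reproducible
#' under `seed`.
#'
#' @param x predictor matrix, samples in rows (a [BloodExprSet-class] is
#'   transposed and its samples become rows).
#' @param labels two-level class labels.
#' @param nComp number of latent components (default 2; must not exceed
#'   the predictor rank).
#' @param nFolds folds for internal validation (default 5; 0 skips CV).
#' @param seed integer seed for the fold assignment.
#' @return list: `train_accuracy`, `train_accuracy_by_class`,
#'   `cv_accuracy`, `cv_accuracy_by_class`, `fitted_class`, `cv_class`.
#' @export
plsDA <- function(x, labels, nComp = 2L, nFolds = 5L, seed = 1L) {
  if (is(x, "BloodExprSet")) x <- t(exprValues(x))
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("plsDA needs exactly two classes")
  if (nComp < 1L) stop("nComp must be >= 1")
  n <- nrow(x)
  if (nComp > min(n - 1L, ncol(x)))
    stop("nComp exceeds the rank of the predictor matrix")
  y <- ifelse(labels == levels(labels)[2L], 1, -1)

  fitPredict <- function(trainIdx, testIdx) {
    Xtr <- x[trainIdx, , drop = FALSE]
    mu <- colMeans(Xtr)
    sdev <- apply(Xtr, 2L, stats::sd)
    keep <- sdev > 0
    if (!any(keep)) return(rep(0, length(testIdx)))
    Z <- sweep(sweep(Xtr[, keep, drop = FALSE], 2L, mu[keep]), 2L,
               sdev[keep], "/")
    yc <- y[trainIdx] - mean(y[trainIdx])
    beta <- .plsFit(Z, yc, min(nComp, length(trainIdx) - 1L, sum(keep)))
    .plsPredict(x[testIdx, keep, drop = FALSE], mu[keep], sdev[keep], beta,
                mean(y[trainIdx]))
  }

  all <- seq_len(n)
  yhatTrain <- fitPredict(all, all)
  fitted <- levels(labels)[(yhatTrain > 0) + 1L]
  accByClass <- function(pred) {
    vapply(levels(labels),
           function(l) mean(pred[labels == l] == l), numeric(1))
  }
  out <- list(
    train_accuracy = mean(fitted == as.character(labels)),
    train_accuracy_by_class = accByClass(fitted),
    fitted_class = fitted)

  if (nFolds >= 2L) {
    ## seed the fold draw without disturbing the caller's RNG stream
    oldSeed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(oldSeed))
      assign(".Random.seed", oldSeed, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    fold <- integer(n)
    for (l in levels(labels)) {
      idx <- sample(which(labels == l))
      fold[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
    yhatCV <- numeric(n)
    for (k in seq_len(nFolds)) {
      test <- which(fold == k)
      yhatCV[test] <- fitPredict(which(fold != k), test)
    }
    cvClass <- levels(labels)[(yhatCV > 0) + 1L]
    out$cv_accuracy <- mean(cvClass == as.character(labels))
    out$cv_accuracy_by_class <- accByClass(cvClass)
    out$cv_class <- cvClass
  }
  out
}

#' Simple regression of a score on a covariate
#'
#' Ordinary least-squares simple linear regression with the two-sided
#' slope test, e.g. a composite TRAC score against age.
#'
#' @param scores numeric response (or [CompositeScore-class]).
#' @param covariate numeric predictor, n >= 3, non-constant.
#' @return list: `slope`, `intercept`, `r_squared`, `p`, `n`.
#' @export
scoreOnCovariate <- function(scores, covariate) {
  if (is(scores, "CompositeScore")) scores <- scoreValues(scores)
  ok <- !is.na(scores) & !is.na(covariate)
  y <- scores[ok]; x <- covariate[ok]
  if (length(y) < 3L) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0) stop("covariate has zero variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       p = sm$coefficients[2L, 4L],
       n = length(y))
}
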