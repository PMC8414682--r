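test_that("composite score averages ratios to cohort means", {
  bes <- makeBes(rbind(t1 = c(2, 4), t2 = c(10, 30)),
                 symbols = c("A", "B"), unit = "RPKM")
  cs <- compositeScore(bes, GeneSet("AB", c("A", "B")))
  expect_equal(unname(scoreValues(cs)), c(7 / 12, 17 / 12))
  expect_equal(mean(scoreValues(cs)), 1)

  # every sample at the cohort mean scores exactly 1
  flat <- makeBes(matrix(5, 3, 4), symbols = c("A", "B", "C"), unit = "RPKM")
  expect_equal(unname(scoreValues(compositeScore(flat, GeneSet("S", c("A", "B", "C"))))),
               rep(1, 4))

  # a single-transcript panel reduces to value / cohort mean
  one <- compositeScore(bes, GeneSet("ONE", "A"))
  expect_equal(unname(scoreValues(one)), c(2, 4) / 3)

  # invariant to rescaling any panel transcript by a positive constant
  scaled <- makeBes(rbind(t1 = c(2, 4) * 1000, t2 = c(10, 30)),
                    symbols = c("A", "B"), unit = "RPKM")
  expect_equal(scoreValues(compositeScore(scaled, GeneSet("AB", c("A", "B")))),
               scoreValues(cs))

  expect_error(compositeScore(bes, GeneSet("XX", "NOTHERE")), "NOTHERE")
  zero <- makeBes(rbind(t1 = c(0, 0), t2 = c(1, 2)),
                  symbols = c("A", "B"), unit = "RPKM")
  expect_error(compositeScore(zero, GeneSet("AB", c("A", "B"))), "zero cohort mean")
})

test_that("the C-statistic equals brute-force pair counting", {
  expect_equal(cStatistic(c(1, 2, 10, 20), c(0, 0, 1, 1)), 1)
  expect_equal(cStatistic(rep(3, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(cStatistic(c(1, 3, 2, 4), c(1, 1, 0, 0)), 0.25)

  set.seed(41)
  for (i in 1:20) {
    n <- sample(c(5, 20, 80, 200), 1)
    scores <- sample(1:8, n, replace = TRUE)  # heavy ties
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(cStatistic(scores, labels), pairCountAUC(scores, labels))
  }

  # lower_is_disease flips the orientation
  expect_equal(cStatistic(c(1, 2, 10, 20), c(1, 1, 0, 0),
                          orientation = "lower_is_disease"), 1)
  expect_error(cStatistic(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("the C-statistic agrees with an independent ROC implementation", {
  set.seed(17)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.5)
  auc <- cStatistic(scores, labels)
  ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                               direction = "<")))
  expect_equal(auc, ref, tolerance = 1e-12)
})

test_that("confusion metrics and the predictive-value inversion agree", {
  cm <- confusionFromPredictiveValues(0.854, 0.750, 48, 48)
  expect_identical(confusionCounts(cm),
                   c(tp = 41L, fp = 7L, fn = 12L, tn = 36L))
  met <- confusionMetrics(cm)
  expect_equal(round(100 * met$sensitivity, 1), 77.4)
  expect_equal(round(100 * met$specificity, 1), 83.7)
  expect_equal(round(100 * met$accuracy, 1), 80.2)
  expect_equal(round(100 * met$ppv, 1), 85.4)
  expect_equal(round(100 * met$npv, 1), 75.0)

  # degenerate margins are missing, not zero
  met2 <- confusionMetrics(ConfusionMatrix(5, 0, 0, 0))
  expect_equal(met2$sensitivity, 1)
  expect_equal(met2$ppv, 1)
  expect_true(is.na(met2$specificity))

  perfect <- confusionMetrics(ConfusionMatrix(10, 0, 0, 10))
  expect_true(all(unlist(perfect) == 1))

  expect_identical(confusionCounts(confusionFromPredictiveValues(1, 1, 5, 5))[c("fp", "fn")],
                   c(fp = 0L, fn = 0L))
  expect_identical(confusionCounts(confusionFromPredictiveValues(0.5, 1, 2, 2))[["tp"]], 1L)

  # round trip: metrics of the reconstruction return ppv/npv within 1/n
  set.seed(13)
  for (i in 1:20) {
    ppv <- runif(1); npv <- runif(1); np <- sample(5:60, 1); nn <- sample(5:60, 1)
    m <- confusionMetrics(confusionFromPredictiveValues(ppv, npv, np, nn))
    expect_lte(abs(m$ppv - ppv), 0.5 / np + 1e-12)
    expect_lte(abs(m$npv - npv), 0.5 / nn + 1e-12)
  }
})

test_that("clinical risk points are additive over the configured factors", {
  tab <- system.file("extdata", "toy_risk_points.yaml", package = "tracseq")
  pts <- function(...) {
    df <- data.frame(sample_id = "p1", ...)
    clinicalRisk(df, tab)$points
  }
  base <- list(age = 39, sex = "F", symptom_type = "noncardiac", diabetes = 0,
               hypertension = 0, family_history = 0, smoking = 0)
  expect_equal(do.call(pts, base), 0)  # all reference levels

  three <- base
  three[c("diabetes", "hypertension", "smoking")] <- 1
  expect_equal(do.call(pts, three), 3)

  # age bands and commutativity of factor order
  older <- base; older$age <- 72
  expect_equal(do.call(pts, older), 4)
  df <- data.frame(sample_id = "p1", smoking = 1, age = 65, sex = "M",
                   symptom_type = "typical", diabetes = 1, hypertension = 1,
                   family_history = 1)
  expect_equal(clinicalRisk(df, tab)$points, 3 + 1 + 2 + 1 + 1 + 1 + 1)
  expect_equal(clinicalRisk(df, tab)$risk_class, 4L)

  # missing covariate: NA with a warning, never silently zero
  dfm <- df; dfm$diabetes <- NA
  expect_warning(res <- clinicalRisk(dfm, tab), "missing")
  expect_true(is.na(res$points))
})

test_that("PLS-DA separates, validates and is duplication-invariant", {
  set.seed(51)
  n <- 40
  x <- rbind(matrix(rnorm(20 * 30, 0), 20),
             matrix(rnorm(20 * 30, 6), 20))
  labels <- rep(c("ctl", "dis"), each = 20)
  fit <- plsDA(x, labels, nComp = 2, nFolds = 5, seed = 1)
  expect_equal(fit$train_accuracy, 1)
  expect_equal(fit$cv_accuracy, 1)

  # duplicating every predictor column leaves predictions unchanged
  fit2 <- plsDA(cbind(x, x), labels, nComp = 2, nFolds = 5, seed = 1)
  expect_identical(fit$fitted_class, fit2$fitted_class)
  expect_identical(fit$cv_class, fit2$cv_class)

  # permuted labels: cross-validated accuracy shows no optimism over
  # chance (fold-wise CV is known to dip slightly below 50% under a
  # permutation null, so the one-sided bound is the meaningful check)
  set.seed(52)
  accs <- replicate(60, {
    perm <- sample(labels)
    plsDA(x, perm, nComp = 2, nFolds = 5, seed = 2)$cv_accuracy
  })
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(mean(accs), 0.5 + 3 * se)
  expect_gt(mean(accs), 0.35)

  expect_error(plsDA(x, rep("one", n)), "two classes")
  expect_error(plsDA(x[, 1:2], labels, nComp = 5), "rank")
})

test_that("PLS-DA class calls agree with an independent implementation", {
  set.seed(61)
  x <- rbind(matrix(rnorm(15 * 25, 0), 15), matrix(rnorm(15 * 25, 1.5), 15))
  colnames(x) <- sprintf("v%02d", 1:25)
  labels <- rep(c("a", "b"), each = 15)
  ours <- plsDA(x, labels, nComp = 2, nFolds = 0)
  ref <- suppressMessages(mixOmics::plsda(x, factor(labels), ncomp = 2))
  refClass <- predict(ref, x)$class$max.dist[, 2]
  agree <- mean(ours$fitted_class == refClass)
  expect_gte(agree, 0.95)
})

test_that("score-on-covariate regression matches closed forms", {
  x <- c(1, 2, 3, 4)
  fit <- suppressWarnings(scoreOnCovariate(2 * x, x))  # exact fit
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)

  fit2 <- scoreOnCovariate(c(1, 3, 2, 4), x)
  expect_equal(fit2$r_squared, 0.64)   # r = 0.8 by hand

  # null: p-values uniform over repeated independent draws
  set.seed(71)
  ps <- replicate(300, scoreOnCovariate(rnorm(20), rnorm(20))$p)
  expect_gt(ks.test(ps, "punif")$p.value, 1e-3)

  expect_error(scoreOnCovariate(1:2, 1:2), "at least 3")
  expect_error(scoreOnCovariate(rnorm(5), rep(1, 5)), "zero variance")
})

test_that("the planted-panel composite discriminates and scales with fold", {
  fix <- defaultCohort()
  panel <- GeneSet("P7", members(tracGeneSet(fix$prof))[1:7])
  cs <- compositeScore(fix$rpkm, panel)
  labels <- isMidPlus(sampleInfo(fix$rpkm)$group)
  expect_gt(cStatistic(cs, labels), 0.8)

  aucs <- vapply(c(1.0, 1.3, 1.7, 2.5), function(f) {
    spec <- MixtureSpec(tracFold = f, seed = 5L)
    prof <- buildProfiles(2000, spec)
    sim <- simulateCohort(prof, spec)
    r <- rpkm(cohortExprs(sim))
    p <- GeneSet("P7", members(tracGeneSet(prof))[1:7])
    cStatistic(compositeScore(r, p), isMidPlus(sampleInfo(r)$group))
  }, numeric(1))
  expect_true(all(diff(aucs) >= 0))
  expect_lt(abs(aucs[1] - 0.5), 0.15)  # no effect, no discrimination
})
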