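test_that("expression filter requires the floor in at least one group", {
  g <- rep(c("LOW", "MID+"), each = 10)
  base <- matrix(1, 3, 20, dimnames = list(c("allLow", "sixty", "high"),
                                           sprintf("s%02d", 1:20)))
  base["allLow", ] <- c(rep(0.02, 10), rep(0.001, 10))
  base["sixty", ] <- c(rep(0.02, 6), rep(0.001, 4),
                       rep(0.02, 6), rep(0.001, 4))
  bes <- makeBes(base, unit = "RPKM",
                 groups = rep(c("LOW", "MID"), each = 10))
  kept <- expressionFilter(bes, groups = g)
  expect_true("allLow" %in% kept)   # 100% of LOW above floor
  expect_false("sixty" %in% kept)   # only 60% in each group
  expect_true("high" %in% kept)

  all_hi <- makeBes(matrix(1, 4, 20), unit = "RPKM")
  expect_identical(expressionFilter(all_hi, groups = g),
                   rownames(all_hi))
})

test_that("the per-transcript test matches Welch oracles", {
  # identical group values: p = 1, fold = 1, t = 0
  m <- rbind(flat = rep(c(1, 2, 3), 4))
  bes <- makeBes(m, unit = "RPKM")
  ids <- colnames(bes)
  deg <- degTest(bes, ids[1:6], ids[7:12], onLog = FALSE)
  expect_equal(deg$p, 1)
  expect_equal(deg$t, 0)
  expect_equal(deg$fold, 1)

  # hand-computed equal-variance case: |t| = 10 / sqrt(8/3)
  m2 <- rbind(t1 = c(10, 12, 14, 20, 22, 24))
  bes2 <- makeBes(m2, unit = "RPKM")
  deg2 <- degTest(bes2, colnames(bes2)[1:3], colnames(bes2)[4:6],
                  onLog = FALSE)
  expect_equal(abs(deg2$t), 6.124, tolerance = 1e-3)

  # random matrices against stats::t.test and Welch one-way ANOVA (F = t^2)
  set.seed(21)
  x <- matrix(rnorm(25 * 14, 5, 1), 25, 14,
              dimnames = list(sprintf("t%02d", 1:25), sprintf("s%02d", 1:14)))
  besr <- makeBes(x, unit = "RPKM")
  selA <- colnames(x)[1:6]; selB <- colnames(x)[7:14]
  deg3 <- degTest(besr, selA, selB, onLog = FALSE)
  g <- factor(rep(c("A", "B"), c(6, 8)))
  for (i in seq_len(25)) {
    tt <- t.test(x[i, 1:6], x[i, 7:14])
    expect_equal(deg3$t[i], unname(tt$statistic), tolerance = 1e-9)
    expect_equal(deg3$p[i], tt$p.value, tolerance = 1e-9)
    fw <- oneway.test(x[i, ] ~ g, var.equal = FALSE)
    expect_equal(deg3$t[i]^2, unname(fw$statistic), tolerance = 1e-9)
  }

  expect_error(degTest(besr, selA[1], selB), "at least 2")
})

test_that("volcano selection applies both thresholds with direction", {
  deg <- data.frame(transcript_id = c("a", "b", "c", "d"),
                    p = c(0.0009, 0.0009, 0.1, 0.0001),
                    fold = c(-1.6, -1.4, -9, 2.1))
  sel <- volcanoSelect(deg, 0.001, 1.5)
  expect_setequal(sel$transcript_id, c("a", "d"))
  expect_identical(sel$direction[sel$transcript_id == "a"], "down")
  expect_identical(sel$direction[sel$transcript_id == "d"], "up")
  expect_error(volcanoSelect(deg, 0, 1.5), "thresholds")
})

test_that("parent-list reduction applies percentile then fold decrease", {
  deg <- data.frame(
    transcript_id = c("lowexp", "kept", "border"),
    p = c(1e-5, 1e-5, 1e-5),
    fold = c(-2.0, -1.41, -1.39),
    pct_rank_A = c(0, 60, 60), pct_rank_B = c(0, 60, 60))
  pl <- parentList(deg, percentileCut = 20, parentFc = 1.4)
  expect_false("lowexp" %in% pl$percentile_ids)  # at the group minimum
  expect_identical(pl$parent_ids, "kept")        # -1.41 kept, -1.39 dropped
  expect_error(parentList(deg, percentileCut = 100), "percentileCut")
})

test_that("cascade stage counts are monotone non-increasing across seeds", {
  for (sd in 1:10) {
    spec <- MixtureSpec(nLow = 10L, nMid = 10L, nTrac = 8L,
                        markersPerType = 3L, librarySizeMean = 5e4,
                        seed = sd)
    sim <- simulateCohort(buildProfiles(500, spec), spec)
    cas <- degCascade(rpkm(cohortExprs(sim)))
    counts <- colSums(cas[, c("pass_filter", "pass_p", "pass_percentile",
                              "pass_parent")])
    expect_true(all(diff(counts) <= 0))
    # nesting: each stage implies the previous
    expect_true(all(cas$pass_p <= cas$pass_filter))
    expect_true(all(cas$pass_percentile <= cas$pass_p))
    expect_true(all(cas$pass_parent <= cas$pass_percentile))
  }
})

test_that("covariate lists reuse the DEG machinery and restrict correctly", {
  fix <- defaultCohort()
  r <- fix$rpkm
  keep <- expressionFilter(r)

  # a covariate identical to the CAD split recovers the volcano selection
  info <- sampleInfo(r)
  r2 <- r
  SummarizedExperiment::colData(r2)$disease <-
    ifelse(isMidPlus(info$group), "b_mid", "a_low")
  cfg <- analysisConfig()
  cfg$covariate_p <- cfg$deg_p
  cfg$covariate_fc <- cfg$deg_fc
  cl <- covariateList(r2[keep, ], "disease", restrictToLow = FALSE,
                      config = cfg)
  ref <- volcanoSelect(degTest(r2[keep, ], "MID+", "LOW"),
                       cfg$deg_p, cfg$deg_fc)
  expect_setequal(cl$ids, ref$transcript_id)

  # age is dichotomized at 60 and analyzed in LOW samples only
  ageList <- covariateList(r[keep, ], "age")
  expect_identical(ageList$n_samples, sum(info$group == "LOW"))
  expect_true(all(grepl("60", ageList$levels)))

  # a random covariate on null data overlaps the TRAC set at chance level
  nullFix <- nullCohort()
  rn <- nullFix$rpkm
  set.seed(31)
  SummarizedExperiment::colData(rn)$coin <-
    sample(c("heads", "tails"), ncol(rn), replace = TRUE)
  keepN <- expressionFilter(rn)
  fakeTrac <- sample(keepN, 50)
  cln <- covariateList(rn[keepN, ], "coin", restrictToLow = FALSE,
                       reference = fakeTrac)
  expectedOverlap <- length(cln$ids) * 50 / length(keepN)
  expect_lte(length(cln$overlap), expectedOverlap + 3 * sqrt(expectedOverlap) + 1)

  expect_error(covariateList(r, "nope"), "unknown covariate")
})

test_that("summary-statistic Welch tests reproduce printed demographics", {
  expect_equal(summaryTTest(5, 1, 10, 5, 1, 10)$t, 0)
  expect_equal(summaryTTest(5, 1, 10, 5, 1, 10)$p, 1)

  age <- summaryTTest(57.5, 1.49, 48, 62.5, 1.41, 48)
  expect_equal(round(age$p, 2), 0.02)
  bmi <- summaryTTest(34.7, 1.32, 48, 31.4, 0.97, 48)
  expect_equal(round(bmi$p, 2), 0.05)

  expect_error(summaryTTest(1, 0, 10, 2, 1, 10), "standard errors")
  expect_error(summaryTTest(1, 1, 1, 2, 1, 10), "sizes")
})

test_that("type-I error is controlled on the null cohort", {
  nullFix <- nullCohort()
  keep <- expressionFilter(nullFix$rpkm)
  deg <- degTest(nullFix$rpkm[keep, ], "MID+", "LOW")
  n <- length(keep)
  expect_lt(abs(mean(deg$p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})
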