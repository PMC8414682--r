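test_that("cell-type indices track planted depletion monotonically", {
  # three-way design: LOW 48 / MID 28 / HIGH 20, Treg 4.7 / 3.2 / 2.8%
  spec <- MixtureSpec(nLow = 48L, nMid = 28L, nHigh = 20L, seed = 4L)
  prof <- buildProfiles(2000, spec)
  sim <- simulateCohort(prof, spec)
  r <- rpkm(cohortExprs(sim))
  idx <- cellTypeIndex(r, markerGeneSets(prof))
  expect_true(idx["Treg_markers", "LOW"] > idx["Treg_markers", "MID"])
  expect_true(idx["Treg_markers", "MID"] > idx["Treg_markers", "HIGH"])

  # granulocyte markers are untouched by a Treg-only depletion (exactly so
  # in expectation, checked on the analytic truth)
  truth <- cohortTruth(sim)
  expect_equal(truth$expected_fold[truth$marker_type == "granulocyte"],
               rep(1, sum(truth$marker_type == "granulocyte")),
               tolerance = 1e-12)

  # a single-transcript set's index is that transcript's group mean
  info <- transcriptInfo(r)
  one <- GeneSet("ONE", info$gene_symbol[500])
  g <- sampleInfo(r)$group
  i1 <- cellTypeIndex(r, list(one))
  expect_equal(i1["ONE", "LOW"],
               mean(exprValues(r)[500, g == "LOW"]))

  # linearity: doubling member RPKM doubles the index
  r2 <- r
  SummarizedExperiment::assay(r2, 1L) <- exprValues(r) * 2
  expect_equal(cellTypeIndex(r2, list(one)), i1 * 2)

  expect_error(cellTypeIndex(r, list(GeneSet("GHOST", "NOSUCH"))), "GHOST")
})

test_that("overlap enrichment matches the enumeration oracle", {
  A <- GeneSet("A", letters[1:5])
  B <- GeneSet("B", letters[2:5])
  res <- overlapEnrichment(A, B, N = 10)
  expect_identical(res$overlap, 4L)
  expect_equal(res$fold, 2)
  expect_equal(res$p, 5 / 210)  # C(5,4) C(5,0) / C(10,4)

  sat <- overlapEnrichment(A, A, N = 5)
  expect_equal(sat$fold, 1)
  expect_equal(sat$p, 1)

  dis <- overlapEnrichment(GeneSet("X", c("a", "b")),
                           GeneSet("Y", c("c", "d")), N = 10)
  expect_identical(dis$overlap, 0L)
  expect_equal(dis$fold, 0)
  expect_equal(dis$p, 1)

  expect_error(overlapEnrichment(A, B, N = 4), "universe")

  # exact equivalence with brute-force enumeration over all draws, N <= 12
  set.seed(81)
  for (i in 1:12) {
    N <- sample(6:12, 1)
    sizeB <- sample(2:(N - 1), 1)
    sizeA <- sample(2:(N - 1), 1)
    universe <- sprintf("g%02d", 1:N)
    b <- universe[1:sizeB]
    a <- sample(universe, sizeA)
    k <- length(intersect(a, b))
    p <- overlapEnrichment(GeneSet("A", a), GeneSet("B", b), N)$p
    expect_equal(p, enumHyperP(N, sizeA, sizeB, k), tolerance = 1e-12)
  }
})

test_that("shuffled overlaps concentrate on the analytic expectation", {
  set.seed(91)
  universe <- sprintf("g%04d", 1:500)
  A <- sample(universe, 60)
  B0 <- sample(universe, 40)
  ks <- replicate(500, length(intersect(A, sample(universe, 40))))
  expected <- 60 * 40 / 500
  expect_lt(abs(mean(ks) - expected), 3 * sd(ks) / sqrt(500))
  expect_equal(overlapEnrichment(GeneSet("A", A), GeneSet("B", B0),
                                 500)$expected, expected)
})

test_that("symbol matching separates exact from close with rule ids", {
  m <- matchSymbols(c("FOXP1", "ELP3", "ABCD"), c("FOXP1", "ELP2", "XYZ"))
  expect_identical(m$exact, "FOXP1")
  expect_identical(nrow(m$close), 1L)
  expect_identical(m$close$symbol_a, "ELP3")
  expect_identical(m$close$rule, "trail1")

  none <- matchSymbols("ELP3", "ERP5")
  expect_length(none$exact, 0L)
  expect_identical(nrow(none$close), 0L)

  # edit distance 1 with identical alphabetic stem
  st <- matchSymbols("AB1C", "AB2C")
  expect_identical(st$close$rule, "edit1_stem")

  # exact and close are disjoint
  both <- matchSymbols(c("ELP2", "ELP3"), "ELP2")
  expect_identical(both$exact, "ELP2")
  expect_false("ELP2" %in% both$close$symbol_b)
})

test_that("marker correlation panels compute Pearson r with p-values", {
  x <- c(1, 2, 3, 4)
  bes <- makeBes(rbind(anchor = x, cor8 = c(1, 3, 2, 4), anti = rev(x)),
                 symbols = c("FOXP3", "AHRR", "PTGER3"), unit = "RPKM")
  res <- markerCorrelations(bes, "FOXP3",
                            GeneSet("P", c("FOXP3", "AHRR", "PTGER3")),
                            onLog = FALSE)
  expect_equal(res$r[res$symbol == "FOXP3"], 1)
  expect_equal(res$r[res$symbol == "AHRR"], 0.8)
  expect_equal(res$r[res$symbol == "PTGER3"], -1)
  expect_equal(res$p[res$symbol == "AHRR"],
               cor.test(x, c(1, 3, 2, 4))$p.value)

  flat <- makeBes(rbind(anchor = x, flat = rep(2, 4)),
                  symbols = c("FOXP3", "FLAT"), unit = "RPKM")
  expect_warning(rf <- markerCorrelations(flat, "FOXP3",
                                          GeneSet("P", "FLAT"),
                                          onLog = FALSE), "zero-variance")
  expect_true(is.na(rf$r))
})

test_that("Treg abundance arithmetic links reductions and folds", {
  expect_equal(tregFoldFromReduction(0), 1)
  expect_equal(tregFoldFromReduction(0.5), 2)
  expect_equal(round(tregFoldFromReduction(0.303), 2), 1.43)
  expect_equal(tregFoldFromFractions(4.7, 3.2), 1.46875)
  expect_equal(round(tregFoldFromFractions(4.7, 3.2), 2), 1.47)
  expect_equal(tregFoldFromFractions(9.4, 3.2), 2.9375)
  expect_equal(tregFoldFromFractions(3, 3), 1)

  # algebraic identity on a grid
  f1 <- seq(1, 10, by = 0.5)
  for (a in f1) for (b in seq(0.5, a, by = 0.5))
    expect_equal(tregFoldFromFractions(a, b),
                 tregFoldFromReduction((a - b) / a), tolerance = 1e-12)

  expect_error(tregFoldFromReduction(1), "reduction")
  expect_error(tregFoldFromFractions(0, 1), "> 0")
})
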