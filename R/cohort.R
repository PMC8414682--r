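## Synthetic whole-blood cohort generator: cell-type mixture model with a
## planted Treg depletion and a planted TRAC down-regulation.

.CELL_TYPES <- c("granulocyte", "monocyte", "B", "NK", "T_conv", "Treg")

## Fixed compartment layout: lymphocyte share of whole-blood RNA is
## spec@lymphFraction; within lymphocytes B and NK take fixed shares and
## T_conv absorbs whatever the Treg fraction leaves, so the lymphocyte total
## is identical across groups and only the Treg/T_conv balance shifts.
.WITHIN_LYMPH_B <- 0.15
.WITHIN_LYMPH_NK <- 0.12
.NONLYMPH_GRAN <- 0.625

#' Mean cell-type RNA fractions for a CAD group
#'
#' @param spec a [MixtureSpec-class].
#' @param group `"LOW"`, `"MID"` or `"HIGH"`.
#' @return named numeric over the six cell types, summing to 1.
#' @export
meanCellFractions <- function(spec, group = c("LOW", "MID", "HIGH")) {
  group <- match.arg(group)
  treg <- switch(group, LOW = spec@tregFracLow, MID = spec@tregFracMid,
                 HIGH = spec@tregFracHigh)
  lymph <- spec@lymphFraction
  nonlymph <- 1 - lymph
  f <- c(
    granulocyte = nonlymph * .NONLYMPH_GRAN,
    monocyte = nonlymph * (1 - .NONLYMPH_GRAN),
    B = lymph * .WITHIN_LYMPH_B,
    NK = lymph * .WITHIN_LYMPH_NK,
    T_conv = lymph * (1 - .WITHIN_LYMPH_B - .WITHIN_LYMPH_NK - treg),
    Treg = lymph * treg
  )
  f
}

## One integer seed drives independent streams for each simulation stage so
## that e.g. regenerating counts does not disturb the drawn profiles.
.stageSeed <- function(seed, stage) {
  (as.integer(seed) %% 214748364L) * 10L +
    match(stage, c("profiles", "fractions", "library", "counts",
                   "covariates"))
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Build per-cell-type expression rate profiles
#'
#' Baseline rates are drawn log-normal to span the configured dynamic range
#' (about 23 log2 units at defaults), modulated per cell type. Each cell
#' type receives `markersPerType` exclusive marker transcripts (rate zero in
#' every other type). One hemoglobin-like transcript is calibrated so that
#' its mixture RPKM sits at `dominantRpkm` (~65,000 at defaults), and
#' `nTrac` mid-to-high expressed non-marker transcripts are designated as
#' the planted TRAC set.
#'
#' @param nTranscripts number of transcripts to simulate.
#' @param spec a [MixtureSpec-class].
#' @return A [CellProfiles-class] object.
#' @export
buildProfiles <- function(nTranscripts, spec = MixtureSpec()) {
  nMarkers <- spec@markersPerType * length(.CELL_TYPES)
  if (nTranscripts < nMarkers + spec@nTrac + 10L)
    stop(sprintf(
      "nTranscripts = %d cannot host %d markers plus %d TRACs",
      nTranscripts, nMarkers, spec@nTrac))
  set.seed(.stageSeed(spec@seed, "profiles"))
  n <- as.integer(nTranscripts)
  ids <- sprintf("t%05d", seq_len(n))
  symbols <- sprintf("SYN%05d", seq_len(n))
  lengths <- as.integer(round(stats::runif(n, 500, 10000)))

  ## shared baseline spanning the dynamic range, then cell-type modulation
  base <- 2^stats::rnorm(n, mean = 0, sd = spec@dynamicRangeLog2 / 6.5)
  rates <- vapply(.CELL_TYPES,
                  function(ct) base * 2^stats::rnorm(n, 0, 1),
                  numeric(n))
  dimnames(rates) <- list(ids, .CELL_TYPES)

  ## exclusive markers, in rate units well above the baseline median
  markerIdx <- seq_len(nMarkers)
  exclusivity <- character(0)
  medBase <- stats::median(base)
  for (k in seq_along(.CELL_TYPES)) {
    ct <- .CELL_TYPES[k]
    rows <- markerIdx[((k - 1) * spec@markersPerType + 1):(k * spec@markersPerType)]
    rates[rows, ] <- 0
    rates[rows, ct] <- medBase * 2^stats::runif(length(rows), 3, 7)
    symbols[rows] <- sprintf("%sMK%02d", gsub("_", "", toupper(ct)),
                             seq_along(rows))
    ex <- rep(ct, length(rows))
    names(ex) <- ids[rows]
    exclusivity <- c(exclusivity, ex)
  }

  ## hemoglobin-like dominant transcript: equal rate in every cell type so
  ## the anchor holds in all groups; calibrated against LOW mean fractions
  domRow <- nMarkers + 1L
  lengths[domRow] <- 600L
  symbols[domRow] <- "HBB_SYN"
  fLow <- meanCellFractions(spec, "LOW")
  aOther <- as.vector(rates %*% fLow)
  aOther[domRow] <- 0
  S <- sum(aOther * lengths)
  R <- spec@dominantRpkm
  aDom <- R * S / (1e9 - R * lengths[domRow])
  if (aDom <= 0) stop("dominantRpkm is unattainably high")
  rates[domRow, ] <- aDom

  ## planted TRACs: non-marker, non-dominant transcripts that are reliably
  ## quantified at the configured depth (expected count >= 25) but below
  ## the extreme top of the distribution -- biomarker-grade transcripts,
  ## mirroring the parent-list requirement of mid-to-high expression
  a <- as.vector(rates %*% fLow)
  expCount <- spec@librarySizeMean * (a * lengths) / sum(a * lengths)
  eligible <- setdiff(seq_len(n), c(markerIdx, domRow))
  hi <- stats::quantile(a[eligible], 0.92)
  pool <- eligible[expCount[eligible] >= 25 & a[eligible] <= hi]
  if (length(pool) < spec@nTrac)
    stop("too few quantifiable transcripts to host the planted TRAC set; ",
         "increase nTranscripts or librarySizeMean")
  tracRows <- sort(sample(pool, spec@nTrac))
  symbols[tracRows] <- sprintf("TRAC%02d", seq_along(tracRows))

  new("CellProfiles", rates = rates, exclusivity = exclusivity,
      lengths = lengths, symbols = symbols,
      tracIds = ids[tracRows], dominantId = ids[domRow])
}

#' Marker and TRAC gene sets of a profile set
#'
#' @param profiles a [CellProfiles-class].
#' @return [markerGeneSets()]: named list of [GeneSet-class], one per cell
#'   type with exclusive markers; [tracGeneSet()]: the planted TRAC set.
#' @export
markerGeneSets <- function(profiles) {
  byType <- split(names(profiles@exclusivity), profiles@exclusivity)
  sets <- lapply(names(byType), function(ct) {
    syms <- profiles@symbols[match(byType[[ct]], rownames(profiles@rates))]
    GeneSet(paste0(ct, "_markers"), syms,
            description = "exclusive cell-type markers")
  })
  names(sets) <- names(byType)
  sets
}

#' @rdname markerGeneSets
#' @export
tracGeneSet <- function(profiles) {
  syms <- profiles@symbols[match(profiles@tracIds, rownames(profiles@rates))]
  GeneSet("TRAC_planted", syms, description = "planted TRAC transcripts")
}

.groupLabels <- function(spec) {
  rep(c("LOW", "MID", "HIGH"), times = c(spec@nLow, spec@nMid, spec@nHigh))
}

## analytic mixture abundance per transcript for one group's mean fractions,
## including the planted TRAC multiplier
.groupAbundance <- function(profiles, spec, group) {
  a <- as.vector(profiles@rates %*% meanCellFractions(spec, group))
  if (group %in% c("MID", "HIGH")) {
    idx <- match(profiles@tracIds, rownames(profiles@rates))
    a[idx] <- a[idx] / spec@tracFold
  }
  a
}

#' Analytic expected group fold change (LOW over MID+)
#'
#' The expected transcript abundance in a group is the fraction-weighted sum
#' of cell-type rates (times the planted TRAC multiplier where it applies);
#' the expected fold is LOW abundance over the sample-size-weighted MID+
#' abundance. A Treg-exclusive marker at the default 4.7\%/3.2\% fractions
#' has fold 0.047/0.032 = 1.46875.
#'
#' @param profiles a [CellProfiles-class].
#' @param spec the [MixtureSpec-class] used.
#' @param transcript transcript id(s); default all.
#' @return numeric vector of expected folds (> 0), named by transcript id.
#' @export
expectedFold <- function(profiles, spec, transcript = NULL) {
  ids <- rownames(profiles@rates)
  aLow <- .groupAbundance(profiles, spec, "LOW")
  aMid <- .groupAbundance(profiles, spec, "MID")
  if (spec@nHigh > 0L) {
    aHigh <- .groupAbundance(profiles, spec, "HIGH")
    aMid <- (spec@nMid * aMid + spec@nHigh * aHigh) / (spec@nMid + spec@nHigh)
  }
  fold <- aLow / aMid
  names(fold) <- ids
  if (is.null(transcript)) return(fold)
  miss <- setdiff(transcript, ids)
  if (length(miss))
    stop("unknown transcript: ", paste(utils::head(miss, 5), collapse = ", "))
  fold[transcript]
}

#' Simulate a whole-blood RNA-seq cohort from cell-type profiles
#'
#' Per sample: cell fractions are drawn Dirichlet around the group means
#' (precision `fractionDispersion`); expected transcript abundance is the
#' fraction-weighted sum of cell-type rates, with the planted TRAC
#' multiplier applied in MID and HIGH samples; the abundance-times-length
#' mass shares are scaled to a log-normally drawn library size and counts
#' are drawn negative-binomial (size `countDispersion`). Clinical
#' covariates (age, sex, BMI, risk-factor flags) are drawn per group from a
#' whole-blood CAD cohort-like model. Fully reproducible from `spec@seed`
#' through split random streams.
#'
#' @param profiles a [CellProfiles-class] from [buildProfiles()].
#' @param spec the same [MixtureSpec-class] used to build the profiles.
#' @return A [SimulatedCohort-class]: counts as a [BloodExprSet-class] with
#'   transcript/sample annotation, the analytic truth table, and true
#'   per-sample cell fractions.
#' @examples
#' spec <- MixtureSpec(nLow = 4L, nMid = 4L, nTrac = 5L,
#'                     markersPerType = 2L, librarySizeMean = 1e4)
#' prof <- buildProfiles(200, spec)
#' sim <- simulateCohort(prof, spec)
#' sim
#' @export
simulateCohort <- function(profiles, spec = MixtureSpec()) {
  groups <- .groupLabels(spec)
  nS <- length(groups)
  nT <- nrow(profiles@rates)
  ids <- rownames(profiles@rates)
  sampleIds <- sprintf("S%03d", seq_len(nS))

  set.seed(.stageSeed(spec@seed, "fractions"))
  fractions <- matrix(NA_real_, nS, length(.CELL_TYPES),
                      dimnames = list(sampleIds, .CELL_TYPES))
  for (g in unique(groups)) {
    sel <- groups == g
    alpha <- meanCellFractions(spec, g) * spec@fractionDispersion
    fractions[sel, ] <- .rdirichlet(sum(sel), alpha)
  }

  set.seed(.stageSeed(spec@seed, "library"))
  sigma <- sqrt(log(1 + spec@librarySizeCV^2))
  libSize <- round(stats::rlnorm(nS, log(spec@librarySizeMean) - sigma^2 / 2,
                                 sigma))
  libSize <- pmax(libSize, 1)

  ## expected abundance and mass shares
  A <- profiles@rates %*% t(fractions)              # transcripts x samples
  tracIdx <- match(profiles@tracIds, ids)
  midplus <- isMidPlus(groups)
  if (length(tracIdx) && any(midplus))
    A[tracIdx, midplus] <- A[tracIdx, midplus] / spec@tracFold
  W <- A * profiles@lengths
  W <- sweep(W, 2L, colSums(W), "/")
  mu <- sweep(W, 2L, libSize, "*")

  set.seed(.stageSeed(spec@seed, "counts"))
  counts <- matrix(stats::rnbinom(nT * nS, mu = mu,
                                  size = spec@countDispersion),
                   nT, nS, dimnames = list(ids, sampleIds))

  samples <- .simulateCovariates(spec, groups, sampleIds)
  samples$total_mapped_reads <- libSize

  transcripts <- data.frame(
    transcript_id = ids, gene_symbol = profiles@symbols,
    length_bp = profiles@lengths, stringsAsFactors = FALSE)

  markerType <- rep("", nT)
  markerType[match(names(profiles@exclusivity), ids)] <- profiles@exclusivity
  truth <- data.frame(
    transcript_id = ids, gene_symbol = profiles@symbols,
    expected_fold = unname(expectedFold(profiles, spec)),
    planted_trac = ids %in% profiles@tracIds,
    marker_type = markerType, stringsAsFactors = FALSE)

  bes <- BloodExprSet(counts, transcripts = transcripts, samples = samples,
                      unit = "counts")
  ## expected counts (for exact sampling-error checks on the count sums)
  S4Vectors::metadata(bes)$expected_counts <- mu
  new("SimulatedCohort", exprs = bes, truth = truth, fractions = fractions)
}

## Group-conditional clinical covariates loosely following a stable-CAD
## catheterization cohort: MID+ patients older, more often male, leaner,
## more medicated. Values are generator color, not analysis targets.
.simulateCovariates <- function(spec, groups, sampleIds) {
  set.seed(.stageSeed(spec@seed, "covariates"))
  n <- length(groups)
  mid <- isMidPlus(groups)
  rb <- function(pLow, pMid) stats::rbinom(n, 1, ifelse(mid, pMid, pLow))
  data.frame(
    sample_id = sampleIds,
    group = groups,
    age = round(stats::rnorm(n, ifelse(mid, 62.5, 57.5), 10.2)),
    sex = ifelse(rb(0.458, 0.562) == 1, "M", "F"),
    bmi = round(stats::rnorm(n, ifelse(mid, 31.4, 34.7), 7.5), 1),
    smoking = rb(0.083, 0.146),
    hypertension = rb(0.708, 0.750),
    dyslipidemia = rb(0.583, 0.708),
    diabetes = rb(0.354, 0.333),
    aspirin = rb(0.521, 0.625),
    family_history = rb(0.30, 0.35),
    symptom_type = sample(c("typical", "atypical", "noncardiac"), n,
                          replace = TRUE, prob = c(0.4, 0.35, 0.25)),
    stringsAsFactors = FALSE)
}
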