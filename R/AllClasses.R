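#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

.EXPR_UNITS <- c("counts", "RPKM", "log2RPKM")

#' BloodExprSet: a transcripts x samples expression container
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] carrying a
#' single expression assay plus the unit it is expressed in (`counts`,
#' `RPKM` or `log2RPKM`). Row metadata holds the transcript annotation
#' (gene symbol, transcript length in bases); column metadata holds the
#' sample annotation (CAD group, total mapped reads, clinical covariates).
#'
#' @slot unit character(1), one of `"counts"`, `"RPKM"`, `"log2RPKM"`.
#' @export
setClass("BloodExprSet",
  contains = "SummarizedExperiment",
  representation(unit = "character"),
  prototype(unit = "counts")
)

setValidity("BloodExprSet", function(object) {
  msg <- NULL
  if (length(object@unit) != 1L || !object@unit %in% .EXPR_UNITS)
    msg <- c(msg, sprintf("'unit' must be one of %s",
                          paste(.EXPR_UNITS, collapse = ", ")))
  if (length(SummarizedExperiment::assays(object)) < 1L)
    return(c(msg, "one assay is required"))
  x <- SummarizedExperiment::assay(object, 1L)
  if (length(object@unit) == 1L && object@unit %in% c("counts", "RPKM") &&
      any(x < 0, na.rm = TRUE))
    msg <- c(msg, sprintf("negative values not allowed for unit '%s'",
                          object@unit))
  rn <- rownames(object)
  cn <- colnames(object)
  if (is.null(rn) || anyDuplicated(rn))
    msg <- c(msg, "row (transcript) names must be present and unique")
  if (is.null(cn) || anyDuplicated(cn))
    msg <- c(msg, "column (sample) names must be present and unique")
  if (is.null(msg)) TRUE else msg
})

#' Construct a BloodExprSet
#'
#' @param values numeric matrix, transcripts in rows, samples in columns.
#'   Row and column names are required (transcript and sample ids).
#' @param transcripts optional data.frame of transcript annotation with
#'   columns `transcript_id`, `gene_symbol`, `length_bp`; matched to rows by
#'   `transcript_id`.
#' @param samples optional data.frame of sample annotation with column
#'   `sample_id` plus e.g. `group`, `total_mapped_reads` and clinical
#'   covariates; matched to columns by `sample_id`.
#' @param unit expression unit of `values`.
#' @return A [BloodExprSet-class] object.
#' @examples
#' m <- matrix(1:4, 2, dimnames = list(c("t1", "t2"), c("s1", "s2")))
#' bes <- BloodExprSet(m)
#' exprUnit(bes)
#' @export
BloodExprSet <- function(values, transcripts = NULL, samples = NULL,
                         unit = c("counts", "RPKM", "log2RPKM")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (nrow(values) == 0L) stop("no transcripts in expression matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs transcript row names and sample column names")
  rd <- S4Vectors::DataFrame(row.names = rownames(values))
  if (!is.null(transcripts)) {
    transcripts <- as.data.frame(transcripts)
    if (anyDuplicated(transcripts$transcript_id))
      stop("duplicate transcript_id in transcript table")
    idx <- match(rownames(values), transcripts$transcript_id)
    if (anyNA(idx))
      stop("transcript table is missing ids: ",
           paste(utils::head(rownames(values)[is.na(idx)], 5), collapse = ", "))
    rd <- S4Vectors::DataFrame(transcripts[idx, , drop = FALSE],
                               row.names = rownames(values))
    if (!is.null(rd$length_bp) && any(rd$length_bp < 1))
      stop("transcript length_bp must be >= 1")
  }
  cd <- S4Vectors::DataFrame(row.names = colnames(values))
  if (!is.null(samples)) {
    samples <- as.data.frame(samples)
    idx <- match(colnames(values), samples$sample_id)
    if (anyNA(idx))
      stop("sample table is missing ids: ",
           paste(utils::head(colnames(values)[is.na(idx)], 5), collapse = ", "))
    cd <- S4Vectors::DataFrame(samples[idx, , drop = FALSE],
                               row.names = colnames(values))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values), rowData = rd, colData = cd)
  new("BloodExprSet", se, unit = unit)
}

#' GeneSet: a named collection of gene symbols
#'
#' Gene symbols are upper-cased and whitespace-stripped on construction;
#' duplicates are removed. Used for marker panels (e.g. the 7-transcript
#' Treg-related diagnostic panel), stress-granule transcript lists and
#' cell-type marker sets.
#'
#' @slot name character(1) set name.
#' @slot description character(1) free-text description.
#' @slot members character vector of unique upper-case gene symbols.
#' @export
setClass("GeneSet",
  representation(name = "character", description = "character",
                 members = "character")
)

setValidity("GeneSet", function(object) {
  msg <- NULL
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a non-empty string")
  if (length(object@members) == 0L)
    msg <- c(msg, "'members' must be non-empty")
  if (anyDuplicated(object@members))
    msg <- c(msg, "'members' must be unique")
  if (any(object@members != toupper(trimws(object@members))))
    msg <- c(msg, "'members' must be upper-cased, trimmed symbols")
  if (is.null(msg)) TRUE else msg
})

#' @param name set name.
#' @param members character vector of gene symbols (normalized on input).
#' @param description free-text description.
#' @rdname GeneSet-class
#' @examples
#' gs <- GeneSet("TREG7", c("DGKA", "DLG1", "ICOSLG", "IKZF4", "SMYD3",
#'                          "TCF3", "TRIM28"))
#' geneSetSize(gs)
#' @export
GeneSet <- function(name, members, description = "") {
  members <- toupper(trimws(as.character(members)))
  members <- unique(members[nzchar(members)])
  new("GeneSet", name = as.character(name),
      description = as.character(description), members = members)
}

#' MixtureSpec: truth object for the synthetic whole-blood cohort
#'
#' Describes the cell-mixture model generating a cohort: group sizes, the
#' RNA-mass fraction contributed by each blood cell type per CAD group, the
#' Treg share of the lymphocyte compartment per group, planted
#' transcript-level effects, sequencing depth and counting noise.
#'
#' @slot nLow,nMid,nHigh integer samples per CAD group (MID+ = MID and HIGH).
#' @slot tregFracLow,tregFracMid,tregFracHigh Treg fraction of the
#'   lymphocyte RNA compartment per group.
#' @slot lymphFraction lymphocyte share of whole-blood informative RNA.
#' @slot fractionDispersion Dirichlet precision for per-sample cell
#'   fractions (larger = less between-patient variation).
#' @slot tracFold planted fold-change (down in MID+) for the TRAC set.
#' @slot nTrac number of planted TRAC transcripts.
#' @slot markersPerType exclusive marker transcripts per cell type.
#' @slot librarySizeMean,librarySizeCV mean and CV of per-sample informative
#'   read counts.
#' @slot dominantRpkm target RPKM of the hemoglobin-like dominant transcript.
#' @slot dynamicRangeLog2 target log2 span of baseline expression rates.
#' @slot countDispersion negative-binomial size parameter for counts.
#' @slot seed integer seed driving the generator's split random streams.
#' @export
setClass("MixtureSpec",
  representation(
    nLow = "integer", nMid = "integer", nHigh = "integer",
    tregFracLow = "numeric", tregFracMid = "numeric", tregFracHigh = "numeric",
    lymphFraction = "numeric", fractionDispersion = "numeric",
    tracFold = "numeric", nTrac = "integer", markersPerType = "integer",
    librarySizeMean = "numeric", librarySizeCV = "numeric",
    dominantRpkm = "numeric", dynamicRangeLog2 = "numeric",
    countDispersion = "numeric", seed = "integer"
  )
)

setValidity("MixtureSpec", function(object) {
  msg <- NULL
  if (object@nLow < 1L || object@nMid < 1L || object@nHigh < 0L)
    msg <- c(msg, "need nLow >= 1, nMid >= 1, nHigh >= 0")
  fr <- c(object@tregFracLow, object@tregFracMid, object@tregFracHigh,
          object@lymphFraction)
  if (any(fr <= 0) || any(fr >= 1))
    msg <- c(msg, "cell fractions must lie strictly in (0, 1)")
  if (object@fractionDispersion <= 0)
    msg <- c(msg, "fractionDispersion must be > 0")
  if (object@countDispersion <= 0)
    msg <- c(msg, "countDispersion must be > 0")
  if (object@tracFold <= 0) msg <- c(msg, "tracFold must be > 0")
  if (object@librarySizeMean < 1) msg <- c(msg, "librarySizeMean must be >= 1")
  for (g in c("Low", "Mid", "High")) {
    f <- meanCellFractions(object, toupper(g))
    if (abs(sum(f) - 1) > 1e-9)
      msg <- c(msg, sprintf("%s group cell fractions do not sum to 1", g))
  }
  if (is.null(msg)) TRUE else msg
})

#' @param nLow,nMid,nHigh samples per group (defaults 48/48/0: a two-group
#'   48 vs 48 design with all non-LOW samples labelled MID).
#' @param tregFracLow,tregFracMid,tregFracHigh Treg fraction of lymphocytes
#'   per group (defaults 4.7\%, 3.2\%, 2.8\%).
#' @param lymphFraction lymphocyte share of whole-blood RNA (default 0.52).
#' @param fractionDispersion Dirichlet precision (default 200).
#' @param tracFold planted TRAC fold, down in MID+ (default 1.7).
#' @param nTrac planted TRAC transcripts (default 40).
#' @param markersPerType exclusive markers per cell type (default 12).
#' @param librarySizeMean,librarySizeCV depth model (defaults 2e5 reads,
#'   30\% CV; set librarySizeMean = 5e6 for full-scale cohorts).
#' @param dominantRpkm hemoglobin-like anchor RPKM (default 65000).
#' @param dynamicRangeLog2 log2 span of baseline rates (default 23).
#' @param countDispersion negative-binomial size (default 10).
#' @param seed integer seed (default 1).
#' @rdname MixtureSpec-class
#' @export
MixtureSpec <- function(nLow = 48L, nMid = 48L, nHigh = 0L,
                        tregFracLow = 0.047, tregFracMid = 0.032,
                        tregFracHigh = 0.028, lymphFraction = 0.52,
                        fractionDispersion = 200, tracFold = 1.7,
                        nTrac = 40L, markersPerType = 12L,
                        librarySizeMean = 2e5, librarySizeCV = 0.30,
                        dominantRpkm = 65000, dynamicRangeLog2 = 23,
                        countDispersion = 10, seed = 1L) {
  new("MixtureSpec",
      nLow = as.integer(nLow), nMid = as.integer(nMid),
      nHigh = as.integer(nHigh),
      tregFracLow = tregFracLow, tregFracMid = tregFracMid,
      tregFracHigh = tregFracHigh, lymphFraction = lymphFraction,
      fractionDispersion = fractionDispersion, tracFold = tracFold,
      nTrac = as.integer(nTrac), markersPerType = as.integer(markersPerType),
      librarySizeMean = librarySizeMean, librarySizeCV = librarySizeCV,
      dominantRpkm = dominantRpkm, dynamicRangeLog2 = dynamicRangeLog2,
      countDispersion = countDispersion, seed = as.integer(seed))
}

#' CellProfiles: per-cell-type expression rate profiles
#'
#' @slot rates matrix, transcripts x cell types, mean expression rate in
#'   arbitrary transcripts-per-cell-RNA units; an exclusive marker has rate
#'   zero in every other cell type.
#' @slot exclusivity named character, marker transcript id -> cell type.
#' @slot lengths integer transcript lengths (bp).
#' @slot symbols character gene symbols, parallel to rows of `rates`.
#' @slot tracIds ids of the planted TRAC transcripts.
#' @slot dominantId id of the hemoglobin-like dominant transcript.
#' @export
setClass("CellProfiles",
  representation(rates = "matrix", exclusivity = "character",
                 lengths = "integer", symbols = "character",
                 tracIds = "character", dominantId = "character")
)

setValidity("CellProfiles", function(object) {
  msg <- NULL
  if (any(object@rates < 0)) msg <- c(msg, "rates must be non-negative")
  if (length(object@lengths) != nrow(object@rates) ||
      length(object@symbols) != nrow(object@rates))
    msg <- c(msg, "lengths/symbols must parallel the rate matrix rows")
  if (any(object@lengths < 1)) msg <- c(msg, "lengths must be >= 1 bp")
  if (length(object@exclusivity)) {
    bad <- vapply(names(object@exclusivity), function(id) {
      ct <- object@exclusivity[[id]]
      any(object@rates[id, colnames(object@rates) != ct] > 0)
    }, logical(1))
    if (any(bad))
      msg <- c(msg, "exclusive markers must have rate 0 outside their cell type")
  }
  if (is.null(msg)) TRUE else msg
})

#' SimulatedCohort: a generated cohort plus its ground truth
#'
#' @slot exprs [BloodExprSet-class] of simulated counts with full transcript
#'   and sample annotation.
#' @slot truth data.frame with one row per transcript: analytic expected
#'   LOW-over-MID+ fold, whether the transcript is a planted TRAC, and its
#'   marker cell type (`""` for non-markers).
#' @slot fractions matrix of true per-sample cell-type fractions.
#' @export
setClass("SimulatedCohort",
  representation(exprs = "BloodExprSet", truth = "data.frame",
                 fractions = "matrix")
)

setValidity("SimulatedCohort", function(object) {
  msg <- NULL
  if (!identical(sort(rownames(object@exprs)),
                 sort(object@truth$transcript_id)))
    msg <- c(msg, "truth table must cover every transcript exactly once")
  if (nrow(object@fractions) != ncol(object@exprs))
    msg <- c(msg, "fractions must have one row per sample")
  if (is.null(msg)) TRUE else msg
})

#' ConfusionMatrix: binary classification counts
#'
#' @slot tp,fp,fn,tn non-negative integer cell counts.
#' @export
setClass("ConfusionMatrix",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 tn = "integer")
)

setValidity("ConfusionMatrix", function(object) {
  v <- c(object@tp, object@fp, object@fn, object@tn)
  if (any(v < 0)) "cell counts must be non-negative" else TRUE
})

#' @param tp,fp,fn,tn cell counts.
#' @rdname ConfusionMatrix-class
#' @export
ConfusionMatrix <- function(tp, fp, fn, tn) {
  new("ConfusionMatrix", tp = as.integer(round(tp)),
      fp = as.integer(round(fp)), fn = as.integer(round(fn)),
      tn = as.integer(round(tn)))
}

#' CompositeScore: per-sample composite transcript score
#'
#' Each panel transcript is expressed as a ratio to its cohort-mean
#' expression (so highly expressed transcripts are not over-represented) and
#' the per-sample score is the mean of those ratios; a cohort-average sample
#' scores 1.
#'
#' @slot score named numeric, one score per sample.
#' @slot panel the [GeneSet-class] used.
#' @slot orientation `"lower_is_disease"` or `"higher_is_disease"`.
#' @export
setClass("CompositeScore",
  representation(score = "numeric", panel = "GeneSet",
                 orientation = "character")
)

setValidity("CompositeScore", function(object) {
  if (!object@orientation %in% c("lower_is_disease", "higher_is_disease"))
    "orientation must be lower_is_disease or higher_is_disease" else TRUE
})
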