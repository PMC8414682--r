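#' @rdname BloodExprSet-class
#' @param object,x a package object.
#' @export
setGeneric("exprUnit", function(object) standardGeneric("exprUnit"))

#' @rdname BloodExprSet-class
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))

#' @rdname BloodExprSet-class
#' @export
setGeneric("transcriptInfo", function(object) standardGeneric("transcriptInfo"))

#' @rdname BloodExprSet-class
#' @export
setGeneric("sampleInfo", function(object) standardGeneric("sampleInfo"))

#' @rdname GeneSet-class
#' @export
setGeneric("geneSetName", function(object) standardGeneric("geneSetName"))

#' @rdname GeneSet-class
#' @export
setGeneric("members", function(object) standardGeneric("members"))

#' @rdname GeneSet-class
#' @export
setGeneric("geneSetSize", function(object) standardGeneric("geneSetSize"))

#' @rdname CompositeScore-class
#' @export
setGeneric("scoreValues", function(object) standardGeneric("scoreValues"))

#' @rdname CompositeScore-class
#' @export
setGeneric("scoreOrientation",
           function(object) standardGeneric("scoreOrientation"))

#' @rdname ConfusionMatrix-class
#' @export
setGeneric("confusionCounts",
           function(object) standardGeneric("confusionCounts"))

#' @rdname SimulatedCohort-class
#' @export
setGeneric("cohortExprs", function(object) standardGeneric("cohortExprs"))

#' @rdname SimulatedCohort-class
#' @export
setGeneric("cohortTruth", function(object) standardGeneric("cohortTruth"))

#' @rdname SimulatedCohort-class
#' @export
setGeneric("cohortFractions",
           function(object) standardGeneric("cohortFractions"))

#' @describeIn BloodExprSet-class unit of the expression assay.
setMethod("exprUnit", "BloodExprSet", function(object) object@unit)

#' @describeIn BloodExprSet-class the expression matrix.
setMethod("exprValues", "BloodExprSet",
          function(object) SummarizedExperiment::assay(object, 1L))

#' @describeIn BloodExprSet-class transcript annotation as a data.frame.
setMethod("transcriptInfo", "BloodExprSet", function(object)
  as.data.frame(SummarizedExperiment::rowData(object)))

#' @describeIn BloodExprSet-class sample annotation as a data.frame.
setMethod("sampleInfo", "BloodExprSet", function(object)
  as.data.frame(SummarizedExperiment::colData(object)))

setMethod("show", "BloodExprSet", function(object) {
  cat(sprintf("BloodExprSet: %d transcripts x %d samples [unit: %s]\n",
              nrow(object), ncol(object), object@unit))
  gr <- SummarizedExperiment::colData(object)$group
  if (!is.null(gr)) {
    tab <- table(factor(gr, levels = c("LOW", "MID", "HIGH")))
    cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
  }
})

#' @describeIn GeneSet-class the set name.
setMethod("geneSetName", "GeneSet", function(object) object@name)

#' @describeIn GeneSet-class the member symbols.
setMethod("members", "GeneSet", function(object) object@members)

#' @describeIn GeneSet-class number of unique member symbols.
setMethod("geneSetSize", "GeneSet", function(object) length(object@members))

setMethod("show", "GeneSet", function(object) {
  cat(sprintf("GeneSet '%s' (%d symbols): %s%s\n", object@name,
              length(object@members),
              paste(utils::head(object@members, 6), collapse = ", "),
              if (length(object@members) > 6) ", ..." else ""))
})

setMethod("show", "MixtureSpec", function(object) {
  cat(sprintf(paste0(
    "MixtureSpec: %d LOW / %d MID / %d HIGH samples\n",
    "  Treg fraction of lymphocytes: %.1f%% / %.1f%% / %.1f%%\n",
    "  planted TRACs: %d at fold %.2f (down in MID+)\n",
    "  library size: %.3g reads (CV %.0f%%), NB size %.3g\n"),
    object@nLow, object@nMid, object@nHigh,
    100 * object@tregFracLow, 100 * object@tregFracMid,
    100 * object@tregFracHigh, object@nTrac, object@tracFold,
    object@librarySizeMean, 100 * object@librarySizeCV,
    object@countDispersion))
})

setMethod("show", "CellProfiles", function(object) {
  cat(sprintf(
    "CellProfiles: %d transcripts x %d cell types, %d exclusive markers\n",
    nrow(object@rates), ncol(object@rates), length(object@exclusivity)))
})

setMethod("show", "SimulatedCohort", function(object) {
  cat("SimulatedCohort\n")
  show(object@exprs)
  cat(sprintf("  planted TRACs: %d\n", sum(object@truth$planted_trac)))
})

#' @describeIn SimulatedCohort-class the simulated counts as a BloodExprSet.
setMethod("cohortExprs", "SimulatedCohort", function(object) object@exprs)

#' @describeIn SimulatedCohort-class the per-transcript truth table.
setMethod("cohortTruth", "SimulatedCohort", function(object) object@truth)

#' @describeIn SimulatedCohort-class true per-sample cell fractions.
setMethod("cohortFractions", "SimulatedCohort",
          function(object) object@fractions)

#' @describeIn CompositeScore-class named per-sample scores.
setMethod("scoreValues", "CompositeScore", function(object) object@score)

#' @describeIn CompositeScore-class score orientation.
setMethod("scoreOrientation", "CompositeScore",
          function(object) object@orientation)

setMethod("show", "CompositeScore", function(object) {
  cat(sprintf(
    "CompositeScore on panel '%s' (%d transcripts, %s): %d samples, mean %.3f\n",
    object@panel@name, length(object@panel@members), object@orientation,
    length(object@score), mean(object@score)))
})

#' @describeIn ConfusionMatrix-class named counts (tp, fp, fn, tn).
setMethod("confusionCounts", "ConfusionMatrix", function(object)
  c(tp = object@tp, fp = object@fp, fn = object@fn, tn = object@tn))

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix: tp=%d fp=%d fn=%d tn=%d\n",
              object@tp, object@fp, object@fn, object@tn))
})
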