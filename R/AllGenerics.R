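#' @name cytonet-accessors
#' @title Accessors for cytonet classes
#' @description Slot accessors for [CytokinePanel-class],
#'   [SyntheticCohort-class], [PreprocessReport-class] and
#'   [CPCASolution-class]. Use these instead of `@`.
#' @param x a cytonet object
#' @param object a cytonet object (for `show`)
NULL

#' @rdname cytonet-accessors
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))
#' @rdname cytonet-accessors
#' @export
setMethod("concentrations", "CytokinePanel",
          function(x) assay(x, "concentrations"))
#' @rdname cytonet-accessors
#' @export
setMethod("concentrations", "SyntheticCohort",
          function(x) assay(x@panel, "concentrations"))

#' @rdname cytonet-accessors
#' @export
setGeneric("detectionLimits", function(x) standardGeneric("detectionLimits"))
#' @rdname cytonet-accessors
#' @export
setMethod("detectionLimits", "CytokinePanel",
          function(x) setNames(rowData(x)$lod, rownames(x)))

#' @rdname cytonet-accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))
#' @rdname cytonet-accessors
#' @export
setMethod("sampleGroups", "CytokinePanel",
          function(x) setNames(colData(x)$group, colnames(x)))

#' @rdname cytonet-accessors
#' @export
setGeneric("sampleCovariates", function(x) standardGeneric("sampleCovariates"))
#' @rdname cytonet-accessors
#' @export
setMethod("sampleCovariates", "CytokinePanel", function(x) {
  cd <- as.data.frame(colData(x))
  cd[, setdiff(colnames(cd), "group"), drop = FALSE]
})

#' @rdname cytonet-accessors
#' @export
setGeneric("cohortPanel", function(x) standardGeneric("cohortPanel"))
#' @rdname cytonet-accessors
#' @export
setMethod("cohortPanel", "SyntheticCohort", function(x) x@panel)

#' @rdname cytonet-accessors
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))
#' @rdname cytonet-accessors
#' @export
setMethod("cohortTruth", "SyntheticCohort", function(x) x@truth)

#' @rdname cytonet-accessors
#' @export
setGeneric("subjectScores", function(x) standardGeneric("subjectScores"))
#' @rdname cytonet-accessors
#' @export
setMethod("subjectScores", "SyntheticCohort", function(x) x@subjectScores)

#' @rdname cytonet-accessors
#' @export
setGeneric("censorMask", function(x) standardGeneric("censorMask"))
#' @rdname cytonet-accessors
#' @export
setMethod("censorMask", "SyntheticCohort", function(x) x@censorMask)

#' @rdname cytonet-accessors
#' @export
setGeneric("outlierLedger", function(x) standardGeneric("outlierLedger"))
#' @rdname cytonet-accessors
#' @export
setMethod("outlierLedger", "SyntheticCohort", function(x) x@outlierLedger)

#' @rdname cytonet-accessors
#' @export
setGeneric("excludedAnalytes", function(x) standardGeneric("excludedAnalytes"))
#' @rdname cytonet-accessors
#' @export
setMethod("excludedAnalytes", "PreprocessReport", function(x) x@excludedAnalytes)

#' @rdname cytonet-accessors
#' @export
setGeneric("undetectableFraction",
           function(x) standardGeneric("undetectableFraction"))
#' @rdname cytonet-accessors
#' @export
setMethod("undetectableFraction", "PreprocessReport",
          function(x) x@undetectableFraction)

#' @rdname cytonet-accessors
#' @export
setGeneric("winsorizedCells", function(x) standardGeneric("winsorizedCells"))
#' @rdname cytonet-accessors
#' @export
setMethod("winsorizedCells", "PreprocessReport", function(x) x@winsorizedCells)

#' @rdname cytonet-accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))
#' @rdname cytonet-accessors
#' @export
setMethod("eigenvalues", "CPCASolution", function(x) x@eigenvalues)

#' @rdname cytonet-accessors
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))
#' @rdname cytonet-accessors
#' @export
setMethod("nComponents", "CPCASolution", function(x) x@nComponents)

#' @rdname cytonet-accessors
#' @param rotated logical; return rotated (default) or unrotated loadings
#' @export
setGeneric("componentLoadings",
           function(x, rotated = TRUE) standardGeneric("componentLoadings"))
#' @rdname cytonet-accessors
#' @export
setMethod("componentLoadings", "CPCASolution", function(x, rotated = TRUE)
  if (rotated) x@loadingsRotated else x@loadingsUnrotated)

#' @rdname cytonet-accessors
#' @export
setGeneric("componentScores", function(x) standardGeneric("componentScores"))
#' @rdname cytonet-accessors
#' @export
setMethod("componentScores", "CPCASolution", function(x) x@scores)

#' @rdname cytonet-accessors
#' @export
setGeneric("groupCorrelations", function(x) standardGeneric("groupCorrelations"))
#' @rdname cytonet-accessors
#' @export
setMethod("groupCorrelations", "CPCASolution", function(x) x@groupCorrelations)

#' @rdname cytonet-accessors
#' @export
setGeneric("networkTable", function(x) standardGeneric("networkTable"))
#' @rdname cytonet-accessors
#' @export
setMethod("networkTable", "CPCASolution", function(x) x@networks)

#' @rdname cytonet-accessors
#' @export
setMethod("show", "PlantedModel", function(object) {
  cat("PlantedModel:", length(object@analyteIds), "analytes,",
      ncol(object@loadings), "planted network(s)\n")
  cat("  group sizes:", paste(sprintf("%s=%d", names(object@groupSizes),
                                      object@groupSizes), collapse = ", "), "\n")
  cat("  censored analytes (rate > 0):",
      sum(object@censorRates > 0), "| seed:", object@seed, "\n")
})

#' @rdname cytonet-accessors
#' @export
setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", ncol(object@panel), "samples x",
      nrow(object@panel), "analytes\n")
  cat("  censored cells:", sum(object@censorMask),
      "| injected outliers:", nrow(object@outlierLedger), "\n")
})

#' @rdname cytonet-accessors
#' @export
setMethod("show", "PreprocessReport", function(object) {
  cat("PreprocessReport\n")
  cat("  cells zeroed below LOD:", object@nZeroed, "\n")
  cat("  excluded analytes (undetectable fraction >",
      object@threshold, "):", length(object@excludedAnalytes), "\n")
  if (length(object@excludedAnalytes))
    cat("   ", paste(object@excludedAnalytes, collapse = ", "), "\n")
  cat("  Winsorized cells:", nrow(object@winsorizedCells), "\n")
  cat("  steps:", paste(object@transform, collapse = " -> "), "\n")
})

#' @rdname cytonet-accessors
#' @export
setMethod("show", "CPCASolution", function(object) {
  cat("CPCASolution:", object@nComponents, "component(s) retained of",
      length(object@eigenvalues), "eigenvalues\n")
  cat("  predictable variance:",
      sprintf("%.1f%% of total", object@pctVarianceOfTotal), "\n")
  if (object@nComponents > 0)
    cat("  per-component share:",
        paste(sprintf("%.1f%%", object@pctPredictableVariance), collapse = ", "),
        "\n")
  cat("  network members at |loading| >=", object@membershipThreshold, ":",
      nrow(object@networks), "\n")
})
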