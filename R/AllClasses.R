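#' CytokinePanel: a multiplex cytokine concentration panel
#'
#' S4 container for a multiplex immunoassay panel, extending
#' [SummarizedExperiment::SummarizedExperiment]. Rows are analytes, columns
#' are samples. The single assay `"concentrations"` holds concentrations in
#' pg/mL; `rowData` carries the per-analyte lower limit of detection
#' (column `lod`); `colData` carries the group label (factor with levels
#' `C/TD`, `C/ND`, `A/TD`, `A/ND`) and the covariates `smoking` (0/1),
#' `bmi` (kg/m^2), `sex` (0/1) and `age_years`.
#'
#' @slot .. see `SummarizedExperiment`; no additional slots.
#' @name CytokinePanel-class
#' @exportClass CytokinePanel
setClass("CytokinePanel", contains = "SummarizedExperiment")

setValidity("CytokinePanel", function(object) {
  msg <- character()
  if (!"concentrations" %in% assayNames(object))
    msg <- c(msg, "assay 'concentrations' is required")
  else {
    conc <- assay(object, "concentrations")
    if (anyNA(conc))
      msg <- c(msg, "concentrations contain missing cells (undetectable must be encoded as a value below LOD, not NA)")
    else if (any(conc < 0))
      msg <- c(msg, "concentrations must be >= 0")
  }
  if (!"lod" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData column 'lod' (limit of detection) is required")
  else if (any(is.na(rowData(object)$lod)) || any(rowData(object)$lod <= 0))
    msg <- c(msg, "every analyte needs a LOD > 0")
  cd <- colData(object)
  if (!"group" %in% colnames(cd))
    msg <- c(msg, "colData column 'group' is required")
  else if (!all(as.character(cd$group) %in% GROUP_LEVELS))
    msg <- c(msg, sprintf("group labels must be among: %s",
                          paste(GROUP_LEVELS, collapse = ", ")))
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "analyte ids must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a CytokinePanel
#'
#' @param concentrations numeric matrix, analytes x samples (pg/mL). A
#'   samples x analytes matrix is transposed automatically when its
#'   dimnames make the orientation unambiguous.
#' @param lod named numeric vector of per-analyte limits of detection
#'   (pg/mL), in row order of `concentrations` when unnamed.
#' @param group character or factor of per-sample group labels among
#'   `C/TD`, `C/ND`, `A/TD`, `A/ND`.
#' @param covariates data.frame with per-sample columns `smoking`, `bmi`,
#'   `sex`, `age_years` (may be NULL for design-only work; regression
#'   requires them).
#' @return a [CytokinePanel-class] object.
#' @examples
#' m <- matrix(rlnorm(40), 4, 10,
#'             dimnames = list(paste0("an", 1:4), paste0("s", 1:10)))
#' CytokinePanel(m, lod = rep(0.1, 4),
#'               group = rep(c("C/TD", "C/ND", "A/TD", "A/ND"), length.out = 10))
#' @export
CytokinePanel <- function(concentrations, lod, group, covariates = NULL) {
  concentrations <- as.matrix(concentrations)
  if (is.null(rownames(concentrations)))
    rownames(concentrations) <- paste0("analyte", seq_len(nrow(concentrations)))
  if (is.null(colnames(concentrations)))
    colnames(concentrations) <- paste0("sample", seq_len(ncol(concentrations)))
  if (length(group) != ncol(concentrations) &&
      length(group) == nrow(concentrations)) {
    concentrations <- t(concentrations)  # given samples x analytes
  }
  group <- factor(as.character(group), levels = GROUP_LEVELS)
  if (is.null(names(lod))) names(lod) <- rownames(concentrations)
  lod <- lod[rownames(concentrations)]
  cd <- DataFrame(group = group, row.names = colnames(concentrations))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (v in colnames(covariates)) cd[[v]] <- covariates[[v]]
  }
  se <- SummarizedExperiment(
    assays = list(concentrations = concentrations),
    rowData = DataFrame(lod = as.numeric(lod), row.names = rownames(concentrations)),
    colData = cd)
  new("CytokinePanel", se)
}

#' PlantedModel: ground truth for synthetic cohort generation
#'
#' Defines K latent cytokine networks (columns of `loadings`), signed
#' per-group network activations, subject- and analyte-level noise, the
#' lognormal back-transform to the concentration scale, per-analyte LOD
#' censoring rates and an outlier rate. [generateCohort()] turns it into a
#' [SyntheticCohort-class].
#'
#' @slot analyteIds character, analyte names (length = number of analytes).
#' @slot groupSizes named integer, samples per group in canonical order.
#' @slot loadings analytes x K numeric matrix of planted network weights.
#' @slot groupActivations groups x K numeric matrix of signed network means.
#' @slot subjectScoreSD numeric > 0, SD of subject scores about their
#'   group activation.
#' @slot analyteNoiseSD per-analyte numeric > 0, SD of analyte-level noise.
#' @slot logScaleMu,logScaleSigma per-analyte lognormal location/scale for
#'   the latent-to-concentration back-transform.
#' @slot lod per-analyte limit of detection (pg/mL).
#' @slot censorRates per-analyte fraction in [0, 1) of samples forced
#'   below LOD by [applyDetectionCensoring()].
#' @slot outlierRate fraction in [0, 1) of cells displaced by
#'   [injectOutliers()].
#' @slot covariateConfounding numeric >= 0; 0 keeps covariates independent
#'   of the planted scores.
#' @slot seed integer RNG seed; generation is bit-reproducible given it.
#' @name PlantedModel-class
#' @exportClass PlantedModel
setClass("PlantedModel", representation(
  analyteIds = "character",
  groupSizes = "integer",
  loadings = "matrix",
  groupActivations = "matrix",
  subjectScoreSD = "numeric",
  analyteNoiseSD = "numeric",
  logScaleMu = "numeric",
  logScaleSigma = "numeric",
  lod = "numeric",
  censorRates = "numeric",
  outlierRate = "numeric",
  covariateConfounding = "numeric",
  seed = "integer"))

setValidity("PlantedModel", function(object) {
  msg <- character()
  p <- length(object@analyteIds)
  K <- ncol(object@loadings)
  if (anyDuplicated(object@analyteIds)) msg <- c(msg, "analyte ids must be unique")
  if (length(object@groupSizes) != length(GROUP_LEVELS) ||
      !identical(names(object@groupSizes), GROUP_LEVELS))
    msg <- c(msg, "groupSizes must be named with the four canonical groups")
  if (any(object@groupSizes < 2L)) msg <- c(msg, "all group sizes must be >= 2")
  if (nrow(object@loadings) != p) msg <- c(msg, "loadings must have one row per analyte")
  if (K >= 1 && any(colSums(abs(object@loadings)) == 0))
    msg <- c(msg, "no planted network column may be all-zero")
  if (!identical(dim(object@groupActivations), c(length(GROUP_LEVELS), K)))
    msg <- c(msg, "groupActivations must be groups x K, conformable with loadings")
  if (object@subjectScoreSD < 0) msg <- c(msg, "subjectScoreSD must be >= 0")
  for (nm in c("analyteNoiseSD", "logScaleMu", "logScaleSigma", "lod", "censorRates"))
    if (length(slot(object, nm)) != p)
      msg <- c(msg, sprintf("%s must have one entry per analyte", nm))
  if (any(object@lod <= 0)) msg <- c(msg, "LODs must be > 0")
  if (any(object@censorRates < 0 | object@censorRates >= 1))
    msg <- c(msg, "censorRates must lie in [0, 1) for every analyte")
  if (object@outlierRate < 0 || object@outlierRate >= 1)
    msg <- c(msg, "outlierRate must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' SyntheticCohort: a generated panel plus its ground truth
#'
#' @slot panel [CytokinePanel-class] of generated concentrations.
#' @slot truth the [PlantedModel-class] that generated it.
#' @slot subjectScores samples x K matrix of latent network scores.
#' @slot censorMask logical analytes x samples matrix; TRUE where a cell
#'   was forced below its analyte's LOD.
#' @slot outlierLedger data.frame of injected outliers
#'   (sample, analyte, original, displaced).
#' @name SyntheticCohort-class
#' @exportClass SyntheticCohort
setClass("SyntheticCohort", representation(
  panel = "CytokinePanel",
  truth = "PlantedModel",
  subjectScores = "matrix",
  censorMask = "matrix",
  outlierLedger = "data.frame"))

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  n <- sum(object@truth@groupSizes)
  p <- length(object@truth@analyteIds)
  if (!identical(dim(object@panel), c(p, n)))
    msg <- c(msg, "panel dimensions must equal n_analytes x sum(groupSizes)")
  if (!identical(dim(object@censorMask), dim(assay(object@panel))))
    msg <- c(msg, "censorMask must be conformable with the panel")
  if (any(object@censorMask)) {
    conc <- assay(object@panel, "concentrations")
    lod <- rowData(object@panel)$lod
    below <- conc < matrix(lod, nrow(conc), ncol(conc))
    if (!all(below[object@censorMask]))
      msg <- c(msg, "every censored cell must lie strictly below its analyte's LOD")
  }
  if (length(msg)) msg else TRUE
})

#' PreprocessReport: ledger of preprocessing decisions
#'
#' @slot undetectableFraction named per-analyte fraction of samples at
#'   zero after below-LOD assignment.
#' @slot excludedAnalytes analytes undetectable in more than the threshold
#'   fraction of samples (strictly greater), dropped from analysis.
#' @slot threshold the exclusion threshold in force.
#' @slot nZeroed number of cells set to zero by below-LOD assignment.
#' @slot winsorizedCells data.frame (sample, analyte, original,
#'   replacement, z) of Winsorized cells.
#' @slot transform character log of the steps applied, in order.
#' @name PreprocessReport-class
#' @exportClass PreprocessReport
setClass("PreprocessReport", representation(
  undetectableFraction = "numeric",
  excludedAnalytes = "character",
  threshold = "numeric",
  nZeroed = "integer",
  winsorizedCells = "data.frame",
  transform = "character"))

#' CPCASolution: a fitted constrained PCA
#'
#' Result of [cpca()]: the group-predicted score matrix, its PCA, the
#' Varimax-rotated solution and the group-component correlation table.
#'
#' @slot predicted samples x analytes matrix of regression-predicted
#'   (group-mean) scores.
#' @slot eigenvalues all eigenvalues of the centred predicted matrix,
#'   descending.
#' @slot nComponents number of retained components K.
#' @slot loadingsUnrotated,loadingsRotated analytes x K loading matrices
#'   (eigenvector x sqrt(eigenvalue) scaling).
#' @slot rotation K x K orthogonal Varimax rotation matrix.
#' @slot scores samples x K rotated component scores, unit variance.
#' @slot pctPredictableVariance per-component percent of the predictable
#'   (between-group) variance carried by each rotated component.
#' @slot totalPredictableVariance trace of the covariance of the centred
#'   predicted matrix.
#' @slot pctVarianceOfTotal percent of the total (Blom-scale) cytokine
#'   variance that is predictable from group membership.
#' @slot groupCorrelations data.frame (group, component, r, p) of Pearson
#'   correlations between group indicators and component scores.
#' @slot networks data.frame (component, analyte, loading, sign) of
#'   network memberships at the threshold in force.
#' @slot membershipThreshold the |loading| membership threshold.
#' @slot extraction character log of how K was chosen.
#' @name CPCASolution-class
#' @exportClass CPCASolution
setClass("CPCASolution", representation(
  predicted = "matrix",
  eigenvalues = "numeric",
  nComponents = "integer",
  loadingsUnrotated = "matrix",
  loadingsRotated = "matrix",
  rotation = "matrix",
  scores = "matrix",
  pctPredictableVariance = "numeric",
  totalPredictableVariance = "numeric",
  pctVarianceOfTotal = "numeric",
  groupCorrelations = "data.frame",
  networks = "data.frame",
  membershipThreshold = "numeric",
  extraction = "character"))

setValidity("CPCASolution", function(object) {
  msg <- character()
  K <- object@nComponents
  if (K > 0) {
    R <- object@rotation
    if (max(abs(crossprod(R) - diag(K))) > 1e-8)
      msg <- c(msg, "rotation must be orthogonal")
    if (max(abs(object@loadingsUnrotated %*% R - object@loadingsRotated)) > 1e-8)
      msg <- c(msg, "rotated loadings must equal unrotated %*% rotation")
  }
  if (length(msg)) msg else TRUE
})
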