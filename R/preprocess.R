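# Preprocessing: below-LOD zeroing, >10% undetectable exclusion, |3.29| SD
# Winsorization, Blom (rank-based inverse normal) transformation.

#' Assign zero to concentrations below the limit of detection
#'
#' Every cell strictly below its analyte's LOD is set to exactly 0; cells
#' at or above the LOD are unchanged. The number of zeroed cells is stored
#' in the panel metadata (`nZeroed`).
#'
#' @param panel a [CytokinePanel-class].
#' @return the panel with below-LOD cells zeroed.
#' @export
assignBelowLOD <- function(panel) {
  stopifnot(is(panel, "CytokinePanel"))
  conc <- assay(panel, "concentrations")
  if (any(conc < 0)) stop("negative concentrations are not valid input")
  lodm <- matrix(detectionLimits(panel), nrow(conc), ncol(conc))
  below <- conc < lodm
  conc[below] <- 0
  assay(panel, "concentrations") <- conc
  metadata(panel)$nZeroed <- sum(below)
  panel
}

#' Exclude analytes undetectable in more than a threshold fraction of samples
#'
#' After [assignBelowLOD()], zeros mark undetectable measurements. Analytes
#' whose zero fraction is strictly greater than `threshold` (default 0.10:
#' "over 10 percent") are dropped from the analysis panel. The input panel
#' is untouched, so the full pre-exclusion panel remains available for the
#' heatmap path.
#'
#' @param panel a [CytokinePanel-class], already below-LOD zeroed.
#' @param threshold exclusion threshold in (0, 1).
#' @return list with `panel` (filtered) and `report`
#'   ([PreprocessReport-class] with per-analyte undetectable fractions and
#'   the exclusion set).
#' @export
filterUndetectable <- function(panel, threshold = 0.10) {
  stopifnot(is(panel, "CytokinePanel"))
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  conc <- assay(panel, "concentrations")
  frac <- rowMeans(conc == 0)
  excluded <- rownames(panel)[frac > threshold]
  report <- new("PreprocessReport",
                undetectableFraction = setNames(frac, rownames(panel)),
                excludedAnalytes = excluded,
                threshold = threshold,
                nZeroed = as.integer(metadata(panel)$nZeroed %||% sum(conc == 0)),
                winsorizedCells = emptyWinsorLedger(),
                transform = c("assign_below_lod_zero", "filter_undetectable"))
  list(panel = panel[setdiff(rownames(panel), excluded), ], report = report)
}

emptyWinsorLedger <- function()
  data.frame(sample = character(), analyte = character(),
             original = numeric(), replacement = numeric(), z = numeric())

#' Winsorize extreme values at a z bound
#'
#' Per analyte, the mean and sample SD (n-1 denominator) are computed once
#' over all samples, including prospective outliers. Cells with
#' `|value - mean| / SD` strictly greater than `zBound` are replaced by
#' `mean +/- zBound * SD` (sign-matching). A single pass: replacements are
#' not re-examined. Analytes with zero SD are skipped with a warning.
#'
#' @param panel a [CytokinePanel-class] (needs >= 3 samples).
#' @param zBound the |z| bound (default 3.29).
#' @return list with `panel` (clipped) and `report`
#'   ([PreprocessReport-class] carrying the Winsorized-cell ledger).
#' @export
winsorize <- function(panel, zBound = 3.29) {
  stopifnot(is(panel, "CytokinePanel"))
  if (ncol(panel) < 3) stop("Winsorization needs at least 3 samples")
  conc <- assay(panel, "concentrations")
  ledger <- emptyWinsorLedger()
  for (j in seq_len(nrow(conc))) {
    x <- conc[j, ]
    m <- mean(x); s <- sd(x)
    if (s == 0) {
      warning("analyte '", rownames(conc)[j],
              "' has zero SD; skipped by Winsorization")
      next
    }
    z <- (x - m) / s
    out <- which(abs(z) > zBound)
    if (!length(out)) next
    repl <- m + sign(z[out]) * zBound * s
    ledger <- rbind(ledger, data.frame(
      sample = colnames(conc)[out], analyte = rownames(conc)[j],
      original = x[out], replacement = repl, z = z[out]))
    conc[j, out] <- repl
  }
  assay(panel, "concentrations") <- conc
  report <- new("PreprocessReport",
                undetectableFraction = numeric(),
                excludedAnalytes = character(),
                threshold = NA_real_,
                nZeroed = 0L,
                winsorizedCells = ledger,
                transform = sprintf("winsorize(|z| > %g)", zBound))
  list(panel = panel, report = report)
}

#' Blom (rank-based inverse normal) transformation
#'
#' Per analyte, each value is replaced by
#' `qnorm((r - 3/8) / (n + 1/4))`, where `r` is its ascending rank among
#' the `n` samples (average rank for ties). The transform is monotone
#' within each analyte and, for tie-free data, symmetric about 0.
#'
#' @param panel a [CytokinePanel-class] with >= 2 samples.
#' @return the panel with Blom scores in place of concentrations.
#' @export
blomTransform <- function(panel) {
  stopifnot(is(panel, "CytokinePanel"))
  n <- ncol(panel)
  if (n < 2) stop("Blom transformation needs at least 2 samples")
  conc <- assay(panel, "concentrations")
  out <- t(apply(conc, 1, function(x)
    qnorm((rank(x, ties.method = "average") - 3 / 8) / (n + 1 / 4))))
  dimnames(out) <- dimnames(conc)
  assay(panel, "concentrations") <- out
  metadata(panel)$blomTransformed <- TRUE
  panel
}

#' Run the full preprocessing chain
#'
#' Applies, in order: below-LOD zeroing, exclusion of analytes undetectable
#' in more than `threshold` of samples, Winsorization at `zBound`, Blom
#' transformation. The full post-zeroing panel is forked before exclusion
#' and returned for the heatmap path, which keeps all analytes.
#'
#' @param panel a raw [CytokinePanel-class].
#' @param threshold exclusion threshold (default 0.10).
#' @param zBound Winsorization bound (default 3.29).
#' @return list with `analysis` (Blom-transformed filtered panel),
#'   `heatmap` (post-zeroing panel with all analytes) and `report`
#'   (combined [PreprocessReport-class]).
#' @examples
#' coh <- applyDetectionCensoring(generateCohort(plantedModel(seed = 1)))
#' pp <- preprocessPanel(cohortPanel(coh))
#' excludedAnalytes(pp$report)
#' @export
preprocessPanel <- function(panel, threshold = 0.10, zBound = 3.29) {
  zeroed <- assignBelowLOD(panel)
  filt <- filterUndetectable(zeroed, threshold)
  wins <- winsorize(filt$panel, zBound)
  blom <- blomTransform(wins$panel)
  report <- new("PreprocessReport",
                undetectableFraction = filt$report@undetectableFraction,
                excludedAnalytes = filt$report@excludedAnalytes,
                threshold = threshold,
                nZeroed = filt$report@nZeroed,
                winsorizedCells = wins$report@winsorizedCells,
                transform = c("assign_below_lod_zero", "filter_undetectable",
                              sprintf("winsorize(|z| > %g)", zBound),
                              "blom_transform"))
  list(analysis = blom, heatmap = zeroed, report = report)
}
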