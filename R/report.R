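# Group-profile heatmap construction and end-to-end orchestration.

#' Group-average z-score profile
#'
#' Each analyte is z-scored over all samples (mean 0, SD 1), then averaged
#' within group, giving a groups x analytes matrix. Uses the pre-exclusion
#' panel by convention, so the heatmap shows all analytes. Zero-SD
#' analytes give a column of zeros with a warning. The group-size-weighted
#' mean of the four group means is 0 for every analyte, because z-scoring
#' is over all samples.
#'
#' @param panel a [CytokinePanel-class] (typically post-zeroing,
#'   pre-Winsorization concentrations).
#' @return groups x analytes numeric matrix, rows in canonical group
#'   order, columns in panel order; attribute `groupSizes`.
#' @export
groupProfile <- function(panel) {
  stopifnot(is(panel, "CytokinePanel"))
  conc <- assay(panel, "concentrations")
  grp <- factor(as.character(sampleGroups(panel)), levels = GROUP_LEVELS)
  z <- t(apply(conc, 1, function(x) {
    s <- sd(x)
    if (s == 0) {
      warning("zero-SD analyte; profile column set to 0")
      return(rep(0, length(x)))
    }
    (x - mean(x)) / s
  }))
  groups <- levels(droplevels(grp))
  prof <- t(vapply(groups, function(g) rowMeans(z[, grp == g, drop = FALSE]),
                   numeric(nrow(conc))))
  dimnames(prof) <- list(groups, rownames(conc))
  attr(prof, "groupSizes") <- as.integer(table(droplevels(grp)))
  prof
}

#' Render a group-profile heatmap
#'
#' Diverging colour map centred at 0 (deviations from the all-sample
#' mean); rows are groups, columns are analytes, no clustering. Written as
#' PNG or PDF according to the file extension.
#'
#' @param profile matrix from [groupProfile()].
#' @param file output path (`.png` or `.pdf`).
#' @param ... passed to [pheatmap::pheatmap()].
#' @return `file`, invisibly.
#' @export
renderHeatmap <- function(profile, file, ...) {
  if (!dir.exists(dirname(file)))
    stop("I/O error: directory does not exist: ", dirname(file))
  lim <- max(abs(profile), 1e-6)
  breaks <- seq(-lim, lim, length.out = 101)
  cols <- colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(100)
  pheatmap::pheatmap(profile, cluster_rows = FALSE, cluster_cols = FALSE,
                     color = cols, breaks = breaks, filename = file,
                     silent = TRUE, ...)
  invisible(file)
}

#' Run the full analysis pipeline from a configuration file
#'
#' Executes simulate (optional) -> preprocess -> univariate -> cpca ->
#' report, writing every artifact plus a machine-readable run log and a
#' summary JSON into the output directory. Any stage failure aborts with
#' the stage name and cause.
#'
#' The YAML configuration understands:
#' \describe{
#'   \item{simulate}{`seed` (and optionally any [plantedModel()] scalar
#'     argument); when present a synthetic cohort is generated.}
#'   \item{input}{`panel`, `lod`, `meta`: CSV paths, used when `simulate`
#'     is absent.}
#'   \item{threshold}{exclusion threshold (default 0.10).}
#'   \item{zBound}{Winsorization bound (default 3.29).}
#'   \item{membershipThreshold}{network |loading| threshold (default 0.40).}
#'   \item{k}{manual component override.}
#'   \item{outdir}{output directory (default `cytonet-out`).}
#' }
#'
#' @param config path to a YAML configuration file.
#' @return the output directory, invisibly.
#' @export
runPipeline <- function(config) {
  cfg <- tryCatch(yaml::read_yaml(config),
                  error = function(e) stop("stage config: ", conditionMessage(e)))
  outdir <- cfg$outdir %||% "cytonet-out"
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  log <- list(package = "cytonet",
              version = as.character(utils::packageVersion("cytonet")),
              config = cfg)

  panel <- if (!is.null(cfg$simulate)) {
    stage("simulate", {
      args <- cfg$simulate
      seed <- as.integer(args$seed %||% 1L)
      model <- plantedModel(seed = seed)
      coh <- applyDetectionCensoring(generateCohort(model))
      writeCohort(coh, file.path(outdir, "cohort"))
      log$seed <- seed
      cohortPanel(coh)
    })
  } else {
    stage("preprocess", {
      for (f in c("panel", "lod", "meta"))
        if (is.null(cfg$input[[f]]) || !file.exists(cfg$input[[f]]))
          stop("missing input file: ", f)
      readPanel(cfg$input$panel, cfg$input$lod, cfg$input$meta)
    })
  }

  pp <- stage("preprocess",
              preprocessPanel(panel, threshold = cfg$threshold %||% 0.10,
                              zBound = cfg$zBound %||% 3.29))
  stage("preprocess", jsonlite::write_json(list(
    undetectable_fraction = as.list(pp$report@undetectableFraction),
    excluded_analytes = pp$report@excludedAnalytes,
    n_zeroed = pp$report@nZeroed,
    winsorized_cells = pp$report@winsorizedCells,
    transform = pp$report@transform),
    file.path(outdir, "preprocess_report.json"), digits = NA,
    auto_unbox = TRUE))

  reg <- stage("univariate", regressAllAnalytes(pp$analysis))
  write.csv(reg, file.path(outdir, "regression_results.csv"),
            row.names = FALSE)

  sol <- stage("cpca", cpca(pp$analysis, k = cfg$k,
                            threshold = cfg$membershipThreshold %||% 0.40))
  stage("cpca", {
    jsonlite::write_json(list(
      eigenvalues = sol@eigenvalues,
      n_components = sol@nComponents,
      loadings_rotated = sol@loadingsRotated,
      rotation = sol@rotation,
      pct_predictable_variance = sol@pctPredictableVariance,
      pct_variance_of_total = sol@pctVarianceOfTotal,
      group_correlations = sol@groupCorrelations,
      membership_threshold = sol@membershipThreshold,
      extraction = sol@extraction),
      file.path(outdir, "cpca_solution.json"), digits = NA,
      auto_unbox = TRUE)
    write.csv(data.frame(analyte = rownames(sol@loadingsRotated),
                         sol@loadingsRotated, check.names = FALSE),
              file.path(outdir, "loadings.csv"), row.names = FALSE)
    write.csv(data.frame(sample = rownames(sol@scores), sol@scores,
                         check.names = FALSE),
              file.path(outdir, "scores.csv"), row.names = FALSE)
    write.csv(sol@networks, file.path(outdir, "networks.csv"),
              row.names = FALSE)
  })

  stage("report", {
    prof <- groupProfile(pp$heatmap)
    renderHeatmap(prof, file.path(outdir, "heatmap.png"))
    write.csv(data.frame(group = rownames(prof), prof, check.names = FALSE),
              file.path(outdir, "group_profile.csv"), row.names = FALSE)
  })

  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  jsonlite::write_json(list(
    n_samples = ncol(panel),
    n_analytes_panel = nrow(panel),
    n_analytes_analyzed = nrow(pp$analysis),
    n_excluded = length(pp$report@excludedAnalytes),
    n_components = sol@nComponents,
    pct_predictable_of_total = sol@pctVarianceOfTotal),
    file.path(outdir, "summary.json"), digits = NA, auto_unbox = TRUE)
  invisible(outdir)
}
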