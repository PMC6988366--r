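test_that("default cohort has the study dimensions and is seed-reproducible", {
  coh <- generateCohort(plantedModel(seed = 11))
  pan <- cohortPanel(coh)
  expect_identical(dim(pan), c(40L, 59L))
  expect_identical(as.integer(table(sampleGroups(pan))[GROUPS4]),
                   c(15L, 12L, 15L, 17L))
  coh2 <- generateCohort(plantedModel(seed = 11))
  expect_identical(concentrations(coh), concentrations(coh2))
  coh3 <- generateCohort(plantedModel(seed = 12))
  expect_true(any(concentrations(coh) != concentrations(coh3)))
})

test_that("noise-free generation gives identical concentrations within group", {
  m <- plantedModel(seed = 5, subjectScoreSD = 0, analyteNoiseSD = 0)
  coh <- generateCohort(m)
  conc <- concentrations(coh)
  grp <- sampleGroups(cohortPanel(coh))
  for (g in GROUPS4) {
    sub <- conc[, grp == g, drop = FALSE]
    expect_equal(max(apply(sub, 1, function(x) diff(range(x)))), 0)
  }
})

test_that("deterministic-count censoring matches the planted rates exactly", {
  coh <- applyDetectionCensoring(generateCohort(plantedModel(seed = 2)))
  mask <- censorMask(coh)
  heavy <- c("GM-CSF" = 16L, "IL-1alpha" = 29L, "IL-4" = 34L,
             "IL-13" = 43L, "IL-1beta" = 43L, "IL-12p70" = 54L)
  expect_identical(as.integer(rowSums(mask)[names(heavy)]), unname(heavy))
  # all other analytes untouched
  expect_true(all(rowSums(mask)[setdiff(rownames(mask), names(heavy))] == 0))
  # every censored cell strictly below its LOD
  lod <- detectionLimits(cohortPanel(coh))
  conc <- concentrations(coh)
  expect_true(all(conc[mask] < matrix(lod, nrow(conc), ncol(conc))[mask]))
  # conservation: censored + uncensored = all cells
  expect_identical(sum(mask) + sum(!mask), length(conc))
})

test_that("a 10% censor rate on 59 samples censors 6 cells (10.2% > 10%)", {
  m <- plantedModel(seed = 3, censorRates = setNames(0.10, "IL-6"))
  coh <- applyDetectionCensoring(generateCohort(m))
  expect_identical(sum(censorMask(coh)["IL-6", ]), 6L)
  expect_gt(6 / 59, 0.10)
})

test_that("zero censor rates leave the panel unchanged", {
  m <- plantedModel(seed = 4, censorRates = 0)
  coh <- generateCohort(m)
  coh2 <- applyDetectionCensoring(coh)
  expect_identical(concentrations(coh), concentrations(coh2))
  expect_false(any(censorMask(coh2)))
})

test_that("censor and outlier rate preconditions are enforced", {
  coh <- generateCohort(plantedModel(seed = 1))
  expect_error(applyDetectionCensoring(coh, censorRates = 1), "\\[0, 1\\)")
  expect_error(injectOutliers(coh, outlierRate = 1), "\\[0, 1\\)")
  expect_error(injectOutliers(coh, outlierRate = 0.01, magnitudeSD = 3.0),
               "3.29")
  expect_error(plantedModel(groupSizes = c("C/TD" = 1L, "C/ND" = 12L,
                                           "A/TD" = 15L, "A/ND" = 17L)),
               ">= 2")
})

test_that("outlier injection with rate 0 is the identity, and an injected cell is ledgered", {
  coh <- generateCohort(plantedModel(seed = 6))
  expect_identical(concentrations(injectOutliers(coh, outlierRate = 0)),
                   concentrations(coh))
  # mild-scale model so a single injected cell is the only extreme value
  m <- plantedModel(analyteIds = paste0("an", 1:8),
                    groupSizes = c("C/TD" = 5L, "C/ND" = 5L,
                                   "A/TD" = 5L, "A/ND" = 5L),
                    loadings = matrix(0.3, 8, 1,
                                      dimnames = list(paste0("an", 1:8), "net1")),
                    groupActivations = matrix(c(0, 1, -1, 0), 4, 1),
                    logScaleSigma = 0.2, censorRates = 0, seed = 7)
  coh <- generateCohort(m)
  inj <- injectOutliers(coh, outlierRate = 1 / (8 * 20), magnitudeSD = 6)
  led <- outlierLedger(inj)
  expect_identical(nrow(led), 1L)
  wres <- winsorize(cohortPanel(inj))
  flagged <- winsorizedCells(wres$report)
  expect_identical(nrow(flagged), 1L)
  expect_identical(flagged$sample, led$sample)
  expect_identical(flagged$analyte, led$analyte)
})

test_that("within-network correlations dominate cross-network correlations", {
  nets <- list(c("IL-2", "TNF-beta", "IL-10", "IL-15"),
               c("MIP-1beta", "MDC", "MCP-4", "PlGF", "CRP"),
               c("Eotaxin-3", "Eotaxin", "bFGF"))
  wins <- 0L; reps <- 50L
  for (s in seq_len(reps)) {
    conc <- log(concentrations(generateCohort(plantedModel(seed = 500 + s))))
    cm <- cor(t(conc))
    within <- unlist(lapply(nets, function(m) {
      cc <- abs(cm[m, m]); cc[upper.tri(cc)]
    }))
    cross <- c(abs(cm[nets[[1]], nets[[2]]]), abs(cm[nets[[1]], nets[[3]]]),
               abs(cm[nets[[2]], nets[[3]]]))
    if (min(within) > max(cross)) wins <- wins + 1L
  }
  expect_gt(wins / reps, 0.5)
})

test_that("group means of subject scores converge to the planted activations", {
  m <- plantedModel(groupSizes = c("C/TD" = 1000L, "C/ND" = 1000L,
                                   "A/TD" = 1000L, "A/ND" = 1000L),
                    seed = 20)
  coh <- generateCohort(m)
  sc <- subjectScores(coh)
  grp <- sampleGroups(cohortPanel(coh))
  se <- m@subjectScoreSD / sqrt(1000)
  for (k in seq_len(ncol(sc))) {
    means <- tapply(sc[, k], grp, mean)[GROUPS4]
    expect_true(all(abs(means - m@groupActivations[, k]) < 3 * se))
  }
})

test_that("cohort round-trips through CSV files", {
  coh <- applyDetectionCensoring(generateCohort(plantedModel(seed = 8)))
  dir <- withr::local_tempdir()
  writeCohort(coh, dir)
  expect_true(all(file.exists(file.path(dir, c("panel.csv", "meta.csv",
                                               "lod.csv", "truth.json")))))
  pan <- readPanel(file.path(dir, "panel.csv"), file.path(dir, "lod.csv"),
                   file.path(dir, "meta.csv"))
  expect_equal(concentrations(pan), concentrations(coh), tolerance = 1e-12)
  expect_identical(as.character(sampleGroups(pan)),
                   as.character(sampleGroups(cohortPanel(coh))))
})
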