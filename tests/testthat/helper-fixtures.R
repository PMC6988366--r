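# Shared fixtures and independent oracles.

GROUPS4 <- c("C/TD", "C/ND", "A/TD", "A/ND")

# small panel builder: conc is analytes x samples
smallPanel <- function(conc, lod = NULL, group = NULL, covariates = NULL,
                       seed = 99) {
  conc <- as.matrix(conc)
  p <- nrow(conc); n <- ncol(conc)
  if (is.null(rownames(conc))) rownames(conc) <- paste0("an", seq_len(p))
  if (is.null(colnames(conc))) colnames(conc) <- paste0("s", seq_len(n))
  if (is.null(lod)) lod <- rep(0.01, p)
  if (is.null(group)) group <- rep(GROUPS4, length.out = n)
  if (is.null(covariates)) {
    set.seed(seed)
    covariates <- data.frame(smoking = rbinom(n, 1, 0.3),
                             bmi = rnorm(n, 24, 2),
                             sex = rbinom(n, 1, 0.5),
                             age_years = runif(n, 2, 3.5))
  }
  CytokinePanel(conc, lod = lod, group = group, covariates = covariates)
}

# Independent standard-normal quantile: Acklam's rational approximation with
# one Halley refinement step. Oracle for the Blom transform; does not call
# qnorm.
invNormAcklam <- function(p) {
  a <- c(-3.969683028665376e+01, 2.209460984245205e+02,
         -2.759285104469687e+02, 1.383577518672690e+02,
         -3.066479806614716e+01, 2.506628277459239e+00)
  b <- c(-5.447609879822406e+01, 1.615858368580409e+02,
         -1.556989798598866e+02, 6.680131188771972e+01,
         -1.328068155288572e+01)
  c_ <- c(-7.784894002430293e-03, -3.223964580411365e-01,
          -2.400758277161838e+00, -2.549732539343734e+00,
          4.374664141464968e+00, 2.938163982698783e+00)
  d <- c(7.784695709041462e-03, 3.224671290700398e-01,
         2.445134137142996e+00, 3.754408661907416e+00)
  plow <- 0.02425
  one <- function(pp) {
    if (pp < plow) {
      q <- sqrt(-2 * log(pp))
      (((((c_[1] * q + c_[2]) * q + c_[3]) * q + c_[4]) * q + c_[5]) * q +
          c_[6]) / ((((d[1] * q + d[2]) * q + d[3]) * q + d[4]) * q + 1)
    } else if (pp <= 1 - plow) {
      q <- pp - 0.5; r <- q * q
      (((((a[1] * r + a[2]) * r + a[3]) * r + a[4]) * r + a[5]) * r + a[6]) *
        q / (((((b[1] * r + b[2]) * r + b[3]) * r + b[4]) * r + b[5]) * r + 1)
    } else {
      q <- sqrt(-2 * log(1 - pp))
      -(((((c_[1] * q + c_[2]) * q + c_[3]) * q + c_[4]) * q + c_[5]) * q +
          c_[6]) / ((((d[1] * q + d[2]) * q + d[3]) * q + d[4]) * q + 1)
    }
  }
  x <- vapply(p, one, numeric(1))
  # Halley refinement against the forward CDF
  e <- pnorm(x) - p
  u <- e * sqrt(2 * pi) * exp(x^2 / 2)
  x - u / (1 + x * u / 2)
}

# evaluate planted-network recovery for one cohort: returns congruences,
# whether member sets match exactly and whether member signs are consistent
evalRecovery <- function(seed, threshold = 0.40, model = NULL) {
  if (is.null(model)) model <- plantedModel(seed = seed)
  coh <- applyDetectionCensoring(generateCohort(model))
  pp <- suppressWarnings(preprocessPanel(cohortPanel(coh)))
  sol <- cpca(pp$analysis, threshold = threshold)
  truth <- cohortTruth(coh)@loadings[rownames(pp$analysis), , drop = FALSE]
  mc <- matchComponents(componentLoadings(sol), truth)
  al <- mc$aligned
  setsOK <- TRUE; signsOK <- TRUE
  for (k in seq_len(ncol(truth))) {
    members <- rownames(truth)[truth[, k] != 0]
    estm <- rownames(al)[abs(al[, k]) >= threshold]
    if (!setequal(estm, members)) setsOK <- FALSE
    if (any(sign(al[members, k]) != sign(truth[members, k]))) signsOK <- FALSE
  }
  list(congruence = mc$congruence, setsOK = setsOK, signsOK = signsOK,
       solution = sol, cohort = coh, panel = pp$analysis)
}
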