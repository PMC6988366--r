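# Per-analyte covariate-adjusted hierarchical regression and the
# multiple-comparison machinery for group characteristic tables.

#' Hierarchical regression of one analyte on covariates then group
#'
#' Step 1 fits `analyte ~ smoking + bmi + sex + age_years`; Step 2 adds
#' three group indicators (reference coding, `C/TD` as reference). Returns
#' the full-model R-squared, the R-squared increment of the group block
#' with its F-test p value, and all six pairwise group contrasts from the
#' Step-2 model (Wald t tests on the residual degrees of freedom).
#' Samples with missing covariates are dropped and counted.
#'
#' @param panel a Blom-transformed [CytokinePanel-class] with covariates.
#' @param analyte analyte id (row name).
#' @param adjustContrasts logical; if TRUE the six pairwise contrast p
#'   values are Holm-adjusted (default FALSE, mirroring unadjusted
#'   per-analyte reporting).
#' @return list with `analyte`, `n`, `nDropped`, `rSquaredFull`,
#'   `rSquaredCovariates`, `deltaRSquaredGroup`, `pGroupBlock` and
#'   `contrasts` (data.frame groupA, groupB, estimate, p).
#' @export
hierarchicalRegression <- function(panel, analyte, adjustContrasts = FALSE) {
  stopifnot(is(panel, "CytokinePanel"))
  if (!analyte %in% rownames(panel)) stop("unknown analyte: ", analyte)
  df <- data.frame(y = assay(panel, "concentrations")[analyte, ],
                   sampleCovariates(panel),
                   group = factor(as.character(sampleGroups(panel)),
                                  levels = GROUP_LEVELS))
  need <- c("y", "smoking", "bmi", "sex", "age_years", "group")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "))
  keep <- complete.cases(df[, need])
  nDropped <- sum(!keep)
  df <- df[keep, need]
  if (any(table(df$group) == 0))
    stop("design is collinear: group '",
         names(which(table(df$group) == 0))[1],
         "' is empty after covariate dropping")
  fit0 <- lm(y ~ smoking + bmi + sex + age_years, data = df)
  fit1 <- lm(y ~ smoking + bmi + sex + age_years + group, data = df)
  if (any(is.na(coef(fit1)))) {
    bad <- names(coef(fit1))[is.na(coef(fit1))]
    stop("design is collinear: ", paste(bad, collapse = ", "))
  }
  r2Full <- summary(fit1)$r.squared
  r2Cov <- summary(fit0)$r.squared
  an <- anova(fit0, fit1)
  pairs <- utils::combn(GROUP_LEVELS, 2)
  beta <- coef(fit1)
  V <- vcov(fit1)
  contrastVec <- function(g) {
    v <- setNames(numeric(length(beta)), names(beta))
    if (g != GROUP_LEVELS[1]) v[paste0("group", g)] <- 1
    v
  }
  contrasts <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    cv <- contrastVec(pairs[1, i]) - contrastVec(pairs[2, i])
    est <- sum(cv * beta)
    se <- sqrt(drop(t(cv) %*% V %*% cv))
    tval <- est / se
    data.frame(groupA = pairs[1, i], groupB = pairs[2, i], estimate = est,
               se = se, p = 2 * pt(-abs(tval), df = fit1$df.residual))
  }))
  if (adjustContrasts) contrasts$p <- holmBonferroni(contrasts$p)$adjusted
  list(analyte = analyte, n = nrow(df), nDropped = nDropped,
       rSquaredFull = r2Full, rSquaredCovariates = r2Cov,
       deltaRSquaredGroup = r2Full - r2Cov,
       pGroupBlock = an[2, "Pr(>F)"], contrasts = contrasts)
}

#' Hierarchical regression for every analyte in a panel
#'
#' @inheritParams hierarchicalRegression
#' @param adjustAcrossAnalytes logical; if TRUE the per-analyte group-block
#'   p values are additionally Holm-adjusted across analytes (off by
#'   default: each analyte is reported at its nominal p).
#' @return data.frame, one row per analyte, with R-squared of the full
#'   model, the group-block increment and its p value.
#' @export
regressAllAnalytes <- function(panel, adjustAcrossAnalytes = FALSE) {
  res <- lapply(rownames(panel), function(a) {
    r <- hierarchicalRegression(panel, a)
    data.frame(analyte = a, n = r$n, rSquaredFull = r$rSquaredFull,
               deltaRSquaredGroup = r$deltaRSquaredGroup,
               pGroupBlock = r$pGroupBlock)
  })
  out <- do.call(rbind, res)
  if (adjustAcrossAnalytes)
    out$pGroupBlockAdjusted <- holmBonferroni(out$pGroupBlock)$adjusted
  out
}

#' Holm-Bonferroni step-down adjustment
#'
#' Step-down adjustment: with p values sorted ascending, adjusted
#' `p_i = max_{j <= i} min(1, (m - j + 1) * p_(j))`; rejections follow the
#' sequential rule at `alpha`. Delegates to [stats::p.adjust()].
#'
#' @param p numeric vector of p values in (0, 1].
#' @param alpha significance level for the rejection flags (default 0.05).
#' @return list with `adjusted` and logical `reject`; empty input gives
#'   empty output.
#' @examples
#' holmBonferroni(c(0.01, 0.04))$adjusted  # 0.02 0.04
#' @export
holmBonferroni <- function(p, alpha = 0.05) {
  if (!length(p)) return(list(adjusted = numeric(), reject = logical()))
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p values must lie in (0, 1]")
  adjusted <- p.adjust(p, method = "holm")
  list(adjusted = adjusted, reject = adjusted <= alpha)
}

#' Omnibus and post hoc tests for group characteristics
#'
#' Continuous variables use the Kruskal-Wallis rank sum test across the
#' four groups; categorical variables use Fisher's exact test when any
#' expected cell count is below 5 and the chi-square test otherwise (the
#' dispatch is overridable per variable). Post hoc pairwise p values are
#' Holm-adjusted via [holmBonferroni()].
#'
#' @param meta data.frame with a `group` column and the variable.
#' @param variable column name to test.
#' @param kind `"continuous"` or `"categorical"`.
#' @param test optional override among `"fisher"`, `"chisq"` for
#'   categorical variables.
#' @return list with `method`, `p`, `statistic` (if defined) and
#'   `posthoc` (data.frame groupA, groupB, p, pAdjusted).
#' @export
groupCharacteristics <- function(meta, variable,
                                 kind = c("continuous", "categorical"),
                                 test = NULL) {
  kind <- match.arg(kind)
  stopifnot(variable %in% colnames(meta), "group" %in% colnames(meta))
  grp <- factor(as.character(meta$group), levels = GROUP_LEVELS)
  grp <- droplevels(grp)
  x <- meta[[variable]]
  if (length(unique(x[!is.na(x)])) < 2)
    stop("variable '", variable, "' is constant; test is degenerate")
  lv <- levels(grp)
  pairs <- utils::combn(lv, 2)
  if (kind == "continuous") {
    om <- kruskal.test(x ~ grp)
    post <- vapply(seq_len(ncol(pairs)), function(i) {
      sel <- grp %in% pairs[, i]
      kruskal.test(x[sel] ~ droplevels(grp[sel]))$p.value
    }, numeric(1))
    method <- "kruskal-wallis"
    stat <- unname(om$statistic)
    pOm <- om$p.value
  } else {
    tab <- table(grp, x)
    expected <- suppressWarnings(chisq.test(tab)$expected)
    useFisher <- if (is.null(test)) any(expected < 5) else test == "fisher"
    testOne <- function(tt) {
      if (useFisher) fisher.test(tt, workspace = 2e7)$p.value
      else suppressWarnings(chisq.test(tt)$p.value)
    }
    pOm <- testOne(tab)
    post <- vapply(seq_len(ncol(pairs)), function(i)
      testOne(tab[pairs[, i], , drop = FALSE]), numeric(1))
    method <- if (useFisher) "fisher-exact" else "chi-square"
    stat <- if (!useFisher)
      unname(suppressWarnings(chisq.test(tab)$statistic)) else NA_real_
  }
  adj <- holmBonferroni(post)
  list(method = method, p = pOm, statistic = stat,
       posthoc = data.frame(groupA = pairs[1, ], groupB = pairs[2, ],
                            p = post, pAdjusted = adj$adjusted,
                            reject = adj$reject))
}
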