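# Constrained principal component analysis: regress the cytokine matrix on
# group membership, PCA the predicted scores, Varimax-rotate, correlate
# group indicators with component scores, assign network membership.

#' Build the group indicator design matrix
#'
#' One 0/1 column per group, in the canonical order
#' `C/TD, C/ND, A/TD, A/ND`. Every row sums to 1 and each column sum is
#' that group's size.
#'
#' @param panel a [CytokinePanel-class], or a factor/character vector of
#'   group labels.
#' @return samples x groups indicator matrix with an attribute
#'   `groupOrder`.
#' @export
buildDesign <- function(panel) {
  grp <- if (is(panel, "CytokinePanel")) sampleGroups(panel) else panel
  grp <- as.character(grp)
  bad <- setdiff(unique(grp), GROUP_LEVELS)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  f <- factor(grp, levels = GROUP_LEVELS)
  G <- sapply(GROUP_LEVELS, function(g) as.numeric(f == g))
  G <- matrix(G, nrow = length(grp),
              dimnames = list(names(grp) %||% seq_along(grp), GROUP_LEVELS))
  G <- G[, colSums(G) > 0, drop = FALSE]  # drop absent groups, keep order
  attr(G, "groupOrder") <- colnames(G)
  G
}

#' Predicted scores: project the cytokine matrix onto the group design
#'
#' Least-squares prediction `G (G'G)^- G' Y` using a pseudoinverse (the
#' four-indicator, intercept-free coding gives a unique projection even
#' though coefficients under an intercept would be rank-deficient). With
#' indicator coding this equals, for every sample, its group's mean
#' vector — the closed form the tests assert.
#'
#' @param Y samples x analytes matrix (typically Blom-transformed).
#' @param G samples x groups indicator matrix from [buildDesign()].
#' @return samples x analytes matrix of predicted (group-mean) scores.
#' @export
predictScores <- function(Y, G) {
  Y <- as.matrix(Y); G <- as.matrix(G)
  if (nrow(Y) != nrow(G))
    stop("Y and G must have the same number of rows (samples)")
  if (any(colSums(abs(G)) == 0))
    stop("rank error: empty group column in the design")
  P <- G %*% (MASS::ginv(crossprod(G)) %*% crossprod(G, Y))
  dimnames(P) <- dimnames(Y)
  P
}

#' PCA of the predicted-score matrix
#'
#' Columns are centred, then the covariance eigendecomposition is taken
#' via SVD. Components are ordered by descending eigenvalue; loadings are
#' scaled as eigenvector times the square root of the eigenvalue, and
#' scores are standardized to unit variance per component, so that
#' `centred predicted = scores %*% t(loadings)`.
#'
#' @param predicted samples x analytes matrix from [predictScores()].
#' @return list with `eigenvalues` (all, descending), `loadings`
#'   (analytes x K for K positive components), `scores` (samples x K,
#'   unit variance), `totalVariance` (trace of the covariance; the total
#'   predictable variance). An all-zero centred matrix gives zero
#'   components with a warning.
#' @export
pcaPredicted <- function(predicted) {
  X <- scale(as.matrix(predicted), center = TRUE, scale = FALSE)
  n <- nrow(X)
  if (max(abs(X)) < 1e-12) {
    warning("centred predicted matrix is zero; no predictable variance")
    return(list(eigenvalues = numeric(0),
                loadings = matrix(0, ncol(X), 0,
                                  dimnames = list(colnames(predicted), NULL)),
                scores = matrix(0, n, 0), totalVariance = 0))
  }
  sv <- svd(X)
  eig <- sv$d^2 / (n - 1)
  pos <- eig > max(eig) * 1e-14
  K <- sum(pos)
  loadings <- sweep(sv$v[, pos, drop = FALSE], 2, sqrt(eig[pos]), `*`)
  scores <- sv$u[, pos, drop = FALSE] * sqrt(n - 1)
  dimnames(loadings) <- list(colnames(predicted), paste0("C", seq_len(K)))
  dimnames(scores) <- list(rownames(predicted), paste0("C", seq_len(K)))
  list(eigenvalues = eig, loadings = loadings, scores = scores,
       totalVariance = sum(eig))
}

#' Choose the number of components to retain
#'
#' Default rule: the count of eigenvalues above a relative tolerance
#' (`tol` times the largest), an automated stand-in for reading a scree
#' plot. `method = "elbow"` instead takes the largest second difference of
#' the scree curve; `k` overrides both.
#'
#' @param eigenvalues numeric, descending.
#' @param method `"tolerance"` (default) or `"elbow"`.
#' @param k manual override.
#' @param tol relative tolerance (default 1e-10).
#' @return integer K with attribute `extraction` describing the choice.
#' @export
extractComponents <- function(eigenvalues, method = c("tolerance", "elbow"),
                              k = NULL, tol = 1e-10) {
  method <- match.arg(method)
  if (!length(eigenvalues) || max(eigenvalues) <= 0)
    stop("extraction error: no positive eigenvalue")
  if (!is.null(k)) {
    K <- as.integer(k)
    attr(K, "extraction") <- sprintf("manual override K = %d", K)
    return(K)
  }
  if (method == "tolerance") {
    K <- as.integer(sum(eigenvalues > tol * max(eigenvalues)))
    return(structure(K, extraction =
      sprintf("tolerance rule (> %g x largest): K = %d", tol, K)))
  }
  e <- eigenvalues
  if (length(e) < 3) {
    K <- 1L
  } else {
    d2 <- e[seq_len(length(e) - 2)] - 2 * e[seq(2, length(e) - 1)] +
      e[seq(3, length(e))]
    # elbow at index i+1 of the scree curve -> retain the components before it
    K <- as.integer(which.max(d2))
  }
  structure(K, extraction = sprintf("elbow heuristic: K = %d", K))
}

#' Correlate group membership with component scores
#'
#' Pearson correlation between each group's 0/1 indicator column (over all
#' samples) and each component's scores, with a two-sided p value from the
#' t distribution on n - 2 degrees of freedom.
#'
#' @param G samples x groups indicator matrix from [buildDesign()].
#' @param scores samples x K component scores (rotated).
#' @return data.frame with columns group, component, r, p.
#' @export
groupComponentCorrelations <- function(G, scores) {
  G <- as.matrix(G); scores <- as.matrix(scores)
  stopifnot(nrow(G) == nrow(scores))
  n <- nrow(G)
  if (any(apply(scores, 2, sd) == 0))
    stop("constant score vector: correlation undefined")
  if (is.null(colnames(scores)) || any(colnames(scores) == ""))
    colnames(scores) <- paste0("C", seq_len(ncol(scores)))
  out <- expand.grid(group = colnames(G),
                     component = colnames(scores),
                     stringsAsFactors = FALSE)
  out$r <- mapply(function(g, k) cor(G[, g], scores[, k]),
                  out$group, out$component)
  tval <- out$r * sqrt((n - 2) / pmax(1 - out$r^2, .Machine$double.eps))
  out$p <- 2 * pt(-abs(tval), df = n - 2)
  out
}

#' Assign analytes to activated/inhibited networks
#'
#' An analyte joins a component's network when its absolute rotated
#' loading is at least `threshold`; a positive loading marks it activated,
#' a negative one inhibited. Members are sorted by loading magnitude.
#' Empty networks are permitted.
#'
#' @param loadingsRotated analytes x K rotated loading matrix.
#' @param threshold |loading| membership threshold, > 0 (default 0.40).
#' @return data.frame with columns component, analyte, loading, sign.
#' @export
assignNetworks <- function(loadingsRotated, threshold = 0.40) {
  if (threshold <= 0) stop("threshold must be > 0")
  L <- as.matrix(loadingsRotated)
  comps <- colnames(L) %||% paste0("C", seq_len(ncol(L)))
  out <- do.call(rbind, lapply(seq_len(ncol(L)), function(k) {
    lk <- L[, k]
    m <- which(abs(lk) >= threshold)
    if (!length(m))
      return(data.frame(component = character(), analyte = character(),
                        loading = numeric(), sign = character()))
    m <- m[order(abs(lk[m]), decreasing = TRUE)]
    data.frame(component = comps[k],
               analyte = rownames(L)[m] %||% as.character(m),
               loading = unname(lk[m]),
               sign = ifelse(lk[m] > 0, "activated", "inhibited"))
  }))
  rownames(out) <- NULL
  out
}

#' Constrained principal component analysis of a cytokine panel
#'
#' The core method: (1) the samples x analytes matrix (Blom-transformed)
#' is regressed on the group indicator design, giving the matrix of
#' predicted scores — the variance in cytokine levels predictable from
#' group membership; (2) PCA of the predicted scores reveals the cytokine
#' networks driven by group; (3) the retained solution is Varimax-rotated
#' with Kaiser normalization; (4) group indicators are correlated with the
#' rotated component scores; (5) analytes are assigned to
#' activated/inhibited networks by loading threshold.
#'
#' With four groups the centred predicted matrix has rank at most 3, so at
#' most three components carry predictable variance.
#'
#' @param panel a Blom-transformed [CytokinePanel-class] (or any panel;
#'   the assay is used as-is).
#' @param k manual override of the number of components.
#' @param threshold network membership |loading| threshold (default 0.40).
#' @param screeMethod `"tolerance"` (default) or `"elbow"`, see
#'   [extractComponents()].
#' @param partialCovariates logical; if TRUE, covariates are regressed out
#'   of the cytokine matrix before the group regression (off by default:
#'   covariate adjustment belongs to the univariate models).
#' @param scoresFrom `"predicted"` (default; scores of the PCA on the
#'   predicted matrix) or `"raw"` (raw data projected on the rotated
#'   loadings, for sensitivity analysis).
#' @return a [CPCASolution-class].
#' @examples
#' coh <- applyDetectionCensoring(generateCohort(plantedModel(seed = 3)))
#' sol <- cpca(preprocessPanel(cohortPanel(coh))$analysis)
#' nComponents(sol)          # 3
#' head(networkTable(sol))
#' @export
cpca <- function(panel, k = NULL, threshold = 0.40,
                 screeMethod = c("tolerance", "elbow"),
                 partialCovariates = FALSE,
                 scoresFrom = c("predicted", "raw")) {
  screeMethod <- match.arg(screeMethod)
  scoresFrom <- match.arg(scoresFrom)
  Y <- t(assay(panel, "concentrations"))  # samples x analytes
  if (partialCovariates) {
    cv <- sampleCovariates(panel)
    X <- cbind(1, as.matrix(cv))
    Y <- Y - X %*% MASS::ginv(crossprod(X)) %*% crossprod(X, Y)
  }
  G <- buildDesign(panel)
  P <- predictScores(Y, G)
  dec <- pcaPredicted(P)
  K <- extractComponents(dec$eigenvalues, method = screeMethod, k = k)
  extraction <- attr(K, "extraction")
  K <- min(as.integer(K), ncol(dec$loadings))
  rot <- varimaxRotate(dec$loadings[, seq_len(K), drop = FALSE])
  scores <- dec$scores[, seq_len(K), drop = FALSE] %*% rot$rotation
  colnames(scores) <- colnames(rot$loadings)
  if (scoresFrom == "raw") {
    Yc <- scale(Y, center = TRUE, scale = FALSE)
    raw <- Yc %*% rot$loadings
    scores <- scale(raw, center = TRUE, scale = TRUE)[, , drop = FALSE]
    attr(scores, "scaled:center") <- NULL
    attr(scores, "scaled:scale") <- NULL
    colnames(scores) <- colnames(rot$loadings)
  }
  corr <- groupComponentCorrelations(G, scores)
  networks <- assignNetworks(rot$loadings, threshold)
  totVarY <- sum(apply(scale(Y, center = TRUE, scale = FALSE), 2, var))
  new("CPCASolution",
      predicted = P,
      eigenvalues = dec$eigenvalues,
      nComponents = as.integer(K),
      loadingsUnrotated = dec$loadings[, seq_len(K), drop = FALSE],
      loadingsRotated = rot$loadings,
      rotation = rot$rotation,
      scores = scores,
      pctPredictableVariance =
        100 * colSums(rot$loadings^2) / dec$totalVariance,
      totalPredictableVariance = dec$totalVariance,
      pctVarianceOfTotal = 100 * dec$totalVariance / totVarY,
      groupCorrelations = corr,
      networks = networks,
      membershipThreshold = threshold,
      extraction = extraction)
}
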