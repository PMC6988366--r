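# Varimax rotation with Kaiser normalization, by pairwise (Jacobi) planar
# rotations. Authored here because rotation of the group-constrained PCA
# solution is part of the package's core method; stats::varimax serves as an
# independent cross-check in the test suite.

varimaxCriterion <- function(L) {
  # sum over components of the variance of squared loadings
  p <- nrow(L)
  sum(apply(L^2, 2, function(s) sum(s^2) / p - (sum(s) / p)^2))
}

#' Varimax rotation with Kaiser normalization
#'
#' Rows are Kaiser-normalized (divided by the square root of their
#' communality), the Varimax criterion — the sum over components of the
#' variance of squared loadings — is maximized by iterative pairwise planar
#' rotations, and rows are de-normalized afterwards. Iteration stops when a
#' full sweep improves the criterion by less than `eps` or after
#' `maxSweeps` sweeps. Rotated columns are ordered by explained sum of
#' squares (descending) and oriented so the largest-magnitude loading is
#' positive; the returned rotation matrix carries the same permutation and
#' signs, so `rotated = loadings %*% rotation` holds exactly.
#'
#' @param loadings analytes x K numeric matrix.
#' @param normalize logical, apply Kaiser row normalization (default TRUE).
#' @param eps convergence tolerance on the criterion (default 1e-8).
#' @param maxSweeps maximum number of full pairwise sweeps (default 1000).
#' @return list with `loadings` (rotated), `rotation` (K x K orthogonal),
#'   `sweeps` and `criterion` (its value per sweep, non-decreasing).
#'   `K = 1` returns the identity rotation.
#' @examples
#' L <- cbind(c(0.9, 0.8, 0, 0), c(0, 0, 0.7, 0.6))
#' theta <- pi / 4
#' Q <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
#' out <- varimaxRotate(L %*% Q)  # recovers L up to sign/permutation
#' @export
varimaxRotate <- function(loadings, normalize = TRUE, eps = 1e-8,
                          maxSweeps = 1000) {
  L <- as.matrix(loadings)
  K <- ncol(L)
  if (K < 1) stop("need at least one component")
  if (K == 1)
    return(list(loadings = L, rotation = matrix(1, 1, 1), sweeps = 0L,
                criterion = varimaxCriterion(L)))
  h <- sqrt(rowSums(L^2))
  zero <- h == 0
  if (any(zero) && normalize)
    warning(sum(zero), " zero-communality row(s) excluded from Kaiser ",
            "normalization")
  W <- L
  if (normalize) W[!zero, ] <- L[!zero, , drop = FALSE] / h[!zero]
  active <- !zero
  A <- W[active, , drop = FALSE]
  p <- nrow(A)
  R <- diag(K)
  crit <- varimaxCriterion(A)
  trace <- crit
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    for (i in seq_len(K - 1)) for (j in seq(i + 1, K)) {
      x <- A[, i]; y <- A[, j]
      u <- x^2 - y^2
      v <- 2 * x * y
      su <- sum(u); sv <- sum(v)
      num <- 2 * (sum(u * v) - su * sv / p)
      den <- sum(u^2 - v^2) - (su^2 - sv^2) / p
      phi <- atan2(num, den) / 4
      if (abs(phi) < 1e-12) next
      cs <- cos(phi); sn <- sin(phi)
      G <- matrix(c(cs, -sn, sn, cs), 2, 2, byrow = TRUE)
      A[, c(i, j)] <- A[, c(i, j)] %*% G
      R[, c(i, j)] <- R[, c(i, j)] %*% G
    }
    newCrit <- varimaxCriterion(A)
    trace <- c(trace, newCrit)
    if (newCrit - crit < eps || sweeps >= maxSweeps) break
    crit <- newCrit
  }
  rotated <- L %*% R
  # deterministic presentation: order by SS loadings, largest loading positive
  ord <- order(colSums(rotated^2), decreasing = TRUE)
  rotated <- rotated[, ord, drop = FALSE]
  R <- R[, ord, drop = FALSE]
  flips <- vapply(seq_len(K), function(k) {
    lk <- rotated[, k]
    if (lk[which.max(abs(lk))] < 0) -1 else 1
  }, numeric(1))
  rotated <- sweep(rotated, 2, flips, `*`)
  R <- sweep(R, 2, flips, `*`)
  colnames(rotated) <- colnames(R) <- paste0("C", seq_len(K))
  rownames(rotated) <- rownames(L)
  list(loadings = rotated, rotation = R, sweeps = sweeps, criterion = trace)
}

#' Tucker congruence between loading vectors
#'
#' The cosine similarity `sum(x * y) / sqrt(sum(x^2) * sum(y^2))`, applied
#' columnwise when given matrices.
#'
#' @param x,y numeric vectors, or matrices with matching rows (congruence
#'   is computed for every column pair).
#' @return a scalar for vectors; a `ncol(x) x ncol(y)` matrix for matrices.
#' @export
tuckerCongruence <- function(x, y) {
  if (is.matrix(x) || is.matrix(y)) {
    x <- as.matrix(x); y <- as.matrix(y)
    stopifnot(nrow(x) == nrow(y))
    num <- crossprod(x, y)
    den <- sqrt(outer(colSums(x^2), colSums(y^2)))
    return(num / den)
  }
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}

#' Match estimated components to a reference by maximum congruence
#'
#' Greedy assignment: estimated columns are matched to reference columns in
#' descending order of absolute Tucker congruence, and each matched column
#' is sign-aligned with its reference.
#'
#' @param estimated,reference loading matrices with matching rows and the
#'   same number of columns.
#' @return list with `order` (permutation of estimated columns), `signs`,
#'   `congruence` (per matched pair, signed so that a perfect match is +1)
#'   and `aligned` (the permuted, sign-corrected estimate).
#' @export
matchComponents <- function(estimated, reference) {
  estimated <- as.matrix(estimated); reference <- as.matrix(reference)
  stopifnot(ncol(estimated) == ncol(reference))
  K <- ncol(reference)
  cg <- tuckerCongruence(estimated, reference)
  ord <- integer(K)
  cand <- abs(cg)
  for (step in seq_len(K)) {
    idx <- which(cand == max(cand), arr.ind = TRUE)[1, ]
    ord[idx[2]] <- idx[1]
    cand[idx[1], ] <- -Inf
    cand[, idx[2]] <- -Inf
  }
  # ord[k]: estimated column matched to reference column k
  signs <- vapply(seq_len(K), function(k) sign(cg[ord[k], k]), numeric(1))
  aligned <- sweep(estimated[, ord, drop = FALSE], 2, signs, `*`)
  congr <- vapply(seq_len(K), function(k) cg[ord[k], k] * signs[k], numeric(1))
  list(order = ord, signs = signs, congruence = congr, aligned = aligned)
}
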