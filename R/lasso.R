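#' Soft-thresholding operator
#'
#' `soft(z, t) = sign(z) * max(|z| - t, 0)`, the proximal map of the L1 norm
#' and the closed-form lasso solution under orthonormal design.
#'
#' @param z numeric vector.
#' @param t threshold (>= 0).
#' @return thresholded vector.
#' @export
soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

#' Lasso by cyclic coordinate descent on the Gram matrix
#'
#' Minimizes `(1/(2n)) ||y - X beta||^2 + lambda ||beta||_1` using covariance
#' updates: with `G = X'X/n` and `c = X'y/n` each coordinate update is
#' `beta_j <- soft(c_j - sum_{k != j} G_jk beta_k, lambda) / G_jj`. A full
#' cycle over all coordinates alternates with sweeps over the active set;
#' convergence is declared when no coefficient moves by more than `tol` in a
#' full cycle. Deterministic given its inputs.
#'
#' @param G p x p Gram matrix `X'X/n`.
#' @param c0 length-p vector `X'y/n`.
#' @param lambda penalty (>= 0).
#' @param tol convergence tolerance on coefficient change (default 1e-7).
#' @param max_passes maximum number of full cycles (default 1e5).
#' @param beta0 optional warm start.
#' @return coefficient vector of length p.
#' @keywords internal
lasso_cd <- function(G, c0, lambda, tol = 1e-7, max_passes = 1e5,
                     beta0 = NULL) {
  p <- length(c0)
  beta <- if (is.null(beta0)) numeric(p) else beta0
  gd <- diag(G)
  # residual correlation r = c0 - G %*% beta, maintained incrementally
  r <- c0 - as.numeric(G %*% beta)
  for (pass in seq_len(max_passes)) {
    delta_max <- 0
    for (j in seq_len(p)) {
      old <- beta[j]
      bj <- soft_threshold(r[j] + gd[j] * old, lambda) / gd[j]
      if (bj != old) {
        r <- r - G[, j] * (bj - old)
        beta[j] <- bj
        delta_max <- max(delta_max, abs(bj - old))
      }
    }
    if (delta_max < tol) break
  }
  beta
}

#' Nodewise lasso regression for one gene
#'
#' Regresses the target gene's (standardized) column on all other columns
#' with an L1 penalty: the nonzero coefficients identify the target's
#' probabilistic neighbors in the Gaussian graphical model.
#'
#' @param X column-standardized samples x genes matrix.
#' @param target gene index or gene ID (column of `X`).
#' @param lambda penalty, typically from [mb_penalty()].
#' @param tol,max_passes solver controls, see [lasso_cd].
#' @return named coefficient vector over the remaining genes (zeros
#'   included).
#' @export
neighborhood_select <- function(X, target, lambda, tol = 1e-7,
                                max_passes = 1e5) {
  stop_if(any(!is.finite(X)), "X contains non-finite entries")
  stop_if(lambda < 0, "lambda must be >= 0")
  if (is.character(target)) target <- match(target, colnames(X))
  stop_if(is.na(target) || target < 1 || target > ncol(X),
          "target column not found")
  n <- nrow(X)
  y <- X[, target]
  Xo <- X[, -target, drop = FALSE]
  G <- crossprod(Xo) / n
  c0 <- as.numeric(crossprod(Xo, y)) / n
  beta <- lasso_cd(G, c0, lambda, tol = tol, max_passes = max_passes)
  names(beta) <- colnames(Xo)
  beta
}
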