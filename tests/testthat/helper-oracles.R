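# Independent oracles and small fixture builders shared across tests.

# Proximal-gradient (ISTA) lasso: minimizes (1/(2n))||y - Xb||^2 + lambda|b|_1
# by iterating b <- soft(b + X'(y - Xb)/(nL), lambda/L) with L the largest
# eigenvalue of X'X/n. A different algorithm family from the package's
# coordinate descent, used to certify its solutions.
ista_lasso <- function(X, y, lambda, iters = 200000, tol = 1e-12) {
  n <- nrow(X)
  G <- crossprod(X) / n
  c0 <- as.numeric(crossprod(X, y)) / n
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  b <- numeric(ncol(X))
  st <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  for (k in seq_len(iters)) {
    bn <- st(b + (c0 - as.numeric(G %*% b)) / L, lambda / L)
    if (max(abs(bn - b)) < tol) { b <- bn; break }
    b <- bn
  }
  b
}

# Brute-force two-group log-rank: hypergeometric O/E/V summed over distinct
# event times, chi-square statistic for stratum 1.
logrank_by_hand <- function(time, event, stratum) {
  stratum <- as.character(stratum)
  g1 <- sort(unique(stratum))[1]
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & stratum == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & stratum == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Tiny expr_set: genes x samples matrix from a list of per-gene value vectors.
toy_expr <- function(gene_values, groups, os_time = NULL, os_event = NULL) {
  m <- do.call(rbind, gene_values)
  rownames(m) <- names(gene_values)
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  clin <- data.frame(sample_id = colnames(m), group = groups,
                     stringsAsFactors = FALSE)
  if (!is.null(os_time)) { clin$os_time <- os_time; clin$os_event <- os_event }
  expr_set(m, clin)
}

# Ground-truth object with independent genes (diagonal precision), for null
# simulations where the generator's graph machinery must be switched off.
diag_truth <- function(p, config) {
  ids <- sprintf("g%03d", seq_len(p))
  adj <- matrix(0, p, p, dimnames = list(ids, ids))
  omega <- diag(p)
  dimnames(omega) <- list(ids, ids)
  structure(list(adjacency_pos = adj, adjacency_neg = adj,
                 precision_pos = omega, precision_neg = omega,
                 de_genes = numeric(0), surv_effects = numeric(0),
                 config = config),
            class = "synthetic_truth")
}

# Standardize columns of a samples x genes matrix (sample sd).
std_cols <- function(X) scale(X, center = TRUE, scale = apply(X, 2, sd))
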