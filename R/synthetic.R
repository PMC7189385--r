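#' Configuration for the synthetic two-group expression study
#'
#' Bundles and validates every knob of the generator: a scale-free gene
#' dependency graph per group (sharing a common core of edges), group-specific
#' sparse precision matrices, planted mean-shift DE genes, per-entry zero
#' inflation of the count matrix, and exponential survival whose log-hazard is
#' linear in selected genes' standardized expression.
#'
#' Defaults mirror a small two-arm cohort: 50 genes, 200 samples per group,
#' tree-like dependency graphs (`attachment_m = 1`) with half the edges shared
#' between groups, 5 DE genes with a one-unit shift on the log2 scale, 10%
#' zero inflation, baseline hazard 0.1 and censoring rate 0.05.
#'
#' @param n_genes number of genes.
#' @param n_samples_pos,n_samples_neg samples in the LN+ / LN- group.
#' @param attachment_m edges added per node in preferential attachment.
#' @param shared_core_fraction proportion in `[0,1]` of edges common to both
#'   groups' graphs.
#' @param n_de_genes number of planted DE genes (`<= n_genes`).
#' @param de_effect mean shift on the log2 scale applied to the LN+ group
#'   (sign per gene drawn at random).
#' @param zero_inflation proportion in `[0,1]` of count entries zeroed.
#' @param surv_effect_genes integer indices of survival-effect genes.
#' @param surv_beta log-hazard slope per effect gene (recycled).
#' @param censor_rate exponential censoring rate (> 0).
#' @param baseline_hazard baseline exponential event rate.
#' @param base_mean baseline mean of the latent log2 expression.
#' @param edge_weight_range magnitude range `(lo, hi)` for off-diagonal
#'   precision entries; defaults to `c(3, 5)` so planted partial
#'   correlations clear the Meinshausen-Buhlmann penalty's detection
#'   threshold at a few hundred samples (see the methods vignette).
#' @param boost diagonal dominance multiplier (>= 1 guarantees positive
#'   definiteness).
#' @param seed integer seed; identical config + seed gives bit-identical data.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 50,
                             n_samples_pos = 200,
                             n_samples_neg = 200,
                             attachment_m = 1,
                             shared_core_fraction = 0.5,
                             n_de_genes = 5,
                             de_effect = 1,
                             zero_inflation = 0.1,
                             surv_effect_genes = integer(0),
                             surv_beta = 1,
                             censor_rate = 0.05,
                             baseline_hazard = 0.1,
                             base_mean = 6,
                             edge_weight_range = c(3, 5),
                             boost = 1,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples_pos = as.integer(n_samples_pos),
              n_samples_neg = as.integer(n_samples_neg),
              attachment_m = as.integer(attachment_m),
              shared_core_fraction = shared_core_fraction,
              n_de_genes = as.integer(n_de_genes),
              de_effect = de_effect,
              zero_inflation = zero_inflation,
              surv_effect_genes = as.integer(surv_effect_genes),
              surv_beta = surv_beta,
              censor_rate = censor_rate,
              baseline_hazard = baseline_hazard,
              base_mean = base_mean,
              edge_weight_range = edge_weight_range,
              boost = boost,
              seed = as.integer(seed))
  with(cfg, {
    stop_if(n_genes < 1 || n_samples_pos < 1 || n_samples_neg < 1 ||
              attachment_m < 1, "counts must be >= 1")
    stop_if(shared_core_fraction < 0 || shared_core_fraction > 1 ||
              zero_inflation < 0 || zero_inflation > 1,
            "proportions must lie in [0, 1]")
    stop_if(n_de_genes < 0 || n_de_genes > n_genes,
            "n_de_genes must be in [0, n_genes]")
    stop_if(censor_rate <= 0, "censor_rate must be > 0")
    stop_if(length(surv_effect_genes) &&
              (min(surv_effect_genes) < 1 || max(surv_effect_genes) > n_genes),
            "surv_effect_genes out of range")
  })
  structure(cfg, class = "synthetic_config")
}

#' Scale-free random graph by preferential attachment
#'
#' Barabasi-Albert growth: nodes arrive one at a time and attach `m` edges to
#' existing nodes with probability proportional to their degree, producing the
#' heavy-tailed, hub-dominated degree distributions seen in gene networks.
#'
#' @param p number of nodes (`>= m + 1`).
#' @param m edges added per arriving node.
#' @param seed optional integer seed (omit to use the current RNG stream).
#' @return symmetric binary adjacency matrix with zero diagonal; dimnames are
#'   gene IDs `g001, g002, ...`.
#' @export
make_scale_free_graph <- function(p, m, seed = NULL) {
  stop_if(m < 1, "m must be >= 1")
  stop_if(p <= m, "need p >= m + 1 nodes for preferential attachment")
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_pa(p, m = m, directed = FALSE)
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  adj[adj > 0] <- 1
  ids <- gene_ids(p)
  dimnames(adj) <- list(ids, ids)
  adj
}

gene_ids <- function(p) sprintf("g%03d", seq_len(p))

#' Precision matrix on a given graph support
#'
#' Places weights of random sign and magnitude `runif(lo, hi)` on the edges of
#' `adjacency` (symmetrically), then sets each diagonal entry to
#' `boost * sum(|off-diagonal row|) + 1`. The matrix is strictly diagonally
#' dominant for `boost >= 1`, hence symmetric positive definite, and its
#' off-diagonal support equals the adjacency exactly.
#'
#' @param adjacency symmetric binary matrix, zero diagonal.
#' @param edge_weight_range magnitude range `c(lo, hi)`, `0 < lo <= hi`.
#' @param boost diagonal multiplier.
#' @return symmetric positive-definite precision matrix (same dimnames).
#' @export
graph_to_precision <- function(adjacency, edge_weight_range = c(3, 5),
                               boost = 1) {
  stop_if(!isSymmetric(unname(adjacency)), "adjacency must be symmetric")
  stop_if(any(diag(adjacency) != 0), "adjacency must have zero diagonal")
  lo <- edge_weight_range[1]; hi <- edge_weight_range[2]
  stop_if(lo <= 0 || hi < lo, "need 0 < lo <= hi")
  p <- nrow(adjacency)
  omega <- matrix(0, p, p, dimnames = dimnames(adjacency))
  up <- which(upper.tri(adjacency) & adjacency != 0)
  if (length(up)) {
    w <- stats::runif(length(up), lo, hi) *
      sample(c(-1, 1), length(up), replace = TRUE)
    omega[up] <- w
    omega <- omega + t(omega)
  }
  diag(omega) <- boost * rowSums(abs(omega)) + 1
  omega
}

#' Ground truth for a synthetic two-group study
#'
#' Builds one preferential-attachment graph, keeps a `shared_core_fraction`
#' of its edges in both groups and rewires the remainder independently per
#' group (so the two graphs share hubs but differ in part of their edges),
#' converts each graph to a precision matrix, and plants signed DE genes and
#' survival effects.
#'
#' @param config a [synthetic_config()].
#' @return object of class `synthetic_truth`: adjacency and precision per
#'   group, `de_genes` (named sign vector, +1 = up in LN+), `surv_effects`
#'   (named slope vector), and the config.
#' @export
synthetic_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  p <- config$n_genes
  ids <- gene_ids(p)
  base <- make_scale_free_graph(p, config$attachment_m)
  edges <- which(upper.tri(base) & base != 0, arr.ind = TRUE)
  n_edges <- nrow(edges)
  n_core <- round(config$shared_core_fraction * n_edges)
  core <- if (n_core > 0) sample.int(n_edges, n_core) else integer(0)

  rewire_rest <- function() {
    adj <- matrix(0, p, p, dimnames = list(ids, ids))
    for (k in core) adj[edges[k, 1], edges[k, 2]] <- 1
    need <- n_edges - n_core
    while (need > 0) {
      i <- sample.int(p, 1); j <- sample.int(p, 1)
      a <- min(i, j); b <- max(i, j)
      if (a == b || adj[a, b] == 1) next
      adj[a, b] <- 1
      need <- need - 1
    }
    adj + t(adj)
  }
  adj_pos <- rewire_rest()
  adj_neg <- rewire_rest()

  prec_pos <- graph_to_precision(adj_pos, config$edge_weight_range,
                                 config$boost)
  prec_neg <- graph_to_precision(adj_neg, config$edge_weight_range,
                                 config$boost)

  de_idx <- if (config$n_de_genes > 0)
    sort(sample.int(p, config$n_de_genes)) else integer(0)
  de_signs <- if (length(de_idx))
    sample(c(-1, 1), length(de_idx), replace = TRUE) else numeric(0)
  names(de_signs) <- ids[de_idx]

  beta <- rep_len(config$surv_beta, length(config$surv_effect_genes))
  names(beta) <- ids[config$surv_effect_genes]

  structure(list(adjacency_pos = adj_pos, adjacency_neg = adj_neg,
                 precision_pos = prec_pos, precision_neg = prec_neg,
                 de_genes = de_signs, surv_effects = beta,
                 config = config),
            class = "synthetic_truth")
}

# exact MVN draw with covariance Omega^{-1}: X = R^{-1} Z, Omega = R'R
rmvn_precision <- function(n, omega) {
  R <- chol(omega)
  z <- matrix(stats::rnorm(n * nrow(omega)), nrow = nrow(omega))
  t(backsolve(R, z))              # n x p
}

#' Sample a zero-inflated expression matrix from the planted model
#'
#' Per sample, latent log2 values are drawn from the group's multivariate
#' normal `N(mu, Omega^-1)`; DE genes receive `+/- de_effect` in the LN+
#' group according to their planted sign; latent values are mapped to
#' nonnegative counts by `2^x - 1` clipped at zero (so the pipeline's
#' `log2(x + 1)` transform inverts it exactly on unclipped entries); finally
#' a `zero_inflation` fraction of entries is set to 0 uniformly at random.
#'
#' @param truth a [synthetic_truth()].
#' @param config the matching [synthetic_config()]; defaults to the one
#'   stored in `truth`.
#' @return an [expr_set] whose clinical table has the group labels (survival
#'   columns are added by [simulate_survival()]).
#' @export
sample_expression <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(config$seed + 1L)
  p <- config$n_genes
  ids <- gene_ids(p)
  mu <- rep(config$base_mean, p)

  draw_group <- function(n, omega, shift) {
    x <- rmvn_precision(n, omega)
    sweep(x, 2, mu + shift, "+")
  }
  shift_pos <- numeric(p)
  shift_pos[match(names(truth$de_genes), ids)] <-
    truth$de_genes * config$de_effect

  xpos <- draw_group(config$n_samples_pos, truth$precision_pos, shift_pos)
  xneg <- draw_group(config$n_samples_neg, truth$precision_neg, 0)
  latent <- rbind(xpos, xneg)               # samples x genes
  counts <- pmax(2^latent - 1, 0)
  if (config$zero_inflation > 0) {
    drop <- stats::runif(length(counts)) < config$zero_inflation
    counts[drop] <- 0
  }
  values <- t(counts)
  sample_ids <- c(sprintf("pos%03d", seq_len(config$n_samples_pos)),
                  sprintf("neg%03d", seq_len(config$n_samples_neg)))
  dimnames(values) <- list(ids, sample_ids)
  clinical <- data.frame(
    sample_id = sample_ids,
    group = rep(c("LNpos", "LNneg"),
                c(config$n_samples_pos, config$n_samples_neg)),
    stringsAsFactors = FALSE)
  expr_set(values, clinical)
}

#' Simulate right-censored survival driven by gene expression
#'
#' Event times are exponential with per-sample hazard
#' `h0 * exp(sum_g beta_g * z_g)` where `z` is the gene's standardized
#' `log2(x + 1)` expression across all samples; censoring times are
#' exponential with rate `censor_rate`; observed time is the minimum and the
#' event indicator is 1 when the event precedes censoring.
#'
#' @param x an [expr_set].
#' @param surv_effects named numeric vector: gene ID -> log-hazard slope
#'   (empty for a null simulation).
#' @param censor_rate exponential censoring rate.
#' @param baseline_hazard baseline event rate `h0`.
#' @param seed integer seed.
#' @return the `expr_set` with `os_time` and `os_event` columns filled in.
#' @export
simulate_survival <- function(x, surv_effects = numeric(0),
                              censor_rate = 0.05, baseline_hazard = 0.1,
                              seed = 1L) {
  stopifnot(inherits(x, "expr_set"))
  unknown <- setdiff(names(surv_effects), rownames(x$values))
  stop_if(length(unknown) > 0, "unknown survival-effect gene(s): ",
          paste(unknown, collapse = ", "))
  set.seed(seed)
  n <- ncol(x$values)
  lp <- numeric(n)
  for (g in names(surv_effects)) {
    lg <- log2(x$values[g, ] + 1)
    s <- stats::sd(lg)
    z <- if (s > 0) (lg - mean(lg)) / s else numeric(n)
    lp <- lp + surv_effects[[g]] * z
  }
  hazard <- baseline_hazard * exp(lp)
  t_event <- stats::rexp(n, rate = hazard)
  t_cens <- stats::rexp(n, rate = censor_rate)
  x$clinical$os_time <- pmin(t_event, t_cens)
  x$clinical$os_event <- as.integer(t_event <= t_cens)
  expr_set(x$values, x$clinical)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: [synthetic_truth()], [sample_expression()] and
#' [simulate_survival()] under one config and seed.
#'
#' @param config a [synthetic_config()].
#' @return list with `truth` (a `synthetic_truth`) and `data` (an
#'   [expr_set] with survival annotations).
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  truth <- synthetic_truth(config)
  dat <- sample_expression(truth, config)
  dat <- simulate_survival(dat, truth$surv_effects,
                           censor_rate = config$censor_rate,
                           baseline_hazard = config$baseline_hazard,
                           seed = config$seed + 2L)
  list(truth = truth, data = dat)
}

#' Write ground truth as JSON + edge-list TSVs
#'
#' @param truth a [synthetic_truth()].
#' @param dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edge_df <- function(adj) {
    idx <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
    ids <- rownames(adj)
    data.frame(gene_a = ids[idx[, 1]], gene_b = ids[idx[, 2]],
               stringsAsFactors = FALSE)
  }
  fp <- file.path(dir, "truth_edges_pos.tsv")
  fn <- file.path(dir, "truth_edges_neg.tsv")
  utils::write.table(edge_df(truth$adjacency_pos), fp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(edge_df(truth$adjacency_neg), fn, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fj <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(de_genes = as.list(truth$de_genes),
         surv_effects = as.list(truth$surv_effects),
         config = unclass(truth$config)),
    fj, auto_unbox = TRUE, digits = NA)
  invisible(c(fp, fn, fj))
}
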