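#' Meinshausen-Buhlmann significance-calibrated lasso penalty
#'
#' `lambda(alpha) = 2 * sigma_hat * n^(-1/2) * qnorm(1 - alpha/(2 p^2))`:
#' the penalty level at which nodewise lasso neighborhood selection controls
#' the probability of falsely connecting distinct connectivity components at
#' level `alpha`, with asymptotic consistency guarantees.
#'
#' @param n number of samples.
#' @param p number of genes (variables) in the regression system.
#' @param alpha significance level in (0, 1), default 0.05.
#' @param sigma_hat per-response noise scale; 1 for standardized data.
#' @return the penalty value (a positive scalar; 0 when `sigma_hat = 0`,
#'   with a warning).
#' @export
mb_penalty <- function(n, p, alpha = 0.05, sigma_hat = 1) {
  stop_if(n < 2 || p < 2, "need n >= 2 and p >= 2")
  stop_if(alpha <= 0 || alpha >= 1, "alpha must be in (0, 1)")
  stop_if(alpha / (2 * p^2) >= 1, "alpha/(2p^2) must be < 1")
  if (sigma_hat == 0) warning("sigma_hat = 0 gives a degenerate penalty of 0")
  2 * sigma_hat * n^(-1 / 2) * stats::qnorm(1 - alpha / (2 * p^2))
}

#' Estimate a gene network by nodewise lasso neighborhood selection
#'
#' Runs [neighborhood_select()] for every gene at the [mb_penalty()] and
#' symmetrizes: under `rule = "or"` an edge \{i, j\} exists when either
#' regression selects the other gene, under `"and"` when both do. The edge
#' weight is the mean absolute value of the (one or two) nonzero
#' coefficients. A pure function of its inputs.
#'
#' @param X samples x genes matrix, column-standardized (within the group
#'   whose network is being estimated).
#' @param group_label provenance string (e.g. `"LNpos"`).
#' @param alpha significance level of the penalty.
#' @param rule symmetrization rule, `"or"` (default) or `"and"`.
#' @param sigma_hat noise scale for the penalty (default 1, the standardized
#'   convention).
#' @return object of class `gene_network`: list with `genes`, `edges`
#'   (data frame `gene_a < gene_b`, `weight`), and provenance fields
#'   `group`, `alpha`, `lambda`, `rule`.
#' @export
build_network <- function(X, group_label = "", alpha = 0.05,
                          rule = c("or", "and"), sigma_hat = 1) {
  rule <- match.arg(rule)
  stop_if(ncol(X) < 3, "need at least 3 genes")
  stop_if(is.null(colnames(X)) || anyDuplicated(colnames(X)),
          "X needs unique gene IDs as colnames")
  n <- nrow(X); p <- ncol(X)
  lambda <- mb_penalty(n, p, alpha, sigma_hat)
  ids <- colnames(X)
  G <- crossprod(X) / n
  # coefficient matrix B[i, j] = coefficient of gene j in gene i's regression
  B <- matrix(0, p, p, dimnames = list(ids, ids))
  for (i in seq_len(p)) {
    beta <- lasso_cd(G[-i, -i, drop = FALSE], G[-i, i], lambda)
    B[i, -i] <- beta
  }
  sel <- B != 0
  joined <- if (rule == "or") sel | t(sel) else sel & t(sel)
  idx <- which(upper.tri(joined) & joined, arr.ind = TRUE)
  if (nrow(idx)) {
    w <- vapply(seq_len(nrow(idx)), function(k) {
      i <- idx[k, 1]; j <- idx[k, 2]
      v <- c(B[i, j], B[j, i])
      mean(abs(v[v != 0]))
    }, numeric(1))
    ord <- order(ids[idx[, 1]], ids[idx[, 2]])
    edges <- data.frame(gene_a = ids[idx[, 1]], gene_b = ids[idx[, 2]],
                        weight = w, stringsAsFactors = FALSE)[ord, ]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(gene_a = character(0), gene_b = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(genes = sort(ids), edges = edges, group = group_label,
                 alpha = alpha, lambda = lambda, rule = rule),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf(
    "gene_network [%s]: %d genes, %d edges (alpha=%g, lambda=%.4g, rule=%s)\n",
    x$group, length(x$genes), nrow(x$edges), x$alpha, x$lambda, x$rule))
  invisible(x)
}

#' Degree centrality table
#'
#' Degree = number of incident edges ("edge genes") per gene. Sorted by
#' degree descending; ties broken by gene ID so the ordering is
#' deterministic.
#'
#' @param net a [build_network()] result.
#' @return data frame `gene_id`, `degree`, sorted descending.
#' @export
degree_centrality <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  deg <- stats::setNames(integer(length(net$genes)), net$genes)
  if (nrow(net$edges)) {
    t1 <- table(net$edges$gene_a); t2 <- table(net$edges$gene_b)
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
    deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
  }
  out <- data.frame(gene_id = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Select hub genes by a degree threshold
#'
#' A gene is a hub when its degree is at least `degree_min` (inclusive; the
#' operational rule "over 26 degrees" with default 26). The coefficient of
#' variation of the selected hubs' degrees (sd/mean) is recorded for
#' reference but never gates selection.
#'
#' @param degrees a degree table from [degree_centrality()] (or a
#'   `gene_network`).
#' @param degree_min inclusive degree threshold (default 26).
#' @param group provenance label.
#' @return object of class `hub_set`: `genes`, `degrees` (named), the rule,
#'   and `degree_cv`.
#' @export
select_hubs <- function(degrees, degree_min = 26, group = "") {
  if (inherits(degrees, "gene_network")) degrees <- degree_centrality(degrees)
  stop_if(nrow(degrees) == 0, "degree table is empty")
  keep <- degrees$degree >= degree_min
  if (!any(keep)) warning("no gene reaches degree ", degree_min,
                          "; hub set is empty")
  d <- stats::setNames(degrees$degree[keep], degrees$gene_id[keep])
  cv <- if (length(d) >= 2 && mean(d) > 0) stats::sd(d) / mean(d) else NA_real_
  structure(list(genes = names(d), degrees = d, degree_min = degree_min,
                 degree_cv = cv, group = group),
            class = "hub_set")
}

#' @export
print.hub_set <- function(x, ...) {
  cat(sprintf("hub_set [%s]: %d hubs (degree >= %d, degree CV %.3f)\n",
              x$group, length(x$genes), x$degree_min, x$degree_cv))
  invisible(x)
}

#' Re-estimate the network over hub genes only
#'
#' The "hub of hubs" analysis: the nodewise lasso is rerun on the
#' column-subset matrix restricted to the hub genes (so the penalty's `p` is
#' the number of hubs) rather than taking the induced subgraph of the full
#' network — connections among hubs are re-estimated without their edge
#' genes.
#'
#' @param X the same samples x genes standardized matrix used for the full
#'   network.
#' @param hubs a [select_hubs()] result or character vector of gene IDs.
#' @param ... passed to [build_network()] (`group_label`, `alpha`, `rule`).
#' @return a `gene_network` over the hub genes.
#' @export
hub_of_hub_network <- function(X, hubs, ...) {
  ids <- if (inherits(hubs, "hub_set")) hubs$genes else hubs
  stop_if(length(ids) < 3, "need at least 3 hub genes")
  missing <- setdiff(ids, colnames(X))
  stop_if(length(missing) > 0, "hub gene(s) absent from X: ",
          paste(utils::head(missing, 5), collapse = ", "))
  build_network(X[, ids, drop = FALSE], ...)
}

#' Scale-free topology diagnostic
#'
#' Bins genes by exact degree `k >= 1`, drops empty bins, and fits ordinary
#' least squares of `log10(count)` on `log10(k)`. A strongly negative slope
#' with high R-squared indicates a power-law (scale-free) degree
#' distribution.
#'
#' @param degrees degree table from [degree_centrality()] (or a
#'   `gene_network`), or a bare integer vector of degrees.
#' @return object of class `scale_free_fit`: `slope`, `intercept`,
#'   `r_squared`, and the `points` (log10 degree / log10 count) used.
#' @export
scale_free_fit <- function(degrees) {
  if (inherits(degrees, "gene_network")) degrees <- degree_centrality(degrees)
  d <- if (is.data.frame(degrees)) degrees$degree else degrees
  d <- d[d >= 1]
  tab <- table(d)
  stop_if(length(tab) < 3, "need at least 3 distinct positive degrees")
  pts <- data.frame(log10_degree = log10(as.numeric(names(tab))),
                    log10_count = log10(as.numeric(tab)))
  fit <- stats::lm(log10_count ~ log10_degree, data = pts)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((pts$log10_count - mean(pts$log10_count))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = 1 - ss_res / ss_tot,
                 points = pts),
            class = "scale_free_fit")
}

#' @export
print.scale_free_fit <- function(x, ...) {
  cat(sprintf("scale_free_fit: slope %.3f, R^2 %.3f (%d degree bins)\n",
              x$slope, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Network TSV / GraphML writers and reader
#'
#' The edge-list TSV has columns `gene_a`, `gene_b`, `weight`, `group` with
#' `gene_a < gene_b` lexicographically. Isolated genes are preserved through
#' a `# genes:` header comment so degree tables round-trip.
#'
#' @param net a `gene_network`.
#' @param path output file.
#' @return the path (writers, invisibly); a `gene_network` (reader).
#' @export
write_network_tsv <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# genes: ", paste(net$genes, collapse = ",")),
               paste0("# alpha: ", net$alpha, " lambda: ",
                      format(net$lambda, digits = 15),
                      " rule: ", net$rule)), con)
  df <- cbind(net$edges, group = rep(net$group, nrow(net$edges)))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path) {
  hdr <- readLines(path, n = 2)
  genes <- strsplit(sub("^# genes: ", "", hdr[1]), ",")[[1]]
  meta <- hdr[2]
  alpha <- as.numeric(sub(".*# alpha: ([^ ]+).*", "\\1", meta))
  lambda <- as.numeric(sub(".*lambda: ([^ ]+).*", "\\1", meta))
  rule <- sub(".*rule: ", "", meta)
  df <- utils::read.delim(path, skip = 2, stringsAsFactors = FALSE,
                          colClasses = c(gene_a = "character",
                                         gene_b = "character",
                                         weight = "numeric",
                                         group = "character"))
  group <- if (nrow(df)) df$group[1] else ""
  structure(list(genes = sort(genes),
                 edges = df[, c("gene_a", "gene_b", "weight")],
                 group = group, alpha = alpha, lambda = lambda, rule = rule),
            class = "gene_network")
}

#' @rdname write_network_tsv
#' @export
write_network_graphml <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Convert a gene_network to an igraph object
#'
#' @param net a `gene_network`.
#' @return an undirected weighted [igraph::graph] including isolated genes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$genes))
}
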