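#' Round half away from zero
#'
#' Decimal rounding where exact .5 cases round up in magnitude (the
#' convention behind percentages such as 52.9 = 100 * 127/240 reported to one
#' decimal), unlike [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Edge-recovery precision, recall and F1
#'
#' Compares an estimated edge set against a reference adjacency matrix.
#' Used to score network estimates against the planted graphs of the
#' synthetic-data generator.
#'
#' @param net a `gene_network` object (or a two-column character matrix /
#'   data frame of edges).
#' @param adjacency symmetric binary reference adjacency with gene IDs as
#'   dimnames.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
edge_f1 <- function(net, adjacency) {
  est <- edge_keys(net)
  ids <- rownames(adjacency)
  idx <- which(upper.tri(adjacency) & adjacency != 0, arr.ind = TRUE)
  truth <- paste(pmin(ids[idx[, 1]], ids[idx[, 2]]),
                 pmax(ids[idx[, 1]], ids[idx[, 2]]), sep = "\t")
  tp <- sum(est %in% truth)
  fp <- length(est) - tp
  fn <- length(truth) - tp
  precision <- if (length(est)) tp / length(est) else NA_real_
  recall <- if (length(truth)) tp / length(truth) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0)
    2 * precision * recall / (precision + recall) else 0
  list(tp = tp, fp = fp, fn = fn,
       precision = precision, recall = recall, f1 = f1)
}

# Canonical "a\tb" keys (a < b lexicographically) for an edge table.
edge_keys <- function(net) {
  ed <- if (inherits(net, "gene_network")) net$edges else as.data.frame(net)
  if (nrow(ed) == 0) return(character(0))
  paste(pmin(ed[[1]], ed[[2]]), pmax(ed[[1]], ed[[2]]), sep = "\t")
}

# Neighbor set of `gene` in a gene_network (character vector, sorted).
neighbors_of <- function(net, gene) {
  ed <- net$edges
  out <- c(ed$gene_b[ed$gene_a == gene], ed$gene_a[ed$gene_b == gene])
  sort(unique(out))
}

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)
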