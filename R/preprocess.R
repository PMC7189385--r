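#' Remove genes with zeros in more than half the samples
#'
#' RNA-seq matrices carry many exact zeros; genes whose expression is zero in
#' more than `max_zero_fraction` of all samples are removed before any
#' transformation. The removal is strict: a gene with zeros in exactly half
#' the samples is kept.
#'
#' @param x an [expr_set].
#' @param max_zero_fraction highest tolerated zero fraction (default 0.5).
#' @return the filtered `expr_set` (sample set unchanged, gene order
#'   preserved).
#' @export
filter_zero_genes <- function(x, max_zero_fraction = 0.5) {
  stopifnot(inherits(x, "expr_set"))
  stop_if(nrow(x$values) == 0 || ncol(x$values) == 0, "empty matrix")
  zf <- rowMeans(x$values == 0)
  expr_set(x$values[zf <= max_zero_fraction, , drop = FALSE], x$clinical)
}

#' Log2 transform and per-gene standardization
#'
#' Applies `x -> log2(x + 1)` then centers and scales each gene to mean 0,
#' sd 1. The scope of the mean/sd is either all samples jointly (the DEG
#' screen's convention) or within each group separately (the network
#' estimator's convention, so each group's network is fitted on its own
#' z-scores). Genes with zero variance in any scope stratum are dropped with
#' a warning.
#'
#' @param x an [expr_set].
#' @param scope `"all_samples"` or `"within_group"`.
#' @return list with `z` (genes x samples standardized matrix), `log2`
#'   (genes x samples log2 matrix, pre-standardization, same genes), and
#'   `dropped` (IDs of zero-variance genes).
#' @export
log2_standardize <- function(x, scope = c("all_samples", "within_group")) {
  stopifnot(inherits(x, "expr_set"))
  scope <- match.arg(scope)
  lg <- log2(x$values + 1)
  strata <- if (scope == "all_samples") list(seq_len(ncol(lg)))
            else split(seq_len(ncol(lg)), x$clinical$group)
  stop_if(any(lengths(strata) < 2),
          "each standardization stratum needs at least 2 samples")
  z <- lg
  keep <- rep(TRUE, nrow(lg))
  for (cols in strata) {
    m <- rowMeans(lg[, cols, drop = FALSE])
    s <- apply(lg[, cols, drop = FALSE], 1, stats::sd)
    keep <- keep & s > 0
    z[, cols] <- (lg[, cols, drop = FALSE] - m) / s
  }
  if (any(!keep))
    warning(sum(!keep), " zero-variance gene(s) dropped: ",
            paste(utils::head(rownames(lg)[!keep], 5), collapse = ", "))
  list(z = z[keep, , drop = FALSE], log2 = lg[keep, , drop = FALSE],
       dropped = rownames(lg)[!keep])
}

#' Two-group differential-expression screen
#'
#' Per gene: a two-sided two-sample t-test on standardized log2 values
#' (Welch by default), a two-sided Wilcoxon rank-sum test, group medians on
#' the log2 (pre-standardization) scale, and a direction call (`up` when the
#' LN+ median exceeds the LN- median). The DEG set comprises genes with
#' t-test p-value strictly below `p_threshold` (no multiplicity correction;
#' a Benjamini-Hochberg column is reported for reference but never gates) and
#' an unambiguous direction. Optionally the Wilcoxon p-value can gate
#' instead.
#'
#' @param x an [expr_set] (already zero-filtered).
#' @param p_threshold DEG p-value cutoff (default 0.005, strict `<`).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @param gate which test's p-value defines DEG membership.
#' @return list with `table` (data frame: `gene_id`, `t_pvalue`,
#'   `wilcoxon_pvalue`, `median_log2_pos`, `median_log2_neg`, `direction`,
#'   `bh_qvalue`, `in_deg_set`) and `deg_genes` (character vector).
#' @export
run_deg <- function(x, p_threshold = 0.005, var_equal = FALSE,
                    gate = c("t", "wilcoxon")) {
  stopifnot(inherits(x, "expr_set"))
  gate <- match.arg(gate)
  ipos <- group_idx(x, "LNpos"); ineg <- group_idx(x, "LNneg")
  stop_if(length(ipos) < 2 || length(ineg) < 2,
          "each group needs at least 2 samples")
  std <- log2_standardize(x, scope = "all_samples")
  z <- std$z; lg <- std$log2
  exact_wilcox <- length(ipos) <= 25 && length(ineg) <= 25

  res <- lapply(rownames(z), function(g) {
    zp <- z[g, ipos]; zn <- z[g, ineg]
    tp <- if (stats::sd(zp) == 0 && stats::sd(zn) == 0) {
      # degenerate: both groups constant (t.test would error)
      if (mean(zp) == mean(zn)) 1 else 0
    } else stats::t.test(zp, zn, var.equal = var_equal)$p.value
    wp <- suppressWarnings(
      stats::wilcox.test(lg[g, ipos], lg[g, ineg],
                         exact = exact_wilcox)$p.value)
    mp <- stats::median(lg[g, ipos]); mn <- stats::median(lg[g, ineg])
    data.frame(gene_id = g, t_pvalue = tp, wilcoxon_pvalue = wp,
               median_log2_pos = mp, median_log2_neg = mn,
               direction = if (mp > mn) "up" else if (mp < mn) "down"
                           else "tie",
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  tab$bh_qvalue <- stats::p.adjust(tab$t_pvalue, method = "BH")
  gate_p <- if (gate == "t") tab$t_pvalue else tab$wilcoxon_pvalue
  tab$in_deg_set <- gate_p < p_threshold & tab$direction != "tie"
  list(table = tab, deg_genes = tab$gene_id[tab$in_deg_set])
}

#' Write / read a DEG table TSV
#'
#' @param deg result of [run_deg()] (or its `table` component).
#' @param path file path.
#' @return `read_deg_tsv()` returns the table data frame.
#' @export
write_deg_tsv <- function(deg, path) {
  tab <- if (is.data.frame(deg)) deg else deg$table
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_deg_tsv
#' @export
read_deg_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
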