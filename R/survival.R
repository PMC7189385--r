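#' Median (or quantile) split of samples by one gene's expression
#'
#' Samples with `log2(x + 1)` expression strictly above the per-gene
#' quantile (default the median) are labeled `"high"`, the rest `"low"`;
#' ties at the cut go to `"low"`, so with an odd number of distinct values
#' the low stratum holds the larger half.
#'
#' @param x an [expr_set].
#' @param gene_id gene to split on.
#' @param quantile cut quantile in (0, 1), default 0.5.
#' @return character vector (`"high"`/`"low"`) named by sample ID.
#' @export
split_by_expression <- function(x, gene_id, quantile = 0.5) {
  stopifnot(inherits(x, "expr_set"))
  stop_if(!gene_id %in% rownames(x$values), "gene not found: ", gene_id)
  stop_if(ncol(x$values) < 2, "need at least 2 samples")
  lg <- log2(x$values[gene_id, ] + 1)
  cut <- stats::quantile(lg, quantile, names = FALSE)
  stats::setNames(ifelse(lg > cut, "high", "low"), colnames(x$values))
}

#' Kaplan-Meier product-limit curve
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the distinct event times
#' `t_i` with `d_i` events among `n_i` at risk; times with only censoring
#' shrink the risk set but leave the curve unchanged. Computed with
#' [survival::survfit()].
#'
#' @param time nonnegative observed times.
#' @param event 0/1 event indicators.
#' @return data frame of class `km_curve` with one row per distinct event
#'   time: `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_estimate <- function(time, event) {
  stop_if(length(time) == 0, "empty stratum")
  stop_if(any(!is.finite(time)) || any(time < 0),
          "times must be finite and >= 0")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  out <- data.frame(time = fit$time[keep],
                    n_risk = fit$n.risk[keep],
                    n_event = fit$n.event[keep],
                    survival = fit$surv[keep])
  rownames(out) <- NULL
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed number of events in one stratum
#' is compared with its hypergeometric expectation given the risk sets; the
#' statistic `(sum O - sum E)^2 / sum V` is referred to chi-square with 1
#' degree of freedom. Computed with [survival::survdiff()].
#'
#' @param time,event observed times and 0/1 indicators.
#' @param stratum two-level grouping vector.
#' @return list with `chisq`, `df = 1`, `p_value`, and the per-stratum
#'   observed/expected event counts.
#' @export
logrank_test <- function(time, event, stratum) {
  stratum <- as.factor(stratum)
  stop_if(nlevels(droplevels(stratum)) != 2,
          "need exactly two nonempty strata")
  stop_if(sum(event) == 0, "no events observed")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ stratum)
  list(chisq = unname(sd_$chisq), df = 1,
       p_value = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
       observed = sd_$obs, expected = sd_$exp)
}

#' Survival screen over a gene list
#'
#' For each gene: median split on expression, Kaplan-Meier per stratum, and
#' a log-rank test; the disadvantaged stratum is the one with more observed
#' than expected events (for a significant gene, the stratum with the worse
#' survival curve). Genes absent from the matrix, or whose split leaves a
#' stratum empty, are skipped with a warning.
#'
#' @param x an [expr_set] with survival annotations.
#' @param gene_list genes to screen (defaults to all).
#' @param quantile split quantile, see [split_by_expression()].
#' @return data frame sorted by p-value: `gene_id`, `n_high`, `n_low`,
#'   `logrank_chisq`, `p_value`, `disadvantaged_stratum`.
#' @export
survival_screen <- function(x, gene_list = rownames(x$values),
                            quantile = 0.5) {
  stopifnot(inherits(x, "expr_set"))
  stop_if(is.null(x$clinical$os_time) || is.null(x$clinical$os_event),
          "survival annotations (os_time, os_event) are required")
  if (length(gene_list) == 0)
    return(data.frame(gene_id = character(0), n_high = integer(0),
                      n_low = integer(0), logrank_chisq = numeric(0),
                      p_value = numeric(0),
                      disadvantaged_stratum = character(0),
                      stringsAsFactors = FALSE))
  absent <- setdiff(gene_list, rownames(x$values))
  if (length(absent))
    warning("skipping gene(s) without expression rows: ",
            paste(utils::head(absent, 5), collapse = ", "))
  gene_list <- setdiff(gene_list, absent)
  tm <- x$clinical$os_time; ev <- x$clinical$os_event
  rows <- lapply(gene_list, function(g) {
    s <- split_by_expression(x, g, quantile)
    if (length(unique(s)) < 2 || sum(ev) == 0) {
      warning("degenerate split for ", g, "; skipped")
      return(NULL)
    }
    lr <- logrank_test(tm, ev, s)
    oe <- lr$observed - lr$expected
    worse <- levels(as.factor(s))[which.max(oe)]
    data.frame(gene_id = g,
               n_high = sum(s == "high"), n_low = sum(s == "low"),
               logrank_chisq = lr$chisq, p_value = lr$p_value,
               disadvantaged_stratum = worse, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(survival_screen(x, character(0)))
  out <- out[order(out$p_value, out$gene_id), ]
  rownames(out) <- NULL
  out
}
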