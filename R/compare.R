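#' Common hubs between two groups' hub sets
#'
#' Intersection of the two hub sets with the overlap expressed as a
#' percentage of each set, rounded half-up to one decimal (so hub sets of
#' 240 and 353 genes sharing 127 give 52.9 and 34.0).
#'
#' @param hubs_a,hubs_b [select_hubs()] results or character vectors.
#' @return list: `common` (sorted gene IDs), `n_a`, `n_b`, `n_common`,
#'   `pct_common_vs_a`, `pct_common_vs_b`.
#' @export
compare_hub_sets <- function(hubs_a, hubs_b) {
  a <- if (inherits(hubs_a, "hub_set")) hubs_a$genes else hubs_a
  b <- if (inherits(hubs_b, "hub_set")) hubs_b$genes else hubs_b
  stop_if(length(a) == 0 || length(b) == 0, "hub sets must be nonempty")
  common <- sort(intersect(a, b))
  list(common = common,
       n_a = length(a), n_b = length(b), n_common = length(common),
       pct_common_vs_a = round_half_up(100 * length(common) / length(a), 1),
       pct_common_vs_b = round_half_up(100 * length(common) / length(b), 1))
}

#' Shared and private edge genes of each hub across two networks
#'
#' For each hub g, counts the neighbors ("edge genes") it shares between the
#' two networks (`shared = |N_A(g) intersect N_B(g)|`) and the neighbors
#' private to each (`private_a`, `private_b`), so that
#' `shared + private_a = degree_a` and `shared + private_b = degree_b`
#' row by row. Summary percentages are reported both as
#' 100 * mean(shared) / mean(degree) (ratio of means, the default display)
#' and as the mean of per-hub shared fractions.
#'
#' @param net_a,net_b two `gene_network` objects over a shared gene universe.
#' @param hubs gene IDs (or a `hub_set`) to profile.
#' @return list with `per_hub` (data frame) and `summary` (means, min-max
#'   ranges, and percentage summaries per group).
#' @export
edge_overlap_per_hub <- function(net_a, net_b, hubs) {
  ids <- if (inherits(hubs, "hub_set")) hubs$genes else hubs
  stop_if(length(ids) == 0, "no hubs supplied")
  absent <- setdiff(ids, union(net_a$genes, net_b$genes))
  if (length(absent))
    warning("hub(s) absent from both networks recorded with degree 0: ",
            paste(utils::head(absent, 5), collapse = ", "))
  rows <- lapply(sort(ids), function(g) {
    na_ <- neighbors_of(net_a, g); nb_ <- neighbors_of(net_b, g)
    shared <- length(intersect(na_, nb_))
    data.frame(hub = g, degree_a = length(na_), degree_b = length(nb_),
               shared = shared,
               private_a = length(na_) - shared,
               private_b = length(nb_) - shared,
               stringsAsFactors = FALSE)
  })
  per_hub <- do.call(rbind, rows)
  summarize <- function(col) c(mean = mean(per_hub[[col]]),
                               min = min(per_hub[[col]]),
                               max = max(per_hub[[col]]))
  pct <- function(deg_col) {
    md <- mean(per_hub[[deg_col]])
    ratio <- if (md > 0) 100 * mean(per_hub$shared) / md else NA_real_
    frac <- per_hub$shared / per_hub[[deg_col]]
    list(ratio_of_means = round_half_up(ratio, 1),
         mean_of_fractions =
           round_half_up(100 * mean(frac[is.finite(frac)]), 1))
  }
  list(per_hub = per_hub,
       summary = list(degree_a = summarize("degree_a"),
                      degree_b = summarize("degree_b"),
                      shared = summarize("shared"),
                      private_a = summarize("private_a"),
                      private_b = summarize("private_b"),
                      pct_shared_a = pct("degree_a"),
                      pct_shared_b = pct("degree_b")))
}

#' Apply one group's hub list to the other group's network
#'
#' Profiles how the degrees and edge genes of hubs selected in one group
#' change when looked up in the other group's network, including the
#' shared/private edge-gene statistics of [edge_overlap_per_hub()].
#'
#' @param hubs_from a `hub_set` (or gene IDs) selected in the source group.
#' @param net_other the other group's `gene_network`.
#' @param net_own the source group's `gene_network`.
#' @return list with `per_hub` (data frame: degrees in both networks,
#'   shared/private counts) and `summary` as in [edge_overlap_per_hub()];
#'   `degree_other = 0` rows are retained.
#' @export
cross_apply_hubs <- function(hubs_from, net_other, net_own) {
  ov <- edge_overlap_per_hub(net_own, net_other, hubs_from)
  names(ov$per_hub)[names(ov$per_hub) == "degree_a"] <- "degree_own"
  names(ov$per_hub)[names(ov$per_hub) == "degree_b"] <- "degree_other"
  names(ov$per_hub)[names(ov$per_hub) == "private_a"] <- "private_own"
  names(ov$per_hub)[names(ov$per_hub) == "private_b"] <- "private_other"
  ov
}

#' Venn partition of the DEG set against the two hub sets
#'
#' Splits the union of three gene sets (DEGs, LN+ hubs, LN- hubs) into its 7
#' disjoint regions, and emits marker-candidate records for every gene in a
#' region intersecting the DEG set: degree in each group's network, group
#' medians on the log2 scale, direction, and t-test p-value, sorted by
#' p-value.
#'
#' @param deg_genes character vector of DEG IDs.
#' @param hubs_pos,hubs_neg `hub_set` objects (or gene ID vectors).
#' @param deg_table the table from [run_deg()].
#' @param degrees_pos,degrees_neg degree tables from [degree_centrality()].
#' @return list with `regions` (named list of 7 sorted gene vectors),
#'   `counts` (named integer vector), and `candidates` (Table-2-style data
#'   frame with a `region` column).
#' @export
venn_partition <- function(deg_genes, hubs_pos, hubs_neg, deg_table = NULL,
                           degrees_pos = NULL, degrees_neg = NULL) {
  A <- unique(deg_genes)
  B <- if (inherits(hubs_pos, "hub_set")) hubs_pos$genes else hubs_pos
  C <- if (inherits(hubs_neg, "hub_set")) hubs_neg$genes else hubs_neg
  regions <- list(
    deg_only            = setdiff(A, union(B, C)),
    hubs_pos_only       = setdiff(B, union(A, C)),
    hubs_neg_only       = setdiff(C, union(A, B)),
    deg_and_hubs_pos    = setdiff(intersect(A, B), C),
    deg_and_hubs_neg    = setdiff(intersect(A, C), B),
    hubs_pos_and_neg    = setdiff(intersect(B, C), A),
    deg_and_both_hubs   = intersect(intersect(A, B), C))
  regions <- lapply(regions, sort)
  counts <- vapply(regions, length, integer(1))

  candidates <- NULL
  if (!is.null(deg_table)) {
    deg_regions <- c("deg_and_both_hubs", "deg_and_hubs_pos",
                     "deg_and_hubs_neg")
    lookup <- function(tab, g) {
      if (is.null(tab)) return(NA_integer_)
      i <- match(g, tab$gene_id)
      ifelse(is.na(i), NA_integer_, tab$degree[i])
    }
    rows <- lapply(deg_regions, function(rg) {
      gs <- regions[[rg]]
      if (!length(gs)) return(NULL)
      i <- match(gs, deg_table$gene_id)
      data.frame(gene_id = gs, region = rg,
                 degree_pos = lookup(degrees_pos, gs),
                 degree_neg = lookup(degrees_neg, gs),
                 median_log2_pos = deg_table$median_log2_pos[i],
                 median_log2_neg = deg_table$median_log2_neg[i],
                 direction = deg_table$direction[i],
                 t_pvalue = deg_table$t_pvalue[i],
                 stringsAsFactors = FALSE)
    })
    candidates <- do.call(rbind, rows)
    if (!is.null(candidates) && nrow(candidates)) {
      candidates <- candidates[order(candidates$region,
                                     candidates$t_pvalue), ]
      rownames(candidates) <- NULL
    }
  }
  list(regions = regions, counts = counts, candidates = candidates)
}
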