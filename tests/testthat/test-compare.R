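test_that("common-hub percentages are rounded half-up to one decimal", {
  a <- paste0("a", 1:240)
  b <- c(a[1:127], paste0("b", 1:226))      # |B| = 353, |A ∩ B| = 127
  cmp <- compare_hub_sets(a, b)
  expect_equal(cmp$n_common, 127)
  expect_equal(cmp$pct_common_vs_a, 52.9)   # 127/240
  expect_equal(cmp$pct_common_vs_b, 36.0)   # 127/353 = 35.977...

  # identity and disjoint extremes
  same <- compare_hub_sets(a, a)
  expect_equal(same$pct_common_vs_a, 100)
  expect_equal(same$pct_common_vs_b, 100)
  disjoint <- compare_hub_sets(paste0("x", 1:5), paste0("y", 1:7))
  expect_equal(disjoint$pct_common_vs_a, 0)
  expect_equal(disjoint$n_common, 0)
  expect_error(compare_hub_sets(character(0), a), "nonempty")

  # symmetry: swapping the sets swaps the percentages
  swapped <- compare_hub_sets(b, a)
  expect_equal(swapped$pct_common_vs_a, cmp$pct_common_vs_b)
  expect_equal(swapped$pct_common_vs_b, cmp$pct_common_vs_a)
  expect_identical(swapped$common, cmp$common)
})

test_that("round_half_up breaks .5 ties upward unlike round()", {
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(c(1.04, 1.05, 1.06), 1), c(1.0, 1.1, 1.1))
})

toy_net <- function(edges, genes, group = "") {
  structure(list(genes = sort(genes),
                 edges = data.frame(gene_a = pmin(edges[, 1], edges[, 2]),
                                    gene_b = pmax(edges[, 1], edges[, 2]),
                                    weight = 1, stringsAsFactors = FALSE),
                 group = group, alpha = 0.05, lambda = 0.1, rule = "or"),
            class = "gene_network")
}

test_that("per-hub shared/private edge genes follow set arithmetic", {
  genes <- c("g", "w", "x", "y", "z")
  net_a <- toy_net(cbind("g", c("x", "y", "z")), genes, "A")
  net_b <- toy_net(cbind("g", c("y", "z", "w")), genes, "B")
  ov <- edge_overlap_per_hub(net_a, net_b, "g")
  expect_equal(ov$per_hub$shared, 2)        # {y, z}
  expect_equal(ov$per_hub$private_a, 1)     # {x}
  expect_equal(ov$per_hub$private_b, 1)     # {w}
  # row identity shared + private = degree
  expect_equal(ov$per_hub$shared + ov$per_hub$private_a, ov$per_hub$degree_a)
  expect_equal(ov$per_hub$shared + ov$per_hub$private_b, ov$per_hub$degree_b)

  # identical networks: shared = degree, private = 0
  same <- edge_overlap_per_hub(net_a, net_a, c("g", "x"))
  expect_equal(same$per_hub$shared, same$per_hub$degree_a)
  expect_true(all(same$per_hub$private_a == 0))
  expect_equal(same$summary$pct_shared_a$ratio_of_means, 100)

  # edge-disjoint networks: shared = 0 everywhere
  net_c <- toy_net(cbind("x", "y"), genes, "C")
  disj <- edge_overlap_per_hub(net_a, net_c, "g")
  expect_equal(disj$per_hub$shared, 0)

  expect_warning(edge_overlap_per_hub(net_a, net_b, c("g", "nope")),
                 "absent")
})

test_that("per-hub identity holds on estimated networks", {
  cfg <- synthetic_config(n_genes = 25, n_samples_pos = 150,
                          n_samples_neg = 150, zero_inflation = 0,
                          n_de_genes = 0, seed = 81)
  sim <- simulate_dataset(cfg)
  std <- log2_standardize(sim$data, "within_group")
  nets <- lapply(c(pos = "LNpos", neg = "LNneg"), function(g)
    build_network(t(std$z[, sim$data$clinical$group == g]), g))
  conn <- select_hubs(degree_centrality(nets$pos), degree_min = 1)
  ov <- edge_overlap_per_hub(nets$pos, nets$neg, conn)
  expect_equal(ov$per_hub$shared + ov$per_hub$private_a, ov$per_hub$degree_a)
  expect_equal(ov$per_hub$shared + ov$per_hub$private_b, ov$per_hub$degree_b)
})

test_that("cross-applied hubs keep their own-network degrees", {
  genes <- c("g", "h", "x", "y", "z")
  net_a <- toy_net(cbind("g", c("x", "y")), genes, "A")
  net_b <- toy_net(cbind("x", "y"), genes, "B")
  ca <- cross_apply_hubs(c("g"), net_b, net_a)
  expect_equal(ca$per_hub$degree_own, 2)
  expect_equal(ca$per_hub$degree_other, 0)   # no edges in B, row retained
  expect_equal(ca$per_hub$shared, 0)

  # hubs applied to their own network: degrees unchanged
  self <- cross_apply_hubs(c("g"), net_a, net_a)
  expect_equal(self$per_hub$degree_other, self$per_hub$degree_own)
})

test_that("shared-core construction shows up in cross-group edge overlap", {
  # planted graphs share half their edges; the estimated shared-edge
  # fraction of common hubs should sit near that level
  fracs <- vapply(1:10, function(s) {
    cfg <- synthetic_config(n_genes = 50, n_samples_pos = 1000,
                            n_samples_neg = 1000, shared_core_fraction = 0.5,
                            zero_inflation = 0, n_de_genes = 0,
                            seed = 500 + s)
    sim <- simulate_dataset(cfg)
    std <- log2_standardize(sim$data, "within_group")
    nets <- lapply(c(pos = "LNpos", neg = "LNneg"), function(g)
      build_network(t(std$z[, sim$data$clinical$group == g]), g))
    hubs <- lapply(nets, function(nt)
      select_hubs(degree_centrality(nt), degree_min = 2))
    common <- compare_hub_sets(hubs$pos, hubs$neg)$common
    ov <- edge_overlap_per_hub(nets$pos, nets$neg, common)
    ov$summary$pct_shared_a$ratio_of_means / 100
  }, numeric(1))
  expect_lt(abs(median(fracs) - 0.5), 0.15)
})

test_that("Venn partition enumerates the seven regions disjointly", {
  A <- c("1", "2", "3"); B <- c("2", "3", "4"); C <- c("3", "4", "5")
  vp <- venn_partition(A, B, C)
  expect_equal(unname(vp$counts["deg_and_both_hubs"]), 1L)   # {3}
  expect_equal(unname(vp$counts["deg_and_hubs_pos"]), 1L)    # {2}
  expect_equal(unname(vp$counts["hubs_pos_and_neg"]), 1L)    # {4}
  expect_equal(unname(vp$counts["deg_only"]), 1L)            # {1}
  expect_equal(unname(vp$counts["hubs_neg_only"]), 1L)       # {5}
  expect_equal(unname(vp$counts["deg_and_hubs_neg"]), 0L)
  expect_equal(unname(vp$counts["hubs_pos_only"]), 0L)
  # disjoint and exhaustive over the union
  all_genes <- unlist(vp$regions)
  expect_equal(sum(vp$counts), length(union(A, union(B, C))))
  expect_false(anyDuplicated(all_genes) > 0)

  # three identical sets collapse to one region
  same <- venn_partition(A, A, A)
  expect_equal(unname(same$counts["deg_and_both_hubs"]), 3L)
  expect_equal(sum(same$counts), 3)

  # pairwise-disjoint sets give three singleton regions
  disj <- venn_partition("a", "b", "c")
  expect_equal(sort(unname(disj$counts), decreasing = TRUE),
               c(1L, 1L, 1L, 0L, 0L, 0L, 0L))
})

test_that("marker-candidate records carry degrees, medians and direction", {
  deg_table <- data.frame(
    gene_id = c("1", "2", "3"),
    t_pvalue = c(0.001, 0.004, 0.0001),
    wilcoxon_pvalue = c(0.002, 0.005, 0.0002),
    median_log2_pos = c(5, 6, 7), median_log2_neg = c(4, 7, 6),
    direction = c("up", "down", "up"), stringsAsFactors = FALSE)
  degrees <- data.frame(gene_id = c("1", "2", "3", "4", "5"),
                        degree = c(10L, 20L, 30L, 5L, 2L))
  vp <- venn_partition(c("1", "2", "3"), c("2", "3", "4"), c("3", "4", "5"),
                       deg_table, degrees, degrees)
  cand <- vp$candidates
  expect_equal(cand$gene_id[cand$region == "deg_and_both_hubs"], "3")
  row3 <- cand[cand$gene_id == "3", ]
  expect_equal(row3$degree_pos, 30L)
  expect_equal(row3$median_log2_pos, 7)
  expect_equal(row3$direction, "up")
  # sorted by p within region
  expect_false(is.unsorted(cand$t_pvalue[cand$region == cand$region[1]]))
})
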