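test_that("significance-calibrated penalty matches the closed form", {
  # 2 * 1 * 100^(-1/2) * qnorm(1 - 0.05/200) = 0.2 * qnorm(0.99975)
  expect_equal(mb_penalty(n = 100, p = 10, alpha = 0.05, sigma_hat = 1),
               0.2 * qnorm(0.99975), tolerance = 1e-12)
  expect_equal(round(mb_penalty(100, 10), 3), 0.696)
  # monotone in p, linear in sigma_hat, degenerate at sigma_hat = 0
  expect_gt(mb_penalty(100, 20), mb_penalty(100, 10))
  expect_equal(mb_penalty(100, 10, sigma_hat = 2),
               2 * mb_penalty(100, 10))
  expect_warning(l0 <- mb_penalty(100, 10, sigma_hat = 0), "degenerate")
  expect_equal(l0, 0)
  expect_error(mb_penalty(1, 10), "n >= 2")
  expect_error(mb_penalty(100, 10, alpha = 1.5), "alpha")
})

test_that("chain graphical model: neighborhoods recovered at small penalty", {
  # chain 1-2-3: gene 2 conditionally depends on both ends, 1 and 3 only
  # through 2
  omega <- matrix(c(2, -1, 0, -1, 3, -1, 0, -1, 2), 3, 3,
                  dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  set.seed(10)
  R <- chol(omega)
  X <- t(backsolve(R, matrix(rnorm(3 * 5000), 3)))
  colnames(X) <- paste0("g", 1:3)
  X <- std_cols(X)
  b2 <- neighborhood_select(X, "g2", lambda = 0.1)
  expect_true(all(b2 != 0))
  b1 <- neighborhood_select(X, "g1", lambda = 0.1)
  expect_true(b1["g2"] != 0)
  expect_equal(unname(b1["g3"]), 0)
})

test_that("network construction is symmetric, deterministic and well-formed", {
  cfg <- synthetic_config(n_genes = 20, n_samples_pos = 150,
                          n_samples_neg = 5, attachment_m = 1,
                          zero_inflation = 0, n_de_genes = 0, seed = 21)
  sim <- simulate_dataset(cfg)
  std <- log2_standardize(sim$data, "within_group")
  X <- t(std$z[, sim$data$clinical$group == "LNpos"])
  net <- build_network(X, "LNpos")
  expect_s3_class(net, "gene_network")
  expect_true(all(net$edges$weight > 0))
  expect_true(all(net$edges$gene_a < net$edges$gene_b))
  expect_false(any(net$edges$gene_a == net$edges$gene_b))

  # pure function: repeated calls agree exactly
  expect_identical(net$edges, build_network(X, "LNpos")$edges)

  # permutation equivariance: shuffling gene columns relabels but preserves
  # the edge set
  perm <- sample(ncol(X))
  net_p <- build_network(X[, perm], "LNpos")
  expect_setequal(edge_keys(net_p), edge_keys(net))

  # handshake lemma on the degree table
  deg <- degree_centrality(net)
  expect_equal(sum(deg$degree), 2 * nrow(net$edges))

  expect_error(build_network(X[, 1:2], "LNpos"), "3 genes")
})

test_that("degree centrality ranks hubs first with deterministic ties", {
  star <- structure(list(
    genes = paste0("g", 1:6),
    edges = data.frame(gene_a = "g1", gene_b = paste0("g", 2:6),
                       weight = 1, stringsAsFactors = FALSE),
    group = "", alpha = 0.05, lambda = 0.1, rule = "or"),
    class = "gene_network")
  deg <- degree_centrality(star)
  expect_equal(deg$degree[deg$gene_id == "g1"], 5)
  expect_true(all(deg$degree[deg$gene_id != "g1"] == 1))
  expect_equal(deg$gene_id[1], "g1")
  expect_equal(deg$gene_id[-1], paste0("g", 2:6))  # lexicographic ties

  edgeless <- structure(list(
    genes = c("a", "b"), edges = star$edges[0, ], group = "",
    alpha = 0.05, lambda = 0.1, rule = "or"), class = "gene_network")
  expect_true(all(degree_centrality(edgeless)$degree == 0))
})

test_that("hub selection applies an inclusive degree threshold", {
  deg <- data.frame(gene_id = c("a", "b", "c"), degree = c(30L, 26L, 25L))
  hubs <- select_hubs(deg, degree_min = 26)
  expect_setequal(hubs$genes, c("a", "b"))
  expect_true(all(hubs$degrees >= hubs$degree_min))

  all_conn <- select_hubs(deg, degree_min = 1)
  expect_setequal(all_conn$genes, c("a", "b", "c"))

  expect_warning(empty <- select_hubs(deg, degree_min = 99), "empty")
  expect_length(empty$genes, 0)
  expect_error(select_hubs(deg[0, ]), "empty")
})

test_that("hub-of-hub network re-estimates over the hub subset", {
  cfg <- synthetic_config(n_genes = 15, n_samples_pos = 200,
                          n_samples_neg = 5, attachment_m = 1,
                          zero_inflation = 0, n_de_genes = 0, seed = 31)
  sim <- simulate_dataset(cfg)
  std <- log2_standardize(sim$data, "within_group")
  X <- t(std$z[, sim$data$clinical$group == "LNpos"])

  # hubs = all genes: identical procedure to the full build
  full <- build_network(X, "LNpos")
  same <- hub_of_hub_network(X, colnames(X), group_label = "LNpos")
  expect_identical(full$edges, same$edges)

  deg <- degree_centrality(full)
  hubs <- select_hubs(deg, degree_min = 2, group = "LNpos")
  if (length(hubs$genes) >= 3) {
    hoh <- hub_of_hub_network(X, hubs, group_label = "LNpos_hubs")
    expect_setequal(hoh$genes, hubs$genes)
    expect_true(all(hoh$edges$gene_a %in% hubs$genes))
    dh <- degree_centrality(hoh)
    expect_equal(sum(dh$degree), 2 * nrow(hoh$edges))
  }
  expect_error(hub_of_hub_network(X, c("g001", "g002")), "3 hub genes")
  expect_error(hub_of_hub_network(X, c("g001", "g002", "zz")), "absent")
})

test_that("hub-of-hub re-estimation recovers a chain restricted to hubs", {
  # chain over 10 genes: re-running the estimator on a gene subset must
  # recover the chain edges among those genes
  p <- 10
  ids <- sprintf("c%02d", 1:p)
  adj <- matrix(0, p, p, dimnames = list(ids, ids))
  for (i in 1:(p - 1)) adj[i, i + 1] <- adj[i + 1, i] <- 1
  f1s <- vapply(1:10, function(s) {
    set.seed(400 + s)
    omega <- graph_to_precision(adj)
    R <- chol(omega)
    X <- t(backsolve(R, matrix(rnorm(p * 400), p)))
    colnames(X) <- ids
    net <- build_network(std_cols(X), "chain")
    edge_f1(net, adj)$f1
  }, numeric(1))
  expect_gte(median(f1s), 0.7)
})

test_that("scale-free fit reproduces exact power laws and flags degeneracy", {
  # counts 16, 4, 1 at degrees 1, 2, 4: count = 16 * k^-2 exactly
  degrees <- rep(c(1, 2, 4), c(16, 4, 1))
  fit <- scale_free_fit(degrees)
  expect_equal(fit$slope, -2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(scale_free_fit(rep(3, 10)), "3 distinct")
})

test_that("attachment graphs look scale-free to the diagnostic", {
  fits <- lapply(1:10, function(s) {
    adj <- make_scale_free_graph(500, 2, seed = 50 + s)
    scale_free_fit(rowSums(adj))
  })
  expect_lt(median(vapply(fits, `[[`, numeric(1), "slope")), -1)
  expect_gte(median(vapply(fits, `[[`, numeric(1), "r_squared")), 0.6)
})

test_that("network TSV and GraphML writers round-trip and export", {
  cfg <- synthetic_config(n_genes = 12, n_samples_pos = 250,
                          n_samples_neg = 5, zero_inflation = 0,
                          n_de_genes = 0, seed = 61)
  sim <- simulate_dataset(cfg)
  std <- log2_standardize(sim$data, "within_group")
  X <- t(std$z[, sim$data$clinical$group == "LNpos"])
  net <- build_network(X, "LNpos")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_network_tsv(net, path)
  back <- read_network_tsv(path)
  expect_identical(back$genes, net$genes)
  expect_equal(back$edges$weight, net$edges$weight, tolerance = 1e-12)
  expect_identical(back$rule, net$rule)
  expect_identical(degree_centrality(back), degree_centrality(net))

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  expect_true(file.size(gml) > 0)
  g <- as_igraph(net)
  expect_equal(igraph::vcount(g), length(net$genes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
})

test_that("and-rule networks are nested within or-rule networks", {
  cfg <- synthetic_config(n_genes = 15, n_samples_pos = 100,
                          n_samples_neg = 5, zero_inflation = 0,
                          n_de_genes = 0, seed = 71)
  sim <- simulate_dataset(cfg)
  std <- log2_standardize(sim$data, "within_group")
  X <- t(std$z[, sim$data$clinical$group == "LNpos"])
  net_or <- build_network(X, "LNpos", rule = "or")
  net_and <- build_network(X, "LNpos", rule = "and")
  expect_true(all(edge_keys(net_and) %in% edge_keys(net_or)))
})
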