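# lymphnet

Group-wise gene-expression network analysis for two-arm RNA-seq studies —
built for the question of whether gene co-expression *wiring*, not just mean
expression, differs between lymph-node-positive (LN+) and
lymph-node-negative (LN−) colon tumors, and whether the hub genes of those
networks carry prognostic information.

Given a genes × samples expression matrix (RSEM-style normalized counts)
and a clinical table with group labels and overall survival, the package
runs, as separate composable functions or one pipeline call:

* **Preprocessing** — drop genes with zeros in more than half the samples,
  log2(x+1), per-gene standardization.
* **DEG screen** — per-gene Welch t-test on standardized values (DEG set at
  p < 0.005, uncorrected, by design), Wilcoxon p, group medians on the log2
  scale and up/down direction calls.
* **Network estimation** — per group, a Gaussian graphical model by
  nodewise LASSO neighborhood selection: each gene i is regressed on all
  others,

  ```
  b(i) = argmin_b  (1/2n) || X_i - X_{-i} b ||^2  +  lambda ||b||_1 ,
  lambda(alpha) = 2 * sigma_hat * n^(-1/2) * Phi^{-1}(1 - alpha / (2 p^2)) ,
  ```

  the significance-calibrated penalty of Meinshausen–Bühlmann neighborhood
  selection (alpha = 0.05 by default, sigma_hat = 1 on standardized data).
  Edges are symmetrized by the *or* rule and weighted by mean absolute
  coefficient. The lasso solver is exact cyclic coordinate descent,
  certified in the tests against an independent proximal-gradient solver
  and against glmnet.
* **Hubs** — degree centrality, inclusive degree threshold, hub-of-hub
  re-estimation over the hub genes only, and a log–log power-law fit of the
  degree distribution (scale-free diagnostic).
* **Comparison** — common hubs with overlap percentages, per-hub shared /
  private edge genes across the two networks, cross-application of one
  group's hubs to the other's network, and the 7-region Venn partition of
  {DEGs, LN+ hubs, LN− hubs} with Table-style marker-candidate records.
* **Survival** — median-split Kaplan–Meier curves and two-group log-rank
  tests per candidate gene (via the `survival` package).
* **Synthetic data** — a generator that plants scale-free graphical models
  with a shared edge core between groups, mean-shift DE genes, zero
  inflation and expression-driven exponential survival, with full ground
  truth for recovery testing.

See `vignettes/lymphnet-methods.Rmd` for the model, conventions, parameter
choices and limitations.

## Worked example

```r
library(lymphnet)

cfg <- list(
  simulate = list(n_genes = 50, n_samples_pos = 400, n_samples_neg = 400,
                  zero_inflation = 0, n_de_genes = 5, de_effect = 2,
                  surv_effect_genes = 1, seed = 1),
  degree_min = 3, seed = 1, out_dir = "run1")
s <- run_pipeline(cfg)
#> [lymphnet] simulated 50 genes x 800 samples (seed 1)
#> [lymphnet] zero filter kept 50/50 genes
#> [lymphnet] 5 DEGs at p < 0.005
#> [lymphnet] LNpos: 32 edges, 5 hubs (degree >= 3)
#> [lymphnet] LNneg: 34 edges, 7 hubs (degree >= 3)
#> [lymphnet] survival screen: 0 gene(s) at p <= 0.05 of 10
```

All 5 planted DE genes are recovered (`s$n_deg` is 5 with
`s$recovery$de_recovered` = 1), and the estimated networks match the
planted graphs well: `s$recovery$f1_pos` = 0.790, `s$recovery$f1_neg` =
0.819. The two groups share 2 of their hub genes
(`s$common_hubs$pct_common_vs_a` = 40% of the LN+ hubs), and both degree
distributions look scale-free (log–log slopes −1.33 and −1.74 with
R² ≈ 0.92–0.96). The hub screen above found no survival signal because the
planted effect gene is not a hub in this draw; screening it directly:

```r
sim <- simulate_dataset(do.call(synthetic_config, cfg$simulate))
survival_screen(sim$data, "g001")
#>   gene_id n_high n_low logrank_chisq      p_value disadvantaged_stratum
#> 1    g001    400   400      196.6355 1.132589e-44                  high
```

— samples with high expression of the planted gene (log-hazard slope 1 per
SD) have sharply worse survival, as constructed. Every stage's table is
also written under `run1/` (`deg.tsv`, `network_pos.tsv`, `degrees_*.tsv`,
`venn_counts.json`, `survival_screen.tsv`, a manifest with md5 sums, and
`summary.json`, which is byte-identical across reruns of the same config
and seed).

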