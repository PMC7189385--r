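#' Run the full two-group network analysis pipeline
#'
#' Orchestrates every stage from one config: simulate (or ingest) expression
#' + clinical data, zero-filter, DEG screen, per-group nodewise-lasso
#' networks, degree tables and scale-free fits, hub selection, hub-of-hub
#' networks, cross-group comparisons and Venn partition, and the survival
#' screen. Every stage output is written as TSV/JSON into `out_dir` along
#' with a manifest (stage, file, md5) and a `summary.json`; two runs with
#' the same config are byte-identical.
#'
#' @param config a named list (or path to a JSON file) with fields:
#'   `simulate` (arguments for [synthetic_config()]) or `expr_path` +
#'   `clin_path`; `p_threshold` (0.005), `alpha` (0.05), `rule` (`"or"`),
#'   `degree_min` (26), `survival_quantile` (0.5), `seed` (1), `out_dir`.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @param quiet suppress per-stage log lines.
#' @return invisibly, the summary list (also written to
#'   `out_dir/summary.json`).
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  defaults <- list(p_threshold = 0.005, alpha = 0.05, rule = "or",
                   degree_min = 26, survival_quantile = 0.5, seed = 1L)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  out_dir <- out_dir %||% config$out_dir
  stop_if(is.null(out_dir), "an output directory is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) if (!quiet) message("[lymphnet] ", ...)
  manifest <- list()
  note <- function(stage, files) {
    manifest[[length(manifest) + 1]] <<-
      data.frame(stage = stage, file = basename(files),
                 md5 = unname(tools::md5sum(files)),
                 stringsAsFactors = FALSE)
  }
  warnings_log <- character(0)
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  # --- input -----------------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    scfg <- do.call(synthetic_config, sim_args)
    sim <- simulate_dataset(scfg)
    truth <- sim$truth; dat <- sim$data
    write_truth(truth, file.path(out_dir, "truth"))
    log_line("simulated ", nrow(dat$values), " genes x ",
             ncol(dat$values), " samples (seed ", scfg$seed, ")")
  } else {
    stop_if(is.null(config$expr_path) || is.null(config$clin_path),
            "config needs either a `simulate` block or expr/clin paths")
    dat <- read_expr_tsv(config$expr_path, config$clin_path)
    log_line("read ", nrow(dat$values), " genes x ", ncol(dat$values),
             " samples")
  }
  write_expr_tsv(dat, file.path(out_dir, "expression.tsv"),
                 file.path(out_dir, "clinical.tsv"))
  note("input", file.path(out_dir, c("expression.tsv", "clinical.tsv")))

  # --- preprocess + DEG ------------------------------------------------
  filtered <- filter_zero_genes(dat)
  log_line("zero filter kept ", nrow(filtered$values), "/",
           nrow(dat$values), " genes")
  deg <- collect(run_deg(filtered, p_threshold = config$p_threshold))
  write_deg_tsv(deg, file.path(out_dir, "deg.tsv"))
  note("deg", file.path(out_dir, "deg.tsv"))
  log_line(length(deg$deg_genes), " DEGs at p < ", config$p_threshold)

  # --- per-group networks ---------------------------------------------
  std <- collect(log2_standardize(filtered, scope = "within_group"))
  groups <- c(pos = "LNpos", neg = "LNneg")
  nets <- list(); degs <- list(); hubs <- list(); sf <- list(); hoh <- list()
  for (k in names(groups)) {
    cols <- filtered$clinical$group == groups[[k]]
    X <- t(std$z[, cols, drop = FALSE])
    nets[[k]] <- build_network(X, group_label = groups[[k]],
                               alpha = config$alpha, rule = config$rule)
    degs[[k]] <- degree_centrality(nets[[k]])
    sf[[k]] <- tryCatch(scale_free_fit(degs[[k]]), error = function(e) NULL)
    hubs[[k]] <- collect(select_hubs(degs[[k]],
                                     degree_min = config$degree_min,
                                     group = groups[[k]]))
    np <- file.path(out_dir, paste0("network_", k, ".tsv"))
    dp <- file.path(out_dir, paste0("degrees_", k, ".tsv"))
    write_network_tsv(nets[[k]], np)
    utils::write.table(degs[[k]], dp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note(paste0("network_", k), c(np, dp))
    log_line(groups[[k]], ": ", nrow(nets[[k]]$edges), " edges, ",
             length(hubs[[k]]$genes), " hubs (degree >= ",
             config$degree_min, ")")
    if (length(hubs[[k]]$genes) >= 3)
      hoh[[k]] <- build_network(X[, hubs[[k]]$genes, drop = FALSE],
                                group_label = paste0(groups[[k]], "_hubs"),
                                alpha = config$alpha, rule = config$rule)
  }

  # --- comparisons -----------------------------------------------------
  comparison <- NULL; venn <- NULL; comparison_skip <- NULL
  if (length(hubs$pos$genes) && length(hubs$neg$genes)) {
    ch <- compare_hub_sets(hubs$pos, hubs$neg)
    overlap <- if (length(ch$common))
      collect(edge_overlap_per_hub(nets$pos, nets$neg, ch$common)) else NULL
    comparison <- list(common_hubs = ch,
                       overlap_summary = overlap$summary)
    if (!is.null(overlap)) {
      op <- file.path(out_dir, "common_hub_overlap.tsv")
      utils::write.table(overlap$per_hub, op, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      note("compare", op)
    }
    venn <- venn_partition(deg$deg_genes, hubs$pos, hubs$neg, deg$table,
                           degs$pos, degs$neg)
    jsonlite::write_json(as.list(venn$counts),
                         file.path(out_dir, "venn_counts.json"),
                         auto_unbox = TRUE, digits = NA)
    note("venn", file.path(out_dir, "venn_counts.json"))
    if (!is.null(venn$candidates) && nrow(venn$candidates)) {
      cp <- file.path(out_dir, "marker_candidates.tsv")
      utils::write.table(venn$candidates, cp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      note("venn", cp)
    }
  } else {
    comparison_skip <- paste0(
      "hub comparison skipped: empty hub set at degree_min = ",
      config$degree_min)
    log_line(comparison_skip)
  }

  # --- survival screen -------------------------------------------------
  surv_tab <- NULL
  if (!is.null(dat$clinical$os_time)) {
    screen_genes <- union(hubs$pos$genes, hubs$neg$genes)
    if (!length(screen_genes)) screen_genes <- deg$deg_genes
    if (length(screen_genes)) {
      surv_tab <- collect(survival_screen(filtered, screen_genes,
                                          quantile = config$survival_quantile))
      sp <- file.path(out_dir, "survival_screen.tsv")
      utils::write.table(surv_tab, sp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      note("survival", sp)
      log_line("survival screen: ", sum(surv_tab$p_value <= 0.05),
               " gene(s) at p <= 0.05 of ", nrow(surv_tab))
    }
  }

  # --- recovery vs truth (simulation runs only) ------------------------
  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- list(
      f1_pos = edge_f1(nets$pos, truth$adjacency_pos)$f1,
      f1_neg = edge_f1(nets$neg, truth$adjacency_neg)$f1,
      de_recovered = if (length(truth$de_genes))
        mean(names(truth$de_genes) %in% deg$deg_genes) else NA)
  }

  # --- summary ---------------------------------------------------------
  summary <- list(
    parameters = list(p_threshold = config$p_threshold,
                      alpha = config$alpha, rule = config$rule,
                      degree_min = config$degree_min,
                      survival_quantile = config$survival_quantile,
                      seed = config$seed),
    n_genes_input = nrow(dat$values),
    n_genes_filtered = nrow(filtered$values),
    n_samples = ncol(dat$values),
    n_samples_pos = sum(dat$clinical$group == "LNpos"),
    n_samples_neg = sum(dat$clinical$group == "LNneg"),
    n_deg = length(deg$deg_genes),
    edges_pos = nrow(nets$pos$edges),
    edges_neg = nrow(nets$neg$edges),
    hubs_pos = length(hubs$pos$genes),
    hubs_neg = length(hubs$neg$genes),
    hub_of_hub_edges_pos = if (!is.null(hoh$pos)) nrow(hoh$pos$edges) else NULL,
    hub_of_hub_edges_neg = if (!is.null(hoh$neg)) nrow(hoh$neg$edges) else NULL,
    common_hubs = if (!is.null(comparison))
      comparison$common_hubs[c("n_common", "pct_common_vs_a",
                               "pct_common_vs_b")] else NULL,
    comparison_skip = comparison_skip,
    scale_free = list(
      pos = if (!is.null(sf$pos)) sf$pos[c("slope", "r_squared")] else NULL,
      neg = if (!is.null(sf$neg)) sf$neg[c("slope", "r_squared")] else NULL),
    venn_counts = if (!is.null(venn)) as.list(venn$counts) else NULL,
    survival_hits = if (!is.null(surv_tab))
      sum(surv_tab$p_value <= 0.05) else NULL,
    recovery = recovery,
    warnings = warnings_log)
  summary <- drop_nulls(summary)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  man <- do.call(rbind, manifest)
  utils::write.table(man, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

drop_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, logical(1))]
  lapply(x, drop_nulls)
}
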