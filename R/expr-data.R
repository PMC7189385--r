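#' Expression set: genes x samples matrix with per-sample clinical annotations
#'
#' The single raw input of the pipeline: a nonnegative genes-by-samples
#' expression matrix (RSEM-style normalized counts) together with a clinical
#' table carrying, per sample, the lymph-node group label (`"LNpos"` /
#' `"LNneg"`) and optionally overall-survival time and event status.
#'
#' @param values numeric matrix, genes in rows (unique rownames = gene IDs),
#'   samples in columns (unique colnames = sample IDs); finite and >= 0.
#' @param clinical data frame with columns `sample_id`, `group` (values
#'   `"LNpos"` or `"LNneg"`), and optionally `os_time` (nonnegative) and
#'   `os_event` (0/1). Row order need not match the matrix; it is aligned.
#' @return an object of class `expr_set`: a list with elements `values`
#'   and `clinical` (aligned to the matrix columns).
#' @export
expr_set <- function(values, clinical) {
  stop_if(!is.matrix(values) || !is.numeric(values),
          "`values` must be a numeric matrix")
  stop_if(is.null(rownames(values)) || anyDuplicated(rownames(values)),
          "gene IDs (rownames) must be present and unique")
  stop_if(is.null(colnames(values)) || anyDuplicated(colnames(values)),
          "sample IDs (colnames) must be present and unique")
  stop_if(any(!is.finite(values)) || any(values < 0),
          "expression values must be finite and >= 0")
  clinical <- as.data.frame(clinical)
  stop_if(!all(c("sample_id", "group") %in% names(clinical)),
          "clinical table needs `sample_id` and `group` columns")
  stop_if(anyDuplicated(clinical$sample_id) > 0,
          "duplicate sample IDs in clinical table")
  missing <- setdiff(colnames(values), clinical$sample_id)
  stop_if(length(missing) > 0,
          "samples without clinical annotation: ",
          paste(utils::head(missing, 5), collapse = ", "))
  clinical <- clinical[match(colnames(values), clinical$sample_id), ,
                       drop = FALSE]
  rownames(clinical) <- NULL
  stop_if(!all(clinical$group %in% c("LNpos", "LNneg")),
          "group labels must be 'LNpos' or 'LNneg'")
  if (!is.null(clinical$os_time)) {
    ok <- is.na(clinical$os_time) | clinical$os_time >= 0
    stop_if(!all(ok), "os_time must be >= 0")
  }
  if (!is.null(clinical$os_event)) {
    ok <- is.na(clinical$os_event) | clinical$os_event %in% c(0, 1)
    stop_if(!all(ok), "os_event must be 0/1")
  }
  structure(list(values = values, clinical = clinical), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d genes x %d samples (%d LNpos, %d LNneg)\n",
              nrow(x$values), ncol(x$values),
              sum(x$clinical$group == "LNpos"),
              sum(x$clinical$group == "LNneg")))
  if (!is.null(x$clinical$os_time))
    cat(sprintf("  survival: %d events / %d annotated\n",
                sum(x$clinical$os_event == 1, na.rm = TRUE),
                sum(!is.na(x$clinical$os_time))))
  invisible(x)
}

#' Read / write the pipeline's expression and clinical TSV formats
#'
#' The expression TSV has gene IDs in the first column (`gene_id`) and one
#' column per sample; the clinical TSV has columns `sample_id`, `group`,
#' and optionally `os_time`, `os_event`.
#'
#' @param expr_path,clin_path file paths.
#' @return `read_expr_tsv()` returns an `expr_set`.
#' @export
read_expr_tsv <- function(expr_path, clin_path) {
  ex <- utils::read.delim(expr_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  values <- as.matrix(ex[, -1, drop = FALSE])
  rownames(values) <- ex[[1]]
  clinical <- utils::read.delim(clin_path, stringsAsFactors = FALSE)
  expr_set(values, clinical)
}

#' @rdname read_expr_tsv
#' @param x an `expr_set`.
#' @export
write_expr_tsv <- function(x, expr_path, clin_path) {
  stopifnot(inherits(x, "expr_set"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$clinical, clin_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expr_path, clin_path))
}

# sample indices of one group
group_idx <- function(x, group) which(x$clinical$group == group)
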