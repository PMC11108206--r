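# Expression-matrix container, file readers, and the expression filter.

#' Construct an expression time-course object
#'
#' Bundles a genes x samples TPM matrix with per-sample metadata
#' (experiment, condition, Zeitgeber time, replicate) after validating the
#' study design. ZT values are reduced modulo 24 so e.g. a sample recorded
#' at ZT 26 is stored at ZT 2.
#'
#' @param values Numeric matrix of non-negative TPM values; rownames are
#'   unique gene ids, colnames are sample ids.
#' @param samples A data.frame with columns `sample_id`, `experiment`,
#'   `condition`, `zt`, `replicate`, one row per column of `values`.
#' @return An object of class `"expr_set"`: a list with elements `values`
#'   and `samples` (rows ordered to match the matrix columns).
#' @export
expression_set <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("values must have unique gene ids as rownames")
  }
  if (is.null(colnames(values))) stop("values must have sample ids as colnames")
  if (any(values < 0)) stop("negative TPM values are not allowed")
  req <- c("sample_id", "experiment", "condition", "zt", "replicate")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols)) {
    stop("sample sheet lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids in sheet")
  absent <- setdiff(colnames(values), samples$sample_id)
  if (length(absent)) {
    stop("no metadata for sample(s): ", paste(absent, collapse = ", "))
  }
  samples <- samples[match(colnames(values), samples$sample_id), req,
                     drop = FALSE]
  rownames(samples) <- NULL
  samples$zt <- as.numeric(samples$zt) %% 24
  structure(list(values = values, samples = samples), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$samples$experiment, x$samples$condition)
  print(tab)
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

#' Read a TPM matrix and its sample sheet
#'
#' Reads a tab-delimited expression matrix (first column gene ids, header
#' row of sample ids) together with a CSV sample sheet with columns
#' `sample_id`, `experiment`, `condition`, `zt_hours`, `replicate`, and
#' returns a validated [expression_set()]. Every matrix column must be
#' described in the sheet; the error names any sample that is not.
#'
#' @param matrix_path Path to the TSV expression matrix.
#' @param samplesheet_path Path to the CSV sample sheet.
#' @return An `expr_set`.
#' @export
read_expression <- function(matrix_path, samplesheet_path) {
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expression matrix needs gene ids plus >= 1 sample")
  gene_ids <- as.character(raw[[1]])
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids in ", matrix_path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  values <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids
  sheet <- utils::read.csv(samplesheet_path, stringsAsFactors = FALSE)
  if ("zt_hours" %in% names(sheet) && !"zt" %in% names(sheet)) {
    names(sheet)[names(sheet) == "zt_hours"] <- "zt"
  }
  expression_set(values, sheet)
}

#' Filter genes by median expression, consistently across experiments
#'
#' A gene is retained if and only if, within *each* experiment, its median
#' TPM strictly exceeds `tpm_threshold` in at least one condition. The
#' median is taken across all samples of an (experiment, condition) cell,
#' replicates pooled. With the default threshold this is the
#' "median TPM > 5 in either condition, consistently in both experiments"
#' rule; boundary genes (median exactly at the threshold) drop.
#'
#' @param mats A single `expr_set` covering all (experiment, condition)
#'   cells, or a list of `expr_set`s that jointly cover them. All must
#'   share the same gene universe in the same order.
#' @param tpm_threshold Strict lower bound on the median TPM (default 5).
#' @return Character vector of retained gene ids, input order preserved.
#' @export
filter_genes <- function(mats, tpm_threshold = 5) {
  if (inherits(mats, "expr_set")) mats <- list(mats)
  stopifnot(length(mats) >= 1, all(vapply(mats, inherits, logical(1),
                                          "expr_set")))
  genes <- rownames(mats[[1]]$values)
  for (m in mats) {
    if (!identical(rownames(m$values), genes)) {
      stop("expression sets have mismatched gene universes")
    }
  }
  # median TPM per gene for every (experiment, condition) cell
  cell_medians <- list()
  for (m in mats) {
    key <- interaction(m$samples$experiment, m$samples$condition, drop = TRUE)
    for (lv in levels(key)) {
      sub <- m$values[, key == lv, drop = FALSE]
      med <- apply(sub, 1, stats::median)
      if (lv %in% names(cell_medians)) {
        # same cell split across inputs: pool by recomputing is not possible
        # without raw columns, so require each cell to come from one input
        stop("(experiment, condition) cell ", lv,
             " appears in more than one expression set")
      }
      cell_medians[[lv]] <- med
    }
  }
  experiments <- unique(sub("\\..*$", "", names(cell_medians)))
  keep <- rep(TRUE, length(genes))
  for (ex in experiments) {
    cells <- cell_medians[grep(paste0("^", ex, "\\."), names(cell_medians))]
    pass_any <- Reduce(`|`, lapply(cells, function(m) m > tpm_threshold))
    keep <- keep & pass_any
  }
  genes[keep]
}

#' Subset an expression set to a gene list
#'
#' @param x An `expr_set`.
#' @param gene_ids Character vector of gene ids to keep (order taken from
#'   `gene_ids`).
#' @return An `expr_set` restricted to those genes.
#' @export
subset_genes <- function(x, gene_ids) {
  stopifnot(inherits(x, "expr_set"))
  missing <- setdiff(gene_ids, rownames(x$values))
  if (length(missing)) {
    stop("gene id(s) not present: ", paste(utils::head(missing, 5),
                                           collapse = ", "))
  }
  expression_set(x$values[gene_ids, , drop = FALSE], x$samples)
}
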