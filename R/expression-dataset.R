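#' Construct an expression dataset
#'
#' The central container of the package: a genes x conditions matrix of
#' log-scale abundances (log-TPM or equivalently transformed absolute
#' abundances), a per-condition growth rate (1/hr), and per-condition
#' metadata used by the filtering steps.
#'
#' @param X numeric matrix, genes in rows (rownames = gene ids), conditions in
#'   columns (colnames = condition ids). Condition ids must be unique.
#' @param growth numeric vector of growth rates (1/hr), one per column of `X`.
#'   `NA` marks an unknown growth rate (such conditions are removed by
#'   [filter_conditions()]).
#' @param meta optional data frame with one row per condition and columns
#'   `condition_id`, `alignment_score`, `replicate_group`, `is_ALE`,
#'   `is_mutant_or_KO`. Missing columns are filled with permissive defaults
#'   (no alignment score, singleton replicate groups, all flags `FALSE`).
#' @param scale `"logTPM"` for log-TPM style data or `"log_absolute"` for
#'   absolute abundances transformed by [normalize_absolute()].
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `X`, `growth` (named by condition), `meta`, `scale` and a character
#'   `log` recording provenance of filtering operations.
#' @export
expression_dataset <- function(X, growth, meta = NULL,
                               scale = c("logTPM", "log_absolute")) {
  scale <- match.arg(scale)
  X <- as.matrix(X)
  if (is.null(rownames(X))) stop("X must have rownames (gene ids)")
  if (is.null(colnames(X))) stop("X must have colnames (condition ids)")
  if (anyDuplicated(colnames(X))) stop("condition ids must be unique")
  if (length(growth) != ncol(X)) {
    stop("growth must have one entry per condition (", ncol(X), ")")
  }
  growth <- stats::setNames(as.numeric(growth), colnames(X))
  if (is.null(meta)) meta <- data.frame(condition_id = colnames(X))
  meta <- as.data.frame(meta)
  if (!"condition_id" %in% names(meta)) {
    stop("meta must contain a condition_id column")
  }
  if (!setequal(meta$condition_id, colnames(X)) ||
      nrow(meta) != ncol(X)) {
    stop("meta$condition_id must match the columns of X exactly")
  }
  meta <- meta[match(colnames(X), meta$condition_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (!"alignment_score" %in% names(meta)) meta$alignment_score <- NA_real_
  if (!"replicate_group" %in% names(meta)) meta$replicate_group <- meta$condition_id
  if (!"is_ALE" %in% names(meta)) meta$is_ALE <- FALSE
  if (!"is_mutant_or_KO" %in% names(meta)) meta$is_mutant_or_KO <- FALSE
  structure(
    list(X = X, growth = growth, meta = meta, scale = scale, log = character()),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", nrow(x$X), "genes x", ncol(x$X), "conditions\n")
  cat("  scale:", x$scale, "\n")
  gr <- x$growth[is.finite(x$growth)]
  if (length(gr)) {
    cat(sprintf("  growth rate: %.3g-%.3g /hr (%d known)\n",
                min(gr), max(gr), length(gr)))
  }
  if (length(x$log)) cat("  provenance entries:", length(x$log), "\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$X)

# internal: subset columns, keeping growth/meta aligned and appending to the log
subset_ds_conditions <- function(ds, keep, note = NULL) {
  stopifnot(is.character(keep) | is.logical(keep) | is.numeric(keep))
  if (is.character(keep)) keep <- match(keep, colnames(ds$X))
  ds$X <- ds$X[, keep, drop = FALSE]
  ds$growth <- ds$growth[keep]
  ds$meta <- ds$meta[keep, , drop = FALSE]
  rownames(ds$meta) <- NULL
  if (!is.null(note)) ds$log <- c(ds$log, note)
  ds
}

# internal: subset rows
subset_ds_genes <- function(ds, keep, note = NULL) {
  ds$X <- ds$X[keep, , drop = FALSE]
  if (!is.null(note)) ds$log <- c(ds$log, note)
  ds
}

#' Read an expression dataset from TSV files
#'
#' The matrix TSV has gene ids in the first column and condition ids in the
#' header; the metadata TSV has columns `condition_id`, `growth_rate` and
#' optionally `alignment_score`, `replicate_group`, `is_ALE`,
#' `is_mutant_or_KO`.
#'
#' @param matrix_path path to the genes x conditions TSV.
#' @param meta_path path to the per-condition metadata TSV.
#' @inheritParams expression_dataset
#' @return An [expression_dataset()].
#' @export
read_expression_tsv <- function(matrix_path, meta_path, scale = "logTPM") {
  tab <- utils::read.delim(matrix_path, check.names = FALSE)
  X <- as.matrix(tab[, -1, drop = FALSE])
  rownames(X) <- as.character(tab[[1]])
  meta <- utils::read.delim(meta_path)
  if (!"growth_rate" %in% names(meta)) {
    stop("metadata TSV must contain a growth_rate column")
  }
  growth <- meta$growth_rate[match(colnames(X), meta$condition_id)]
  expression_dataset(X, growth, meta, scale = scale)
}

#' Write an expression dataset to TSV files
#'
#' @param ds an [expression_dataset()].
#' @param matrix_path,meta_path output paths.
#' @return Invisibly, `ds`.
#' @export
write_expression_tsv <- function(ds, matrix_path, meta_path) {
  tab <- data.frame(gene = rownames(ds$X), ds$X, check.names = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- ds$meta
  meta$growth_rate <- unname(ds$growth)
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(ds)
}
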