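#' Drop conditions with unusable growth or alignment metadata
#'
#' Conditions whose growth rate is missing (`NA`) or zero are removed, as are
#' conditions whose alignment score falls below `min_alignment`. Conditions
#' without a recorded alignment score are retained.
#'
#' @param ds an [expression_dataset()].
#' @param min_alignment minimum acceptable alignment score; the boundary value
#'   itself is retained (the cut is strictly "less than").
#' @return The filtered dataset; dropped conditions are recorded in `ds$log`.
#' @export
filter_conditions <- function(ds, min_alignment = 80) {
  stopifnot(inherits(ds, "expression_dataset"))
  bad_growth <- !is.finite(ds$growth) | ds$growth <= 0
  aln <- ds$meta$alignment_score
  bad_aln <- !is.na(aln) & aln < min_alignment
  drop <- bad_growth | bad_aln
  if (all(drop)) stop("all conditions dropped by growth/alignment filters")
  notes <- character()
  if (any(bad_growth)) {
    notes <- c(notes, paste0("filter_conditions: dropped (growth missing/zero): ",
                             paste(colnames(ds$X)[bad_growth], collapse = ", ")))
  }
  if (any(bad_aln & !bad_growth)) {
    notes <- c(notes, paste0("filter_conditions: dropped (alignment < ",
                             min_alignment, "): ",
                             paste(colnames(ds$X)[bad_aln & !bad_growth],
                                   collapse = ", ")))
  }
  ds <- subset_ds_conditions(ds, !drop)
  ds$log <- c(ds$log, notes)
  ds
}

#' Average biological replicates within conditions
#'
#' Expression (on the stored log scale) and growth rates are averaged
#' arithmetically across all columns sharing a `replicate_group`; the result
#' has one column per group, named by the group. ALE and mutant/knock-out
#' flags must agree within a group.
#'
#' @param ds an [expression_dataset()].
#' @return A dataset with one column per replicate group.
#' @export
average_replicates <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  grp <- as.character(ds$meta$replicate_group)
  if (anyNA(grp)) stop("replicate_group must be defined for every condition")
  groups <- unique(grp)
  for (g in groups) {
    idx <- grp == g
    if (length(unique(ds$meta$is_ALE[idx])) > 1 ||
        length(unique(ds$meta$is_mutant_or_KO[idx])) > 1) {
      stop("conflicting ALE/mutant flags within replicate group '", g, "'")
    }
  }
  counts <- table(grp)[groups]
  Xm <- t(rowsum(t(ds$X), grp)[groups, , drop = FALSE]) /
    rep(as.numeric(counts), each = nrow(ds$X))
  colnames(Xm) <- groups
  growth <- tapply(ds$growth, grp, mean)[groups]
  first <- match(groups, grp)
  meta <- data.frame(
    condition_id = groups,
    alignment_score = as.numeric(tapply(ds$meta$alignment_score, grp, mean)[groups]),
    replicate_group = groups,
    is_ALE = ds$meta$is_ALE[first],
    is_mutant_or_KO = ds$meta$is_mutant_or_KO[first]
  )
  out <- expression_dataset(Xm, growth, meta, scale = ds$scale)
  out$log <- c(ds$log, sprintf(
    "average_replicates: %d conditions collapsed into %d replicate groups",
    length(grp), length(groups)))
  out
}

#' Detect duplicated expression profiles between conditions
#'
#' Flags condition pairs whose all-by-all Spearman correlation is 1 within
#' `tol`. A rank correlation of exactly 1 is vanishingly unlikely to arise
#' from independent experiments, so such pairs indicate duplicated columns
#' (possibly after a monotone transformation).
#'
#' @param ds an [expression_dataset()].
#' @param tol tolerance on `1 - rho`.
#' @return data frame with columns `cond1`, `cond2`, `rho` (possibly empty).
#' @export
detect_duplicate_conditions <- function(ds, tol = 1e-12) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ncol(ds$X) < 2) stop("need at least 2 conditions")
  rho <- suppressWarnings(stats::cor(ds$X, method = "spearman",
                                     use = "pairwise.complete.obs"))
  hits <- which(upper.tri(rho) & (1 - rho) <= tol, arr.ind = TRUE)
  data.frame(
    cond1 = colnames(ds$X)[hits[, 1]],
    cond2 = colnames(ds$X)[hits[, 2]],
    rho = rho[hits]
  )
}

#' Remove duplicated conditions
#'
#' By default both members of each duplicated pair are removed (when the two
#' duplicated columns report different growth rates, neither can be trusted);
#' `policy = "drop_one"` keeps the first member.
#'
#' @param ds an [expression_dataset()].
#' @param pairs result of [detect_duplicate_conditions()]; computed if `NULL`.
#' @param policy `"drop_both"` or `"drop_one"`.
#' @param tol passed to [detect_duplicate_conditions()] when `pairs` is `NULL`.
#' @return The dataset without the duplicated conditions.
#' @export
drop_duplicate_conditions <- function(ds, pairs = NULL,
                                      policy = c("drop_both", "drop_one"),
                                      tol = 1e-12) {
  policy <- match.arg(policy)
  if (is.null(pairs)) pairs <- detect_duplicate_conditions(ds, tol = tol)
  if (nrow(pairs) == 0) return(ds)
  drop <- if (policy == "drop_both") {
    unique(c(pairs$cond1, pairs$cond2))
  } else {
    unique(pairs$cond2)
  }
  keep <- !(colnames(ds$X) %in% drop)
  if (!any(keep)) stop("all conditions are duplicated; nothing left to keep")
  subset_ds_conditions(ds, keep, note = paste0(
    "drop_duplicate_conditions (", policy, "): removed ",
    paste(drop, collapse = ", ")))
}

#' Construct a raw absolute-abundance table
#'
#' Holds non-negative raw abundances (protein copies per cell, fmol/mgDW, ...)
#' prior to log transformation.
#'
#' @param A non-negative numeric matrix with gene rownames and condition
#'   colnames.
#' @param growth optional growth rates per condition.
#' @param meta optional condition metadata as in [expression_dataset()].
#' @return An object of class `raw_abundance_table`.
#' @export
raw_abundance_table <- function(A, growth = NULL, meta = NULL) {
  A <- as.matrix(A)
  if (is.null(rownames(A)) || is.null(colnames(A))) {
    stop("A must have gene rownames and condition colnames")
  }
  if (any(A < 0, na.rm = TRUE)) stop("abundances must be non-negative")
  if (is.null(growth)) growth <- rep(NA_real_, ncol(A))
  structure(list(A = A, growth = growth, meta = meta),
            class = "raw_abundance_table")
}

#' Transform absolute abundances to a log-TPM-like scale
#'
#' Applies `x = 6 + log_b(a / sum(a))` per condition, where `sum(a)` is the
#' column total. With base 10 this is exactly `log10(TPM)` for a
#' transcripts-per-million style renormalization. Zeros are replaced, before
#' the transform, by the smallest non-zero value of the whole table.
#'
#' @param raw a [raw_abundance_table()].
#' @param log_base base of the logarithm (10 by default; use `exp(1)` for a
#'   natural-log variant).
#' @return An [expression_dataset()] with `scale = "log_absolute"`.
#' @export
normalize_absolute <- function(raw, log_base = 10) {
  stopifnot(inherits(raw, "raw_abundance_table"))
  A <- raw$A
  nz <- A[is.finite(A) & A > 0]
  if (length(nz) == 0) stop("all abundances are zero; cannot normalize")
  n_zero <- sum(A == 0, na.rm = TRUE)
  A[!is.na(A) & A == 0] <- min(nz)
  tot <- colSums(A, na.rm = TRUE)
  X <- 6 + sweep(log(A, base = log_base), 2, log(tot, base = log_base), `-`)
  ds <- expression_dataset(X, raw$growth, raw$meta, scale = "log_absolute")
  ds$log <- sprintf(
    "normalize_absolute: base %.6g, %d zero(s) replaced by %.6g",
    log_base, n_zero, min(nz))
  ds
}

#' Keep genes measured in every condition; drop duplicated profiles
#'
#' Genes with any missing value are removed, and among genes with identical
#' expression profiles only the first is kept.
#'
#' @param ds an [expression_dataset()].
#' @return The filtered dataset.
#' @export
filter_complete_genes <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  complete <- stats::complete.cases(ds$X)
  notes <- character()
  if (any(!complete)) {
    notes <- c(notes, sprintf("filter_complete_genes: %d gene(s) with missing values dropped",
                              sum(!complete)))
  }
  ds <- subset_ds_genes(ds, complete)
  dup <- duplicated(ds$X)
  if (any(dup)) {
    notes <- c(notes, paste0("filter_complete_genes: duplicated profiles dropped: ",
                             paste(rownames(ds$X)[dup], collapse = ", ")))
  }
  ds <- subset_ds_genes(ds, !dup)
  ds$log <- c(ds$log, notes)
  ds
}

#' Restrict to "neutral" condition subsets
#'
#' Drops adaptive-laboratory-evolution (ALE) conditions and/or mutant and
#' knock-out conditions based on the metadata flags.
#'
#' @param ds an [expression_dataset()].
#' @param exclude_ALE drop conditions flagged `is_ALE`.
#' @param exclude_mutants drop conditions flagged `is_mutant_or_KO`.
#' @return The subset dataset.
#' @export
subset_conditions <- function(ds, exclude_ALE = FALSE, exclude_mutants = FALSE) {
  stopifnot(inherits(ds, "expression_dataset"))
  drop <- rep(FALSE, ncol(ds$X))
  if (exclude_ALE) drop <- drop | ds$meta$is_ALE
  if (exclude_mutants) drop <- drop | ds$meta$is_mutant_or_KO
  if (all(drop)) stop("all conditions excluded by the requested subset")
  if (!any(drop)) return(ds)
  subset_ds_conditions(ds, !drop, note = sprintf(
    "subset_conditions: dropped %d condition(s) (exclude_ALE=%s, exclude_mutants=%s)",
    sum(drop), exclude_ALE, exclude_mutants))
}

#' Remove a list of genes from the dataset
#'
#' Used for sensitivity analyses such as removing AT-rich outlier genes.
#' Ids not present in the dataset are logged, not fatal.
#'
#' @param ds an [expression_dataset()].
#' @param gene_list character vector of gene ids to remove.
#' @return The reduced dataset.
#' @export
exclude_genes <- function(ds, gene_list) {
  stopifnot(inherits(ds, "expression_dataset"))
  gene_list <- unique(as.character(gene_list))
  if (length(gene_list) == 0) return(ds)
  hit <- rownames(ds$X) %in% gene_list
  if (all(hit)) stop("excluding every gene would leave an empty dataset")
  unknown <- setdiff(gene_list, rownames(ds$X))
  note <- sprintf("exclude_genes: removed %d of %d listed gene(s)",
                  sum(hit), length(gene_list))
  if (length(unknown)) {
    note <- paste0(note, "; not found: ", length(unknown))
  }
  subset_ds_genes(ds, !hit, note = note)
}
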