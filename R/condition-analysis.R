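#' All-by-all condition correlation matrix
#'
#' Pairwise Pearson correlations between conditions, computed over genes on
#' the stored log scale; genes missing in either column are excluded
#' pairwise. Both `r` and `r^2` matrices are returned (Spearman is exposed
#' via `method` for the pruning workflow).
#'
#' @param ds an [expression_dataset()].
#' @param method `"pearson"` or `"spearman"`.
#' @return A list of class `condition_corr_matrix` with `condition_ids`,
#'   `R` (correlations) and `R2`.
#' @export
condition_correlation_matrix <- function(ds, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "expression_dataset"))
  if (ncol(ds$X) < 2) stop("need at least 2 conditions")
  if (nrow(ds$X) < 3) stop("need at least 3 genes")
  R <- suppressWarnings(stats::cor(ds$X, method = method,
                                   use = "pairwise.complete.obs"))
  # zero-variance columns yield NA correlations; the diagonal is 1 by
  # definition
  diag(R) <- 1
  structure(list(condition_ids = colnames(ds$X), R = R, R2 = R^2,
                 method = method),
            class = "condition_corr_matrix")
}

#' Per-condition predictivity of codon bias from expression
#'
#' For each condition, the squared Pearson correlation between per-gene log
#' expression in that condition and the per-gene codon-bias score, over the
#' genes present in both inputs.
#'
#' @param ds an [expression_dataset()].
#' @param scores data frame with columns `id` and `score` (see
#'   [score_genes()]).
#' @param rank_based use Spearman instead of Pearson (off by default).
#' @return A data frame of class `predictivity_profile` with columns
#'   `condition_id`, `growth_rate`, `r`, `r2`, `n_genes`.
#' @export
per_condition_cub_r2 <- function(ds, scores, rank_based = FALSE) {
  stopifnot(inherits(ds, "expression_dataset"))
  common <- intersect(rownames(ds$X), scores$id)
  if (length(common) < 3) {
    stop("fewer than 3 genes shared between expression data and scores")
  }
  s <- scores$score[match(common, scores$id)]
  method <- if (rank_based) "spearman" else "pearson"
  r <- apply(ds$X[common, , drop = FALSE], 2, function(x) {
    suppressWarnings(stats::cor(x, s, method = method,
                                use = "pairwise.complete.obs"))
  })
  out <- data.frame(condition_id = colnames(ds$X),
                    growth_rate = unname(ds$growth),
                    r = unname(r), r2 = unname(r)^2,
                    n_genes = length(common))
  class(out) <- c("predictivity_profile", "data.frame")
  out
}

#' Trend between growth rate and expression-CUB predictivity
#'
#' Spearman rank correlation (average-rank ties, asymptotic two-sided p)
#' between a condition's growth rate and its expression-codon-bias `r^2`.
#'
#' @param profile output of [per_condition_cub_r2()].
#' @return A list with `rho`, `p` and `n`.
#' @export
growth_predictivity_trend <- function(profile) {
  ok <- is.finite(profile$growth_rate) & is.finite(profile$r2)
  if (sum(ok) < 3) stop("need at least 3 conditions with defined values")
  if (stats::sd(profile$r2[ok]) == 0) {
    stop("predictivity is constant across conditions; trend undefined")
  }
  ct <- suppressWarnings(stats::cor.test(profile$growth_rate[ok],
                                         profile$r2[ok],
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Iteratively prune highly correlated conditions
#'
#' In each iteration the all-by-all Spearman correlation matrix of the
#' remaining conditions is recomputed, the pair with the highest off-diagonal
#' correlation is located (ties resolved to the lowest-index pair), and one
#' member of the pair is removed uniformly at random. Pruning stops when
#' `target_n` conditions remain.
#'
#' @param ds an [expression_dataset()].
#' @param target_n number of conditions to keep (>= 2).
#' @param seed integer seed for the random member choice.
#' @return The pruned dataset; the removal order is attached as
#'   `attr(, "prune_log")` (data frame: `iteration`, `cond_a`, `cond_b`,
#'   `removed`, `max_rho`).
#' @export
prune_redundant_conditions <- function(ds, target_n, seed = 1L) {
  stopifnot(inherits(ds, "expression_dataset"))
  n <- ncol(ds$X)
  if (!is.numeric(target_n) || target_n < 2 || target_n > n) {
    stop("target_n must be between 2 and the number of conditions (", n, ")")
  }
  keep <- colnames(ds$X)
  log_rows <- list()
  withr::with_seed(as.integer(seed), {
    it <- 0L
    while (length(keep) > target_n) {
      it <- it + 1L
      rho <- suppressWarnings(stats::cor(ds$X[, keep, drop = FALSE],
                                         method = "spearman",
                                         use = "pairwise.complete.obs"))
      rho[lower.tri(rho, diag = TRUE)] <- -Inf
      best <- which(rho == max(rho), arr.ind = TRUE)
      best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
      pair <- keep[c(best[1], best[2])]
      removed <- pair[sample.int(2, 1)]
      log_rows[[it]] <- data.frame(iteration = it, cond_a = pair[1],
                                   cond_b = pair[2], removed = removed,
                                   max_rho = max(rho))
      keep <- setdiff(keep, removed)
    }
  })
  out <- subset_ds_conditions(ds, keep, note = sprintf(
    "prune_redundant_conditions: %d -> %d conditions (seed %d)",
    n, length(keep), as.integer(seed)))
  attr(out, "prune_log") <- if (length(log_rows)) {
    do.call(rbind, log_rows)
  } else {
    data.frame(iteration = integer(), cond_a = character(),
               cond_b = character(), removed = character(),
               max_rho = numeric())
  }
  out
}
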