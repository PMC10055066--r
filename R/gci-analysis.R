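#' Growth Correlation Index per gene
#'
#' The Growth Correlation Index (GCI) of a gene is the Pearson correlation
#' `r` between the gene's log-scale expression across conditions and the
#' corresponding growth rates. Positive GCI marks genes whose relative
#' expression increases under rapid growth, negative GCI genes upregulated
#' under slow growth. Missing expression values are handled pairwise; genes
#' with zero expression variance or fewer than 3 complete pairs are flagged
#' `defined = FALSE`.
#'
#' @param ds an [expression_dataset()].
#' @return A data frame of class `gci_result` with columns `gene`, `r`,
#'   `n_conditions`, `defined`.
#' @export
compute_gci <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ncol(ds$X) < 3) stop("need at least 3 conditions to compute GCI")
  mu <- ds$growth
  r <- vapply(seq_len(nrow(ds$X)), function(g) {
    suppressWarnings(stats::cor(ds$X[g, ], mu, use = "pairwise.complete.obs"))
  }, numeric(1))
  n_used <- vapply(seq_len(nrow(ds$X)), function(g) {
    sum(is.finite(ds$X[g, ]) & is.finite(mu))
  }, integer(1))
  defined <- is.finite(r) & n_used >= 3
  out <- data.frame(gene = rownames(ds$X), r = ifelse(defined, r, NA_real_),
                    n_conditions = n_used, defined = defined)
  class(out) <- c("gci_result", "data.frame")
  out
}

#' Permutation null for the Growth Correlation Index
#'
#' For each gene independently, the growth-rate vector is shuffled and one
#' permuted GCI computed from the randomly paired data, giving a null sample
#' of the same size as the observed GCI set. Shuffling one side of the pair
#' is equivalent in distribution to shuffling both.
#'
#' @param ds an [expression_dataset()].
#' @param seed integer seed; the null set is reproducible from it.
#' @param n_replicates permuted values per gene (1 as in the headline
#'   analysis; larger values give a per-gene null spread).
#' @return A list of class `null_gci_set`: `values` (data frame `gene`, `r`,
#'   with `n_replicates` rows per gene when > 1), `seed`, `mean`, `sd`.
#' @export
permuted_gci <- function(ds, seed = 1L, n_replicates = 1L) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ncol(ds$X) < 3) stop("need at least 3 conditions")
  mu <- ds$growth
  n_genes <- nrow(ds$X)
  rmat <- matrix(NA_real_, n_genes, n_replicates)
  withr::with_seed(as.integer(seed), {
    for (g in seq_len(n_genes)) {
      x <- ds$X[g, ]
      for (i in seq_len(n_replicates)) {
        rmat[g, i] <- suppressWarnings(
          stats::cor(x, sample(mu), use = "pairwise.complete.obs"))
      }
    }
  })
  values <- data.frame(gene = rep(rownames(ds$X), times = n_replicates),
                       r = as.vector(rmat))
  ok <- is.finite(values$r)
  structure(list(values = values, seed = as.integer(seed),
                 mean = mean(values$r[ok]), sd = stats::sd(values$r[ok])),
            class = "null_gci_set")
}

# sample skewness (moment estimator m3 / m2^(3/2))
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}

# histogram mode with Freedman-Diaconis bins
histogram_mode <- function(x) {
  x <- x[is.finite(x)]
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  mid <- h$mids[which.max(h$counts)]
  mid
}

#' Summarize observed GCI against its permutation null
#'
#' @param observed a `gci_result` from [compute_gci()].
#' @param null a `null_gci_set` from [permuted_gci()].
#' @return A list with the observed `min`, `max`, `mean`, `mode`
#'   (Freedman-Diaconis histogram mode) and `skewness`, the `null_mean` and
#'   `null_sd`, and `frac_beyond_2sd`, the fraction of observed `|r|`
#'   exceeding twice the null SD.
#' @export
gci_summary <- function(observed, null) {
  r <- observed$r[observed$defined]
  if (length(r) == 0 || nrow(null$values) == 0) {
    stop("observed and null sets must be non-empty")
  }
  list(
    n = length(r),
    min = min(r), max = max(r), mean = mean(r),
    mode = histogram_mode(r),
    skewness = sample_skewness(r),
    null_mean = null$mean, null_sd = null$sd,
    frac_beyond_2sd = mean(abs(r) > 2 * null$sd)
  )
}

#' Relationship between GCI and mean expression
#'
#' Pearson correlation between each gene's mean log expression across
#' conditions and its GCI, reported as `r^2` with a two-sided p-value.
#'
#' @param gci a `gci_result` from [compute_gci()].
#' @param ds the [expression_dataset()] the GCI was computed from.
#' @return A list with `r2`, `p`, `n`.
#' @export
gci_vs_mean_expression <- function(gci, ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  keep <- gci$defined
  if (sum(keep) < 3) stop("need at least 3 genes with defined GCI")
  m <- rowMeans(ds$X[match(gci$gene[keep], rownames(ds$X)), , drop = FALSE],
                na.rm = TRUE)
  if (stats::sd(m) == 0 || stats::sd(gci$r[keep]) == 0) {
    stop("degenerate variance; correlation undefined")
  }
  ct <- stats::cor.test(m, gci$r[keep])
  list(r2 = unname(ct$estimate)^2, p = ct$p.value, n = sum(keep))
}
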