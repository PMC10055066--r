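# merge the three per-gene quantities into one complete-case data frame
assemble_model_data <- function(cub, mean_expr, gci) {
  as_named <- function(x, value_col) {
    if (is.data.frame(x)) {
      gene_col <- intersect(c("gene", "id"), names(x))[1]
      if (is.na(gene_col)) stop("data frame input needs a gene/id column")
      stats::setNames(x[[value_col]], x[[gene_col]])
    } else {
      if (is.null(names(x))) stop("vector inputs must be named by gene")
      x
    }
  }
  cub <- as_named(cub, "score")
  mean_expr <- as_named(mean_expr, "mean_expr")
  gci <- as_named(gci, "r")
  genes <- Reduce(intersect, list(names(cub), names(mean_expr), names(gci)))
  d <- data.frame(gene = genes, score = unname(cub[genes]),
                  expr = unname(mean_expr[genes]), gci = unname(gci[genes]))
  d[stats::complete.cases(d), , drop = FALSE]
}

#' Fit the four nested models predicting codon bias
#'
#' Ordinary least squares fits of the codon-bias score on (1) mean log
#' expression alone, (2) GCI alone, (3) both as additive predictors, and
#' (4) both plus their interaction. Genes lacking any of the three
#' quantities are excluded listwise so all four models share the same `n`.
#'
#' @param cub per-gene codon-bias scores: a named numeric vector or a data
#'   frame with `id`/`gene` and `score` columns (e.g. [score_genes()] output).
#' @param mean_expr per-gene mean log expression, named vector or data frame
#'   with a `mean_expr` column.
#' @param gci per-gene GCI, named vector or a `gci_result` data frame.
#' @param standardize center and scale both predictors before fitting.
#' @return An object of class `cub_model_fits`: a list with `fits` (named
#'   list of `lm` objects: `expr_only`, `gci_only`, `additive`,
#'   `interaction`), `summary` (data frame: model, n, r2, adj_r2,
#'   p_overall) and `coefficients` (long data frame of estimates and SEs).
#' @export
fit_models <- function(cub, mean_expr, gci, standardize = FALSE) {
  d <- assemble_model_data(cub, mean_expr, gci)
  if (nrow(d) < 10) stop("need at least 10 genes with all quantities defined")
  if (standardize) {
    d$expr <- as.numeric(scale(d$expr))
    d$gci <- as.numeric(scale(d$gci))
  }
  if (stats::sd(d$expr) == 0 || stats::sd(d$gci) == 0) {
    stop("rank-deficient design: a predictor is constant")
  }
  forms <- list(
    expr_only = score ~ expr,
    gci_only = score ~ gci,
    additive = score ~ expr + gci,
    interaction = score ~ expr * gci
  )
  fits <- lapply(forms, stats::lm, data = d)
  summ <- lapply(fits, summary)
  overall_p <- vapply(summ, function(s) {
    f <- s$fstatistic
    unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE))
  }, numeric(1))
  summary_df <- data.frame(
    model = names(forms),
    n = nrow(d),
    r2 = vapply(summ, `[[`, 0, "r.squared"),
    adj_r2 = vapply(summ, `[[`, 0, "adj.r.squared"),
    p_overall = overall_p,
    row.names = NULL
  )
  coef_df <- do.call(rbind, lapply(names(fits), function(m) {
    ct <- summ[[m]]$coefficients
    data.frame(model = m, term = rownames(ct), estimate = ct[, 1],
               se = ct[, 2], p = ct[, 4], row.names = NULL)
  }))
  structure(list(fits = fits, summary = summary_df,
                 coefficients = coef_df, data = d),
            class = "cub_model_fits")
}

#' @export
print.cub_model_fits <- function(x, ...) {
  cat("Nested codon-bias models (n =", x$summary$n[1], "genes)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Variance inflation factors for the additive design
#'
#' `VIF_j = 1 / (1 - R_j^2)` where `R_j^2` comes from regressing predictor
#' `j` on the remaining predictors. Values near 1 indicate no collinearity;
#' values above 5 are conventionally considered problematic.
#'
#' @param mean_expr,gci per-gene predictors, named vectors or data frames as
#'   in [fit_models()].
#' @return A data frame of class `vif_report` with columns `predictor`,
#'   `vif`. Near-singular designs (VIF > 1e6) trigger a warning.
#' @export
vif <- function(mean_expr, gci) {
  as_vec <- function(x, col) {
    if (is.data.frame(x)) {
      gene_col <- intersect(c("gene", "id"), names(x))[1]
      stats::setNames(x[[col]], x[[gene_col]])
    } else x
  }
  e <- as_vec(mean_expr, "mean_expr")
  g <- as_vec(gci, "r")
  if (!is.null(names(e)) && !is.null(names(g))) {
    genes <- intersect(names(e), names(g))
    e <- e[genes]; g <- g[genes]
  }
  ok <- is.finite(e) & is.finite(g)
  e <- e[ok]; g <- g[ok]
  if (length(e) < 3) stop("need at least 3 genes")
  if (stats::sd(e) == 0 || stats::sd(g) == 0) {
    stop("constant predictor; VIF undefined")
  }
  X <- cbind(expr = e, gci = g)
  v <- vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  if (any(v > 1e6)) warning("near-singular design: VIF exceeds 1e6")
  out <- data.frame(predictor = colnames(X), vif = v)
  class(out) <- c("vif_report", "data.frame")
  out
}

#' Predicted codon-bias surface over an expression grid
#'
#' Evaluates an additive or interaction fit on every combination of the
#' expression grid and the supplied GCI values. Under the additive model the
#' lines for different GCI values are parallel; the interaction model lets
#' the expression slope depend on GCI.
#'
#' @param fit one of the `lm` fits from [fit_models()] (`additive` or
#'   `interaction`), or a `cub_model_fits` object together with `model`.
#' @param expr_grid numeric vector of expression values (non-empty).
#' @param gci_values numeric vector of GCI values (non-empty).
#' @param model which fit to use when `fit` is a `cub_model_fits`.
#' @return Data frame with columns `expr`, `gci`, `predicted`.
#' @export
prediction_surface <- function(fit, expr_grid, gci_values,
                               model = c("additive", "interaction")) {
  if (inherits(fit, "cub_model_fits")) {
    model <- match.arg(model)
    fit <- fit$fits[[model]]
  }
  stopifnot(inherits(fit, "lm"))
  if (!all(c("expr", "gci") %in% all.vars(stats::formula(fit)))) {
    stop("fit must use both expr and gci as predictors")
  }
  if (length(expr_grid) == 0 || length(gci_values) == 0) {
    stop("empty prediction grid")
  }
  grid <- expand.grid(expr = expr_grid, gci = gci_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$predicted <- unname(stats::predict(fit, newdata = grid))
  grid
}

#' Compare linear and quadratic dependence of codon bias on GCI
#'
#' An AIC comparison of `score ~ gci` against `score ~ gci + gci^2`,
#' offered as a simple check on whether the codon-bias/GCI relationship is
#' adequately linear.
#'
#' @param cub,gci as in [fit_models()].
#' @return Data frame with one row per model form: `form`, `aic`,
#'   `adj_r2`.
#' @export
compare_gci_linearity <- function(cub, gci) {
  gvec <- if (is.data.frame(gci)) stats::setNames(gci$r, gci$gene) else gci
  dummy <- stats::setNames(rep(0, length(gvec)), names(gvec))
  d <- assemble_model_data(cub, dummy, gvec)
  lin <- stats::lm(score ~ gci, data = d)
  quad <- stats::lm(score ~ gci + I(gci^2), data = d)
  data.frame(
    form = c("linear", "quadratic"),
    aic = c(stats::AIC(lin), stats::AIC(quad)),
    adj_r2 = c(summary(lin)$adj.r.squared, summary(quad)$adj.r.squared)
  )
}
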