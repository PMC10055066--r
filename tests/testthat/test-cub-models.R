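make_model_data <- function(n, b = c(0.3, 0.08, 0.15, 0), noise = 0.05,
                            rho = 0.3, seed = 1) {
  p <- correlated_predictors(n, rho, seed = seed)
  withr::with_seed(seed + 1000, {
    y <- b[1] + b[2] * p$x1 + b[3] * p$x2 + b[4] * p$x1 * p$x2 +
      rnorm(n, 0, noise)
  })
  genes <- sprintf("g%05d", seq_len(n))
  list(cub = stats::setNames(y, genes),
       expr = stats::setNames(p$x1, genes),
       gci = stats::setNames(p$x2, genes),
       b = b)
}

test_that("a noiseless linear response is fit exactly", {
  d <- make_model_data(50, b = c(2, 3, 0, 0), noise = 0, rho = 0)
  fits <- suppressWarnings(fit_models(d$cub, d$expr, d$gci))  # perfect fit
  expect_equal(unname(coef(fits$fits$expr_only)), c(2, 3), tolerance = 1e-10)
  expect_equal(fits$summary$adj_r2[fits$summary$model == "expr_only"], 1,
               tolerance = 1e-10)
})

test_that("coefficients match the normal-equations brute force", {
  d <- make_model_data(40, seed = 3)
  fits <- fit_models(d$cub, d$expr, d$gci)
  X_add <- cbind(d$expr, d$gci)
  expect_equal(unname(coef(fits$fits$additive)),
               unname(bf_ols(X_add, d$cub)), tolerance = 1e-10)
  X_int <- cbind(d$expr, d$gci, d$expr * d$gci)
  expect_equal(unname(coef(fits$fits$interaction)),
               unname(bf_ols(X_int, d$cub)), tolerance = 1e-10)
})

test_that("adjusted R2 follows its definition and the nesting holds", {
  for (seed in 1:4) {
    d <- make_model_data(60, noise = 0.3, seed = 10 + seed)
    fits <- fit_models(d$cub, d$expr, d$gci)
    s <- fits$summary
    n <- s$n[1]
    p_terms <- c(expr_only = 1, gci_only = 1, additive = 2, interaction = 3)
    for (m in s$model) {
      expect_equal(s$adj_r2[s$model == m],
                   1 - (1 - s$r2[s$model == m]) * (n - 1) /
                     (n - p_terms[[m]] - 1),
                   tolerance = 1e-12)
    }
    # R2 non-decreasing along the nesting
    r2 <- stats::setNames(s$r2, s$model)
    expect_gte(r2["interaction"], r2["additive"] - 1e-12)
    expect_gte(r2["additive"], max(r2["expr_only"], r2["gci_only"]) - 1e-12)
    expect_true(all(s$adj_r2 <= s$r2 + 1e-12))
  }
})

test_that("a response independent of both predictors has adj R2 near zero", {
  withr::with_seed(70, {
    genes <- sprintf("g%05d", 1:10000)
    cub <- stats::setNames(rnorm(10000), genes)
    expr <- stats::setNames(rnorm(10000), genes)
    gci <- stats::setNames(rnorm(10000), genes)
  })
  fits <- fit_models(cub, expr, gci)
  expect_true(all(abs(fits$summary$adj_r2) < 0.005))
  expect_true(all(fits$summary$p_overall > 1e-4))
})

test_that("coefficients are recovered within three standard errors", {
  d <- make_model_data(2000, b = c(0.4, 0.12, 0.2, 0.05), noise = 0.1,
                       seed = 21)
  fits <- fit_models(d$cub, d$expr, d$gci)
  ct <- fits$coefficients[fits$coefficients$model == "interaction", ]
  expect_equal(ct$term, c("(Intercept)", "expr", "gci", "expr:gci"))
  expect_true(all(abs(ct$estimate - d$b) < 3 * ct$se))
})

test_that("inputs too small or degenerate are rejected", {
  d <- make_model_data(30, seed = 5)
  expect_error(fit_models(d$cub[1:5], d$expr[1:5], d$gci[1:5]),
               "at least 10")
  const <- stats::setNames(rep(1, 30), names(d$expr))
  expect_error(fit_models(d$cub, const, d$gci), "constant")
})

test_that("variance inflation follows the closed form", {
  p0 <- correlated_predictors(200, 0, seed = 31)
  v0 <- vif(p0$x1, p0$x2)
  expect_equal(v0$vif, c(1, 1), tolerance = 1e-10)
  p5 <- correlated_predictors(200, 0.5, seed = 32)
  v5 <- vif(p5$x1, p5$x2)
  expect_equal(v5$vif, c(4 / 3, 4 / 3), tolerance = 1e-9)
  expect_equal(round(v5$vif[1], 4), 1.3333)
  # near-collinear predictors warn
  p99 <- correlated_predictors(200, 1 - 1e-9, seed = 33)
  expect_warning(v99 <- vif(p99$x1, p99$x2), "near-singular")
  expect_true(all(v99$vif > 1e6))
  expect_error(vif(rep(1, 10), rnorm(10)), "constant")
})

test_that("vif agrees with the car reference implementation", {
  skip_if_not_installed("car")
  d <- make_model_data(150, rho = 0.4, seed = 34)
  ours <- vif(d$expr, d$gci)
  ref <- car::vif(stats::lm(d$cub ~ d$expr + d$gci))
  expect_equal(ours$vif, unname(ref), tolerance = 1e-8)
})

test_that("prediction surfaces reflect additivity and interaction", {
  d <- make_model_data(200, b = c(0.4, 0.1, 0.2, 0.08), noise = 0.02,
                       seed = 41)
  fits <- fit_models(d$cub, d$expr, d$gci)
  grid <- seq(-2, 2, length.out = 9)
  surf_add <- prediction_surface(fits, grid, c(-0.5, 0.5), model = "additive")
  # additive: the gap between the two GCI lines is constant over expression
  gap <- surf_add$predicted[surf_add$gci == 0.5] -
    surf_add$predicted[surf_add$gci == -0.5]
  expect_equal(gap, rep(gap[1], 9), tolerance = 1e-10)
  # hand evaluation at one grid point
  b <- coef(fits$fits$interaction)
  surf_int <- prediction_surface(fits, 1.5, 0.5, model = "interaction")
  expect_equal(surf_int$predicted,
               unname(b[1] + b[2] * 1.5 + b[3] * 0.5 + b[4] * 1.5 * 0.5),
               tolerance = 1e-10)
  # zero interaction coefficient collapses to the additive surface
  d0 <- make_model_data(500, b = c(0.4, 0.1, 0.2, 0), noise = 0, seed = 42)
  f0 <- suppressWarnings(fit_models(d0$cub, d0$expr, d0$gci))  # perfect fit
  s_add <- prediction_surface(f0, grid, c(-1, 0, 1), model = "additive")
  s_int <- prediction_surface(f0, grid, c(-1, 0, 1), model = "interaction")
  expect_equal(s_int$predicted, s_add$predicted, tolerance = 1e-8)
  expect_error(prediction_surface(fits, numeric(0), 1), "empty")
  expect_error(prediction_surface(fits$fits$expr_only, grid, 1), "both expr and gci")
})

test_that("linearity check prefers the true model form", {
  gci <- data.frame(gene = sprintf("g%04d", 1:500),
                    r = seq(-0.8, 0.8, length.out = 500))
  withr::with_seed(43, {
    lin_cub <- stats::setNames(0.4 + 0.2 * gci$r + rnorm(500, 0, 0.05),
                               gci$gene)
    quad_cub <- stats::setNames(0.4 + 0.3 * gci$r^2 + rnorm(500, 0, 0.05),
                                gci$gene)
  })
  cmp_lin <- compare_gci_linearity(lin_cub, gci)
  expect_lt(cmp_lin$aic[cmp_lin$form == "linear"],
            cmp_lin$aic[cmp_lin$form == "quadratic"] + 2)
  cmp_quad <- compare_gci_linearity(quad_cub, gci)
  expect_lt(cmp_quad$aic[cmp_quad$form == "quadratic"],
            cmp_quad$aic[cmp_quad$form == "linear"])
})
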