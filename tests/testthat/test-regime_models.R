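test_that("LAR recovers a noiseless linear recurrence exactly", {
  x <- numeric(400); x[1:2] <- c(1, 0.5)
  for (t in 3:400) x[t] <- 0.3 + 0.6 * x[t - 1] - 0.2 * x[t - 2]
  f <- fit_lar(embed_series(x, 2, 1))
  expect_equal(f$intercept, 0.3, tolerance = 1e-8)
  expect_equal(f$slopes, c(0.6, -0.2), tolerance = 1e-8)
  expect_equal(predict_one_step(f, c(x[399], x[400])),
               0.3 + 0.6 * x[400] - 0.2 * x[399], tolerance = 1e-10)
})

test_that("LAR agrees with lm() and its slopes vanish on iid targets", {
  set.seed(2)
  x <- rnorm(1500)
  pm <- embed_series(x, 3, 1)
  f <- fit_lar(pm)
  d <- glucodyn:::design_from_phase(pm)
  ref <- lm(d$y ~ d$X)
  expect_equal(unname(coef(ref)), c(f$intercept, f$slopes), tolerance = 1e-10)
  se <- sqrt(diag(vcov(ref)))[-1]
  expect_true(all(abs(f$slopes) < 3.5 * se))
})

test_that("constant series yields the degenerate constant model", {
  f <- fit_lar(embed_series(rep(7, 60), 2, 1))
  expect_equal(f$intercept, 7)
  expect_equal(f$slopes, c(0, 0))
  expect_equal(predict_one_step(f, c(7, 7)), 7)
  fa <- fit_aar(embed_series(rep(7, 60), 2, 1))
  expect_equal(predict_one_step(fa, c(7, 7)), 7, tolerance = 1e-10)
})

test_that("AAR tracks LAR on linear truth and beats it on curved truth", {
  x <- gen_linear_data(1200, seed = 5)
  pm <- embed_series(x, 2, 1)
  fl <- fit_lar(pm); fa <- fit_aar(pm)
  rmse <- function(f) sqrt(f$rss / f$n)
  expect_lt(abs(rmse(fa) - rmse(fl)) / rmse(fl), 0.01)
  # noisy quadratic map: additive smooth truth, misspecified for LAR
  set.seed(6)
  z <- numeric(1000); z[1] <- 0.4
  for (t in 2:1000) {
    z[t] <- min(max(3.8 * z[t - 1] * (1 - z[t - 1]) + rnorm(1, 0, 0.01),
                    0.01), 0.99)
  }
  pmq <- embed_series(z, 2, 1)
  expect_lt(fit_aar(pmq)$mape, fit_lar(pmq)$mape)
})

test_that("NNAR training is reproducible and near-linear on linear truth", {
  x <- gen_linear_data(900, seed = 7)
  pm <- embed_series(x, 2, 1)
  f1 <- fit_nnar(pm, q = 2, seed = 42)
  f2 <- fit_nnar(pm, q = 2, seed = 42)
  expect_identical(f1$net$wts, f2$net$wts)
  fl <- fit_lar(pm)
  rmse <- function(f) sqrt(f$rss / f$n)
  expect_lt(rmse(f1), 1.05 * rmse(fl))
  fauto <- fit_nnar(pm, q = "auto", seed = 1)
  expect_true(fauto$q %in% 1:4)
})

test_that("SETAR recovers threshold and coefficients from simulated data", {
  y <- gen_setar_data(2000, seed = 1)
  f <- fit_setar(embed_series(y, 2, 1), delta = 0)
  expect_lt(abs(f$th), 0.1)
  expect_equal(f$coef_low[1:2], c(2, 0.8), tolerance = 0.15)
  expect_equal(f$coef_high[1:2], c(-2, 0.8), tolerance = 0.15)
  # regime occupancy respects the 10% floor
  Y <- glucodyn:::design_from_phase(embed_series(y, 2, 1))$X[, 1]
  expect_gte(mean(Y <= f$th), 0.10)
  expect_gte(mean(Y > f$th), 0.10)
})

test_that("superfluous regimes lose to LAR on common-AIC comparison", {
  x <- gen_linear_data(1500, seed = 9)
  pm <- embed_series(x, 2, 1)
  best <- select_model(list(fit_lar(pm), fit_setar(pm)))
  expect_equal(best$kind, "LAR")
})

test_that("the default LSTAR grid matches the reference protocol", {
  g <- lstar_grid()
  expect_equal(g$n_thresholds, 200L)
  expect_equal(g$n_smoothing, 40L)
  expect_equal(g$n_thresholds * g$n_smoothing, 8000L)
  expect_equal(g$gamma_range, c(1, 40))
  expect_equal(g$c_quantile_range, c(0.1, 0.9))
  expect_equal(g$min_regime_fraction, 0.10)
})

test_that("LSTAR recovers a steep transition and blends regimes at G = 1/2", {
  y <- gen_lstar_data(2000, seed = 3)
  pm <- embed_series(y, 1, 1)
  f <- fit_lstar(pm)
  expect_lt(abs(f$c), 0.02)
  expect_gt(f$gamma, 10)
  # at Y = c the prediction is the average of the two regime equations
  at_c <- predict_one_step(f, f$c)
  low <- f$coef_low[1] + f$coef_low[2] * f$c
  high <- f$coef_high[1] + f$coef_high[2] * f$c
  expect_equal(at_c, (low + high) / 2, tolerance = 1e-10)
})

test_that("LSTAR in the steep limit reproduces SETAR predictions", {
  y <- gen_setar_data(2000, seed = 9)
  pm <- embed_series(y, 2, 1)
  fs <- fit_setar(pm, delta = 0)
  fl <- fit_lstar(pm)
  X <- pm[1:(nrow(pm) - 1), , drop = FALSE]
  actual <- pm[2:nrow(pm), 2]
  ps <- apply(X, 1, function(v) predict_one_step(fs, v))
  pl <- apply(X, 1, function(v) predict_one_step(fl, v))
  r_setar <- sqrt(mean((ps - actual)^2))
  r_lstar <- sqrt(mean((pl - actual)^2))
  expect_lt(abs(r_setar - r_lstar) / r_setar, 0.02)
})

test_that("model selection minimises AIC with MAPE and simplicity ties", {
  mk <- function(kind, aic, mape) {
    structure(list(kind = kind, aic = aic, mape = mape),
              class = c(paste0("glucodyn_", tolower(kind)), "glucodyn_model"))
  }
  expect_equal(select_model(list(mk("LAR", -1418.52, 0.0016),
                                 mk("LSTAR", -1440.71, 0.0011)))$kind, "LSTAR")
  expect_equal(select_model(list(mk("NNAR", -10, 0.002),
                                 mk("SETAR", -10, 0.001)))$kind, "SETAR")
  expect_equal(select_model(list(mk("LSTAR", -10, 0.002),
                                 mk("LAR", -10, 0.002)))$kind, "LAR")
  single <- mk("AAR", 0, 0)
  expect_identical(select_model(list(single)), single)
  expect_error(select_model(list()), "no candidate")
})

test_that("all five families agree on linear truth (nesting property)", {
  x <- gen_linear_data(1200, seed = 11)
  pm <- embed_series(x, 2, 1)
  fl <- fit_lar(pm)
  fits <- list(fl, fit_aar(pm), fit_nnar(pm, seed = 3), fit_setar(pm),
               fit_lstar(pm))
  for (f in fits) {
    expect_lt(abs(f$mape - fl$mape) / fl$mape, 0.05)
  }
})

test_that("one-step prediction validates the phase vector dimension", {
  f <- fit_lar(embed_series(gen_linear_data(300, 1), 2, 1))
  expect_error(predict_one_step(f, c(1, 2, 3)), "length 3")
})
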