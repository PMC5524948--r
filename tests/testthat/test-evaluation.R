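test_that("error metrics match closed forms", {
  perfect <- compute_errors(c(90, 120, 250), c(90, 120, 250))
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$mape, 0)
  offset <- compute_errors(c(105, 125), c(100, 120))
  expect_equal(offset$rmse, 5)
  expect_equal(offset$mae, 5)
  mixed <- compute_errors(c(100, 110), c(100, 100))
  expect_equal(mixed$rmse, sqrt(50))
  expect_equal(mixed$mae, 5)
  expect_error(compute_errors(1:3, 1:4), "equal length")
  withz <- compute_errors(c(1, 2), c(0, 2))
  expect_equal(withz$mape_excluded, 1)
  expect_equal(withz$mape, 0)
})

test_that("RMSE dominates MAE and metrics are permutation symmetric", {
  set.seed(20)
  for (i in 1:20) {
    p <- runif(50, 40, 400); a <- runif(50, 40, 400)
    e <- compute_errors(p, a)
    expect_gte(e$rmse, e$mae)
    perm <- sample(50)
    e2 <- compute_errors(p[perm], a[perm])
    expect_equal(e$rmse, e2$rmse)
    expect_equal(e$mae, e2$mae)
  }
})

test_that("CG-EGA grades a perfect forecast 100% A in every range", {
  # a trace passing through hypo-, eu- and hyper-glycemia
  v <- c(seq(160, 250, by = 10), seq(240, 60, by = -10), seq(65, 120, by = 5))
  gs <- make_series(v)
  r <- cg_ega(gs, gs)
  expect_equal(unname(r$zone_percent[["A"]]), 100)
  for (rng in names(r$by_range)) {
    br <- r$by_range[[rng]]
    if (!any(is.nan(br))) expect_equal(unname(br[["A"]]), 100)
  }
})

test_that("CG-EGA zone percentages always partition the pairs", {
  set.seed(21)
  for (i in 1:10) {
    ref <- make_series(pmax(runif(80, 50, 300), 30))
    prd <- make_series(pmax(ref$glucose + rnorm(80, 0, 25), 30))
    r <- cg_ega(ref, prd)
    expect_equal(sum(r$zone_percent), 100, tolerance = 1e-9)
    for (rng in names(r$by_range)) {
      br <- r$by_range[[rng]]
      if (!any(is.nan(br))) expect_equal(sum(br), 100, tolerance = 1e-9)
    }
  }
})

test_that("clinically dangerous discordance never grades A or B", {
  ref <- make_series(c(90, 80, 70, 60, 50))    # falling through hypoglycemia
  prd <- make_series(c(100, 105, 110, 120, 130))  # predicted rising
  r <- cg_ega(ref, prd)
  expect_equal(unname(r$zone_percent[["A"]] + r$zone_percent[["B"]]), 0)
})

test_that("added noise degrades zone A monotonically", {
  gs <- simulate_cgm(cgm_sim_config(days = 2, seed = 13))
  za <- vapply(c(0, 8, 20, 45), function(s) {
    set.seed(99)
    noisy <- glucose_series(gs$time,
                            pmax(gs$glucose + rnorm(length(gs), 0, s), 30))
    cg_ega(gs, noisy)$zone_percent[["A"]]
  }, numeric(1))
  expect_true(all(diff(za) < 0))
  expect_equal(za[1], 100)
})

test_that("evaluate_predictions reports per-landmark errors", {
  gs <- simulate_cgm(cgm_sim_config(days = 3, seed = 2))
  res <- sliding_predict(gs, pipeline_config(ph_minutes = 30,
                                             model_kind = "lar"))
  ev <- evaluate_predictions(res)
  expect_gte(ev$errors$rmse, ev$errors$mae)
  expect_equal(sum(ev$cg_ega$zone_percent), 100, tolerance = 1e-9)
  expect_true(all(names(ev$by_landmark) %in% unique(res$landmark)))
  ns <- vapply(ev$by_landmark, `[[`, numeric(1), "n")
  expect_equal(sum(ns), nrow(res))
})
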