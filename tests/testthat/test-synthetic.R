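test_that("benchmark maps reproduce hand-iterated values", {
  expect_equal(generate_chaotic_benchmark("logistic", n = 3, x0 = 0.2,
                                          burn_in = 0),
               c(0.2, 0.64, 0.9216))
  h <- generate_chaotic_benchmark("henon", n = 2, x0 = c(0, 0), burn_in = 0)
  expect_equal(h, c(0, 1))    # 1 - 1.4 * 0^2 + 0
  expect_identical(generate_chaotic_benchmark("logistic", n = 100, seed = 7),
                   generate_chaotic_benchmark("logistic", n = 100, seed = 7))
  l <- generate_chaotic_benchmark("lorenz_x", n = 500, seed = 2)
  expect_true(all(is.finite(l)))
  expect_gt(diff(range(l)), 10)   # visits both attractor wings
  expect_error(generate_chaotic_benchmark("logistic", n = 10, x0 = 2,
                                          burn_in = 0),
               "diverged")
})

test_that("simulated CGM has the declared grid, bounds and determinism", {
  cfg <- cgm_sim_config(days = 5, seed = 11)
  gs <- simulate_cgm(cfg)
  expect_equal(length(gs), 5 * 288)
  expect_equal(unique(diff(as.numeric(gs$time))), 300)
  expect_true(all(gs$glucose > 20 & gs$glucose < 500))
  expect_identical(simulate_cgm(cfg)$glucose, gs$glucose)
  # different seeds give different traces
  expect_false(identical(simulate_cgm(cgm_sim_config(days = 5, seed = 12))$glucose,
                         gs$glucose))
})

test_that("hypo_intensity = 0 keeps the trace out of hypoglycemia", {
  gs <- simulate_cgm(cgm_sim_config(days = 4, seed = 3, hypo_intensity = 0))
  expect_gte(min(gs$glucose), 70)
})

test_that("risk knobs move the risk indices monotonically", {
  lgi_at <- function(hy) {
    gs <- simulate_cgm(cgm_sim_config(days = 4, seed = 5, hypo_intensity = hy,
                                      hyper_intensity = 0))
    risk_indices(gs$glucose)$lgi
  }
  expect_gt(lgi_at(0.8), lgi_at(0.2))
  hgi_at <- function(hp) {
    gs <- simulate_cgm(cgm_sim_config(days = 4, seed = 5, hypo_intensity = 0,
                                      hyper_intensity = hp))
    risk_indices(gs$glucose)$hgi
  }
  expect_gt(hgi_at(0.8), hgi_at(0.2))
})

test_that("presets cover every hypo- and hyper-glycemia risk category", {
  cats <- lapply(cgm_presets(days = 5, seed = 1), function(cfg) {
    ri <- risk_indices(simulate_cgm(cfg)$glucose)
    classify_risk(ri$lgi, ri$hgi)
  })
  hypo <- vapply(cats, `[[`, character(1), "hypo_category")
  hyper <- vapply(cats, `[[`, character(1), "hyper_category")
  expect_true(all(c("minimal", "low", "moderate", "high") %in% hypo))
  expect_true(all(c("low", "moderate", "high") %in% hyper))
})

test_that("the noiseless deterministic core is chaotic", {
  gs <- simulate_cgm(cgm_sim_config(days = 5, seed = 1, noise_sd = 0))
  ly <- lyapunov_exponent(gs$glucose, m = 3, tau = 1)
  expect_gt(ly$lambda, 0.05)
})
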