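test_that("risk indices follow the symmetrising transform", {
  # zero crossing of 1.509*((ln BG)^1.084 - 5.381)
  bg0 <- exp(5.381^(1 / 1.084))
  ri <- risk_indices(rep(bg0, 10))
  expect_lt(ri$lgi + ri$hgi, 1e-6)
  low <- risk_indices(rep(50, 10))
  expect_equal(low$hgi, 0)
  expect_gt(low$lgi, 5)          # high hypoglycemia risk
  high <- risk_indices(rep(300, 10))
  expect_equal(high$lgi, 0)
  expect_gt(high$hgi, 9)         # high hyperglycemia risk
  expect_error(risk_indices(c(100, 0)), "positive")
})

test_that("LGI falls and HGI rises monotonically with the glucose level", {
  lo <- seq(25, 110, by = 5)
  lgis <- vapply(lo, function(v) risk_indices(rep(v, 3))$lgi, numeric(1))
  expect_true(all(diff(lgis) < 0))
  hi <- seq(115, 495, by = 10)
  hgis <- vapply(hi, function(v) risk_indices(rep(v, 3))$hgi, numeric(1))
  expect_true(all(diff(hgis) > 0))
})

test_that("risk categories step exactly at the printed cut-points", {
  eps <- 1e-9
  hypo <- function(l) classify_risk(l, 0)$hypo_category
  expect_equal(hypo(0.5), "minimal")
  expect_equal(hypo(1.1 - eps), "minimal")
  expect_equal(hypo(1.1), "low")
  expect_equal(hypo(2.5), "low")
  expect_equal(hypo(2.5 + eps), "moderate")
  expect_equal(hypo(3.0), "moderate")
  expect_equal(hypo(5), "moderate")
  expect_equal(hypo(5 + eps), "high")
  hyper <- function(h) classify_risk(0, h)$hyper_category
  expect_equal(hyper(4.5 - eps), "low")
  expect_equal(hyper(4.5), "moderate")
  expect_equal(hyper(9), "moderate")
  expect_equal(hyper(9 + eps), "high")
  expect_equal(hyper(10), "high")
})

test_that("intra-day indices match closed forms on simple traces", {
  const <- intra_day_indices(rep(100, 288))
  expect_equal(const$sd, 0)
  expect_equal(const$cv, 0)
  expect_equal(const$mage, 0)
  expect_equal(const$conga, 0)
  expect_equal(const$j_index, 10)   # 0.001 * (100 + 0)^2, ideal-control edge
  # mean 150, SD 50 -> J = 0.001 * 200^2 = 40, the inadequate-control edge
  x <- 150 + 50 * rep(c(-1, 1), 144) * sqrt(287 / 288)  # sample SD exactly 50
  iv <- intra_day_indices(x)
  expect_equal(iv$sd, 50, tolerance = 1e-12)
  expect_equal(iv$j_index, 40, tolerance = 1e-6)
  expect_error(intra_day_indices(rep(100, 10), conga_hours = 1),
               "too short")
})

test_that("MAGE averages only excursions exceeding one SD", {
  # triangular wave 100 <-> 160: every excursion is 60, SD ~ 21
  wave <- rep(c(100, 115, 130, 145, 160, 145, 130, 115), 36)
  expect_equal(mean(wave), 130)
  m <- intra_day_indices(wave)$mage
  expect_equal(m, 60, tolerance = 1)
})

test_that("CONGA is the SD of differences n hours apart", {
  set.seed(2)
  x <- 130 + cumsum(rnorm(576))
  iv <- intra_day_indices(x, conga_hours = 2)
  expect_equal(iv$conga, sd(x[25:576] - x[1:552]))
})

test_that("inter-day indices behave on aligned and flat traces", {
  day <- 120 + 30 * sin(2 * pi * seq_len(288) / 288)
  two <- make_series(rep(day, 2))
  ii <- inter_day_indices(two)
  expect_equal(ii$modd, 0)
  flat <- make_series(rep(120, 576))
  fi <- inter_day_indices(flat)
  expect_equal(fi$gvi, 1)
  expect_equal(fi$pgs, 0)         # fully in range, factor (1 - TIR) = 0
  expect_true(is.na(inter_day_indices(make_series(rep(120, 200)))$modd))
  # variability raises GVI above 1
  expect_gt(ii$gvi, 1)
})

test_that("scaling deviations about the mean never shrinks the spread indices", {
  set.seed(4)
  x <- 140 + 25 * sin(2 * pi * seq_len(288) / 96) + rnorm(288, 0, 5)
  scale_by <- function(k) mean(x) + k * (x - mean(x))
  for (k in c(1.5, 3)) {
    a <- intra_day_indices(x)
    b <- intra_day_indices(scale_by(k))
    expect_gte(b$sd, a$sd)
    expect_gte(b$mage, a$mage)
    expect_gte(b$conga, a$conga)
    expect_gte(inter_day_indices(make_series(scale_by(k)))$gvi,
               inter_day_indices(make_series(x))$gvi)
  }
})

test_that("landmark report covers all windows with consistent categories", {
  gs <- simulate_cgm(cgm_sim_config(days = 3, seed = 6))
  rep <- landmark_report(gs)
  expect_equal(sum(rep$windows$n), length(gs))
  expect_true(all(rep$windows$lgi >= 0 & rep$windows$hgi >= 0))
  expect_true(all(rep$windows$hypo_category %in%
                    c("minimal", "low", "moderate", "high")))
  with(rep$overall, {
    expect_equal(cv, sd / mean(gs$glucose), tolerance = 1e-12)
    expect_gte(gvi, 1)
  })
})
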