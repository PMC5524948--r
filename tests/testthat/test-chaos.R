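test_that("delay embedding lays out the delay vectors row-wise", {
  pm <- embed_series(1:6, m = 2, tau = 2)
  expect_equal(unclass(pm)[, 1], 1:4)
  expect_equal(unclass(pm)[, 2], 3:6)
  expect_equal(attr(pm, "m"), 2)
  one <- embed_series(c(4, 2, 7), m = 1, tau = 3)
  expect_equal(as.numeric(one), c(4, 2, 7))
  expect_error(embed_series(1:5, m = 3, tau = 3), "at least 7")
})

test_that("embed/reconstruct round trip is exact for random cases", {
  set.seed(10)
  for (i in 1:50) {
    n <- sample(10:80, 1)
    x <- rnorm(n)
    m <- sample(1:5, 1)
    tau <- sample(1:5, 1)
    if (m * tau > n) next
    expect_identical(reconstruct_series(embed_series(x, m, tau)), x)
  }
})

test_that("AMI profile has its maximum at lag zero and vanishes for iid data", {
  set.seed(1)
  x <- rnorm(10000)
  a <- average_mutual_information(x, max_lag = 10, bins = 16)
  expect_equal(which.max(a$ami), 1)      # lag 0 = histogram entropy
  expect_gt(a$ami[1], 1)                 # entropy of 16 occupied bins
  expect_true(all(a$ami[-1] < 0.05))     # independence up to estimator bias
  expect_equal(a$tau, 1)
})

test_that("AMI at the period of a cyclic series equals AMI at lag zero", {
  x <- rep(c(3, 1, 4, 1.5, 9, 2.6, 5.3), 100)   # period 7, n = 700
  a <- average_mutual_information(x, max_lag = 10, bins = 8)
  expect_equal(a$ami[8], a$ami[1], tolerance = 1e-10)
})

test_that("AMI is invariant under affine rescaling", {
  set.seed(3)
  x <- cumsum(rnorm(2000))
  # a random walk's AMI decays monotonically (no local minimum): the
  # fallback warning is expected and irrelevant to the invariance check
  a1 <- suppressWarnings(average_mutual_information(x, max_lag = 8, bins = 12))
  a2 <- suppressWarnings(average_mutual_information(5 * x - 40, max_lag = 8,
                                                    bins = 12))
  expect_equal(a1$ami, a2$ami, tolerance = 1e-10)
  expect_equal(a1$tau, a2$tau)
})

test_that("ACF delay selection hits the 1/e crossing of AR(1) processes", {
  set.seed(1)
  n <- 200000
  ar5 <- as.numeric(arima.sim(list(ar = 0.5), n))
  expect_equal(select_delay_acf(ar5, 30), 2)    # 0.25 < 1/e < 0.5
  ar9 <- as.numeric(arima.sim(list(ar = 0.9), n))
  expect_equal(select_delay_acf(ar9, 30), 10)   # 0.9^10 < 1/e < 0.9^9
  expect_equal(select_delay_acf(rnorm(5000), 30), 1)
})

test_that("Cao's method identifies canonical embedding dimensions", {
  h <- generate_chaotic_benchmark("henon", n = 5000, seed = 1)
  expect_equal(cao_embedding_dimension(h, tau = 1, m_max = 8)$m, 2)
  s <- sin(2 * pi * seq_len(3000) / exp(3.7))   # incommensurate period ~40.4
  expect_equal(cao_embedding_dimension(s, tau = 10, m_max = 8)$m, 2)
  set.seed(1)
  expect_warning(r <- cao_embedding_dimension(rnorm(3000), tau = 1, m_max = 8),
                 "stochastic")
  expect_equal(r$m, 8)
  expect_false(r$saturated)
})

test_that("phase-space denoising averages only within neighbourhoods", {
  x <- rnorm(200)
  expect_identical(denoise_phase(x, m = 3, radius = 0), x)
  expect_equal(denoise_phase(rep(5, 50), m = 3, radius = 1), rep(5, 50))
  # brute-force oracle on a small series
  set.seed(8)
  y <- rnorm(40)
  m <- 3; radius <- 0.8
  T <- length(y) - m + 1
  Z <- sapply(0:(m - 1), function(k) y[(1 + k):(T + k)])
  num <- numeric(length(y)); den <- numeric(length(y))
  for (i in 1:T) {
    d <- sqrt(rowSums((Z - rep(Z[i, ], each = T))^2))
    mv <- colMeans(Z[d <= radius, , drop = FALSE])
    idx <- i:(i + m - 1)
    num[idx] <- num[idx] + mv
    den[idx] <- den[idx] + 1
  }
  expect_equal(denoise_phase(y, m, radius), num / den, tolerance = 1e-12)
  # contraction toward local means
  set.seed(9)
  z <- rnorm(300)
  expect_lte(var(denoise_phase(z, 2, 0.5)), var(z))
  # two well-separated clusters never mix
  clust <- rep(c(0, 100), each = 30) + rnorm(60, 0, 0.01)
  dn <- denoise_phase(clust, 2, 1)
  expect_true(all(abs(dn[1:29] - 0) < 1))
  expect_true(all(abs(dn[32:60] - 100) < 1))
})

test_that("correlation dimension matches geometry of known sets", {
  set.seed(1)
  expect_equal(correlation_dimension(runif(4000), m = 2, tau = 1)$d2, 2,
               tolerance = 0.15)
  ramp <- seq(0, 1, length.out = 3000)
  expect_equal(correlation_dimension(ramp, m = 2, tau = 1)$d2, 1,
               tolerance = 0.1)
  h <- generate_chaotic_benchmark("henon", n = 5000, seed = 1)
  expect_equal(correlation_dimension(h, m = 2, tau = 1)$d2, 1.22,
               tolerance = 0.15)
})

test_that("correlation sums agree with a brute-force oracle", {
  h <- generate_chaotic_benchmark("henon", n = 400, seed = 2)
  m <- 2; tau <- 1; theiler <- 2
  radii <- c(0.05, 0.1, 0.3, 0.6)
  Z <- cbind(h[1:399], h[2:400])
  D <- as.matrix(dist(Z))
  cnt <- numeric(4); np <- 0
  for (i in 1:396) for (j in (i + theiler + 1):399) {
    np <- np + 1
    cnt <- cnt + (D[i, j] < radii)
  }
  expect_equal(glucodyn:::.corr_sum(h, m, tau, radii, theiler), cnt / np,
               tolerance = 1e-12)
})

test_that("Lyapunov exponents match known systems", {
  x <- generate_chaotic_benchmark("logistic", n = 5000, seed = 1)
  expect_equal(lyapunov_exponent(x, m = 1, tau = 1)$lambda, log(2),
               tolerance = 0.1)
  h <- generate_chaotic_benchmark("henon", n = 5000, seed = 1)
  expect_equal(lyapunov_exponent(h, m = 2, tau = 1)$lambda, 0.42,
               tolerance = 0.08 / 0.42)
  s <- sin(2 * pi * seq_len(3000) / exp(3.7))
  expect_lte(abs(lyapunov_exponent(s, m = 2, tau = 10)$lambda), 0.02)
})

test_that("recurrence matrices are symmetric 0/1 with unit diagonal", {
  set.seed(5)
  x <- cumsum(rnorm(120))
  R <- recurrence_matrix(x, m = 2, tau = 1, cutoff = 1)
  expect_true(all(R %in% c(0L, 1L)))
  expect_identical(R, t(R))
  expect_true(all(diag(R) == 1L))
  R2 <- recurrence_matrix(x, m = 2, tau = 1, cutoff = diff(range(x)) * 3)
  expect_true(all(R2 == 1L))
})
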