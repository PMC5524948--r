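# Shared fixture builders.  All fixtures are generated in code; seeds are
# fixed so every run sees identical data.

t0_utc <- as.POSIXct("2023-04-01 00:00:00", tz = "UTC")

# A glucose series on the regular 5-min grid starting at `start`.
make_series <- function(values, start = t0_utc, by_min = 5) {
  glucose_series(start + 60 * seq(0, by = by_min,
                                  length.out = length(values)), values)
}

# Two-regime SETAR process switching on the previous value at threshold 0;
# wide amplitude so the 10-90% quantile span (hence the threshold grid) is
# broad relative to the estimator's sampling error.
gen_setar_data <- function(n, seed, th = 0, delta = 2, phi = 0.8, sd = 1) {
  set.seed(seed)
  y <- numeric(n)
  for (t in 2:n) {
    y[t] <- if (y[t - 1] <= th) delta + phi * y[t - 1] + rnorm(1, 0, sd)
            else -delta + phi * y[t - 1] + rnorm(1, 0, sd)
  }
  y
}

# LSTAR process with logistic transition G(y; gamma0, c0) on the previous
# value; steep transitions make the location c sharply identified.
gen_lstar_data <- function(n, seed, c0 = 0, gamma0 = 40, delta = 0.5,
                           phi = 0.8, sd = 0.1) {
  set.seed(seed)
  y <- numeric(n)
  for (t in 2:n) {
    G <- 1 / (1 + exp(-gamma0 * (y[t - 1] - c0)))
    y[t] <- (1 - G) * (delta + phi * y[t - 1]) +
      G * (-delta + phi * y[t - 1]) + rnorm(1, 0, sd)
  }
  y
}

# Noisy linear AR(2) series, the "linear truth" for nesting checks.
gen_linear_data <- function(n, seed, sd = 0.3) {
  set.seed(seed)
  x <- numeric(n)
  for (t in 3:n) x[t] <- 0.5 + 0.5 * x[t - 1] + 0.3 * x[t - 2] + rnorm(1, 0, sd)
  x
}

# Exactly linear-recurrent glucose-like trace: damped oscillation about
# 120 mg/dL satisfies an order-2 linear recurrence with intercept.
gen_recurrence_series <- function(n) {
  t <- seq_len(n)
  make_series(120 + 30 * 0.999^t * cos(2 * pi * t / 40))
}
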