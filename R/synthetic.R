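#' Generate a canonical chaotic benchmark series
#'
#' Deterministic trajectories of textbook chaotic systems, used to validate
#' the nonlinear-analysis routines against known invariants (e.g. the
#' logistic map at growth rate 4 has largest Lyapunov exponent `ln 2`; the Henon
#' map has correlation dimension about 1.22 and embeds at dimension 2).
#'
#' @param system `"logistic"`, `"henon"` or `"lorenz_x"` (the x coordinate
#'   of the Lorenz-63 flow, sampled every `params$dt` time units).
#' @param n Number of samples to return, after burn-in.
#' @param params Named list of system parameters; defaults are the classic
#'   chaotic settings (`r` 4; `a` 1.4, `b` 0.3;
#'   `sigma = 10, rho = 28, beta = 8/3, dt = 0.05`).
#' @param x0 Initial state (scalar for logistic, length-2 for henon,
#'   length-3 for lorenz_x).  If `NULL`, drawn reproducibly from `seed`.
#' @param seed Integer seed used only when `x0` is `NULL`.
#' @param burn_in Transient samples discarded before recording; use 0 to
#'   start exactly at `x0`.
#' @return Numeric vector of length `n`.
#' @examples
#' generate_chaotic_benchmark("logistic", n = 3, x0 = 0.2, burn_in = 0)
#' @export
generate_chaotic_benchmark <- function(system = c("logistic", "henon", "lorenz_x"),
                                       n, params = list(), x0 = NULL,
                                       seed = 1L, burn_in = 1000L) {
  system <- match.arg(system)
  stopifnot(n >= 1, burn_in >= 0)
  total <- n + burn_in
  out <- switch(system,
    logistic = {
      r <- params$r %||% 4
      x <- x0 %||% with_private_seed(seed, function() runif(1, 0.1, 0.9))
      iterate_map(function(s) r * s * (1 - s), x, total, take = 1L)
    },
    henon = {
      a <- params$a %||% 1.4
      b <- params$b %||% 0.3
      s <- x0 %||% with_private_seed(seed, function() runif(2, -0.1, 0.1))
      iterate_map(function(s) c(1 - a * s[1]^2 + s[2], b * s[1]), s, take = 1L,
                  total)
    },
    lorenz_x = {
      p <- list(sigma = params$sigma %||% 10, rho = params$rho %||% 28,
                beta = params$beta %||% 8 / 3)
      dt <- params$dt %||% 0.05
      s <- x0 %||% with_private_seed(seed, function() c(runif(3, -1, 1) + c(1, 1, 20)))
      lorenz_rk4(s, p, dt, total)
    })
  if (any(!is.finite(out))) {
    stop("trajectory diverged (non-finite values); check parameters")
  }
  out[(burn_in + 1):total]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Iterate a (possibly vector-valued) map, recording component `take`.
iterate_map <- function(f, state, total, take = 1L) {
  out <- numeric(total)
  for (i in seq_len(total)) {
    out[i] <- state[take]
    state <- f(state)
    if (any(!is.finite(state))) {
      out[i:total] <- NaN
      break
    }
  }
  out
}

# Fixed-step RK4 for the Lorenz-63 system; one recorded sample per `dt`.
lorenz_rk4 <- function(state, p, dt, total, substeps = 5L) {
  deriv <- function(s) {
    c(p$sigma * (s[2] - s[1]),
      s[1] * (p$rho - s[3]) - s[2],
      s[1] * s[2] - p$beta * s[3])
  }
  h <- dt / substeps
  out <- numeric(total)
  for (i in seq_len(total)) {
    out[i] <- state[1]
    for (j in seq_len(substeps)) {
      k1 <- deriv(state)
      k2 <- deriv(state + h / 2 * k1)
      k3 <- deriv(state + h / 2 * k2)
      k4 <- deriv(state + h * k3)
      state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
  }
  out
}

#' Configuration for the synthetic CGM generator
#'
#' @param days Number of monitored days (4-7 is typical of free-living CGM
#'   studies).
#' @param seed Integer seed; identical configurations and seeds give
#'   bit-identical traces.
#' @param noise_sd Sensor noise standard deviation, mg/dL.
#' @param meal_times Clock hours of the daily meals.
#' @param basal_level Baseline glucose, mg/dL.
#' @param hypo_intensity,hyper_intensity Severity knobs in \[0, 1\]: 0
#'   disables the nocturnal/afternoon dips (resp. exaggerated meal
#'   excursions); larger values monotonically increase the low (resp. high)
#'   glucose risk index.
#' @return A list of class `cgm_sim_config`.
#' @export
cgm_sim_config <- function(days = 5, seed = 1L, noise_sd = 5,
                           meal_times = c(7.5, 12.75, 19),
                           basal_level = 120,
                           hypo_intensity = 0.3, hyper_intensity = 0.3) {
  stopifnot(days >= 1, noise_sd >= 0,
            hypo_intensity >= 0, hypo_intensity <= 1,
            hyper_intensity >= 0, hyper_intensity <= 1,
            all(meal_times >= 0 & meal_times < 24), basal_level > 0)
  structure(list(days = as.integer(days), seed = as.integer(seed),
                 noise_sd = noise_sd, meal_times = meal_times,
                 basal_level = basal_level,
                 hypo_intensity = hypo_intensity,
                 hyper_intensity = hyper_intensity),
            class = "cgm_sim_config")
}

#' Simulate a synthetic CGM trace
#'
#' Emulates a multi-day free-living CGM recording sampled every 5 minutes:
#' a smoothed chaotic deterministic core (a low-pass filtered logistic map,
#' which keeps a positive largest Lyapunov exponent) rides on a circadian
#' baseline; meal responses with chaotically modulated amplitudes rise over
#' about an hour and decay over three; optional nocturnal and late-afternoon
#' dips produce hypoglycemic exposure; truncated Gaussian sensor noise is
#' added last.  With `hypo_intensity = 0` the deterministic part is floored
#' at `70 + 3 * noise_sd` and the noise is truncated at 3 standard
#' deviations, so no reading falls below 70 mg/dL.
#'
#' This generator mimics the sampling grid, circadian landmark structure,
#' chaotic irregularity and risk strata of real CGM data, not its
#' physiology: there is no insulin-glucose feedback, no meal announcements,
#' and dips/excursions are stylised.
#'
#' @param config A [cgm_sim_config()].
#' @param start Start timestamp (`POSIXct`); defaults to midnight.
#' @return A [glucose_series()] of `days * 288` samples.
#' @examples
#' gs <- simulate_cgm(cgm_sim_config(days = 4, seed = 42))
#' gs
#' @export
simulate_cgm <- function(config = cgm_sim_config(),
                         start = as.POSIXct("2023-04-01 00:00:00", tz = "UTC")) {
  stopifnot(inherits(config, "cgm_sim_config"))
  n <- config$days * 288L
  tmin <- seq(0, by = 5, length.out = n)           # minutes since start
  hour_of_day <- (tmin / 60) %% 24

  sim <- with_private_seed(config$seed, function() {
    # chaotic core: a logistic map advanced once every 3 samples (one step
    # per 15 min), so the largest Lyapunov exponent is ln(2)/3 ~ 0.23 per
    # 5-min sample -- the magnitude reported for real CGM traces -- then
    # low-pass filtered (recursive EMA) into glucose-like slow fluctuation.
    # Linear filtering and the sample-and-hold clock preserve positivity of
    # the exponent.
    n_map <- ceiling((n + 1L) / 3) + 1L
    y <- generate_chaotic_benchmark("logistic", n = n_map,
                                    x0 = runif(1, 0.2, 0.8), burn_in = 500L)
    yh <- y[ceiling(seq_len(n + 1L) / 3)]
    z <- stats::filter(yh, 0.94, method = "recursive", init = yh[1]) * 0.06
    z <- as.numeric(stats::filter(z, 0.6, method = "recursive",
                                  init = z[1])) * 0.4
    dev <- 10 * (z - mean(z)) / sd(z)
    eps <- pmin(pmax(rnorm(n, 0, config$noise_sd), -3 * config$noise_sd),
                3 * config$noise_sd)
    list(y = yh, dev = dev[seq_len(n)], eps = eps)
  })

  circadian <- config$basal_level + 6 * cos(2 * pi * (hour_of_day - 16) / 24)

  # meal responses: gamma-like rise/decay, peak ~90 min after the meal;
  # amplitude modulated by the chaotic state at mealtime
  meals <- numeric(n)
  for (d in seq_len(config$days) - 1L) {
    for (mt in config$meal_times) {
      m0 <- (d * 24 + mt) * 60
      u <- (tmin - m0) / 90
      on <- u > 0 & u < 6
      y_meal <- sim$y[max(1L, min(n, floor(m0 / 5) + 1L))]
      amp <- (30 + 105 * config$hyper_intensity) * (0.75 + 0.5 * y_meal)
      meals[on] <- meals[on] + amp * (u[on]^2) * exp(2 * (1 - u[on]))
    }
  }

  # hypoglycemic dips: nightly (03:00) and late afternoon (17:00)
  dips <- numeric(n)
  if (config$hypo_intensity > 0) {
    for (d in seq_len(config$days) - 1L) {
      for (dh in c(3, 17)) {
        c0 <- (d * 24 + dh) * 60
        y_dip <- sim$y[max(1L, min(n, floor(c0 / 5) + 1L))]
        depth <- config$hypo_intensity * (60 + 30 * y_dip)
        width <- 45 * (1 + 1.2 * config$hypo_intensity)
        dips <- dips + depth * exp(-0.5 * ((tmin - c0) / width)^2)
      }
    }
  }

  det <- circadian + sim$dev + meals - dips
  if (config$hypo_intensity == 0) {
    det <- pmax(det, 70 + 3 * config$noise_sd)
  }
  values <- pmin(pmax(det + sim$eps, 25), 495)
  glucose_series(start + 60 * tmin, values, sampling_minutes = 5)
}

#' Preset simulator configurations spanning the risk categories
#'
#' Named configurations whose simulated traces reach, respectively, the
#' minimal/low/moderate/high hypoglycemia (LGI) and low/moderate/high
#' hyperglycemia (HGI) risk categories.
#'
#' @param days,seed,noise_sd Passed to every preset.
#' @return Named list of [cgm_sim_config()] objects.
#' @export
cgm_presets <- function(days = 5, seed = 1L, noise_sd = 5) {
  cfg <- function(hypo, hyper, basal = 120) {
    cgm_sim_config(days = days, seed = seed, noise_sd = noise_sd,
                   basal_level = basal,
                   hypo_intensity = hypo, hyper_intensity = hyper)
  }
  list(
    stable       = cfg(0.00, 0.00),  # LGI minimal, HGI low
    hypo_low     = cfg(0.60, 0.00),
    hypo_moderate = cfg(0.80, 0.00),
    hypo_high    = cfg(1.00, 0.00),
    hyper_moderate = cfg(0.00, 0.60, basal = 140),
    hyper_high   = cfg(0.00, 1.00, basal = 160),
    mixed_high   = cfg(1.00, 1.00, basal = 130)
  )
}
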