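#' Augmented Dickey-Fuller stationarity test
#'
#' Fits the ADF regression (constant and linear trend) with the lag order
#' chosen by AIC up to `trunc((n-1)^(1/3))`, and interpolates the p-value
#' of the unit-root statistic from the classical Dickey-Fuller critical
#' value table.  The conventional direction is used: rejecting the
#' unit-root null (p below `alpha`) declares the series stationary.
#'
#' @param x Numeric series, length at least 20.
#' @param alpha Significance threshold (default 0.05).
#' @return List with `statistic`, `p_value`, `lag_order`, `is_stationary`.
#' @export
test_stationarity <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 20) stop("need at least 20 observations")
  if (var(x) == 0) {
    warning("constant series: unit-root regression is degenerate")
    return(list(statistic = NA_real_, p_value = 1, lag_order = 0L,
                is_stationary = FALSE))
  }
  kmax <- max(0L, trunc((n - 1)^(1 / 3)))
  dy <- diff(x)
  adf_fit <- function(k) {
    # common sample across k so AICs are comparable
    idx <- (kmax + 1):(n - 1)                    # rows = time t of dy_t
    X <- cbind(1, idx, x[idx])
    if (k > 0) {
      for (i in seq_len(k)) X <- cbind(X, dy[idx - i])
    }
    f <- lm.fit(X, dy[idx])
    rss <- sum(f$residuals^2)
    nn <- length(idx)
    list(aic = nn * log(rss / nn) + 2 * (k + 3), fit = f, n = nn)
  }
  aics <- vapply(0:kmax, function(k) adf_fit(k)$aic, numeric(1))
  k <- which.min(aics) - 1L
  f <- adf_fit(k)
  rss <- sum(f$fit$residuals^2)
  se <- sqrt(rss / (f$n - (k + 3)) * diag(chol2inv(f$fit$qr$qr[1:(k + 3),
                                                              1:(k + 3)])))
  stat <- f$fit$coefficients[3] / se[3]
  # Dickey-Fuller critical values (trend case), interpolated in both the
  # sample size and the statistic
  tbl <- -matrix(c(4.38, 4.15, 4.04, 3.99, 3.98, 3.96,
                   3.95, 3.80, 3.73, 3.69, 3.68, 3.66,
                   3.60, 3.50, 3.45, 3.43, 3.42, 3.41,
                   3.24, 3.18, 3.15, 3.13, 3.13, 3.12,
                   1.14, 1.19, 1.22, 1.23, 1.24, 1.25,
                   0.80, 0.87, 0.90, 0.92, 0.93, 0.94,
                   0.50, 0.58, 0.62, 0.64, 0.65, 0.66,
                   0.15, 0.24, 0.28, 0.31, 0.32, 0.33), nrow = 6)
  ns <- c(25, 50, 100, 250, 500, 1e5)
  probs <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
  row <- vapply(seq_len(8), function(j) {
    approx(ns, tbl[, j], xout = min(max(f$n, 25), 1e5), rule = 2)$y
  }, numeric(1))
  p <- approx(row, probs, xout = stat, rule = 2)$y
  list(statistic = unname(stat), p_value = p, lag_order = k,
       is_stationary = p < alpha)
}

#' Variance-stabilising transform and differencing
#'
#' Applies an optional natural-log transform followed by `d`-th order
#' differencing, retaining the information needed for exact inversion.
#'
#' @param x Positive numeric series (positivity required for `"log"`).
#' @param transform `"log"` or `"none"`.
#' @param d Differencing order (>= 0).
#' @return List with `w` (working series, length `length(x) - d`) and
#'   `state` (transform kind, order, initial values).
#' @export
transform_series <- function(x, transform = c("log", "none"), d = 1L) {
  transform <- match.arg(transform)
  x <- as.numeric(x)
  if (transform == "log") {
    if (any(x <= 0)) stop("log transform requires positive values")
    g <- log(x)
  } else {
    g <- x
  }
  init <- list()
  w <- g
  for (i in seq_len(d)) {
    init[[i]] <- w[1]
    w <- diff(w)
  }
  list(w = w, state = list(transform = transform, d = as.integer(d),
                           init = init))
}

#' @rdname transform_series
#' @param w Working series from [transform_series()].
#' @param state Transform state from [transform_series()].
#' @export
inverse_transform <- function(w, state) {
  for (i in rev(seq_len(state$d))) {
    w <- cumsum(c(state$init[[i]], w))
  }
  if (state$transform == "log") exp(w) else w
}

#' Forecasting pipeline configuration
#'
#' @param train_hours Length of the sliding training window, hours
#'   (default 8, i.e. 96 samples at 5-minute sampling).
#' @param ph_minutes Prediction horizon, minutes (30 or 60).
#' @param model_kind One of `"lar"`, `"aar"`, `"nnar"`, `"setar"`,
#'   `"lstar"`, `"auto"` (fit all five, keep the AIC winner).
#' @param transform `"log"` or `"none"`.
#' @param differencing Differencing order, 0 or 1.
#' @param denoise Apply phase-space denoising to the training window
#'   (radius from [denoise_radius()] on the standardised window).
#' @param origin_stride Samples between successive forecast origins (and
#'   refits); default is the horizon, giving continuous non-overlapping
#'   forecasts.
#' @param m_range Admissible embedding dimensions.
#' @param max_lag Largest delay probed by AMI/ACF.
#' @param landmark_embedding Estimate `(m, tau)` from the training samples
#'   belonging to the forecast origin's landmark interval (falling back to
#'   the whole window when too few).
#' @param q NNAR hidden units or `"auto"`.
#' @param seed Seed for the (NNAR) stochastic fit.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(train_hours = 8, ph_minutes = 30,
                            model_kind = c("lstar", "lar", "aar", "nnar",
                                           "setar", "auto"),
                            transform = c("log", "none"), differencing = 1L,
                            denoise = TRUE, origin_stride = NULL,
                            m_range = c(2L, 6L), max_lag = 20L,
                            landmark_embedding = TRUE, q = "auto",
                            seed = 1L) {
  model_kind <- match.arg(model_kind)
  transform <- match.arg(transform)
  stopifnot(train_hours > 0, ph_minutes > 0, differencing %in% c(0L, 1L),
            m_range[1] >= 1, m_range[2] >= m_range[1])
  structure(list(train_hours = train_hours, ph_minutes = ph_minutes,
                 model_kind = model_kind, transform = transform,
                 differencing = as.integer(differencing), denoise = denoise,
                 origin_stride = origin_stride,
                 m_range = as.integer(m_range), max_lag = as.integer(max_lag),
                 landmark_embedding = landmark_embedding, q = q,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Estimate (tau, m) for a training segment.  Linear models use the ACF
# 1/e rule for the delay, nonlinear ones the first AMI minimum; the
# dimension comes from Cao's method, clamped to the configured range.
estimate_embedding <- function(seg, config) {
  len <- length(seg)
  max_lag <- min(config$max_lag, max(2L, floor(len / 4)))
  tau <- tryCatch({
    if (config$model_kind %in% c("lar", "aar")) {
      suppressWarnings(select_delay_acf(seg, max_lag))
    } else {
      suppressWarnings(average_mutual_information(seg, max_lag)$tau)
    }
  }, error = function(e) 1L)
  tau <- max(1L, min(tau, floor((len - 10) / max(1, config$m_range[2]))))
  m_max <- min(config$m_range[2] + 1L, floor((len - 2) / tau))
  m <- tryCatch({
    if (m_max >= 2) {
      cao <- suppressWarnings(cao_embedding_dimension(seg, tau, m_max))
      # no saturation = no evidence of deterministic structure at any
      # probed dimension; prefer the parsimonious end for modelling
      if (cao$saturated) cao$m else config$m_range[1]
    } else config$m_range[1]
  }, error = function(e) config$m_range[1])
  m <- max(config$m_range[1], min(m, config$m_range[2]))
  list(m = as.integer(m), tau = as.integer(tau))
}

fit_model_kind <- function(pm, config) {
  switch(config$model_kind,
    lar = fit_lar(pm),
    aar = fit_aar(pm),
    nnar = fit_nnar(pm, q = config$q, seed = config$seed),
    setar = fit_setar(pm),
    lstar = fit_lstar(pm),
    auto = {
      cand <- list()
      for (f in list(fit_lar,
                     fit_aar,
                     function(p) fit_nnar(p, q = config$q, seed = config$seed),
                     fit_setar,
                     fit_lstar)) {
        fit <- tryCatch(f(pm), error = function(e) NULL)
        if (!is.null(fit)) cand[[length(cand) + 1]] <- fit
      }
      select_model(cand)
    })
}

#' Sliding-window multi-step glucose forecasting
#'
#' Walks forecast origins along the series.  At each origin the trailing
#' training window (8 monitoring hours by default) is log-transformed and
#' differenced, optionally denoised in phase space, embedded with `(m,
#' tau)` re-estimated from the window (by default from the samples sharing
#' the origin's landmark interval), and the configured model is fitted.
#' One-step predictions are then iterated `ph_minutes / sampling` times,
#' feeding each prediction back as an input, and the final value is
#' inverse-transformed to mg/dL and scored against the reading actually
#' realised at the target time.  Nothing after the origin is ever used for
#' fitting, so there is no look-ahead leakage.
#'
#' @param series A [glucose_series()] without gaps.
#' @param config A [pipeline_config()].
#' @return A data frame of class `prediction_result` with columns
#'   `timestamp`, `actual`, `predicted`, `ph_minutes`, `landmark`, plus
#'   attributes `config` and `log` (skipped origins).
#' @export
sliding_predict <- function(series, config = pipeline_config()) {
  stopifnot(inherits(series, "glucose_series"),
            inherits(config, "pipeline_config"))
  if (nrow(series$gaps) > 0) {
    stop("series contains sampling gaps; split at gaps before forecasting")
  }
  interval <- series$sampling_minutes
  if (config$ph_minutes %% interval != 0) {
    stop("ph_minutes must be a multiple of the sampling interval")
  }
  h <- config$ph_minutes %/% interval
  train_n <- round(config$train_hours * 60 / interval)
  x <- series$glucose
  n <- length(x)
  if (n < train_n + h + 1) stop("series shorter than one training window + horizon")
  d <- config$differencing
  tr <- transform_series(x, config$transform, d)
  w <- c(rep(NA_real_, d), tr$w)        # w[i] aligned with x[i]
  stride <- config$origin_stride %||% h
  origins <- seq(train_n, n - h, by = stride)
  lm_all <- landmark_of(series$time)
  rows <- vector("list", length(origins))
  skipped <- character(0)
  for (oi in seq_along(origins)) {
    o <- origins[oi]
    tr_idx <- (o - train_n + 1 + d):o
    wtr <- w[tr_idx]
    # embedding segment: training samples in the origin's landmark interval
    seg <- wtr
    if (config$landmark_embedding) {
      same <- lm_all[tr_idx] == lm_all[o]
      r <- rle(same)
      if (any(r$values & r$lengths >= 40)) {
        ends <- cumsum(r$lengths)
        pick <- which(r$values & r$lengths >= 40)
        pick <- pick[length(pick)]        # most recent qualifying run
        seg <- wtr[(ends[pick] - r$lengths[pick] + 1):ends[pick]]
      }
    }
    emb <- estimate_embedding(seg, config)
    wfit <- wtr
    if (config$denoise) {
      mu <- mean(wtr); s <- sd(wtr)
      if (s > 0) {
        wfit <- mu + s * denoise_phase((wtr - mu) / s, emb$m,
                                       denoise_radius(emb$m))
      }
    }
    res <- tryCatch({
      pm <- embed_series(wfit, emb$m, emb$tau)
      model <- fit_model_kind(pm, config)
      # iterated predictions are confined to the window's observed
      # increment range, and the inverted forecast to the window's glucose
      # envelope plus 10%: an 8-h-conditioned forecast leaving either is a
      # fitting artefact, not physiology
      preds <- forecast_iterated(model, wtr, h, range(wtr))
      xhat <- invert_forecast(preds, x[o], config)
      xwin <- x[(o - train_n + 1):o]
      xhat <- min(max(xhat, 0.9 * min(xwin)), 1.1 * max(xwin))
      list(xhat = xhat, model = model)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- c(skipped, sprintf("origin %d: %s", o, conditionMessage(res)))
      next
    }
    rows[[oi]] <- data.frame(
      timestamp = series$time[o + h],
      actual = x[o + h],
      predicted = res$xhat,
      ph_minutes = config$ph_minutes,
      landmark = lm_all[o + h],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("every forecast origin failed: ",
                         paste(head(skipped, 3), collapse = "; "))
  attr(out, "config") <- config
  attr(out, "log") <- skipped
  class(out) <- c("prediction_result", class(out))
  out
}

# Map h iterated working-scale predictions back to mg/dL at the horizon.
invert_forecast <- function(preds, x_origin, config) {
  last <- preds[length(preds)]
  if (config$differencing == 1L) {
    if (config$transform == "log") exp(log(x_origin) + sum(preds))
    else x_origin + sum(preds)
  } else {
    if (config$transform == "log") exp(last) else last
  }
}
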