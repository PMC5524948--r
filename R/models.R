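# Phase-space autoregressive predictors.
#
# All five model families regress the next scalar observation on the m
# delay coordinates of the current phase-space vector.  Internally the
# design uses "lag order": lag 1 is the most recent coordinate, lag i is
# the value i-1 delays back.  Fit-quality scores share one convention so
# they are comparable across families: AIC = n log(RSS/n) + 2(k+1) with k
# the (effective) number of mean parameters, MAPE the in-sample mean
# absolute percentage error.

# One-step-ahead design from a phase matrix: predictors are the reversed
# coordinates of row t (most recent first), target the next observation,
# which is the last coordinate of row t+1.
design_from_phase <- function(pm) {
  m <- attr(pm, "m"); tau <- attr(pm, "tau")
  stopifnot(!is.null(m), !is.null(tau))
  T <- nrow(pm)
  if (T < m + 2) stop("phase matrix too short to fit: ", T, " rows")
  X <- pm[seq_len(T - 1), rev(seq_len(m)), drop = FALSE]
  colnames(X) <- paste0("lag", seq_len(m))
  list(X = X, y = pm[2:T, m], m = m, tau = tau)
}

gaussian_aic <- function(rss, n, k) n * log(rss / n) + 2 * (k + 1)

in_sample_mape <- function(res, y) {
  ok <- y != 0
  mean(abs(res[ok] / y[ok]))
}

new_fitted_model <- function(kind, d, extra, rss, k_eff) {
  n <- length(d$y)
  structure(
    c(list(kind = kind, m = d$m, tau = d$tau, n = n, rss = rss,
           aic = gaussian_aic(rss, n, k_eff),
           mape = in_sample_mape(extra$residuals, d$y)),
      extra[setdiff(names(extra), "residuals")]),
    class = c(paste0("glucodyn_", tolower(kind)), "glucodyn_model")
  )
}

#' @export
print.glucodyn_model <- function(x, ...) {
  cat(sprintf("<%s phase-space AR> m=%d tau=%d n=%d AIC=%.2f MAPE=%.4g\n",
              x$kind, x$m, x$tau, x$n, x$aic, x$mape))
  invisible(x)
}

#' Fit a linear autoregressive model in phase space (LAR)
#'
#' Ordinary least squares of the next observation on the `m` delay
#' coordinates.  Zero-variance (e.g. constant-series) lags are dropped from
#' the regression and their coefficients fixed at zero; any remaining exact
#' collinearity is an error naming the offending lags.
#'
#' @param pm A `phase_matrix` from [embed_series()].
#' @return A fitted model object (class `glucodyn_model`) with elements
#'   `intercept` and `slopes` (lag order), plus shared `aic`/`mape` scores.
#' @export
fit_lar <- function(pm) {
  d <- design_from_phase(pm)
  keep <- apply(d$X, 2, function(col) var(col) > 0)
  Xk <- cbind(`(Intercept)` = 1, d$X[, keep, drop = FALSE])
  q <- qr(Xk)
  if (q$rank < ncol(Xk)) {
    bad <- colnames(Xk)[q$pivot[(q$rank + 1):ncol(Xk)]]
    stop("collinear lags in LAR design: ", paste(bad, collapse = ", "))
  }
  beta <- qr.coef(q, d$y)
  res <- d$y - drop(Xk %*% beta)
  slopes <- numeric(d$m)
  slopes[keep] <- beta[-1]
  new_fitted_model("LAR", d,
                   list(intercept = unname(beta[1]), slopes = slopes,
                        residuals = res),
                   sum(res^2), k_eff = sum(keep) + 1)
}

#' Fit an additive autoregressive model (AAR)
#'
#' Additive model with one penalized cubic regression spline per delay
#' coordinate, `y = mu + sum_i s_i(lag_i)`, fitted by [mgcv::gam()] with
#' smoothness chosen by generalized cross-validation.  Lags without enough
#' distinct values for a spline basis enter linearly; zero-variance lags
#' are dropped.
#'
#' @param pm A `phase_matrix`.
#' @param k_basis Spline basis size per term; default adapts to the sample
#'   size.
#' @return A fitted model object wrapping the `gam` fit.
#' @export
fit_aar <- function(pm, k_basis = NULL) {
  d <- design_from_phase(pm)
  df <- as.data.frame(d$X)
  df$.y <- d$y
  n <- length(d$y)
  if (is.null(k_basis)) k_basis <- max(5L, min(10L, floor(n / (3 * d$m))))
  terms <- vapply(seq_len(d$m), function(i) {
    v <- d$X[, i]
    u <- length(unique(v))
    if (u < 3) return(NA_character_)
    if (u <= k_basis + 1) return(colnames(d$X)[i])     # linear term
    sprintf("s(%s, bs = 'cr', k = %d)", colnames(d$X)[i], k_basis)
  }, character(1))
  terms <- terms[!is.na(terms)]
  form <- if (length(terms)) {
    stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  } else {
    .y ~ 1
  }
  fit <- mgcv::gam(form, data = df, method = "GCV.Cp")
  res <- stats::residuals(fit)
  new_fitted_model("AAR", d, list(gam = fit, residuals = res),
                   sum(res^2), k_eff = sum(fit$edf))
}

#' Fit a neural-network autoregressive model (NNAR)
#'
#' Time-lagged feed-forward network with one hidden layer of `q` tanh units
#' and a linear output, trained by gradient descent from several random
#' restarts under a fixed seed (so refits are bit-identical).  With
#' `q = "auto"` the hidden-layer size is chosen over a small range by AIC,
#' ties broken by MAPE.
#'
#' @param pm A `phase_matrix`.
#' @param q Hidden units, or `"auto"`.
#' @param seed Integer seed controlling weight initialisation.
#' @param restarts Random restarts per candidate size.
#' @param decay,maxit Weight decay and iteration cap passed to
#'   [nnet::nnet()].
#' @return A fitted model object wrapping the best network and its input
#'   scaling.
#' @export
fit_nnar <- function(pm, q = "auto", seed = 1L, restarts = 5L,
                     decay = 1e-4, maxit = 500L) {
  d <- design_from_phase(pm)
  ctr <- colMeans(d$X)
  scl <- pmax(apply(d$X, 2, sd), 1e-12)
  Xs <- scale(d$X, ctr, scl)
  y_ctr <- mean(d$y); y_scl <- max(sd(d$y), 1e-12)
  ys <- (d$y - y_ctr) / y_scl
  cand <- if (identical(q, "auto")) 1:4 else as.integer(q)
  fits <- with_private_seed(seed, function() {
    lapply(cand, function(qi) {
      best <- NULL
      for (r in seq_len(restarts)) {
        f <- nnet::nnet(Xs, ys, size = qi, linout = TRUE, decay = decay,
                        maxit = maxit, trace = FALSE)
        if (is.null(best) || f$value < best$value) best <- f
      }
      best
    })
  })
  score <- vapply(fits, function(f) {
    res <- ys - drop(f$fitted.values)
    gaussian_aic(sum((res * y_scl)^2), length(ys), length(f$wts))
  }, numeric(1))
  if (any(!is.finite(score))) stop("NNAR training diverged")
  pick <- which.min(score)
  fit <- fits[[pick]]
  res <- (ys - drop(fit$fitted.values)) * y_scl
  new_fitted_model("NNAR", d,
                   list(net = fit, q = cand[pick], center = ctr, scale = scl,
                        y_center = y_ctr, y_scale = y_scl, residuals = res),
                   sum(res^2), k_eff = length(fit$wts))
}

#' Fit a self-exciting threshold AR model (SETAR)
#'
#' Two-regime piecewise-linear model switching on the delayed coordinate
#' `Y_t = lag_{delta+1}`: the low regime (order `L`) applies when
#' `Y_t <= th`, the high regime (order `H`) otherwise.  The threshold is
#' searched over up to `n_thresholds` candidate values of the transition
#' variable that leave at least `min_frac` of the observations in each
#' regime; regime coefficients are least squares and candidates are ranked
#' by pooled AIC (the sum of per-regime Gaussian AICs).  When `delta` is
#' `NULL` the threshold delay is also chosen by pooled AIC over
#' `0..m-1`.
#'
#' @param pm A `phase_matrix`.
#' @param orders Regime AR orders `c(L, H)`, each at most `m`; default
#'   `c(m, m)`.
#' @param delta Threshold delay in `0..m-1`, or `NULL` to search.
#' @param n_thresholds Maximum number of threshold candidates.
#' @param min_frac Minimum fraction of observations per regime.
#' @return A fitted model object with `th`, `delta`, `coef_low`,
#'   `coef_high` (intercept first), and `orders`.
#' @export
fit_setar <- function(pm, orders = NULL, delta = NULL, n_thresholds = 200L,
                      min_frac = 0.10) {
  d <- design_from_phase(pm)
  if (is.null(orders)) orders <- c(d$m, d$m)
  L <- orders[1]; H <- orders[2]
  stopifnot(L >= 1, H >= 1, L <= d$m, H <= d$m)
  deltas <- if (is.null(delta)) 0:(d$m - 1) else as.integer(delta)
  n <- length(d$y)
  Xlow <- cbind(1, d$X[, seq_len(L), drop = FALSE])
  Xhigh <- cbind(1, d$X[, seq_len(H), drop = FALSE])
  best <- NULL
  for (dl in deltas) {
    Y <- d$X[, dl + 1]
    cand <- sort(unique(Y))
    ranks <- vapply(cand, function(th) mean(Y <= th), numeric(1))
    cand <- cand[ranks >= min_frac & ranks <= 1 - min_frac]
    if (length(cand) > n_thresholds) {
      cand <- cand[unique(round(seq(1, length(cand),
                                    length.out = n_thresholds)))]
    }
    for (th in cand) {
      lo <- Y <= th
      n1 <- sum(lo); n2 <- n - n1
      if (n1 <= L + 2 || n2 <= H + 2) next
      f1 <- lm.fit(Xlow[lo, , drop = FALSE], d$y[lo])
      f2 <- lm.fit(Xhigh[!lo, , drop = FALSE], d$y[!lo])
      rss1 <- sum(f1$residuals^2); rss2 <- sum(f2$residuals^2)
      pooled <- n1 * log(rss1 / n1) + n2 * log(rss2 / n2) +
        2 * (L + 1) + 2 * (H + 1)
      if (is.null(best) || pooled < best$pooled) {
        best <- list(pooled = pooled, th = th, delta = dl, f1 = f1, f2 = f2,
                     rss = rss1 + rss2, lo = lo)
      }
    }
  }
  if (is.null(best)) {
    stop("degenerate regimes: no threshold candidate leaves at least ",
         round(100 * min_frac), "% of observations in each regime")
  }
  res <- numeric(n)
  res[best$lo] <- best$f1$residuals
  res[!best$lo] <- best$f2$residuals
  new_fitted_model("SETAR", d,
                   list(th = best$th, delta = best$delta,
                        coef_low = unname(coef(best$f1)),
                        coef_high = unname(coef(best$f2)),
                        orders = c(L = L, H = H),
                        pooled_aic = best$pooled, residuals = res),
                   best$rss, k_eff = (L + 1) + (H + 1) + 1)
}

#' LSTAR hyper-parameter grid
#'
#' Defaults follow the reference fitting protocol: 200 candidate locations
#' `c` between the 0.1 and 0.9 quantiles of the transition variable, 40
#' smoothness values `gamma` from 1 to 40, and at least 10% of the
#' observations on each side of `c`.
#'
#' @param n_thresholds,n_smoothing Grid sizes for `c` and `gamma`.
#' @param gamma_range,c_quantile_range Grid limits.
#' @param min_regime_fraction Minimum occupancy per regime.
#' @return A list of class `lstar_grid`.
#' @export
lstar_grid <- function(n_thresholds = 200L, n_smoothing = 40L,
                       gamma_range = c(1, 40),
                       c_quantile_range = c(0.1, 0.9),
                       min_regime_fraction = 0.10) {
  stopifnot(n_thresholds >= 2, n_smoothing >= 2, all(gamma_range > 0),
            all(c_quantile_range > 0 & c_quantile_range < 1))
  structure(list(n_thresholds = as.integer(n_thresholds),
                 n_smoothing = as.integer(n_smoothing),
                 gamma_range = gamma_range,
                 c_quantile_range = c_quantile_range,
                 min_regime_fraction = min_regime_fraction),
            class = "lstar_grid")
}

#' Fit a logistic smooth-transition AR model (LSTAR)
#'
#' Blends a low and a high linear regime with the logistic weight
#' `G(Y; gamma, c) = 1 / (1 + exp(-gamma (Y - c)))`: the low regime is
#' weighted by `1 - G` and the high regime by `G`, so that as
#' `gamma -> Inf` the model converges to the corresponding SETAR.  Linear
#' parameters are estimated by least squares at every point of the
#' `(c, gamma)` grid; the best grid point is then refined by bounded
#' quasi-Newton search (c kept inside its quantile range, preserving the
#' minimum regime occupancy; gamma inside its grid range).
#'
#' @param pm A `phase_matrix`.
#' @param grid An [lstar_grid()].
#' @param orders Regime AR orders `c(L, H)`; default `c(m, m)`.
#' @param delta Threshold delay defining the transition variable
#'   `Y_t = lag_{delta+1}` (default 0, the most recent coordinate).
#' @param refine Refine `(c, gamma)` continuously after the grid search.
#' @return A fitted model object with `c`, `gamma`, `coef_low`,
#'   `coef_high`, `delta` and `orders`.
#' @export
fit_lstar <- function(pm, grid = lstar_grid(), orders = NULL, delta = 0L,
                      refine = TRUE) {
  d <- design_from_phase(pm)
  if (is.null(orders)) orders <- c(d$m, d$m)
  L <- orders[1]; H <- orders[2]
  stopifnot(L >= 1, H >= 1, L <= d$m, H <= d$m, inherits(grid, "lstar_grid"))
  Y <- d$X[, delta + 1]
  qs <- quantile(Y, grid$c_quantile_range, names = FALSE)
  if (qs[1] >= qs[2]) stop("degenerate transition variable")
  c_grid <- seq(qs[1], qs[2], length.out = grid$n_thresholds)
  g_grid <- seq(grid$gamma_range[1], grid$gamma_range[2],
                length.out = grid$n_smoothing)
  Xlow <- cbind(1, d$X[, seq_len(L), drop = FALSE])
  Xhigh <- cbind(1, d$X[, seq_len(H), drop = FALSE])
  gs <- .lstar_grid(Xlow, Xhigh, d$y, Y, c_grid, g_grid)
  if (!is.finite(gs$best_rss)) stop("LSTAR grid search failed on all points")
  cc <- c_grid[gs$best_c_index]
  gg <- g_grid[gs$best_g_index]
  rss_fun <- function(par) {
    g <- .lstar_grid(Xlow, Xhigh, d$y, Y, par[1], par[2])
    g$best_rss
  }
  if (refine) {
    opt <- optim(c(cc, gg), rss_fun, method = "L-BFGS-B",
                 lower = c(qs[1], grid$gamma_range[1]),
                 upper = c(qs[2], grid$gamma_range[2]))
    if (opt$value <= gs$best_rss) {
      cc <- opt$par[1]; gg <- opt$par[2]
    }
  }
  fin <- .lstar_grid(Xlow, Xhigh, d$y, Y, cc, gg)
  beta <- fin$best_beta
  G <- 1 / (1 + exp(-gg * (Y - cc)))
  Z <- cbind(Xlow * (1 - G), Xhigh * G)
  res <- d$y - drop(Z %*% beta)
  new_fitted_model("LSTAR", d,
                   list(c = cc, gamma = gg,
                        coef_low = beta[seq_len(L + 1)],
                        coef_high = beta[(L + 2):(L + H + 2)],
                        delta = as.integer(delta),
                        orders = c(L = L, H = H), grid = grid,
                        residuals = res),
                   fin$best_rss, k_eff = (L + 1) + (H + 1) + 2)
}

#' Select the best fitted model
#'
#' Minimum AIC wins; ties are broken by lower MAPE, then by simplicity
#' (LAR before AAR before SETAR before LSTAR before NNAR).
#'
#' @param candidates List of fitted model objects.
#' @return The selected fitted model.
#' @export
select_model <- function(candidates) {
  if (!length(candidates)) stop("no candidate models")
  simplicity <- c(LAR = 1, AAR = 2, SETAR = 3, LSTAR = 4, NNAR = 5)
  ord <- order(vapply(candidates, `[[`, numeric(1), "aic"),
               vapply(candidates, `[[`, numeric(1), "mape"),
               simplicity[vapply(candidates, `[[`, character(1), "kind")])
  candidates[[ord[1]]]
}

#' One-step prediction from a phase-space point
#'
#' Evaluates the fitted map at a phase-space vector given in embedding
#' coordinate order (oldest to most recent, as in the rows of
#' [embed_series()]), returning the predicted next scalar observation.  No
#' noise term is added.
#'
#' @param model A fitted model object.
#' @param vector Numeric vector of length `m`.
#' @return Predicted next value (scalar).
#' @export
predict_one_step <- function(model, vector) {
  UseMethod("predict_one_step")
}

check_phase_vector <- function(model, vector) {
  if (length(vector) != model$m) {
    stop("phase vector has length ", length(vector), ", model expects m = ",
         model$m)
  }
  rev(vector)   # lag order: most recent first
}

#' @export
predict_one_step.glucodyn_lar <- function(model, vector) {
  lags <- check_phase_vector(model, vector)
  model$intercept + sum(model$slopes * lags)
}

#' @export
predict_one_step.glucodyn_aar <- function(model, vector) {
  lags <- check_phase_vector(model, vector)
  nd <- as.data.frame(as.list(stats::setNames(lags,
                                              paste0("lag", seq_along(lags)))))
  as.numeric(predict(model$gam, newdata = nd))
}

#' @export
predict_one_step.glucodyn_nnar <- function(model, vector) {
  lags <- check_phase_vector(model, vector)
  xs <- (lags - model$center) / model$scale
  drop(predict(model$net, matrix(xs, nrow = 1))) * model$y_scale +
    model$y_center
}

#' @export
predict_one_step.glucodyn_setar <- function(model, vector) {
  lags <- check_phase_vector(model, vector)
  Yv <- lags[model$delta + 1]
  if (Yv <= model$th) {
    model$coef_low[1] + sum(model$coef_low[-1] *
                              lags[seq_len(model$orders["L"])])
  } else {
    model$coef_high[1] + sum(model$coef_high[-1] *
                               lags[seq_len(model$orders["H"])])
  }
}

#' @export
predict_one_step.glucodyn_lstar <- function(model, vector) {
  lags <- check_phase_vector(model, vector)
  Yv <- lags[model$delta + 1]
  G <- 1 / (1 + exp(-model$gamma * (Yv - model$c)))
  low <- model$coef_low[1] + sum(model$coef_low[-1] *
                                   lags[seq_len(model$orders["L"])])
  high <- model$coef_high[1] + sum(model$coef_high[-1] *
                                     lags[seq_len(model$orders["H"])])
  (1 - G) * low + G * high
}

# Iterated multi-step forecast on a scalar (working-scale) series: feed
# each one-step prediction back as the newest observation.  `clip` bounds
# each fed-back prediction (typically the training window's envelope) so a
# locally overfit nonlinear map cannot run away over the iteration.
forecast_iterated <- function(model, w, h, clip = NULL) {
  m <- model$m; tau <- model$tau
  need <- (m - 1) * tau + 1
  if (length(w) < need) stop("history too short to form a phase vector")
  out <- numeric(h)
  for (s in seq_len(h)) {
    len <- length(w)
    vec <- w[len - rev(seq_len(m) - 1L) * tau]   # embedding order
    p <- predict_one_step(model, vec)
    if (!is.null(clip)) p <- min(max(p, clip[1]), clip[2])
    out[s] <- p
    w <- c(w, p)
  }
  out
}
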