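#' Takens delay embedding
#'
#' Builds the phase matrix of delay vectors
#' `[x_t, x_{t+tau}, ..., x_{t+(m-1)tau}]`, one per row, for
#' `t = 1 .. n - (m-1)*tau`.  Coordinates advance in time across a row, so
#' the last column holds the most recent value of each vector.
#'
#' @param x Numeric series.
#' @param m Embedding dimension (>= 1).
#' @param tau Time delay in samples (>= 1).
#' @return A numeric matrix of class `phase_matrix` with attributes `m`,
#'   `tau` and `source_length`.
#' @examples
#' embed_series(1:6, m = 2, tau = 2)
#' @export
embed_series <- function(x, m, tau) {
  stopifnot(m >= 1, tau >= 1)
  n <- length(x)
  T <- n - (m - 1) * tau
  if (T < 1) {
    stop("series of length ", n, " too short: embedding at m=", m,
         ", tau=", tau, " needs at least ", (m - 1) * tau + 1, " samples")
  }
  Z <- vapply(seq_len(m) - 1L, function(k) x[(1 + k * tau):(T + k * tau)],
              numeric(T))
  Z <- matrix(Z, nrow = T)
  structure(Z, m = m, tau = tau, source_length = n,
            class = c("phase_matrix", "matrix", "array"))
}

#' Reconstruct a scalar series from a phase matrix
#'
#' Inverse of [embed_series()]: the first column supplies the first `T`
#' observations and the trailing `(m-1)*tau` observations are read from the
#' later coordinates of the final rows, giving back all
#' `T + (m-1)*tau` original values.  `reconstruct_series(embed_series(x))`
#' is exact for any admissible `(m, tau)`.
#'
#' @param pm A `phase_matrix` (any numeric matrix with `m`/`tau`
#'   attributes, e.g. a matrix of phase-space predictions).
#' @return Numeric vector of length `nrow(pm) + (m-1)*tau`.
#' @export
reconstruct_series <- function(pm) {
  m <- attr(pm, "m"); tau <- attr(pm, "tau")
  stopifnot(!is.null(m), !is.null(tau))
  T <- nrow(pm)
  if (m > 1 && tau > T) {
    stop("matrix with ", T, " rows does not cover all ", T + (m - 1) * tau,
         " source observations (needs tau <= rows); the source series is ",
         "not recoverable")
  }
  x <- numeric(T + (m - 1) * tau)
  x[seq_len(T)] <- pm[, 1]
  if (m > 1) {
    for (j in seq_len((m - 1) * tau)) {
      k <- ceiling(j / tau) + 1L          # column holding observation T + j
      r <- T + j - (k - 1L) * tau         # row of that column
      x[T + j] <- pm[r, k]
    }
  }
  x
}

#' Average mutual information profile and delay selection
#'
#' Estimates `AMI(tau) = sum_ij p_ij(tau) log(p_ij(tau) / (p_i p_j))`
#' (natural log) from the joint histogram of `(x_t, x_{t+tau})`, using a
#' common equal-width binning of the series.  The delay returned is the
#' first local minimum of the profile, the standard prescription for
#' delay-embedding nonlinear models; see [select_delay_acf()] for the
#' linear-model counterpart.
#'
#' @param x Numeric series.
#' @param max_lag Largest lag evaluated.
#' @param bins Number of histogram bins; default is Freedman-Diaconis.
#' @return List with `ami` (profile at lags `0..max_lag`), `lags` and
#'   `tau` (selected delay).
#' @export
average_mutual_information <- function(x, max_lag = 50, bins = NULL) {
  n <- length(x)
  stopifnot(max_lag >= 1, n > max_lag + 1)
  if (diff(range(x)) == 0) {
    warning("constant series: AMI identically 0, tau defaults to 1")
    return(list(ami = rep(0, max_lag + 1), lags = 0:max_lag, tau = 1L))
  }
  if (is.null(bins)) bins <- max(2L, grDevices::nclass.FD(x))
  breaks <- seq(min(x), max(x), length.out = bins + 1)
  disc <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  ami <- vapply(0:max_lag, function(lag) {
    a <- disc[1:(n - lag)]
    b <- disc[(1 + lag):n]
    joint <- table(a, b) / (n - lag)
    pi_ <- rowSums(joint); pj <- colSums(joint)
    idx <- joint > 0
    sum(joint[idx] * log(joint[idx] / outer(pi_, pj)[idx]))
  }, numeric(1))
  tau <- NA_integer_
  for (lag in 1:(max_lag - 1)) {
    if (ami[lag + 1] < ami[lag] && ami[lag + 1] <= ami[lag + 2]) {
      tau <- lag
      break
    }
  }
  if (is.na(tau)) {
    warning("no local minimum of AMI within max_lag; using max_lag")
    tau <- max_lag
  }
  list(ami = ami, lags = 0:max_lag, tau = as.integer(tau))
}

#' Delay selection from the autocorrelation function
#'
#' Returns the smallest lag at which the autocorrelation first falls below
#' `1/e`, the usual delay prescription for linear phase-space models.
#'
#' @param x Numeric series.
#' @param max_lag Largest lag considered.
#' @return Integer delay.
#' @export
select_delay_acf <- function(x, max_lag = 50) {
  stopifnot(length(x) > max_lag + 1)
  rho <- as.numeric(acf(x, lag.max = max_lag, plot = FALSE,
                        demean = TRUE)$acf)[-1]
  hit <- which(rho < exp(-1))
  if (!length(hit)) {
    warning("autocorrelation never drops below 1/e within max_lag")
    return(as.integer(max_lag))
  }
  as.integer(hit[1])
}

#' Minimum embedding dimension by Cao's method
#'
#' Computes Cao's `E1(m) = E(m+1) / E(m)` from mean nearest-neighbour
#' distance ratios (max norm) together with his companion statistic
#' `E2(m) = E*(m+1) / E*(m)`.  The selected dimension is the smallest `m`
#' from which `E1` stops changing, i.e. every later step of the profile is
#' smaller than `1 - threshold` in absolute value.  Stochastic input is
#' screened with `E2`: for noise-like data `E2(m)` stays indistinguishable
#' from 1 at every `m` (there is no deterministic structure for the extra
#' coordinate to reveal), in which case `m_max` is returned with a
#' warning -- for such data `E1` also creeps upward indefinitely, so no
#' finite dimension is meaningful.
#'
#' @param x Numeric series.
#' @param tau Time delay in samples.
#' @param m_max Largest dimension probed.
#' @param threshold Saturation threshold; `1 - threshold` is both the
#'   allowed residual change in `E1` beyond the selected dimension and the
#'   margin by which `E2` must leave 1 somewhere for the series to count
#'   as deterministic (default 0.95).
#' @return List with `m`, `e1` and `e2` (profiles over `m = 1..m_max-1`)
#'   and `saturated` (logical).
#' @export
cao_embedding_dimension <- function(x, tau, m_max = 10, threshold = 0.95) {
  stopifnot(length(x) >= m_max * tau + 2)
  prof <- .cao_e_profile(as.numeric(x), as.integer(tau), as.integer(m_max))
  E <- prof$E; Es <- prof$Estar
  e1 <- E[-1] / E[-length(E)]             # E1(m), m = 1..m_max-1
  e2 <- Es[-1] / Es[-length(Es)]
  tol <- 1 - threshold
  sel <- NA_integer_
  if (any(abs(e2 - 1) > tol)) {
    inc <- abs(diff(e1))
    for (m in seq_len(length(inc))) {
      if (all(inc[m:length(inc)] <= tol)) {
        sel <- m
        break
      }
    }
  }
  saturated <- !is.na(sel)
  if (!saturated) {
    warning("E1 does not saturate up to m_max = ", m_max,
            "; input looks stochastic, returning m_max")
    sel <- m_max
  }
  list(m = as.integer(sel), e1 = e1, e2 = e2, saturated = saturated)
}

#' @describeIn denoise_phase Radius schedule on standardised data: wide
#'   neighbourhoods (0.2) at low embedding dimensions `m <= 3`, essentially
#'   none (1e-4) at `m >= 6`, log-interpolated in between.
#' @export
denoise_radius <- function(m) {
  if (m <= 3) return(0.2)
  if (m >= 6) return(1e-4)
  10^(approx(c(3, 6), log10(c(0.2, 1e-4)), xout = m)$y)
}

#' Phase-space denoising by local neighbourhood averaging
#'
#' Embeds the series at delay 1 in an `m`-dimensional space, replaces each
#' delay vector by the mean of all vectors within a Euclidean `radius`
#' (always including itself), and reconstructs the series by averaging the
#' overlapping coordinates.  The radius is interpreted on the scale of the
#' data passed in; standardise first to use the [denoise_radius()]
#' schedule.  `radius = 0` returns the input unchanged.
#'
#' @param x Numeric series.
#' @param m Embedding dimension used for the neighbourhoods.
#' @param radius Neighbourhood radius (>= 0), on the data's scale.
#' @return Denoised numeric series, same length as `x`.
#' @export
denoise_phase <- function(x, m, radius) {
  stopifnot(radius >= 0, m >= 1)
  if (radius == 0 || m == 1) return(as.numeric(x))
  .denoise_phase(as.numeric(x), as.integer(m), radius)
}

#' Correlation dimension (Grassberger-Procaccia)
#'
#' Estimates D2 as the slope of `log C(r)` against `log r` over an
#' automatically selected scaling region, where `C(r)` is the fraction of
#' embedded vector pairs (more than `theiler` samples apart in time) closer
#' than `r`.  The scaling region is the window of consecutive radii whose
#' local slopes are most nearly constant; if even the best window has very
#' uneven slopes the estimate is flagged low-confidence.
#'
#' @param x Numeric series.
#' @param m,tau Embedding dimension and delay.
#' @param theiler Temporal exclusion window in samples (default `m * tau`).
#' @param n_radii Number of log-spaced radii probed.
#' @return List with `d2`, `log_r`, `log_c`, `scaling_region` (indices) and
#'   `low_confidence`.
#' @export
correlation_dimension <- function(x, m, tau, theiler = NULL, n_radii = 24) {
  x <- as.numeric(x)
  if (is.null(theiler)) theiler <- m * tau
  T <- length(x) - (m - 1) * tau
  stride <- max(1L, floor(T / 400))
  ds <- .dist_sample(x, as.integer(m), as.integer(tau),
                     as.integer(theiler), as.integer(stride))
  qs <- quantile(ds[ds > 0], c(0.005, 0.5))
  radii <- exp(seq(log(qs[1]), log(qs[2]), length.out = n_radii))
  C <- .corr_sum(x, as.integer(m), as.integer(tau), radii,
                 as.integer(theiler))
  ok <- C > 0
  lr <- log(radii[ok]); lc <- log(C[ok])
  slopes <- diff(lc) / diff(lr)
  w <- 6L
  if (length(slopes) < w) stop("too few populated radii for a scaling region")
  sds <- vapply(seq_len(length(slopes) - w + 1),
                function(i) sd(slopes[i:(i + w - 1)]), numeric(1))
  i0 <- which.min(sds)
  reg <- i0:(i0 + w)                       # indices into lr/lc
  fit <- lm(lc[reg] ~ lr[reg])
  d2 <- unname(coef(fit)[2])
  list(d2 = d2, log_r = lr, log_c = lc, scaling_region = reg,
       low_confidence = sds[i0] > 0.2 * abs(mean(slopes[reg[-length(reg)]])))
}

#' Largest Lyapunov exponent (Rosenstein method)
#'
#' Tracks the divergence of each embedded point from its nearest neighbour
#' (excluding temporally close neighbours) and averages the log distances
#' into a divergence curve `S(k)`; the exponent is the slope of the linear
#' regression of `S` on `k` over the initial growth phase, detected as the
#' contiguous run of steps whose increments stay above a quarter of the
#' initial increment (before the curve saturates).  Reported per sample
#' step.
#'
#' @param x Numeric series.
#' @param m,tau Embedding dimension and delay.
#' @param theiler Temporal exclusion window (default `m * tau`).
#' @param kmax Length of the divergence curve, in steps.
#' @param fit_range Optional integer vector of steps (0-based) to fit on,
#'   overriding the automatic growth-phase detection.
#' @return List with `lambda` (per sample step), `s` (divergence curve),
#'   `steps` and `fit_range`.
#' @export
lyapunov_exponent <- function(x, m, tau, theiler = NULL, kmax = 30,
                              fit_range = NULL) {
  x <- as.numeric(x)
  if (is.null(theiler)) theiler <- m * tau
  s <- .rosenstein_curve(x, as.integer(m), as.integer(tau),
                         as.integer(theiler), as.integer(kmax))
  if (is.null(fit_range)) {
    inc <- diff(s)
    s0 <- max(inc[1:min(3, length(inc))])
    if (s0 <= 0) {
      fit_range <- 0:min(5, kmax)          # flat curve: regular dynamics
    } else {
      last <- 1L
      while (last < length(inc) && inc[last + 1] >= 0.25 * s0) last <- last + 1L
      fit_range <- 0:max(3L, last)
    }
  }
  ks <- fit_range
  fit <- lm(s[ks + 1] ~ ks)
  list(lambda = unname(coef(fit)[2]), s = s, steps = 0:kmax,
       fit_range = fit_range)
}

#' Recurrence matrix of an embedded series
#'
#' Binary matrix with entry `(i, j) = 1` when embedded vectors `z_i` and
#' `z_j` lie within `cutoff` of each other; symmetric with a unit diagonal.
#' Plotting it (e.g. with `image()`) gives the classical recurrence plot.
#'
#' @param x Numeric series.
#' @param m,tau Embedding dimension and delay.
#' @param cutoff Distance cutoff (> 0).
#' @return Integer 0/1 matrix, `T x T`.
#' @export
recurrence_matrix <- function(x, m, tau, cutoff) {
  stopifnot(cutoff > 0)
  Z <- embed_series(as.numeric(x), m, tau)
  D <- as.matrix(stats::dist(Z))
  matrix(as.integer(D <= cutoff), nrow = nrow(D))
}

#' Nonlinear characterisation report
#'
#' Convenience wrapper running the full characterisation: AMI delay, Cao
#' embedding dimension, correlation dimension and largest Lyapunov
#' exponent.
#'
#' @param x Numeric series.
#' @param max_lag,m_max Search ranges for delay and dimension.
#' @return List with `tau`, `m`, `ami`, `cao_e1`, `correlation_dimension`,
#'   `lyapunov` and the component results.
#' @export
chaos_report <- function(x, max_lag = 30, m_max = 8) {
  ami <- average_mutual_information(x, max_lag = max_lag)
  cao <- cao_embedding_dimension(x, tau = ami$tau, m_max = m_max)
  d2 <- correlation_dimension(x, m = cao$m, tau = ami$tau)
  ly <- lyapunov_exponent(x, m = cao$m, tau = ami$tau)
  list(tau = ami$tau, m = cao$m, ami = ami$ami, cao_e1 = cao$e1,
       correlation_dimension = d2$d2, lyapunov = ly$lambda,
       d2_detail = d2, lyapunov_detail = ly)
}
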