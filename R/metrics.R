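#' Low and high blood-glucose risk indices (LGI, HGI)
#'
#' Each reading is mapped through the Kovatchev symmetrising transform
#' `f(BG) = 1.509 * ((ln BG)^1.084 - 5.381)` (BG in mg/dL), whose zero
#' crossing sits near 112.5 mg/dL, and converted to a risk score
#' `10 * f(BG)^2`.  Scores on the low side (`f < 0`) average into the
#' low glucose index, scores on the high side into the high glucose index.
#' Averaging (rather than a raw sum) keeps the indices comparable across
#' recordings of different length, which is what the standard LBGI/HBGI
#' risk categories assume.
#'
#' @param values Positive glucose readings, mg/dL.
#' @return Named list `lgi`, `hgi` (both nonnegative).
#' @examples
#' risk_indices(rep(50, 10))   # deep hypoglycemia: high LGI, zero HGI
#' @export
risk_indices <- function(values) {
  if (any(values <= 0)) stop("glucose values must be positive")
  f <- 1.509 * (log(values)^1.084 - 5.381)
  r <- 10 * f^2
  list(lgi = mean(ifelse(f < 0, r, 0)), hgi = mean(ifelse(f > 0, r, 0)))
}

#' Categorise hypo- and hyper-glycemia risk
#'
#' Categories follow the printed LGI/HGI cut-points: hypoglycemia risk is
#' minimal below 1.1, low from 1.1 to 2.5, moderate above 2.5 up to 5, and
#' high above 5; hyperglycemia risk is low below 4.5, moderate from 4.5 to
#' 9, and high above 9.  Values falling exactly on a cut-point are assigned
#' to the lower-severity category except where the wording is strict
#' ("greater than").
#'
#' @param lgi,hgi Nonnegative risk indices from [risk_indices()].
#' @return Named list `hypo_category`, `hyper_category`.
#' @export
classify_risk <- function(lgi, hgi) {
  stopifnot(lgi >= 0, hgi >= 0)
  hypo <- if (lgi < 1.1) "minimal" else if (lgi <= 2.5) "low"
          else if (lgi <= 5) "moderate" else "high"
  hyper <- if (hgi < 4.5) "low" else if (hgi <= 9) "moderate" else "high"
  list(hypo_category = hypo, hyper_category = hyper)
}

#' Intra-day glycemic variability indices
#'
#' Computes, for a single day's (or window's) readings: the sample standard
#' deviation (SD, mg/dL); the coefficient of variation (CV = SD / mean,
#' dimensionless); the J-index `0.001 * (mean + SD)^2` whose bands read
#' 10-20 ideal, 20-30 good, above 40 inadequate control; MAGE, the mean
#' amplitude of glycemic excursions exceeding one SD between successive
#' turning points (turning points found on a 3-point moving-average
#' smoothed trace); and CONGA_n, the standard deviation of differences
#' between readings `n` hours apart.
#'
#' @param values Glucose readings, mg/dL, uniformly sampled.
#' @param conga_hours Lag for CONGA, hours (default 1).
#' @param interval_mins Sampling interval, minutes.
#' @return Named list `sd`, `cv`, `j_index`, `mage`, `conga`.
#' @export
intra_day_indices <- function(values, conga_hours = 1, interval_mins = 5) {
  n <- length(values)
  if (n < 2) stop("need at least 2 samples")
  lag <- round(conga_hours * 60 / interval_mins)
  if (lag >= n) stop("series too short for CONGA at ", conga_hours, " h")
  s <- sd(values)
  m <- mean(values)
  list(sd = s,
       cv = s / m,
       j_index = 0.001 * (m + s)^2,
       mage = mage(values, s),
       conga = sd(values[(lag + 1):n] - values[1:(n - lag)]))
}

# MAGE, Service-style: smooth with a 3-point moving average, take turning
# points, then average the absolute excursions between successive turning
# points that exceed one (raw) SD.  Returns 0 when no excursion qualifies.
mage <- function(values, s = sd(values)) {
  n <- length(values)
  if (n < 3 || s == 0) return(0)
  sm <- as.numeric(stats::filter(values, rep(1 / 3, 3), sides = 2))
  sm[1] <- values[1]; sm[n] <- values[n]
  d <- diff(sm)
  d <- d[d != 0]
  if (!length(d)) return(0)
  # indices of sign changes on the de-flattened difference sequence
  keep <- which(diff(sm) != 0)
  turn <- keep[which(diff(sign(d)) != 0)] + 1L
  pts <- values[c(1L, turn, n)]
  exc <- abs(diff(pts))
  exc <- exc[exc > s]
  if (!length(exc)) 0 else mean(exc)
}

#' Inter-day glycemic variability indices
#'
#' MODD is the mean absolute difference between readings taken at the same
#' clock time on consecutive days (undefined, returned as `NA`, with fewer
#' than two full days).  GVI is the arc length of the glucose trace (time
#' in minutes vs glucose in mg/dL) divided by the length of the straight
#' segment joining its endpoints; a perfectly flat trace gives exactly 1,
#' non-diabetic traces typically 1.0-1.2, high variability above 1.5.
#' PGS = GVI x mean glucose x (1 - fraction of time in 70-180 mg/dL).
#'
#' @param series A [glucose_series()].
#' @return Named list `modd`, `gvi`, `pgs`.
#' @export
inter_day_indices <- function(series) {
  stopifnot(inherits(series, "glucose_series"))
  x <- series$glucose
  n <- length(x)
  per_day <- round(1440 / series$sampling_minutes)
  modd <- if (n >= per_day + 1) {
    mean(abs(x[(per_day + 1):n] - x[1:(n - per_day)]))
  } else NA_real_
  dt <- series$sampling_minutes
  arc <- sum(sqrt(dt^2 + diff(x)^2))
  chord <- sqrt((dt * (n - 1))^2 + (x[n] - x[1])^2)
  gvi <- arc / chord
  tir <- mean(x >= 70 & x <= 180)
  list(modd = modd, gvi = gvi, pgs = gvi * mean(x) * (1 - tir))
}

#' Variability and risk report per landmark window
#'
#' Applies [risk_indices()], [classify_risk()] and [intra_day_indices()] to
#' every (day, landmark) window of a CGM trace, and [inter_day_indices()]
#' to the whole trace.
#'
#' @param series A [glucose_series()].
#' @param conga_hours Lag for CONGA, hours.
#' @return List with `windows` (data frame, one row per window) and
#'   `overall` (whole-trace indices and categories).
#' @export
landmark_report <- function(series, conga_hours = 1) {
  seg <- segment_landmarks(series)
  rows <- lapply(seq_len(nrow(seg)), function(i) {
    w <- window_series(seg, i)
    ri <- risk_indices(w$glucose)
    cl <- classify_risk(ri$lgi, ri$hgi)
    iv <- if (length(w) > conga_hours * 60 / w$sampling_minutes + 1) {
      intra_day_indices(w$glucose, conga_hours, w$sampling_minutes)
    } else {
      list(sd = NA_real_, cv = NA_real_, j_index = NA_real_,
           mage = NA_real_, conga = NA_real_)
    }
    data.frame(date = seg$date[i], landmark = seg$landmark[i], n = seg$n[i],
               lgi = ri$lgi, hgi = ri$hgi,
               hypo_category = cl$hypo_category,
               hyper_category = cl$hyper_category,
               sd = iv$sd, cv = iv$cv, j_index = iv$j_index,
               mage = iv$mage, conga = iv$conga)
  })
  ri <- risk_indices(series$glucose)
  overall <- c(ri, classify_risk(ri$lgi, ri$hgi),
               intra_day_indices(series$glucose, conga_hours,
                                 series$sampling_minutes),
               inter_day_indices(series))
  list(windows = do.call(rbind, rows), overall = overall)
}
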