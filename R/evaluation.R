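#' Numerical prediction-error metrics
#'
#' @param predicted,actual Equal-length numeric vectors, mg/dL.
#' @return List with `rmse`, `mae`, `mape` (fraction; pairs with a zero
#'   actual value are excluded and counted in `mape_excluded`), and `n`.
#' @examples
#' compute_errors(c(100, 110), c(100, 100))
#' @export
compute_errors <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have equal length")
  }
  if (!length(predicted)) stop("no pairs to evaluate")
  err <- predicted - actual
  ok <- actual != 0
  list(rmse = sqrt(mean(err^2)),
       mae = mean(abs(err)),
       mape = mean(abs(err[ok] / actual[ok])),
       mape_excluded = sum(!ok),
       n = length(err))
}

# ---- continuous glucose error-grid analysis -------------------------------
#
# Point accuracy uses the classical Clarke error-grid zones, with the
# rate-dependent boundary expansions of the continuous variant: when the
# reference is falling at 1-2 mg/dL/min the upper A/B boundaries stretch by
# 10 mg/dL (20 when falling faster); when rising, the lower boundaries
# stretch symmetrically.  Rate accuracy grades the predicted vs reference
# rate of change on a grid (all rates in mg/dL/min):
#   A: within 1 of the reference rate (within 2 when |ref rate| > 2);
#   E: opposite directions, both beyond 1 (clinically dangerous);
#   C: reference near flat (|rate| <= 1) but prediction beyond 2;
#   D: prediction near flat (|rate| <= 1) but reference beyond 2;
#   B: everything else.
# The combined zone per pair is the worse of the point and rate zones, with
# E collapsed into D to match the four-zone A-D reporting convention.

clarke_point_zone <- function(ref, pred) {
  # A takes precedence, as in the original grid's construction
  if (abs(pred - ref) <= 0.2 * ref || (ref < 70 && pred < 70)) return("A")
  if ((ref >= 180 && pred <= 70) || (ref <= 70 && pred >= 180)) return("E")
  if ((ref >= 240 && pred >= 70 && pred <= 180) ||
      (ref <= 70 && pred >= 70 && pred <= 180)) return("D")
  if ((ref >= 70 && ref <= 290 && pred >= ref + 110) ||
      (ref >= 130 && ref <= 180 && pred <= 7 / 5 * ref - 182)) return("C")
  "B"
}

point_zone <- function(ref, pred, ref_rate) {
  # boundary expansion: evaluate also with the prediction pulled toward the
  # reference by the allowance and keep the most favourable zone
  sev <- c(A = 1, B = 2, C = 3, D = 4, E = 5)
  allow_up <- if (ref_rate < -2) 20 else if (ref_rate <= -1) 10 else 0
  allow_dn <- if (ref_rate > 2) 20 else if (ref_rate >= 1) 10 else 0
  zones <- clarke_point_zone(ref, pred)
  if (allow_up > 0 && pred > ref) {
    zones <- c(zones, clarke_point_zone(ref, max(ref, pred - allow_up)))
  }
  if (allow_dn > 0 && pred < ref) {
    zones <- c(zones, clarke_point_zone(ref, min(ref, pred + allow_dn)))
  }
  names(sev)[min(sev[zones])]
}

rate_zone <- function(rr, pr) {
  band <- if (abs(rr) > 2) 2 else 1
  if (abs(pr - rr) <= band) return("A")
  if ((rr <= -1 && pr >= 1) || (rr >= 1 && pr <= -1)) return("E")
  if (abs(rr) <= 1 && abs(pr) > 2) return("C")
  if (abs(pr) <= 1 && abs(rr) > 2) return("D")
  "B"
}

#' Continuous glucose error-grid analysis (CG-EGA)
#'
#' Grades each prediction by combining point accuracy (Clarke zones with
#' rate-dependent boundary expansion) and rate accuracy (agreement between
#' the predicted and reference rates of change, estimated by finite
#' differences between consecutive aligned samples; one-sided at the
#' endpoints).  The zones mean: A, no effect on clinical action; B, little
#' or no effect on clinical outcome; C, possible effect on clinical
#' outcome; D, possible significant medical risk.  Results are also
#' stratified by the reference range: hypoglycemia (< 70), euglycemia
#' (70-180) and hyperglycemia (> 180 mg/dL).
#'
#' @param reference,predicted Aligned [glucose_series()] objects (same
#'   timestamps), at least 2 samples.
#' @return List of class `cg_ega_result`: `zone_percent` (named A-D,
#'   summing to 100), `by_range` (zone percentages within each reference
#'   range) and `n_pairs`.
#' @export
cg_ega <- function(reference, predicted) {
  stopifnot(inherits(reference, "glucose_series"),
            inherits(predicted, "glucose_series"))
  if (length(reference) != length(predicted) ||
      any(reference$time != predicted$time)) {
    stop("reference and predicted series must share timestamps")
  }
  n <- length(reference)
  if (n < 2) stop("need at least 2 aligned samples for rates")
  dt <- diff(as.numeric(reference$time)) / 60      # minutes
  rate_of <- function(v) {
    inner <- diff(v) / dt
    c(inner[1], (head(inner, -1) + tail(inner, -1)) / 2, inner[n - 1])
  }
  rr <- rate_of(reference$glucose)
  pr <- rate_of(predicted$glucose)
  zones <- character(n)
  for (i in seq_len(n)) {
    pz <- point_zone(reference$glucose[i], predicted$glucose[i], rr[i])
    rz <- rate_zone(rr[i], pr[i])
    sev <- c(A = 1, B = 2, C = 3, D = 4, E = 5)
    z <- names(sev)[max(sev[pz], sev[rz])]
    zones[i] <- if (z == "E") "D" else z
  }
  range_of <- ifelse(reference$glucose < 70, "hypo",
                     ifelse(reference$glucose > 180, "hyper", "eu"))
  pct <- function(z) {
    100 * vapply(c("A", "B", "C", "D"), function(k) mean(z == k), numeric(1))
  }
  by_range <- lapply(split(zones, factor(range_of,
                                         c("hypo", "eu", "hyper"))), pct)
  structure(list(zone_percent = pct(zones), by_range = by_range,
                 n_pairs = n),
            class = "cg_ega_result")
}

#' @export
print.cg_ega_result <- function(x, ...) {
  cat("<CG-EGA>", x$n_pairs, "pairs; zones:",
      paste(sprintf("%s=%.1f%%", names(x$zone_percent), x$zone_percent),
            collapse = " "), "\n")
  invisible(x)
}

#' Evaluate a prediction run
#'
#' Computes error metrics and CG-EGA for a [sliding_predict()] result,
#' overall and per landmark interval.
#'
#' @param result A `prediction_result` data frame.
#' @return List with `errors`, `cg_ega` and `by_landmark` (error metrics
#'   per landmark).
#' @export
evaluate_predictions <- function(result) {
  stopifnot(inherits(result, "prediction_result"))
  ref <- glucose_series(result$timestamp, result$actual,
                        sampling_minutes = diff(as.numeric(
                          result$timestamp[1:2])) / 60)
  prd <- glucose_series(result$timestamp, pmax(result$predicted, 1),
                        sampling_minutes = ref$sampling_minutes)
  by_lm <- lapply(split(result, result$landmark), function(df) {
    compute_errors(df$predicted, df$actual)
  })
  list(errors = compute_errors(result$predicted, result$actual),
       cg_ega = cg_ega(ref, prd),
       by_landmark = by_lm)
}
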