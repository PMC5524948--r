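#' Construct a validated CGM glucose series
#'
#' A `glucose_series` is the package's universal input: a uniformly sampled
#' (default every 5 minutes) sequence of subcutaneous glucose readings in
#' mg/dL with strictly increasing timestamps.  Sampling gaps larger than
#' 1.5 times the declared interval are flagged, never imputed; downstream
#' analyses must split at gaps.
#'
#' @param timestamps `POSIXct` vector, strictly increasing.
#' @param values Numeric glucose concentrations, mg/dL, all positive.
#' @param sampling_minutes Declared sampling interval in minutes.
#' @return An object of class `glucose_series`: a list with elements
#'   `time`, `glucose`, `sampling_minutes` and `gaps` (a data frame with one
#'   row per flagged gap: index after which the gap occurs, and its length
#'   in minutes).
#' @examples
#' t0 <- as.POSIXct("2023-04-01 08:00:00", tz = "UTC")
#' gs <- glucose_series(t0 + 60 * seq(0, 20, by = 5), c(110, 112, 115, 113, 111))
#' gs
#' @export
glucose_series <- function(timestamps, values, sampling_minutes = 5) {
  if (inherits(timestamps, "character")) {
    timestamps <- as.POSIXct(timestamps, tz = "UTC")
  }
  if (!inherits(timestamps, "POSIXct")) {
    stop("`timestamps` must be POSIXct (or ISO-8601 strings)")
  }
  values <- as.numeric(values)
  if (length(timestamps) != length(values)) {
    stop("`timestamps` and `values` must have equal length")
  }
  if (anyNA(timestamps) || anyNA(values)) {
    stop("missing timestamps or glucose values are not allowed")
  }
  dt <- diff(as.numeric(timestamps)) / 60
  if (any(dt <= 0)) {
    stop("timestamps must be strictly increasing (violation after index ",
         which(dt <= 0)[1], ")")
  }
  if (any(values <= 0)) {
    stop("glucose values must be positive (violation at index ",
         which(values <= 0)[1], ")")
  }
  gap_after <- which(dt > 1.5 * sampling_minutes)
  gaps <- data.frame(after_index = gap_after, minutes = dt[gap_after])
  structure(
    list(time = timestamps, glucose = values,
         sampling_minutes = sampling_minutes, gaps = gaps),
    class = "glucose_series"
  )
}

#' @export
print.glucose_series <- function(x, ...) {
  cat(sprintf("<glucose_series> %d samples @ %g min, %s .. %s\n",
              length(x$glucose), x$sampling_minutes,
              format(x$time[1]), format(x$time[length(x$time)])))
  cat(sprintf("  glucose [mg/dL]: min %.1f / median %.1f / max %.1f; %d gap(s)\n",
              min(x$glucose), median(x$glucose), max(x$glucose), nrow(x$gaps)))
  invisible(x)
}

#' @export
length.glucose_series <- function(x) length(x$glucose)

# Subset by sample index, keeping the class and re-deriving gap flags.
subset_series <- function(series, idx) {
  glucose_series(series$time[idx], series$glucose[idx],
                 series$sampling_minutes)
}

#' Read a CGM trace from CSV
#'
#' Expects two columns, `timestamp` (ISO-8601) and `glucose_mgdl`; a header
#' row is optional.  Rows failing to parse raise an error naming the line.
#'
#' @param path Path to the CSV file.
#' @param sampling_minutes Declared sampling interval in minutes.
#' @return A [glucose_series()].
#' @export
read_cgm_csv <- function(path, sampling_minutes = 5) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("timestamp", first, ignore.case = TRUE)
  df <- read.csv(path, header = has_header, stringsAsFactors = FALSE,
                 col.names = c("timestamp", "glucose_mgdl"))
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  bad <- which(is.na(ts))
  if (length(bad)) {
    stop("unparseable timestamp at data line ", bad[1] + has_header,
         ": '", df$timestamp[bad[1]], "'")
  }
  val <- suppressWarnings(as.numeric(df$glucose_mgdl))
  bad <- which(is.na(val))
  if (length(bad)) {
    stop("unparseable glucose value at data line ", bad[1] + has_header,
         ": '", df$glucose_mgdl[bad[1]], "'")
  }
  glucose_series(ts, val, sampling_minutes)
}

#' Write a CGM trace to CSV
#'
#' Emits the same dialect [read_cgm_csv()] consumes, so read-write-read
#' round trips are exact.
#'
#' @param series A [glucose_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cgm_csv <- function(series, path) {
  stopifnot(inherits(series, "glucose_series"))
  df <- data.frame(
    timestamp = format(series$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    # 17 significant digits guarantee an exact double round trip
    glucose_mgdl = formatC(series$glucose, digits = 17, format = "g")
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# The seven landmark intervals tiling a 24-h day, with half-open [start, end)
# boundaries in minutes after midnight.
landmark_table <- function() {
  data.frame(
    label = c("night", "morning", "late_morning", "noon", "afternoon",
              "early_evening", "evening"),
    start_min = c(0, 6 * 60, 10 * 60, 12.5 * 60, 16 * 60, 18.5 * 60, 21.5 * 60),
    end_min = c(6 * 60, 10 * 60, 12.5 * 60, 16 * 60, 18.5 * 60, 21.5 * 60, 24 * 60),
    stringsAsFactors = FALSE
  )
}

#' Landmark label of each timestamp
#'
#' The day is divided into seven clinically motivated landmark intervals:
#' morning (06:00-10:00), late morning (10:00-12:30), noon (12:30-16:00),
#' afternoon (16:00-18:30), early evening (18:30-21:30), evening
#' (21:30-24:00) and night (00:00-06:00).  Windows are half-open
#' `[start, end)`, so a sample at exactly 10:00 is late morning.
#'
#' @param timestamps `POSIXct` vector.
#' @return Character vector of landmark labels.
#' @export
landmark_of <- function(timestamps) {
  lt <- as.POSIXlt(timestamps)
  mins <- lt$hour * 60 + lt$min + lt$sec / 60
  tab <- landmark_table()
  idx <- findInterval(mins, tab$start_min)
  tab$label[idx]
}

#' Segment a CGM series into landmark windows per calendar day
#'
#' @param series A [glucose_series()].
#' @return A data frame with one row per non-empty (day, landmark) window:
#'   `date`, `landmark`, `start_index`, `end_index`, `n`; every sample of
#'   the input belongs to exactly one row.  The per-window sub-series can
#'   be recovered with `window_series()`.
#' @seealso [landmark_of()]
#' @export
segment_landmarks <- function(series) {
  stopifnot(inherits(series, "glucose_series"))
  lab <- landmark_of(series$time)
  day <- as.Date(format(series$time, "%Y-%m-%d"))
  key <- paste(day, lab)
  # runs of constant (day, landmark) are contiguous because time is sorted
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(
    date = day[starts],
    landmark = lab[starts],
    start_index = starts,
    end_index = ends,
    n = r$lengths,
    stringsAsFactors = FALSE
  )
  attr(out, "series") <- series
  class(out) <- c("landmark_segmentation", class(out))
  out
}

#' Extract the sub-series of one landmark window
#'
#' @param segmentation Result of [segment_landmarks()].
#' @param row Row index into the segmentation table.
#' @return A [glucose_series()] restricted to that window.
#' @export
window_series <- function(segmentation, row) {
  series <- attr(segmentation, "series")
  subset_series(series,
                segmentation$start_index[row]:segmentation$end_index[row])
}

#' Detect hypo- or hyper-glycemic episodes
#'
#' An episode is a maximal run of at least two consecutive readings below
#' 70 mg/dL (hypoglycemia) or above 180 mg/dL (hyperglycemia).  Isolated
#' single qualifying readings are not episodes.
#'
#' @param series A [glucose_series()].
#' @param kind `"hypo"` or `"hyper"`.
#' @return Data frame with columns `kind`, `start_index`, `end_index`,
#'   `extreme_value` (the nadir for hypo, the peak for hyper); zero rows if
#'   no episode.
#' @examples
#' t0 <- as.POSIXct("2023-04-01 03:00:00", tz = "UTC")
#' gs <- glucose_series(t0 + 60 * seq(0, 15, by = 5), c(80, 65, 66, 80))
#' detect_episodes(gs, "hypo")
#' @export
detect_episodes <- function(series, kind = c("hypo", "hyper")) {
  stopifnot(inherits(series, "glucose_series"))
  kind <- match.arg(kind)
  qual <- if (kind == "hypo") series$glucose < 70 else series$glucose > 180
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 2L
  if (!any(keep)) {
    return(data.frame(kind = character(), start_index = integer(),
                      end_index = integer(), extreme_value = numeric()))
  }
  s <- starts[keep]; e <- ends[keep]
  extreme <- mapply(function(a, b) {
    if (kind == "hypo") min(series$glucose[a:b]) else max(series$glucose[a:b])
  }, s, e)
  data.frame(kind = kind, start_index = s, end_index = e,
             extreme_value = extreme)
}
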