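# Heightened-activity windows and prolonged wakefulness.
#
# The n (default 16) continuous hours of highest aggregated activity serve as
# a coarse proxy for a cluster's average waking time; the circular complement
# is prolonged wakefulness, where posting happens at a time of habitual rest.

#' Time of day n hours past t
#'
#' @param t Hour of day in `[0, 24)`.
#' @param n Offset in hours (may be negative).
#' @return `(t + n) mod 24`.
#' @export
hour_shift <- function(t, n) (t + n) %% 24

#' Does time point s fall within n hours past t?
#'
#' Implements the circular case split with strict inequalities: when the
#' window does not wrap midnight, `t < s < t + n`; when it wraps,
#' `s > t` or `s < (t + n) mod 24`. The start point itself is excluded.
#'
#' @param s,t Hours of day in `[0, 24)`.
#' @param n Window length in hours.
#' @return Logical flag.
#' @export
in_window <- function(s, t, n) {
  e <- hour_shift(t, n)
  ifelse(t < e, t < s & s < e, s > t | s < e)
}

#' Heightened-activity window of a cluster
#'
#' Finds the onset g maximizing the circular sum of curve values over the 4n
#' bins whose start falls in `[g, g + n)`; equivalent to an exhaustive scan
#' over all 96 candidate onsets. Ties are broken to the earliest onset at or
#' after 0:00.
#'
#' @param curve Smoothed cluster activity curve (96 values; all finite, not
#'   all zero).
#' @param n Window length in hours (default 16; must be in `(0, 24]`).
#' @return An `activity_window`: list with `onset`, `end`, `n`,
#'   `window_bins` (bin indices inside the window) and `complement`
#'   (the prolonged-wakefulness interval `c(end, onset)`).
#' @export
heightened_onset <- function(curve, n = 16) {
  v <- curve_values(curve)
  if (!all(is.finite(v))) stop("curve must be finite")
  if (all(v == 0)) stop("heightened-activity window undefined for an all-zero curve")
  if (n <= 0 || n > 24) stop("n must be in (0, 24]")
  w <- round(4 * n)
  if (abs(w - 4 * n) > 1e-9) stop("n must be a multiple of 15 minutes")
  ext <- c(v, v)
  sums <- vapply(seq_len(N_BINS), function(b) sum(ext[b:(b + w - 1)]),
                 numeric(1))
  best <- which(sums >= max(sums) - 1e-12)[1]   # earliest onset after 0:00
  onset <- time_grid()[best]
  structure(list(onset = onset, end = hour_shift(onset, n), n = n,
                 window_bins = ((best - 1 + seq_len(w) - 1) %% N_BINS) + 1L,
                 complement = c(hour_shift(onset, n), onset)),
            class = "activity_window")
}

#' @export
print.activity_window <- function(x, ...) {
  cat(sprintf("<activity_window onset=%s end=%s n=%gh>\n",
              format_hour(x$onset), format_hour(x$end), x$n))
  invisible(x)
}

format_hour <- function(h) {
  sprintf("%02d:%02d", floor(h) %% 24, round((h %% 1) * 60))
}

#' Prolonged-wakefulness interval of a window
#'
#' The circular complement `[end, onset)` of the heightened-activity window,
#' `24 - n` hours long.
#'
#' @param window An `activity_window`.
#' @return List with `start`, `end`, `hours` (length) and `bins` (bin
#'   indices; empty when `n = 24`).
#' @export
prolonged_wakefulness <- function(window) {
  stopifnot(inherits(window, "activity_window"))
  hours <- (24 - window$n) %% 24
  bins <- setdiff(seq_len(N_BINS), window$window_bins)
  list(start = window$end, end = window$onset, hours = hours, bins = bins)
}

#' Align a curve by inferred waking time
#'
#' Circularly shifts the curve so that the window onset sits at position 0;
#' the result is indexed by hours since waking. Values are preserved, only
#' rotated, so alignment is a bijection on bins.
#'
#' @param curve 96-bin curve.
#' @param window An `activity_window` (its onset defines the shift).
#' @return Numeric vector of 96 values, position 1 = onset bin.
#' @export
align_by_waking <- function(curve, window) {
  stopifnot(inherits(window, "activity_window"))
  v <- curve_values(curve)
  shift <- bin_index(window$onset) - 1L
  v[((seq_len(N_BINS) - 1 + shift) %% N_BINS) + 1L]
}

#' Locate activity peaks on a smoothed curve
#'
#' Local maxima under circular adjacency (strictly greater than both
#' neighbours), sorted by value; the top k are returned. A constant curve has
#' no peaks.
#'
#' @param curve 96-bin curve.
#' @param k Maximum number of peaks to return (default 2).
#' @return data.frame `time, value` (possibly zero rows), highest first.
#' @export
find_peaks <- function(curve, k = 2) {
  v <- curve_values(curve)
  prev <- v[c(N_BINS, seq_len(N_BINS - 1))]
  nxt <- v[c(seq_len(N_BINS - 1) + 1, 1)]
  is_peak <- v > prev & v > nxt
  idx <- which(is_peak)
  idx <- idx[order(-v[idx])]
  idx <- utils::head(idx, k)
  data.frame(time = time_grid()[idx], value = v[idx])
}
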