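#' The diurnal time grid
#'
#' The day is divided into 96 half-open 15-minute intervals \eqn{[t, t + 1/4)}
#' with `t` in hours. Bin 1 starts at 00:00, bin 96 at 23:45; the grid is
#' circular, so bin 96 precedes bin 1.
#'
#' @return Numeric vector of the 96 bin-start hours (0, 0.25, ..., 23.75).
#' @export
time_grid <- function() {
  seq(0, 23.75, by = 0.25)
}

#' Number of bins in the diurnal grid
#' @keywords internal
N_BINS <- 96L

#' Map an hour-of-day to its 15-minute bin index
#'
#' @param hour Numeric hour of day in `[0, 24)` (fractional hours allowed).
#' @return Integer bin index in `1:96`; the bin whose interval contains `hour`.
#' @export
bin_index <- function(hour) {
  stopifnot(all(is.finite(hour)), all(hour >= 0), all(hour < 24))
  as.integer(floor(hour * 4)) + 1L
}

#' Construct a diurnal curve
#'
#' A diurnal curve is a numeric vector on the 96-bin grid carrying its kind
#' (`"activity"`, `"ratio"` or `"count"`) and whether it is normalized to sum
#' to one. Ratio curves may contain `NA` for bins where the ratio is
#' undefined (empty denominator).
#'
#' @param values Numeric vector of length 96.
#' @param kind One of `"activity"`, `"ratio"`, `"count"`.
#' @param normalized Logical; if `TRUE` and `kind = "activity"`, values must
#'   sum to 1 within `1e-9`.
#' @return A `diurnal_curve` object.
#' @export
diurnal_curve <- function(values, kind = c("activity", "ratio", "count"),
                          normalized = FALSE) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) != N_BINS) {
    stop("a diurnal curve has exactly ", N_BINS, " values, got ", length(values))
  }
  if (kind != "ratio" && anyNA(values)) {
    stop("NA values are only permitted in ratio curves")
  }
  if (kind %in% c("activity", "count") && any(values < 0, na.rm = TRUE)) {
    stop("activity and count curves must be non-negative")
  }
  if (normalized && kind == "activity" &&
      abs(sum(values) - 1) > 1e-9) {
    stop("normalized activity curve must sum to 1 (got ", sum(values), ")")
  }
  structure(values, class = "diurnal_curve", kind = kind,
            normalized = normalized)
}

#' @export
print.diurnal_curve <- function(x, ...) {
  cat(sprintf("<diurnal_curve kind=%s%s sum=%.6g range=[%.4g, %.4g]>\n",
              attr(x, "kind"),
              if (isTRUE(attr(x, "normalized"))) " normalized" else "",
              sum(x, na.rm = TRUE), min(x, na.rm = TRUE), max(x, na.rm = TRUE)))
  invisible(x)
}

#' Extract the 96 numeric values of a curve
#' @param x A `diurnal_curve` or numeric vector of length 96.
#' @return Plain numeric vector of length 96.
#' @export
curve_values <- function(x) {
  v <- as.numeric(unclass(x))
  if (length(v) != N_BINS) stop("expected a 96-bin curve")
  v
}

#' Circular Gaussian smoothing of a diurnal curve
#'
#' Rolling average over a `window_bins`-bin Gaussian window with standard
#' deviation `sigma_bins` (both in 15-minute bins), looping the values around
#' midnight. Weights are normalized so a constant curve is a fixed point and
#' the total mass of the curve is preserved. The default `window_bins = 6`,
#' `sigma_bins = 3` corresponds to a 90-minute window. Weight `i` (0-based,
#' `i = 0, ..., w-1`) is `exp(-((i - (w-1)/2)^2) / (2 sigma^2))`, applied at
#' offset `i - floor((w-1)/2)`; for an even window the nominal centre falls
#' between samples, so the window extends one bin further to the right, as in
#' a centred rolling window over an even number of points.
#'
#' `NA` values (undefined ratio bins) are handled by renormalizing the kernel
#' over the defined neighbours; a bin whose whole window is `NA` stays `NA`.
#'
#' @param curve A `diurnal_curve` or numeric vector of length 96.
#' @param window_bins Window length in bins (default 6 = 90 minutes).
#' @param sigma_bins Gaussian standard deviation in bins (default 3).
#' @return Smoothed curve of the same class/kind as the input.
#' @export
smooth_circular <- function(curve, window_bins = 6L, sigma_bins = 3) {
  if (!is.numeric(sigma_bins) || length(sigma_bins) != 1 || sigma_bins <= 0) {
    stop("sigma_bins must be a positive number")
  }
  if (window_bins < 1) stop("window_bins must be >= 1")
  v <- curve_values(curve)
  w <- as.integer(window_bins)
  centre <- (w - 1) / 2
  weights <- exp(-((seq_len(w) - 1 - centre)^2) / (2 * sigma_bins^2))
  offsets <- seq_len(w) - 1 - floor(centre)
  out <- numeric(N_BINS)
  if (!anyNA(v)) {
    weights <- weights / sum(weights)
    for (b in seq_len(N_BINS)) {
      idx <- ((b - 1 + offsets) %% N_BINS) + 1L
      out[b] <- sum(weights * v[idx])
    }
  } else {
    for (b in seq_len(N_BINS)) {
      idx <- ((b - 1 + offsets) %% N_BINS) + 1L
      vals <- v[idx]
      ok <- !is.na(vals)
      out[b] <- if (any(ok)) sum(weights[ok] * vals[ok]) / sum(weights[ok]) else NA_real_
    }
  }
  if (inherits(curve, "diurnal_curve")) {
    structure(out, class = "diurnal_curve", kind = attr(curve, "kind"),
              normalized = attr(curve, "normalized"))
  } else {
    out
  }
}
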