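# Content-type ratio statistics under the Harm-Score scheme.
#
# Ratios exclude the "Other" category (unknown reliability) from the
# denominator; the potentially disinformative ratio r^H is the share of a
# user's classified posts whose category has Harm Score >= 7. Cluster ratios
# average the member users' ratios with equal weight; bins where a user has
# no classified posts are undefined for that user and are masked from the
# cluster mean rather than zero-filled.

#' Per-bin content-type ratio curve of one user
#'
#' Numerator: the user's posts in `target` categories per bin; denominator:
#' posts in all classifiable categories (excluding "Other"). Bins with an
#' empty denominator are `NA`.
#'
#' @param profile A `user_profile`.
#' @param target Category set (subset of [classifiable_categories()]);
#'   default the potentially disinformative set.
#' @return A `diurnal_curve` of kind `"ratio"` (values in `[0,1]` or `NA`).
#' @export
user_ratio_curve <- function(profile, target = disinformative_categories()) {
  bad <- setdiff(target, classifiable_categories())
  if (length(bad)) {
    stop("target categories must be classifiable (not 'Other'): ",
         paste(bad, collapse = ", "))
  }
  num <- profile_category_counts(profile, target)
  den <- profile_category_counts(profile, classifiable_categories())
  diurnal_curve(ifelse(den > 0, num / den, NA_real_), kind = "ratio")
}

#' Overall (whole-day) content-type ratio of one user
#'
#' @inheritParams user_ratio_curve
#' @return Scalar ratio, or `NA` when the user has no classified posts.
#' @export
user_overall_ratio <- function(profile, target = disinformative_categories()) {
  num <- sum(profile_category_counts(profile, target))
  den <- sum(profile_category_counts(profile, classifiable_categories()))
  if (den > 0) num / den else NA_real_
}

#' Per-bin cluster ratio: unweighted mean of member user ratios
#'
#' Members whose ratio is undefined at a bin are excluded from that bin's
#' mean; a bin where no member is defined is `NA`.
#'
#' @param ratio_curves Named list of user ratio curves.
#' @param members Member user ids (nonempty).
#' @return A `diurnal_curve` of kind `"ratio"`.
#' @export
cluster_ratio_curve <- function(ratio_curves, members) {
  if (!length(members)) stop("cannot average an empty cluster")
  mat <- vapply(members, function(u) curve_values(ratio_curves[[u]]),
                numeric(N_BINS))
  vals <- rowMeans(mat, na.rm = TRUE)
  vals[!is.finite(vals)] <- NA_real_
  diurnal_curve(vals, kind = "ratio")
}

#' Circular linear interpolation over undefined bins
#'
#' @param v Numeric vector with `NA` runs (not all-NA).
#' @return Vector with `NA`s replaced by linear interpolation between the
#'   circular neighbours.
#' @export
circular_interpolate <- function(v) {
  n <- length(v)
  if (!anyNA(v)) return(v)
  ok <- which(!is.na(v))
  if (!length(ok)) stop("cannot interpolate an all-undefined curve")
  out <- v
  for (i in which(is.na(v))) {
    prev <- ok[which.min(((i - ok) %% n))]      # nearest defined before i
    dist_prev <- (i - prev) %% n
    nxt <- ok[which.min(((ok - i) %% n))]       # nearest defined after i
    dist_next <- (nxt - i) %% n
    w <- dist_prev / (dist_prev + dist_next)
    out[i] <- (1 - w) * v[prev] + w * v[nxt]
  }
  out
}

#' Smoothed cluster ratio curve (coarse and harmonically smoothed variants)
#'
#' Pipeline: per-user Gaussian smoothing of the ratio curves (window 6 bins,
#' sigma 3, NA-aware) -> unweighted cluster mean -> circular interpolation of
#' any residual undefined bins (flagged) -> Fourier truncation keeping the m
#' largest harmonics, with m chosen by the multi-metric elbow rule. The
#' coarse variant is the plain cluster mean of the unsmoothed user ratio
#' curves.
#'
#' @param profiles Named list of `user_profile`s.
#' @param members Member user ids.
#' @param target Category set (default disinformative).
#' @param window_bins,sigma_bins Gaussian pre-smoothing parameters.
#' @param m_range Candidate harmonic counts for [select_m()].
#' @return List: `coarse` (ratio curve with possible NAs), `smooth` (the
#'   96-bin smoothed ratio set R), `m`, `votes`, `interpolated_bins`.
#' @export
smooth_ratio <- function(profiles, members, target = disinformative_categories(),
                         window_bins = 6L, sigma_bins = 3, m_range = 1:4) {
  if (!length(members)) stop("cannot smooth an empty cluster")
  raw <- lapply(members, function(u) user_ratio_curve(profiles[[u]], target))
  names(raw) <- members
  defined <- vapply(raw, function(r) any(!is.na(curve_values(r))), logical(1))
  if (!any(defined)) stop("all member ratio curves are undefined")
  raw <- raw[defined]
  coarse <- cluster_ratio_curve(raw, names(raw))
  smoothed <- lapply(raw, smooth_circular, window_bins = window_bins,
                     sigma_bins = sigma_bins)
  mean_curve <- cluster_ratio_curve(smoothed, names(raw))
  vals <- curve_values(mean_curve)
  interp <- which(is.na(vals))
  if (length(interp) == N_BINS) stop("all bins undefined after smoothing")
  vals <- circular_interpolate(vals)
  sel <- select_m(vals, m_range = m_range)
  R <- reconstruct_top_m(dft(vals), sel$m)
  list(coarse = coarse, smooth = R, m = sel$m, votes = sel$votes,
       interpolated_bins = interp)
}

#' Times of increased susceptibility: bins above the third quartile
#'
#' Q3 is the 0.75 quantile (linear interpolation between order statistics)
#' of the 96 smoothed ratio values; returned are the bins whose value
#' strictly exceeds it (at most 24 for all-distinct values).
#'
#' @param R Smoothed ratio curve (96 finite values).
#' @return Integer bin indices, with bin-start hours as the `"hours"`
#'   attribute.
#' @export
susceptibility_times <- function(R) {
  v <- curve_values(R)
  if (anyNA(v)) stop("susceptibility requires R defined on all bins")
  q3 <- stats::quantile(v, 0.75, type = 7, names = FALSE)
  bins <- which(v > q3)
  attr(bins, "hours") <- time_grid()[bins]
  bins
}

#' Correlation between users' post volume and their disinformative ratio
#'
#' Spearman rank correlation between total posts per user and the user's
#' overall potentially disinformative ratio.
#'
#' @param profiles Named list of `user_profile`s (>= 3 with defined ratios).
#' @param target Category set (default disinformative).
#' @return A [stat_result()] with statistic `rho`.
#' @export
posts_vs_ratio_correlation <- function(profiles,
                                       target = disinformative_categories()) {
  totals <- vapply(profiles, function(p) p$total_posts, numeric(1))
  ratios <- vapply(profiles, user_overall_ratio, numeric(1), target = target)
  ok <- !is.na(ratios)
  if (sum(ok) < 3) stop("need at least 3 users with a defined ratio")
  spearman(totals[ok], ratios[ok])
}

#' Correlation between diurnal activity and diurnal ratio
#'
#' Spearman rank correlation over the 96 paired bins of an activity curve
#' and a ratio curve (coarse or smoothed variant); undefined bins are
#' dropped pairwise.
#'
#' @param activity 96-bin activity curve.
#' @param ratio 96-bin ratio curve (NAs allowed).
#' @return A [stat_result()]; `n1` reports the number of bins used.
#' @export
activity_ratio_correlation <- function(activity, ratio) {
  a <- curve_values(activity); r <- curve_values(ratio)
  spearman(a, r)
}
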