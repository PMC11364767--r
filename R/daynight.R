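# Day/night partitions and comparisons.
#
# Three definitions of "day": by clock (fixed borders from the annual-average
# sunrise/sunset rounded to the quarter hour), by daylight (monthly geometric
# sunrise/sunset), and by inferred waking (the heightened-activity window).
# A safety margin of s hours around each border is excluded before comparing
# ratio distributions between day and night.

deg2rad <- function(d) d * pi / 180

#' Default coordinates for users without a location
#'
#' The geographical centre of the Italian peninsula (Rieti, the historical
#' *umbilicus Italiae*), used wherever posts carry no usable coordinates.
#'
#' @return Named vector `c(lat, lon)` in degrees.
#' @export
italy_centroid <- function() c(lat = 42.40, lon = 12.86)

#' Geometric sunrise and sunset in local civil time
#'
#' NOAA-style geometric computation at solar altitude -0.833 deg (standard
#' refraction + solar disc correction), converted from UTC to the civil time
#' zone in force on the date (CET/CEST for the default zone).
#'
#' @param lat,lon Latitude/longitude in degrees (`|lat| < 66`; polar
#'   day/night is not supported).
#' @param date A `Date`.
#' @param tz Civil time zone (default "Europe/Rome").
#' @return Named numeric vector `c(sunrise, sunset)` in fractional local
#'   civil hours.
#' @export
solar_times <- function(lat, lon, date, tz = "Europe/Rome") {
  if (abs(lat) >= 66) stop("polar latitudes unsupported (|lat| must be < 66)")
  date <- as.Date(date)
  doy <- as.integer(format(date, "%j"))
  gamma <- 2 * pi / 365 * (doy - 1 + 0.5)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(gamma) -
                      0.032077 * sin(gamma) - 0.014615 * cos(2 * gamma) -
                      0.040849 * sin(2 * gamma))
  decl <- 0.006918 - 0.399912 * cos(gamma) + 0.070257 * sin(gamma) -
    0.006758 * cos(2 * gamma) + 0.000907 * sin(2 * gamma) -
    0.002697 * cos(3 * gamma) + 0.00148 * sin(3 * gamma)
  zenith <- deg2rad(90.833)
  cos_ha <- (cos(zenith) / (cos(deg2rad(lat)) * cos(decl))) -
    tan(deg2rad(lat)) * tan(decl)
  if (abs(cos_ha) > 1) stop("sun does not rise/set at this location and date")
  ha <- acos(cos_ha) * 180 / pi
  sunrise_utc <- 720 - 4 * (lon + ha) - eqtime   # minutes
  sunset_utc <- 720 - 4 * (lon - ha) - eqtime
  offset <- utc_offset_hours(date, tz)
  c(sunrise = (sunrise_utc / 60 + offset) %% 24,
    sunset = (sunset_utc / 60 + offset) %% 24)
}

utc_offset_hours <- function(date, tz) {
  noon <- as.POSIXct(paste(format(as.Date(date)), "12:00:00"), tz = tz)
  z <- format(noon, "%z")
  sign <- if (substr(z, 1, 1) == "-") -1 else 1
  sign * (as.numeric(substr(z, 2, 3)) + as.numeric(substr(z, 4, 5)) / 60)
}

#' Clock-day borders: annual-average sun times rounded to the quarter hour
#'
#' Averages the geometric sunrise (resp. sunset) in local civil time over
#' the first day of each of the 12 months and rounds to the nearest 15
#' minutes. At the Italian centroid this yields 6:30 and 18:45.
#'
#' @param lat,lon Location (default [italy_centroid()], 42.40 N, 12.86 E).
#' @param year Calendar year (default 2020).
#' @param tz Civil time zone.
#' @return Named vector `c(day_start, day_end)` in hours.
#' @export
clock_day_borders <- function(lat = italy_centroid()[["lat"]],
                              lon = italy_centroid()[["lon"]], year = 2020,
                              tz = "Europe/Rome") {
  firsts <- as.Date(sprintf("%d-%02d-01", year, 1:12))
  st <- vapply(firsts, function(d) solar_times(lat, lon, d, tz), numeric(2))
  round_quarter <- function(h) round(h * 4) / 4
  c(day_start = round_quarter(mean(st["sunrise", ])),
    day_end = round_quarter(mean(st["sunset", ])))
}

label_bins <- function(day_start, day_end, s) {
  day_len <- (day_end - day_start) %% 24
  night_len <- 24 - day_len
  if (2 * s >= day_len || 2 * s >= night_len) {
    stop("safety margin 2s leaves an empty day or night period")
  }
  mid <- time_grid() + 0.125
  lab <- rep("excluded", N_BINS)
  lab[in_circular_interval(mid, (day_start + s) %% 24, (day_end - s) %% 24)] <- "day"
  lab[in_circular_interval(mid, (day_end + s) %% 24, (day_start - s) %% 24)] <- "night"
  lab
}

#' Day/night partition of the diurnal grid
#'
#' Bins are labelled `day`, `night` or `excluded` (within the safety margin
#' `s` of a border; a bin belongs to the side containing its midpoint).
#'
#' * `clock`: fixed borders, `day = [start+s, end-s)`,
#'   `night = [end+s, start-s)` circularly.
#' * `daylight`: the same construction per month, with the month's
#'   first-day geometric sunrise/sunset at `lat`/`lon`; labels form a
#'   96 x 12 matrix.
#' * `waking`: borders from a heightened-activity window,
#'   `day = [onset+s, onset+n-s)`, `night = [onset+n+s, onset-s)`.
#'
#' @param definition `"clock"`, `"daylight"` or `"waking"`.
#' @param s Safety margin in hours (default 1).
#' @param borders For `clock`: `c(day_start, day_end)` hours (default the
#'   Italian clock-day 6:30/18:45).
#' @param lat,lon,year,tz For `daylight`.
#' @param window For `waking`: an `activity_window`.
#' @return A `day_night_partition`: list with `definition`, `s`, `labels`
#'   (length-96 vector, or 96 x 12 matrix for daylight) and `borders`.
#' @export
day_night_partition <- function(definition = c("clock", "daylight", "waking"),
                                s = 1, borders = c(6.5, 18.75),
                                lat = italy_centroid()[["lat"]],
                                lon = italy_centroid()[["lon"]], year = 2020,
                                tz = "Europe/Rome", window = NULL) {
  definition <- match.arg(definition)
  if (s < 0) stop("safety margin must be >= 0")
  out <- switch(definition,
    clock = list(labels = label_bins(borders[1], borders[2], s),
                 borders = c(day_start = borders[1], day_end = borders[2])),
    daylight = {
      firsts <- as.Date(sprintf("%d-%02d-01", year, 1:12))
      st <- vapply(firsts, function(d) solar_times(lat, lon, d, tz),
                   numeric(2))
      labs <- vapply(1:12, function(m) {
        label_bins(st["sunrise", m], st["sunset", m], s)
      }, character(N_BINS))
      colnames(labs) <- month.abb
      list(labels = labs, borders = st)
    },
    waking = {
      if (!inherits(window, "activity_window")) {
        stop("waking partition needs an activity_window")
      }
      list(labels = label_bins(window$onset, window$end, s),
           borders = c(onset = window$onset, end = window$end))
    })
  structure(c(list(definition = definition, s = s), out),
            class = "day_night_partition")
}

partition_samples <- function(values, partition) {
  lab <- partition$labels
  if (is.matrix(lab)) {
    values <- as.matrix(values)
    if (!all(dim(values) == dim(lab))) {
      stop("daylight partition needs a 96 x 12 value matrix (bins x months)")
    }
  } else {
    values <- curve_values(values)
  }
  day <- values[lab == "day"]; night <- values[lab == "night"]
  list(day = day[!is.na(day)], night = night[!is.na(night)])
}

#' Mann-Whitney comparison of day vs night ratio distributions
#'
#' Compares the per-bin ratio values labelled `day` (sample x) with those
#' labelled `night` (sample y) after excluding the safety margin. With
#' `alternative = "less"` the test asks whether the day distribution is
#' stochastically smaller; the result's note reports which side is smaller
#' at the 0.05 level.
#'
#' @param values 96-bin ratio values (vector), or bins x months matrix for
#'   the daylight partition.
#' @param partition A `day_night_partition`.
#' @param alternative `"two"`, `"less"` or `"greater"` (for the day side).
#' @return A [stat_result()].
#' @export
day_night_test <- function(values, partition, alternative = "two") {
  sm <- partition_samples(values, partition)
  if (!length(sm$day) || !length(sm$night)) {
    stop("a side is empty after margin exclusion")
  }
  res <- mann_whitney(sm$day, sm$night, alternative = alternative)
  smaller <- if (res$p < 0.05) {
    if (res$statistic[["U"]] < res$n1 * res$n2 / 2) "day" else "night"
  } else "none"
  res$note <- paste0(if (!is.null(res$note)) paste0(res$note, "; "),
                     "smaller side: ", smaller)
  res
}

#' One-sided comparison of two clusters' diurnal ratio distributions
#'
#' Tests whether cluster a's 96-bin ratio distribution is smaller than
#' cluster b's (Mann-Whitney). Bins undefined in either curve are dropped
#' pairwise; the count of dropped bins is reported in the note.
#'
#' @param curve_a,curve_b 96-bin ratio curves (coarse or smoothed).
#' @param alternative Default `"less"` (a below b).
#' @return A [stat_result()].
#' @export
cluster_ratio_comparison <- function(curve_a, curve_b, alternative = "less") {
  a <- curve_values(curve_a); b <- curve_values(curve_b)
  ok <- !is.na(a) & !is.na(b)
  res <- mann_whitney(a[ok], b[ok], alternative = alternative)
  res$note <- paste0(if (!is.null(res$note)) paste0(res$note, "; "),
                     "bins dropped: ", sum(!ok))
  res
}

#' Lockdown vs outside-lockdown posting comparison per cluster
#'
#' For each cluster: percent change, from the period outside the lockdown
#' interval to the lockdown period, in (i) posts per day and user, (ii)
#' potentially disinformative posts per day and user, and (iii) the mean
#' per-user disinformative ratio. Changes are `(lockdown - outside) /
#' outside * 100`; an undefined change (zero outside rate) is `NA`. A
#' Pearson chi-squared on the cluster x period disinformative post counts
#' accompanies the table.
#'
#' @param posts Post table.
#' @param assignments Named character vector user -> cluster name.
#' @param lockdown `c(start, end)` Dates (inclusive).
#' @param date_span `c(start, end)` Dates of the full span (default the
#'   observed range).
#' @return List with `table` (long data.frame) and `chisq` (a
#'   [stat_result()], `NULL` if any cell is empty).
#' @export
lockdown_compare <- function(posts, assignments, lockdown,
                             date_span = range(as.Date(format(
                               posts$timestamp, "%Y-%m-%d")))) {
  lockdown <- as.Date(lockdown); date_span <- as.Date(date_span)
  if (lockdown[1] < date_span[1] || lockdown[2] > date_span[2]) {
    stop("lockdown interval must lie within the date span")
  }
  dates <- as.Date(format(posts$timestamp, "%Y-%m-%d"))
  in_ld <- dates >= lockdown[1] & dates <= lockdown[2]
  days_ld <- as.numeric(lockdown[2] - lockdown[1]) + 1
  days_out <- as.numeric(date_span[2] - date_span[1]) + 1 - days_ld
  if (days_out <= 0) stop("no days outside the lockdown period")
  cl <- assignments[posts$user_id]
  disinfo <- posts$category %in% disinformative_categories()
  classif <- posts$category %in% classifiable_categories()
  clusters <- sort(unique(assignments))
  rows <- list()
  counts <- matrix(0, length(clusters), 2,
                   dimnames = list(clusters, c("outside", "lockdown")))
  for (cname in clusters) {
    members <- names(assignments)[assignments == cname]
    n_users <- length(members)
    sel <- cl == cname
    rate <- function(idx, ndays) sum(idx) / (ndays * n_users)
    per_user_ratio <- function(period_idx) {
      r <- vapply(members, function(u) {
        m <- sel & posts$user_id == u & period_idx
        den <- sum(m & classif)
        if (den > 0) sum(m & disinfo) / den else NA_real_
      }, numeric(1))
      mean(r, na.rm = TRUE)
    }
    metrics <- rbind(
      data.frame(metric = "posts_per_day_user",
                 outside = rate(sel & !in_ld, days_out),
                 lockdown = rate(sel & in_ld, days_ld)),
      data.frame(metric = "disinfo_posts_per_day_user",
                 outside = rate(sel & !in_ld & disinfo, days_out),
                 lockdown = rate(sel & in_ld & disinfo, days_ld)),
      data.frame(metric = "mean_user_disinfo_ratio",
                 outside = per_user_ratio(!in_ld),
                 lockdown = per_user_ratio(in_ld))
    )
    metrics$cluster <- cname
    metrics$pct_change <- ifelse(metrics$outside > 0,
                                 (metrics$lockdown - metrics$outside) /
                                   metrics$outside * 100, NA_real_)
    rows[[cname]] <- metrics
    counts[cname, ] <- c(sum(sel & !in_ld & disinfo), sum(sel & in_ld & disinfo))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  chisq <- if (nrow(counts) >= 2 && all(rowSums(counts) > 0) &&
                 all(colSums(counts) > 0)) {
    chi_square(counts)
  } else NULL
  list(table = tab[, c("cluster", "metric", "outside", "lockdown",
                       "pct_change")],
       counts = counts, chisq = chisq)
}
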