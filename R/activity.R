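# Per-user and per-cluster diurnal activity curves.
#
# A user's activity level in a 15-minute interval is the proportion of their
# posts falling in that interval; cluster curves are unweighted means of the
# member curves, so every user carries the same weight regardless of volume.

assert_tz_aware <- function(ts) {
  if (!inherits(ts, "POSIXct")) {
    stop("timestamps must be timezone-aware POSIXct ",
         "(parse with an explicit time zone before binning)")
  }
  tzone <- attr(ts, "tzone")
  if (is.null(tzone) || !nzchar(tzone[1])) {
    stop("timestamps carry no time zone; set one (e.g. 'Europe/Rome') ",
         "so posts are binned in local civil time")
  }
  invisible(ts)
}

local_hour <- function(ts) {
  assert_tz_aware(ts)
  lt <- as.POSIXlt(ts)
  lt$hour + lt$min / 60 + lt$sec / 3600
}

#' Bin posts into per-user 96 x category count matrices
#'
#' Timestamps are interpreted in their civil time zone; a post at local time
#' `h` lands in the bin starting at `floor(4 h) / 4` hours. Every post lands
#' in exactly one bin.
#'
#' @param posts Post table with columns `user_id`, `timestamp` (tz-aware
#'   POSIXct) and `category`.
#' @return Named list (by user) of 96 x 8 integer count matrices, with the
#'   content categories as columns.
#' @export
bin_posts <- function(posts) {
  cats <- content_categories()
  if (nrow(posts)) {
    bad <- !posts$category %in% cats
    if (any(bad)) stop("unknown content category: ",
                       paste(unique(posts$category[bad]), collapse = ", "))
  }
  h <- if (nrow(posts)) local_hour(posts$timestamp) else numeric()
  bins <- factor(floor(h * 4) + 1L, levels = 1:N_BINS)
  tab <- table(user = posts$user_id,
               bin = bins,
               category = factor(posts$category, levels = cats))
  users <- dimnames(tab)$user
  out <- lapply(users, function(u) {
    m <- matrix(as.integer(tab[u, , ]), nrow = N_BINS,
                dimnames = list(NULL, cats))
    m
  })
  names(out) <- users
  out
}

#' Build user profiles from a post table
#'
#' @param posts Post table (see [bin_posts()]).
#' @return Named list of `user_profile` objects, each carrying `user_id`,
#'   `total_posts` and the 96 x 8 bin-by-category `counts` matrix.
#' @export
user_profiles <- function(posts) {
  counts <- bin_posts(posts)
  out <- lapply(names(counts), function(u) {
    structure(list(user_id = u, counts = counts[[u]],
                   total_posts = sum(counts[[u]])),
              class = "user_profile")
  })
  names(out) <- names(counts)
  out
}

profile_category_counts <- function(profile, categories = NULL) {
  m <- profile$counts
  if (is.null(categories)) return(rowSums(m))
  missing <- setdiff(categories, colnames(m))
  if (length(missing)) stop("unknown content category: ",
                            paste(missing, collapse = ", "))
  rowSums(m[, categories, drop = FALSE])
}

#' Diurnal activity curve of one user
#'
#' The proportion of the user's posts (optionally restricted to a category
#' set, e.g. the potentially disinformative one) falling in each 15-minute
#' bin. The curve sums to 1.
#'
#' @param profile A `user_profile` from [user_profiles()].
#' @param categories Optional character vector restricting the counted
#'   categories; `NULL` means all content.
#' @return A normalized `diurnal_curve`.
#' @export
user_activity <- function(profile, categories = NULL) {
  counts <- profile_category_counts(profile, categories)
  total <- sum(counts)
  if (total == 0) {
    stop("activity curve undefined for user '", profile$user_id,
         "': no posts", if (!is.null(categories)) " in the requested categories")
  }
  diurnal_curve(counts / total, kind = "activity", normalized = TRUE)
}

#' Mean diurnal activity of a cluster
#'
#' Unweighted mean of the member users' normalized activity curves: each
#' user's activity level carries the same weight, so the cluster curve also
#' sums to 1.
#'
#' @param curves Named list of normalized `diurnal_curve`s (one per user).
#' @param members Character vector of member user ids.
#' @return A normalized `diurnal_curve`.
#' @export
cluster_activity <- function(curves, members) {
  if (!length(members)) stop("cannot average an empty cluster")
  missing <- setdiff(members, names(curves))
  if (length(missing)) stop("no activity curve for user(s): ",
                            paste(missing, collapse = ", "))
  mat <- vapply(members, function(u) curve_values(curves[[u]]),
                numeric(N_BINS))
  diurnal_curve(rowMeans(mat), kind = "activity", normalized = TRUE)
}

#' Potentially disinformative diurnal activity of a cluster
#'
#' Each member's curve is normalized over the disinformative categories only
#' (Political, Fake and Hoax, Conspiracy and Junk Science); members with no
#' disinformative posts are excluded, since their curve is undefined. The
#' unweighted mean over the remaining members is then smoothed with a
#' 90-minute circular Gaussian window (default `sigma_bins = 6`, as used for
#' this signal; set `smooth = FALSE` for the raw mean).
#'
#' @param profiles Named list of `user_profile`s.
#' @param members Member user ids.
#' @param smooth Apply circular Gaussian smoothing (default `TRUE`).
#' @param window_bins,sigma_bins Smoothing parameters in bins.
#' @return A normalized `diurnal_curve` (smoothing preserves the unit sum).
#' @export
disinformative_activity <- function(profiles, members, smooth = TRUE,
                                    window_bins = 6L, sigma_bins = 6) {
  if (!length(members)) stop("cannot average an empty cluster")
  fH <- disinformative_categories()
  has_disinfo <- vapply(members, function(u) {
    sum(profile_category_counts(profiles[[u]], fH)) > 0
  }, logical(1))
  if (!any(has_disinfo)) {
    stop("cluster has no potentially disinformative posts; ",
         "its disinformative activity curve is undefined")
  }
  curves <- lapply(members[has_disinfo],
                   function(u) user_activity(profiles[[u]], fH))
  names(curves) <- members[has_disinfo]
  out <- cluster_activity(curves, members[has_disinfo])
  if (smooth) out <- smooth_circular(out, window_bins, sigma_bins)
  out
}

#' Write / read a diurnal curve as CSV
#'
#' Two columns: `bin_start_hour,value`, 96 rows.
#' @param curve A `diurnal_curve` or numeric vector of length 96.
#' @param path File path.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(data.frame(bin_start_hour = time_grid(),
                              value = curve_values(curve)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(identical(names(df), c("bin_start_hour", "value")),
            nrow(df) == N_BINS)
  df$value
}
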