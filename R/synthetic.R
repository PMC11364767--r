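# Synthetic post streams with planted diurnal-archetype structure.
#
# The generator emulates the statistical shape the analysis assumes: users
# partitioned into morning / intermediate / evening / infrequent archetypes,
# bimodal time-of-day intensities (mixtures of wrapped normals), heavy-tailed
# per-user post counts with the infrequent archetype below the 240-post
# threshold, 8-category content draws with archetype-dependent and
# night-elevated disinformative probabilities, and a multi-month date span
# containing a lockdown sub-interval with an elevated posting rate.

#' Membership of an hour in a circular interval [start, end)
#' @keywords internal
in_circular_interval <- function(hour, start, end) {
  if (isTRUE(all.equal(start, end))) return(rep(FALSE, length(hour)))
  if (start < end) hour >= start & hour < end else hour >= start | hour < end
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic post-stream generator
#'
#' Defaults describe the study conditions the generator emulates: a span from
#' 2020-01-22 to 2022-08-01 containing Italy's first lockdown (2020-03-09 to
#' 2020-05-18) with an elevated posting rate, four archetypes with bimodal
#' diurnal peaks, log-normal post counts (the infrequent archetype truncated
#' below the 240-post threshold), and a night-time elevation of the
#' disinformative category probabilities.
#'
#' @param n_users Number of users to generate.
#' @param cluster_proportions Named simplex over the four archetypes
#'   (morning, intermediate, evening, infrequent); must sum to 1.
#' @param peaks Named list (one entry per archetype) of data.frames with
#'   columns `time` (peak centre, hours in `[0,24)`), `sd` (wrapped-normal
#'   spread in hours) and `weight` (mixture weight, summing to 1).
#' @param posts_per_user Named list per archetype with `meanlog`, `sdlog`,
#'   `min`, `max` of a truncated log-normal post-count law.
#' @param category_probs Matrix (archetype x 8 categories) of content-type
#'   simplices; rows must sum to 1 and columns follow [content_categories()].
#' @param night_disinfo_boost Multiplier (> 0) applied to the disinformative
#'   category probabilities for posts falling inside `night_interval`
#'   (probabilities renormalized afterwards). 1 = no elevation.
#' @param night_interval Circular `[start, end)` interval in hours defining
#'   night for the boost.
#' @param date_span Date vector `c(start, end)` (inclusive).
#' @param lockdown `NULL`, or list with `start`, `end` (Dates inside
#'   `date_span`) and `rate_multiplier` (>= 0) scaling daily posting rates.
#' @param infrequent_threshold Post-count threshold below which a user is an
#'   infrequent poster (default 240).
#' @param tz Time zone of the generated civil timestamps.
#' @param seed Integer seed; the generator is deterministic given the config.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_users = 400,
                             cluster_proportions = c(morning = 0.25,
                                                     intermediate = 0.25,
                                                     evening = 0.15,
                                                     infrequent = 0.35),
                             peaks = default_peaks(),
                             posts_per_user = default_post_counts(),
                             category_probs = default_category_probs(),
                             night_disinfo_boost = 1.5,
                             night_interval = c(22.5, 6.5),
                             date_span = as.Date(c("2020-01-22", "2022-08-01")),
                             lockdown = list(start = as.Date("2020-03-09"),
                                             end = as.Date("2020-05-18"),
                                             rate_multiplier = 1.8),
                             infrequent_threshold = 240,
                             tz = "Europe/Rome",
                             seed = 1L) {
  cfg <- list(n_users = n_users, cluster_proportions = cluster_proportions,
              peaks = peaks, posts_per_user = posts_per_user,
              category_probs = category_probs,
              night_disinfo_boost = night_disinfo_boost,
              night_interval = night_interval,
              date_span = as.Date(date_span), lockdown = lockdown,
              infrequent_threshold = infrequent_threshold, tz = tz,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

archetype_names <- function() c("morning", "intermediate", "evening", "infrequent")

#' @rdname synthetic_config
#' @export
default_peaks <- function() {
  list(
    morning      = data.frame(time = c(9.5, 16.0),  sd = c(1.5, 2.0),
                              weight = c(0.60, 0.40)),
    intermediate = data.frame(time = c(12.75, 21.25), sd = c(1.75, 1.75),
                              weight = c(0.60, 0.40)),
    evening      = data.frame(time = c(15.0, 23.25), sd = c(2.5, 1.5),
                              weight = c(0.35, 0.65)),
    infrequent   = data.frame(time = 14.0, sd = 8.0, weight = 1.0)
  )
}

#' @rdname synthetic_config
#' @export
default_post_counts <- function(threshold = 240) {
  frequent <- list(meanlog = log(500), sdlog = 0.6, min = threshold, max = 5000)
  list(morning = frequent, intermediate = frequent, evening = frequent,
       infrequent = list(meanlog = log(60), sdlog = 1.0, min = 1,
                         max = threshold - 1))
}

#' @rdname synthetic_config
#' @export
default_category_probs <- function() {
  cats <- content_categories()
  m <- rbind(
    morning      = c(0.05, 0.56, 0.04, 0.06, 0.14, 0.08, 0.04, 0.03),
    intermediate = c(0.05, 0.53, 0.04, 0.06, 0.14, 0.08, 0.04, 0.06),
    evening      = c(0.03, 0.44, 0.04, 0.06, 0.13, 0.15, 0.08, 0.07),
    infrequent   = c(0.07, 0.60, 0.04, 0.06, 0.13, 0.05, 0.03, 0.02)
  )
  colnames(m) <- cats
  m
}

validate_synthetic_config <- function(cfg) {
  if (!is.numeric(cfg$n_users) || length(cfg$n_users) != 1 || cfg$n_users < 0) {
    stop("n_users must be a single non-negative number")
  }
  p <- cfg$cluster_proportions
  if (!setequal(names(p), archetype_names())) {
    stop("cluster_proportions must be named after the four archetypes")
  }
  if (abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
    stop("cluster_proportions must be a simplex summing to 1")
  }
  for (a in archetype_names()) {
    pk <- cfg$peaks[[a]]
    if (is.null(pk)) stop("missing peaks for archetype ", a)
    if (any(pk$time < 0 | pk$time >= 24)) stop("peak times must be in [0,24)")
    if (any(pk$sd <= 0)) stop("peak concentrations (sd) must be positive")
    if (abs(sum(pk$weight) - 1) > 1e-9) stop("peak weights must sum to 1")
  }
  cp <- cfg$category_probs
  if (!identical(colnames(cp), content_categories()) ||
      !setequal(rownames(cp), archetype_names())) {
    stop("category_probs must be an archetype x 8-category matrix")
  }
  if (any(abs(rowSums(cp) - 1) > 1e-9) || any(cp < 0)) {
    stop("each category_probs row must be a simplex summing to 1")
  }
  if (cfg$night_disinfo_boost <= 0) stop("night_disinfo_boost must be > 0")
  if (length(cfg$date_span) != 2 || cfg$date_span[1] > cfg$date_span[2]) {
    stop("empty or inverted date_span")
  }
  if (!is.null(cfg$lockdown)) {
    ld <- cfg$lockdown
    if (ld$start < cfg$date_span[1] || ld$end > cfg$date_span[2] ||
        ld$start > ld$end) {
      stop("lockdown interval must lie inside date_span")
    }
    if (ld$rate_multiplier < 0) stop("lockdown rate_multiplier must be >= 0")
  }
  if (cfg$infrequent_threshold <= 0) stop("infrequent_threshold must be > 0")
  invisible(cfg)
}

#' Read a generator configuration from a YAML file
#'
#' The file mirrors the [synthetic_config()] arguments as key trees; any key
#' left out keeps its default. Dates are ISO strings; `peaks` maps archetype
#' names to lists with `time`, `sd` and `weight` vectors; `category_probs`
#' maps archetype names to 8-value simplices in [content_categories()]
#' order.
#'
#' @param path YAML file path.
#' @return A validated `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (key in c("n_users", "night_disinfo_boost", "night_interval",
                "infrequent_threshold", "tz", "seed")) {
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  }
  if (!is.null(y$cluster_proportions)) {
    args$cluster_proportions <- unlist(y$cluster_proportions)
  }
  if (!is.null(y$peaks)) {
    args$peaks <- lapply(y$peaks, function(p) {
      data.frame(time = unlist(p$time), sd = unlist(p$sd),
                 weight = unlist(p$weight))
    })
  }
  if (!is.null(y$posts_per_user)) args$posts_per_user <- y$posts_per_user
  if (!is.null(y$category_probs)) {
    m <- do.call(rbind, lapply(y$category_probs, unlist))
    colnames(m) <- content_categories()
    args$category_probs <- m
  }
  if (!is.null(y$date_span)) args$date_span <- as.Date(unlist(y$date_span))
  if (!is.null(y$lockdown)) {
    args$lockdown <- if (identical(y$lockdown, "none")) NULL else {
      list(start = as.Date(y$lockdown$start), end = as.Date(y$lockdown$end),
           rate_multiplier = y$lockdown$rate_multiplier)
    }
  }
  do.call(synthetic_config, args)
}

rlnorm_trunc <- function(n, meanlog, sdlog, lower, upper) {
  plo <- stats::plnorm(lower, meanlog, sdlog)
  phi <- stats::plnorm(upper, meanlog, sdlog)
  u <- stats::runif(n, plo, phi)
  pmin(pmax(stats::qlnorm(u, meanlog, sdlog), lower), upper)
}

#' Generate user specifications
#'
#' Draws each user's archetype from `cluster_proportions` and a target post
#' count from the archetype's truncated log-normal law; infrequent users'
#' counts are strictly below the infrequent threshold.
#'
#' @param config A [synthetic_config()].
#' @return A data.frame with columns `user_id`, `archetype`, `n_posts`,
#'   `lat`, `lon`.
#' @export
generate_users <- function(config) {
  validate_synthetic_config(config)
  n <- as.integer(config$n_users)
  if (n == 0) {
    return(data.frame(user_id = character(), archetype = character(),
                      n_posts = integer(), lat = numeric(), lon = numeric(),
                      stringsAsFactors = FALSE))
  }
  with_seed(config$seed, {
    arch <- sample(archetype_names(), n, replace = TRUE,
                   prob = config$cluster_proportions[archetype_names()])
    counts <- integer(n)
    for (a in archetype_names()) {
      idx <- which(arch == a)
      if (!length(idx)) next
      law <- config$posts_per_user[[a]]
      counts[idx] <- as.integer(round(rlnorm_trunc(length(idx), law$meanlog,
                                                   law$sdlog, law$min, law$max)))
    }
    # around the Italian centroid, jittered; rounded so file IO round-trips
    lat <- round(42.40 + stats::runif(n, -1.5, 1.5), 4)
    lon <- round(12.86 + stats::runif(n, -1.5, 1.5), 4)
    data.frame(user_id = sprintf("u%05d", seq_len(n)), archetype = arch,
               n_posts = counts, lat = lat, lon = lon,
               stringsAsFactors = FALSE)
  })
}

#' Generate a table of timestamped posts
#'
#' Per user, post days are drawn uniformly over the date span (lockdown days
#' up-weighted by the rate multiplier) and times of day from the archetype's
#' wrapped-normal mixture; content categories come from the archetype simplex,
#' with disinformative probabilities multiplied by `night_disinfo_boost`
#' inside the configured night interval.
#'
#' @param users Output of [generate_users()].
#' @param config The same [synthetic_config()].
#' @return A data.frame of posts: `user_id`, `timestamp` (POSIXct, civil time
#'   in `config$tz`), `category`, `lat`, `lon`, sorted by user then time.
#' @export
generate_posts <- function(users, config) {
  validate_synthetic_config(config)
  empty <- data.frame(user_id = character(),
                      timestamp = as.POSIXct(character(), tz = config$tz),
                      category = character(), lat = numeric(), lon = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(users) == 0) return(empty)
  days <- seq(config$date_span[1], config$date_span[2], by = "day")
  if (!length(days)) stop("empty date_span")
  day_w <- rep(1, length(days))
  if (!is.null(config$lockdown)) {
    in_ld <- days >= config$lockdown$start & days <= config$lockdown$end
    day_w[in_ld] <- config$lockdown$rate_multiplier
  }
  with_seed(config$seed + 1L, {
    total <- sum(users$n_posts)
    uid <- rep(users$user_id, users$n_posts)
    arch <- rep(users$archetype, users$n_posts)
    lat <- rep(users$lat, users$n_posts)
    lon <- rep(users$lon, users$n_posts)
    day <- days[sample.int(length(days), total, replace = TRUE, prob = day_w)]
    hour <- numeric(total)
    for (a in archetype_names()) {
      idx <- which(arch == a)
      if (!length(idx)) next
      pk <- config$peaks[[a]]
      comp <- sample.int(nrow(pk), length(idx), replace = TRUE, prob = pk$weight)
      hour[idx] <- (stats::rnorm(length(idx), pk$time[comp], pk$sd[comp])) %% 24
    }
    night <- in_circular_interval(hour, config$night_interval[1],
                                  config$night_interval[2])
    cats <- content_categories()
    disinfo <- cats %in% disinformative_categories()
    category <- character(total)
    for (a in archetype_names()) {
      p_day <- config$category_probs[a, ]
      p_night <- p_day
      p_night[disinfo] <- p_night[disinfo] * config$night_disinfo_boost
      p_night <- p_night / sum(p_night)
      for (ngt in c(FALSE, TRUE)) {
        idx <- which(arch == a & night == ngt)
        if (!length(idx)) next
        category[idx] <- cats[sample.int(length(cats), length(idx),
                                         replace = TRUE,
                                         prob = if (ngt) p_night else p_day)]
      }
    }
    secs <- round(hour * 3600)
    stamp <- sprintf("%s %02d:%02d:%02d", format(day),
                     secs %/% 3600, (secs %% 3600) %/% 60, secs %% 60)
    ts <- as.POSIXct(stamp, tz = config$tz)
    # wall times skipped by the spring DST transition do not exist; shift +1h
    bad <- is.na(ts)
    if (any(bad)) {
      h2 <- (secs[bad] %/% 3600 + 1) %% 24
      ts[bad] <- as.POSIXct(sprintf("%s %02d:%02d:%02d", format(day[bad]), h2,
                                    (secs[bad] %% 3600) %/% 60, secs[bad] %% 60),
                            tz = config$tz)
    }
    out <- data.frame(user_id = uid, timestamp = ts, category = category,
                      lat = lat, lon = lon, stringsAsFactors = FALSE)
    out <- out[order(out$user_id, out$timestamp, out$category), ]
    rownames(out) <- NULL
    out
  })
}

format_iso8601 <- function(ts) {
  raw <- format(ts, "%Y-%m-%dT%H:%M:%S%z")
  sub("([+-][0-9]{2})([0-9]{2})$", "\\1:\\2", raw)
}

#' Write a post table to CSV
#'
#' Columns `user_id,timestamp,category,lat,lon`; timestamps ISO-8601 with UTC
#' offset. [read_posts()] on the written file reproduces the table exactly,
#' including the time zone.
#'
#' @param posts Post table as from [generate_posts()].
#' @param path Output file path.
#' @export
write_posts <- function(posts, path) {
  num <- function(x) ifelse(is.na(x), "", sprintf("%.4f", x))
  lines <- c("user_id,timestamp,category,lat,lon",
             if (nrow(posts)) {
               paste(posts$user_id, format_iso8601(posts$timestamp),
                     posts$category, num(posts$lat), num(posts$lon), sep = ",")
             })
  writeLines(lines, path)
  invisible(path)
}

#' Read a post table written by [write_posts()]
#'
#' @param path CSV file path.
#' @param tz Time zone in which timestamps are represented (civil time used
#'   for diurnal binning).
#' @return Post table data.frame; malformed rows raise an error naming the
#'   line number.
#' @export
read_posts <- function(path, tz = "Europe/Rome") {
  if (!file.exists(path)) stop("post file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "user_id,timestamp,category,lat,lon") {
    stop("malformed post file (bad or missing header): ", path)
  }
  body <- lines[-1]
  empty <- data.frame(user_id = character(),
                      timestamp = as.POSIXct(character(), tz = tz),
                      category = character(), lat = numeric(), lon = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(body)) return(empty)
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(parts)
  # a trailing empty lon field drops in strsplit; pad rows of 4 fields
  parts[nf == 4] <- lapply(parts[nf == 4], function(p) c(p, ""))
  nf <- lengths(parts)
  if (any(nf != 5)) {
    stop("parse error in ", path, " at line ",
         which(nf != 5)[1] + 1L, ": expected 5 comma-separated fields")
  }
  m <- do.call(rbind, parts)
  ts_raw <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", m[, 2])
  ts <- as.POSIXct(ts_raw, format = "%Y-%m-%dT%H:%M:%S%z", tz = tz)
  if (anyNA(ts)) {
    stop("parse error in ", path, " at line ", which(is.na(ts))[1] + 1L,
         ": invalid ISO-8601 timestamp '", m[which(is.na(ts))[1], 2], "'")
  }
  bad_cat <- !(m[, 3] %in% content_categories())
  if (any(bad_cat)) {
    stop("parse error in ", path, " at line ", which(bad_cat)[1] + 1L,
         ": unknown category '", m[which(bad_cat)[1], 3], "'")
  }
  data.frame(user_id = m[, 1], timestamp = ts, category = m[, 3],
             lat = suppressWarnings(as.numeric(ifelse(m[, 4] == "", NA, m[, 4]))),
             lon = suppressWarnings(as.numeric(ifelse(m[, 5] == "", NA, m[, 5]))),
             stringsAsFactors = FALSE)
}
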