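# End-to-end orchestration: simulate/ingest -> activity -> clustering ->
# harmonics -> rhythm -> ratios -> day/night -> statistics, with CSV
# artifacts and a JSON manifest. All stages are deterministic given the
# configured seeds, so two runs with the same config produce byte-identical
# artifacts.

#' Pipeline run configuration
#'
#' Defaults mirror the analysis constants: infrequent threshold 240 posts,
#' circular Gaussian smoothing with a 6-bin (90 min) window and sigma 3
#' (sigma 6 for disinformative activity), k = 3 archetype clusters, harmonic
#' count m selected in 1..4, a 16-hour heightened-activity window, and a 1-h
#' safety margin around day/night borders.
#'
#' @param posts_path Optional CSV of posts ([read_posts()] format); when
#'   `NULL`, posts are generated from `synthetic`.
#' @param synthetic A [synthetic_config()] used when `posts_path` is `NULL`.
#' @param infrequent_threshold Posts below which a user is infrequent.
#' @param smooth_window,smooth_sigma Gaussian window (bins) and sigma for
#'   activity and ratio smoothing.
#' @param disinfo_sigma Sigma (bins) for disinformative-activity smoothing.
#' @param k Number of k-means archetypes among frequent users.
#' @param m_range Candidate harmonic counts.
#' @param waking_hours Heightened-activity window length n (hours).
#' @param margin Safety margin s (hours) for day/night comparisons.
#' @param clock_borders Day-by-clock borders in hours (6:30 and 18:45).
#' @param lat,lon Reference coordinates for solar computations.
#' @param year Calendar year for the daylight partition.
#' @param compute_validity Also compute the cluster validity-score table
#'   over `k_range` (slower).
#' @param k_range Candidate cluster counts for the validity table.
#' @param dip_draws Pseudo-sample resolution for the dip test.
#' @param dip_B Monte-Carlo resamples for the dip null.
#' @param seed Master seed for clustering restarts and seeded statistics.
#' @param tz Civil time zone.
#' @return A `run_config` list.
#' @export
run_config <- function(posts_path = NULL, synthetic = synthetic_config(),
                       infrequent_threshold = 240, smooth_window = 6L,
                       smooth_sigma = 3, disinfo_sigma = 6, k = 3L,
                       m_range = 1:4, waking_hours = 16, margin = 1,
                       clock_borders = c(6.5, 18.75),
                       lat = italy_centroid()[["lat"]],
                       lon = italy_centroid()[["lon"]], year = 2020,
                       compute_validity = FALSE, k_range = 2:6,
                       dip_draws = 10000L, dip_B = 2000L, seed = 1L,
                       tz = "Europe/Rome") {
  structure(list(posts_path = posts_path, synthetic = synthetic,
                 infrequent_threshold = infrequent_threshold,
                 smooth_window = smooth_window, smooth_sigma = smooth_sigma,
                 disinfo_sigma = disinfo_sigma, k = k, m_range = m_range,
                 waking_hours = waking_hours, margin = margin,
                 clock_borders = clock_borders, lat = lat, lon = lon,
                 year = year, compute_validity = compute_validity,
                 k_range = k_range, dip_draws = dip_draws, dip_B = dip_B,
                 seed = as.integer(seed), tz = tz),
            class = "run_config")
}

write_table <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

stat_row <- function(res, label) {
  data.frame(label = label, test = res$test,
             statistic = paste(sprintf("%s=%.6g", names(res$statistic),
                                       res$statistic), collapse = ";"),
             p = res$p, sided = res$sided, n1 = res$n1, n2 = res$n2,
             note = if (is.null(res$note)) "" else res$note,
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured input and writes CSV artifacts
#' plus a JSON manifest to `out_dir`. Idempotent for fixed seeds.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, a list with the main in-memory results (assignments,
#'   cluster curves, windows, ratio curves, test tables, manifest path).
#' @export
run_pipeline <- function(config = run_config(), out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  # ---- ingest / simulate -------------------------------------------------
  if (!is.null(config$posts_path)) {
    if (!file.exists(config$posts_path)) {
      stop("ingest: post file not found: ", config$posts_path)
    }
    say("ingest: reading %s", config$posts_path)
    posts <- read_posts(config$posts_path, tz = config$tz)
    date_span <- range(as.Date(posts$timestamp))
    lockdown <- config$synthetic$lockdown
  } else {
    say("simulate: %d users", config$synthetic$n_users)
    users <- generate_users(config$synthetic)
    posts <- generate_posts(users, config$synthetic)
    date_span <- config$synthetic$date_span
    lockdown <- config$synthetic$lockdown
    write_posts(posts, file.path(out_dir, "posts.csv"))
  }
  if (!nrow(posts)) stop("activity: no posts to analyse")

  # ---- activity ----------------------------------------------------------
  say("activity: binning %d posts", nrow(posts))
  profiles <- user_profiles(posts)
  act <- lapply(profiles, user_activity)
  smoothed <- lapply(act, smooth_circular, window_bins = config$smooth_window,
                     sigma_bins = config$smooth_sigma)

  # ---- clustering --------------------------------------------------------
  split <- split_infrequent(profiles, config$infrequent_threshold)
  say("clustering: %d frequent / %d infrequent users",
      length(split$frequent), length(split$infrequent))
  if (length(split$frequent) < config$k) {
    stop("clustering: fewer frequent users than clusters requested")
  }
  model <- fit_archetypes(smoothed[split$frequent], config$k,
                          seed = config$seed)
  names_k <- name_clusters(model$centroids)
  assignments <- c(stats::setNames(names_k[model$assignments],
                                   names(model$assignments)),
                   stats::setNames(rep("infrequent", length(split$infrequent)),
                                   split$infrequent))
  cluster_names <- c(sort(unique(names_k)), "infrequent")
  write_table(data.frame(user_id = names(assignments),
                         cluster = unname(assignments)),
              out_dir, "assignments.csv")
  if (config$compute_validity) {
    say("clustering: validity scores over k in {%s}",
        paste(config$k_range, collapse = ","))
    vs <- validity_scores(smoothed[split$frequent], config$k_range,
                          seed = config$seed)
    write_table(vs, out_dir, "validity_scores.csv")
  }

  members <- lapply(cluster_names, function(cn) {
    names(assignments)[assignments == cn]
  })
  names(members) <- cluster_names

  # ---- harmonic smoothing of cluster activity ---------------------------
  say("harmonics: cluster activity curves")
  grid <- time_grid()
  curves_raw <- lapply(members, function(m) cluster_activity(act, m))
  m_sel <- lapply(curves_raw, function(cv) select_m(curve_values(cv),
                                                    m_range = config$m_range))
  curves_smooth <- mapply(function(cv, sel) {
    reconstruct_top_m(dft(curve_values(cv)), sel$m)
  }, curves_raw, m_sel, SIMPLIFY = FALSE)
  act_tab <- do.call(rbind, lapply(cluster_names, function(cn) {
    data.frame(cluster = cn, bin_start_hour = grid,
               coarse = curve_values(curves_raw[[cn]]),
               smooth = curves_smooth[[cn]])
  }))
  write_table(act_tab, out_dir, "cluster_activity.csv")
  write_table(data.frame(cluster = cluster_names,
                         m = vapply(m_sel, `[[`, integer(1), "m")),
              out_dir, "harmonic_m.csv")

  # ---- disinformative activity ------------------------------------------
  say("harmonics: disinformative activity curves")
  disinfo_act <- lapply(members, function(m) {
    tryCatch(disinformative_activity(profiles, m,
                                     window_bins = config$smooth_window,
                                     sigma_bins = config$disinfo_sigma),
             error = function(e) NULL)
  })
  ok <- !vapply(disinfo_act, is.null, logical(1))
  if (any(ok)) {
    dtab <- do.call(rbind, lapply(cluster_names[ok], function(cn) {
      sel <- select_m(curve_values(disinfo_act[[cn]]),
                      m_range = config$m_range)
      data.frame(cluster = cn, bin_start_hour = grid,
                 smooth = reconstruct_top_m(dft(curve_values(
                   disinfo_act[[cn]])), sel$m))
    }))
    write_table(dtab, out_dir, "disinfo_activity.csv")
  }

  # ---- rhythm ------------------------------------------------------------
  say("rhythm: heightened-activity windows (n = %g h)", config$waking_hours)
  windows <- lapply(curves_smooth, heightened_onset, n = config$waking_hours)
  write_table(do.call(rbind, lapply(cluster_names, function(cn) {
    w <- windows[[cn]]
    pk <- find_peaks(curves_smooth[[cn]], 2)
    data.frame(cluster = cn, onset = w$onset, end = w$end, n = w$n,
               peak1 = if (nrow(pk) >= 1) pk$time[1] else NA,
               peak2 = if (nrow(pk) >= 2) pk$time[2] else NA)
  })), out_dir, "waking_windows.csv")

  # ---- ratios ------------------------------------------------------------
  say("ratios: disinformative ratio curves")
  ratios <- lapply(members, function(m) {
    smooth_ratio(profiles, m, window_bins = config$smooth_window,
                 sigma_bins = config$smooth_sigma, m_range = config$m_range)
  })
  write_table(do.call(rbind, lapply(cluster_names, function(cn) {
    data.frame(cluster = cn, bin_start_hour = grid,
               coarse = curve_values(ratios[[cn]]$coarse),
               smooth = ratios[[cn]]$smooth)
  })), out_dir, "ratio_curves.csv")
  write_table(do.call(rbind, lapply(cluster_names, function(cn) {
    bins <- susceptibility_times(ratios[[cn]]$smooth)
    if (!length(bins)) return(NULL)
    data.frame(cluster = cn, bin = bins, hour = attr(bins, "hours"))
  })), out_dir, "susceptibility_times.csv")

  say("ratios: correlations")
  cor_rows <- list()
  for (cn in cluster_names) {
    pr <- profiles[members[[cn]]]
    res <- tryCatch(posts_vs_ratio_correlation(pr), error = function(e) NULL)
    if (!is.null(res)) {
      cor_rows[[paste0("posts_", cn)]] <-
        stat_row(res, paste0("posts_vs_ratio:", cn))
    }
    cor_rows[[paste0("act_coarse_", cn)]] <- stat_row(
      activity_ratio_correlation(curves_raw[[cn]], ratios[[cn]]$coarse),
      paste0("activity_vs_ratio_coarse:", cn))
    cor_rows[[paste0("act_smooth_", cn)]] <- stat_row(
      activity_ratio_correlation(curves_smooth[[cn]], ratios[[cn]]$smooth),
      paste0("activity_vs_ratio_smooth:", cn))
  }
  cor_rows[["posts_total"]] <- stat_row(posts_vs_ratio_correlation(profiles),
                                        "posts_vs_ratio:total")
  write_table(do.call(rbind, cor_rows), out_dir, "correlations.csv")

  # ---- day/night ---------------------------------------------------------
  say("daynight: partitions and U tests")
  part_clock <- day_night_partition("clock", s = config$margin,
                                    borders = config$clock_borders)
  part_light <- day_night_partition("daylight", s = config$margin,
                                    lat = config$lat, lon = config$lon,
                                    year = config$year, tz = config$tz)
  dn_rows <- list()
  monthly <- monthly_ratio_matrix(posts, assignments, tz = config$tz)
  for (cn in cluster_names) {
    cc <- ratios[[cn]]$coarse
    dn_rows[[paste0(cn, "_clock")]] <- stat_row(
      day_night_test(cc, part_clock), paste0(cn, ":clock"))
    if (!is.null(monthly[[cn]])) {
      dn_rows[[paste0(cn, "_daylight")]] <- stat_row(
        day_night_test(monthly[[cn]], part_light), paste0(cn, ":daylight"))
    }
    part_wake <- day_night_partition("waking", s = config$margin,
                                     window = windows[[cn]])
    dn_rows[[paste0(cn, "_waking")]] <- stat_row(
      day_night_test(cc, part_wake), paste0(cn, ":waking"))
  }
  write_table(do.call(rbind, dn_rows), out_dir, "daynight_tests.csv")

  say("daynight: pairwise cluster ratio comparisons")
  pair_rows <- list()
  for (a in cluster_names) for (b in cluster_names) {
    if (a == b) next
    pair_rows[[paste(a, b, "coarse")]] <- stat_row(
      cluster_ratio_comparison(ratios[[a]]$coarse, ratios[[b]]$coarse),
      paste0(a, "<", b, ":coarse"))
    pair_rows[[paste(a, b, "smooth")]] <- stat_row(
      cluster_ratio_comparison(ratios[[a]]$smooth, ratios[[b]]$smooth),
      paste0(a, "<", b, ":smooth"))
  }
  write_table(do.call(rbind, pair_rows), out_dir, "cluster_comparisons.csv")

  # ---- lockdown ----------------------------------------------------------
  ld <- NULL
  if (!is.null(lockdown)) {
    say("daynight: lockdown comparison")
    ld <- lockdown_compare(posts, assignments,
                           c(lockdown$start, lockdown$end), date_span)
    write_table(ld$table, out_dir, "lockdown_changes.csv")
  }

  # ---- stats -------------------------------------------------------------
  say("stats: dip tests and content-type association")
  stat_rows <- list()
  for (cn in cluster_names) {
    ps <- expand_curve_sample(curves_smooth[[cn]] - min(curves_smooth[[cn]]) +
                                1e-12, draws = config$dip_draws,
                              seed = config$seed)
    stat_rows[[paste0("dip_", cn)]] <- stat_row(
      dip_test(ps, B = config$dip_B, seed = config$seed),
      paste0("dip_smoothed_activity:", cn))
  }
  cat_counts <- table(assignments[posts$user_id], posts$category)
  stat_rows[["chisq_cat"]] <- stat_row(chi_square(as.matrix(cat_counts)),
                                       "content_type_vs_cluster")
  if (!is.null(ld) && !is.null(ld$chisq)) {
    stat_rows[["chisq_ld"]] <- stat_row(ld$chisq, "disinfo_vs_lockdown")
  }
  write_table(do.call(rbind, stat_rows), out_dir, "stat_tests.csv")

  # ---- manifest ----------------------------------------------------------
  manifest <- list(
    package = "chronospread",
    version = as.character(utils::packageVersion("chronospread")),
    seed = config$seed,
    synthetic_seed = if (is.null(config$posts_path)) config$synthetic$seed,
    parameters = list(
      infrequent_threshold = config$infrequent_threshold,
      smooth_window = config$smooth_window,
      smooth_sigma = config$smooth_sigma,
      disinfo_sigma = config$disinfo_sigma, k = config$k,
      m_range = config$m_range, waking_hours = config$waking_hours,
      margin = config$margin, clock_borders = config$clock_borders,
      lat = config$lat, lon = config$lon, year = config$year,
      dip_draws = config$dip_draws, dip_B = config$dip_B),
    n_posts = nrow(posts), n_users = length(profiles),
    clusters = cluster_names,
    artifacts = sort(list.files(out_dir, pattern = "\\.csv$"))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  say("done: %d artifacts in %s", length(manifest$artifacts), out_dir)
  invisible(list(posts = posts, profiles = profiles,
                 assignments = assignments, model = model,
                 curves = curves_smooth, windows = windows, ratios = ratios,
                 daynight = dn_rows, lockdown = ld,
                 manifest = manifest_path))
}

#' Per-month cluster ratio matrices for the daylight partition
#'
#' Computes, for each cluster, a 96 x 12 matrix of the cluster's mean
#' disinformative ratio by bin and calendar month (months pooled across
#' years).
#'
#' @param posts Post table.
#' @param assignments Named user -> cluster vector.
#' @param tz Civil time zone used for binning.
#' @return Named list of 96 x 12 matrices (NA where undefined).
#' @export
monthly_ratio_matrix <- function(posts, assignments, tz = "Europe/Rome") {
  mon <- as.integer(format(posts$timestamp, "%m"))
  out <- list()
  for (cn in unique(assignments)) {
    mat <- matrix(NA_real_, N_BINS, 12, dimnames = list(NULL, month.abb))
    for (m in 1:12) {
      sub <- posts[mon == m & assignments[posts$user_id] == cn, , drop = FALSE]
      if (!nrow(sub)) next
      pr <- user_profiles(sub)
      curves <- lapply(pr, user_ratio_curve)
      defined <- vapply(curves, function(x) any(!is.na(curve_values(x))),
                        logical(1))
      if (!any(defined)) next
      mat[, m] <- curve_values(
        cluster_ratio_curve(curves[defined], names(curves)[defined]))
    }
    out[[cn]] <- mat
  }
  out
}
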