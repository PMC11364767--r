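test_that("solar times are symmetric about solar noon and sane at the equator", {
  for (date in c("2020-01-01", "2020-04-15", "2020-08-01")) {
    st <- solar_times(42.4, 12.86, as.Date(date))
    # solar noon in civil hours: 12 - lon/15 (+ equation of time) + offset;
    # sunrise and sunset must be symmetric around their own midpoint
    mid <- (st["sunrise"] + st["sunset"]) / 2
    expect_equal(unname(st["sunset"] - mid), unname(mid - st["sunrise"]),
                 tolerance = 1 / 60)
  }
  eq <- solar_times(0, 0, as.Date("2020-03-20"), tz = "UTC")
  expect_lt(abs((eq["sunset"] - eq["sunrise"]) - 12), 10 / 60)

  expect_error(solar_times(70, 20, as.Date("2020-06-21")), "polar")
})

test_that("solar times match a second independent implementation within 2 min", {
  dates <- as.Date(c("2020-01-01", "2020-03-15", "2020-06-21", "2020-09-01",
                     "2020-12-21"))
  for (d in as.list(dates)) {
    st <- solar_times(41.9, 12.5, d, tz = "UTC")
    sr2 <- almanac_sun(41.9, 12.5, d, rising = TRUE)
    ss2 <- almanac_sun(41.9, 12.5, d, rising = FALSE)
    expect_lt(abs(st[["sunrise"]] - sr2), 2 / 60)
    expect_lt(abs(st[["sunset"]] - ss2), 2 / 60)
  }
})

test_that("annual-average clock-day borders reproduce 6:30 and 18:45", {
  borders <- clock_day_borders()
  expect_equal(unname(borders["day_start"]), 6.5)
  expect_equal(unname(borders["day_end"]), 18.75)
})

test_that("quarter-hour rounding goes to the nearest grid point", {
  round_quarter <- function(h) round(h * 4) / 4
  expect_equal(round_quarter(6 + 36 / 60), 6.5)      # 6:36 -> 6:30
  expect_equal(round_quarter(18 + 50 / 60), 18.75)   # 18:50 -> 18:45
  expect_equal(round_quarter(6 + 37 / 60), 6.5)
  expect_equal(round_quarter(6 + 39 / 60), 6.75)
})

test_that("clock partition applies the safety margin on both sides", {
  p <- day_night_partition("clock", s = 1, borders = c(6.5, 18.75))
  mid <- time_grid() + 0.125
  expect_equal(p$labels == "day", mid >= 7.5 & mid < 17.75)
  expect_equal(p$labels == "night", mid >= 19.75 | mid < 5.5)
  expect_equal(sum(p$labels == "excluded"), 96 - sum(p$labels != "excluded"))
  expect_equal(sum(p$labels == "day"), (17.75 - 7.5) * 4)
  expect_equal(sum(p$labels == "night"), (24 - 19.75 + 5.5) * 4)

  p0 <- day_night_partition("clock", s = 0, borders = c(6.5, 18.75))
  expect_equal(sum(p0$labels == "excluded"), 0)
  expect_error(day_night_partition("clock", s = 7, borders = c(6.5, 18.75)),
               "empty")
})

test_that("waking partition follows the window borders", {
  v <- numeric(96); v[bin_index(6.5) + 0:63] <- 1
  w <- heightened_onset(v, 16)
  p <- day_night_partition("waking", s = 1, window = w)
  mid <- time_grid() + 0.125
  expect_equal(p$labels == "day", mid >= 7.5 & mid < 21.5)
  expect_equal(p$labels == "night", mid >= 23.5 | mid < 5.5)
  expect_error(day_night_partition("waking", s = 1), "activity_window")
})

test_that("daylight partition labels vary by month", {
  p <- day_night_partition("daylight", s = 1, year = 2020)
  expect_equal(dim(p$labels), c(96, 12))
  expect_true(all(p$labels %in% c("day", "night", "excluded")))
  # June days are longer than December days
  expect_gt(sum(p$labels[, "Jun"] == "day"), sum(p$labels[, "Dec"] == "day"))
})

test_that("day/night U test on partitions matches expectations", {
  p <- day_night_partition("clock", s = 1, borders = c(6.5, 18.75))
  # interchangeable values on both sides: U near n1 n2 / 2 and p large
  res <- day_night_test(rep(c(0.2, 0.3), 48), p)
  expect_lt(abs(unname(res$statistic["U"]) - res$n1 * res$n2 / 2), 25)
  expect_gt(res$p, 0.5)
  expect_match(res$note, "none")

  # day values uniformly below: one-tailed detection, day reported smaller
  v <- ifelse(p$labels == "day", 0.1, 0.5) + seq(0, 1e-4, length.out = 96)
  res2 <- day_night_test(v, p, alternative = "less")
  expect_lt(res2$p, 1e-6)
  expect_match(res2$note, "smaller side: day")

  p_all_excluded <- p; p_all_excluded$labels[] <- "excluded"
  expect_error(day_night_test(v, p_all_excluded), "empty")
})

test_that("cluster ratio comparison counts dropped bins and separates", {
  a <- rep(0.1, 96); b <- rep(0.5, 96)
  a <- a + seq(0, 1e-3, length.out = 96); b <- b + seq(0, 1e-3, length.out = 96)
  res <- cluster_ratio_comparison(a, b, "less")
  expect_equal(unname(res$statistic["U"]), 0)
  expect_lt(res$p, 1e-10)

  a[5] <- NA; b[9] <- NA
  res2 <- cluster_ratio_comparison(a, b, "less")
  expect_match(res2$note, "bins dropped: 2")

  # 5-bin toy: U equals the concordant-pair count by hand
  x <- c(1, 4, 2, 8, 6); y <- c(3, 5, 7, 9, 10)
  res3 <- mann_whitney(x, y, "less")
  expect_equal(unname(res3$statistic["U"]),
               sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "==")))
})

test_that("lockdown comparison computes percent changes per cluster", {
  mk_posts <- function(user, dates, times, category) {
    data.frame(user_id = user,
               timestamp = as.POSIXct(paste(dates, times), tz = "Europe/Rome"),
               category = category, lat = NA_real_, lon = NA_real_,
               stringsAsFactors = FALSE)
  }
  # 10-day span, lockdown days 6..10; user a: 1 post/day outside,
  # 2/day inside; user b: flat 1/day, all disinformative
  span <- as.Date("2020-03-01") + 0:9
  ld <- as.Date(c("2020-03-06", "2020-03-10"))
  pa <- mk_posts("a", format(rep(span, c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2))),
                 "10:00:00", "Mainstream Media")
  pb <- mk_posts("b", format(span), "22:00:00", "Political")
  posts <- rbind(pa, pb)
  res <- lockdown_compare(posts, c(a = "morning", b = "evening"), ld,
                          date_span = range(span))
  tab <- res$table
  get <- function(cl, metric, col) tab[tab$cluster == cl &
                                         tab$metric == metric, col]
  expect_equal(get("morning", "posts_per_day_user", "pct_change"), 100)
  expect_equal(get("evening", "posts_per_day_user", "pct_change"), 0)
  expect_equal(get("evening", "disinfo_posts_per_day_user", "pct_change"), 0)
  expect_equal(get("evening", "mean_user_disinfo_ratio", "outside"), 1)
  expect_true(is.na(get("morning", "disinfo_posts_per_day_user",
                        "pct_change")))  # zero outside rate flagged

  expect_error(lockdown_compare(posts, c(a = "m", b = "e"),
                                as.Date(c("2019-01-01", "2019-02-01")),
                                range(span)),
               "within the date span")
})

test_that("lockdown percent changes are invariant to global rate rescaling", {
  cfg <- tiny_config(n_users = 10, seed = 6, days = 60)
  posts <- generate_posts(generate_users(cfg), cfg)
  assign <- setNames(rep("all", 10), unique(posts$user_id))
  ld <- as.Date(c("2020-03-09", "2020-04-15"))
  base <- lockdown_compare(posts, assign, ld)$table
  doubled <- rbind(posts, posts)       # double every count
  res2 <- lockdown_compare(doubled, assign, ld)$table
  expect_equal(base$pct_change, res2$pct_change, tolerance = 1e-9)
})
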