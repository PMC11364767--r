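test_that("generator handles the empty case and is seed-deterministic", {
  cfg0 <- tiny_config(n_users = 0)
  expect_equal(nrow(generate_users(cfg0)), 0)
  expect_equal(nrow(generate_posts(generate_users(cfg0), cfg0)), 0)

  cfg <- tiny_config(n_users = 12, seed = 42, days = 40)
  u1 <- generate_users(cfg); u2 <- generate_users(cfg)
  expect_identical(u1, u2)
  p1 <- generate_posts(u1, cfg); p2 <- generate_posts(u2, cfg)
  expect_identical(p1, p2)

  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_posts(p1, f1); write_posts(p2, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical
})

test_that("archetype counts follow the configured proportions", {
  cfg <- tiny_config(n_users = 1000, seed = 1,
                     cluster_proportions = c(morning = 0.25,
                                             intermediate = 0.25,
                                             evening = 0.25,
                                             infrequent = 0.25))
  u <- generate_users(cfg)
  counts <- table(factor(u$archetype, levels = archetype <- c(
    "morning", "intermediate", "evening", "infrequent")))
  sd3 <- 3 * sqrt(1000 * 0.25 * 0.75)
  expect_true(all(abs(counts - 250) <= sd3))
})

test_that("infrequent users stay strictly below the threshold", {
  cfg <- tiny_config(n_users = 150, seed = 5)
  u <- generate_users(cfg)
  expect_true(all(u$n_posts[u$archetype == "infrequent"] <
                    cfg$infrequent_threshold))
  expect_true(all(u$n_posts[u$archetype != "infrequent"] >=
                    cfg$infrequent_threshold))
  p <- generate_posts(u, cfg)
  expect_equal(as.integer(table(p$user_id)[u$user_id]), u$n_posts)
  expect_true(all(p$category %in% content_categories()))
  d <- as.Date(format(p$timestamp, "%Y-%m-%d"))  # civil date, not UTC
  expect_true(all(d >= cfg$date_span[1] & d <= cfg$date_span[2]))
})

test_that("a high-concentration single peak puts the modal bin at its centre", {
  cfg <- tiny_config(
    n_users = 1, seed = 2,
    cluster_proportions = c(morning = 1, intermediate = 0, evening = 0,
                            infrequent = 0),
    peaks = list(morning = data.frame(time = 9.5 + 0.125, sd = 0.35,
                                      weight = 1),
                 intermediate = default_peaks()$intermediate,
                 evening = default_peaks()$evening,
                 infrequent = default_peaks()$infrequent),
    posts_per_user = local({
      p <- default_post_counts()
      p$morning <- list(meanlog = log(10000), sdlog = 1e-6, min = 10000,
                        max = 10000)
      p
    }))
  posts <- generate_posts(generate_users(cfg), cfg)
  counts <- rowSums(bin_posts(posts)[[1]])
  expect_equal(which.max(counts), bin_index(9.5))
})

test_that("configuration invariants are enforced", {
  expect_error(tiny_config(cluster_proportions = c(morning = 0.5,
                                                   intermediate = 0.5,
                                                   evening = 0.2,
                                                   infrequent = -0.2)),
               "simplex")
  expect_error(synthetic_config(date_span = as.Date(c("2020-05-01",
                                                      "2020-04-01"))),
               "date_span|lockdown")
  expect_error(tiny_config(night_disinfo_boost = 0), "boost")
})

test_that("post tables round-trip through CSV exactly", {
  p <- posts_at(c("00:10:00", "13:37:21", "23:59:59"), user = "u42",
                category = c("Political", "Other", "Scientific"))
  p$lat <- c(42.1234, NA, 45.0)
  p$lon <- c(12.5, NA, 9.19)
  f <- tempfile(fileext = ".csv")
  write_posts(p, f)
  back <- read_posts(f)
  expect_equal(back$user_id, p$user_id)
  expect_true(all(back$timestamp == p$timestamp))
  expect_equal(back$category, p$category)
  expect_equal(back$lat, p$lat)
  expect_equal(back$lon, p$lon)

  empty <- p[0, ]
  write_posts(empty, f)
  expect_equal(readLines(f), "user_id,timestamp,category,lat,lon")
  expect_equal(nrow(read_posts(f)), 0)
})

test_that("summer (CEST) wall times survive the round trip", {
  p <- posts_at("15:30:00", date = "2020-07-15")
  expect_equal(format(p$timestamp, "%z"), "+0200")
  f <- tempfile(fileext = ".csv")
  write_posts(p, f)
  expect_match(readLines(f)[2], "[+]02:00,")
  back <- read_posts(f)
  expect_equal(format(back$timestamp, "%H:%M"), "15:30")
})

test_that("malformed rows raise parse errors naming the line", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("user_id,timestamp,category,lat,lon",
               "u1,2020-02-10T09:00:00+01:00,Political,,",
               "u2,2020-02-10T09:00:00+01:00,NotACategory,,"), f)
  expect_error(read_posts(f), "line 3.*NotACategory")
  writeLines(c("user_id,timestamp,category,lat,lon",
               "u1,not-a-time,Political,,"), f)
  expect_error(read_posts(f), "line 2")
  writeLines(c("wrong,header"), f)
  expect_error(read_posts(f), "header")
})

test_that("night boost elevates the night-time disinformative share", {
  cfg <- tiny_config(n_users = 40, seed = 3, days = 60,
                     night_disinfo_boost = 2)
  p <- generate_posts(generate_users(cfg), cfg)
  lt <- as.POSIXlt(p$timestamp)
  hr <- lt$hour + lt$min / 60
  night <- hr >= cfg$night_interval[1] | hr < cfg$night_interval[2]
  cls <- p$category %in% classifiable_categories()
  dis <- p$category %in% disinformative_categories()
  expect_gt(mean(dis[cls & night]), mean(dis[cls & !night]))
})

test_that("a YAML config file reproduces the equivalent in-code config", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "n_users: 8",
    "seed: 13",
    "night_disinfo_boost: 2.0",
    "cluster_proportions:",
    "  morning: 0.5",
    "  intermediate: 0.25",
    "  evening: 0.25",
    "  infrequent: 0.0",
    "date_span: ['2020-02-01', '2020-03-31']",
    "lockdown:",
    "  start: '2020-03-09'",
    "  end: '2020-03-31'",
    "  rate_multiplier: 1.5"), f)
  cfg <- read_synthetic_config(f)
  ref <- synthetic_config(
    n_users = 8, seed = 13, night_disinfo_boost = 2,
    cluster_proportions = c(morning = 0.5, intermediate = 0.25,
                            evening = 0.25, infrequent = 0),
    date_span = as.Date(c("2020-02-01", "2020-03-31")),
    lockdown = list(start = as.Date("2020-03-09"),
                    end = as.Date("2020-03-31"), rate_multiplier = 1.5))
  expect_identical(generate_posts(generate_users(cfg), cfg),
                   generate_posts(generate_users(ref), ref))
})
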