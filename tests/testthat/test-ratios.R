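test_that("Harm-Score classification flags HS >= 7 as disinformative", {
  res <- classify_harm(c("Political", "Mainstream Media", "Satire",
                         "Fake and Hoax", "Conspiracy and Junk Science"))
  expect_equal(res$disinformative, c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(res$harm_score, c(7, 2, 3, 8, 9))
  expect_error(classify_harm("Tabloid"), "unknown content category")

  hs <- harm_scheme(merged = FALSE)
  expect_equal(nrow(hs), 9)
  expect_true(all(diff(hs$harm_score) > 0))
  expect_equal(hs$category[hs$harm_score == 6], "Shadow")
  expect_setequal(disinformative_categories(),
                  c("Political", "Fake and Hoax",
                    "Conspiracy and Junk Science"))
  expect_false("Other" %in% classifiable_categories())
})

test_that("user ratios exclude Other from the denominator", {
  prof <- profile_from_counts(list(
    Political = { v <- integer(96); v[5] <- 2; v },
    Other = { v <- integer(96); v[5] <- 2; v },
    "Mainstream Media" = { v <- integer(96); v[5] <- 6; v }))
  r <- curve_values(user_ratio_curve(prof))
  expect_equal(r[5], 2 / 8)            # Other's 2 posts don't count
  expect_true(is.na(r[6]))             # empty denominator -> undefined

  prof2 <- profile_from_counts(list(
    "Fake and Hoax" = { v <- integer(96); v[1] <- 3; v },
    Scientific = { v <- integer(96); v[1] <- 7; v }))
  expect_equal(curve_values(user_ratio_curve(prof2))[1], 0.3)

  expect_error(user_ratio_curve(prof, target = "Other"), "classifiable")
  expect_equal(user_overall_ratio(prof), 2 / 8)
})

test_that("cluster ratios mask undefined members instead of zero-filling", {
  mk <- function(vals) diurnal_curve(vals, kind = "ratio")
  base <- rep(NA_real_, 96)
  a <- base; a[1] <- 0.2; a[2] <- 0.6
  b <- base; b[1] <- 0.4
  curves <- list(a = mk(a), b = mk(b))
  cl <- curve_values(cluster_ratio_curve(curves, c("a", "b")))
  expect_equal(cl[1], 0.3)             # both defined -> mean
  expect_equal(cl[2], 0.6)             # only a defined -> a's value
  expect_true(is.na(cl[3]))            # nobody defined
  expect_equal(curve_values(cluster_ratio_curve(curves["a"], "a")), a)
  expect_error(cluster_ratio_curve(curves, character()), "empty")
})

test_that("circular interpolation bridges undefined runs across midnight", {
  v <- rep(NA_real_, 96)
  v[95] <- 1; v[3] <- 5
  out <- circular_interpolate(v)
  expect_equal(out[96], 2)             # 1/4 of the way from 1 to 5
  expect_equal(out[1], 3)
  expect_equal(out[2], 4)
  expect_equal(out[c(95, 3)], c(1, 5))
  expect_error(circular_interpolate(rep(NA_real_, 96)), "all-undefined")
})

test_that("smooth_ratio preserves constants and finds planted phases", {
  const_prof <- profile_from_counts(list(
    Political = rep(1L, 96), "Mainstream Media" = rep(3L, 96)))
  res <- smooth_ratio(list(u = const_prof), "u")
  expect_equal(curve_values(res$coarse), rep(0.25, 96))
  expect_equal(res$smooth, rep(0.25, 96), tolerance = 1e-9)

  # sinusoidal elevation peaking at 3:00: the smoothed R peaks within 2 bins
  t <- time_grid()
  p_dis <- 0.25 + 0.2 * cos(2 * pi * (t - 3) / 24)
  counts_dis <- as.integer(round(400 * p_dis))
  prof <- profile_from_counts(list(
    Political = counts_dis,
    "Mainstream Media" = as.integer(400 - counts_dis)))
  res2 <- smooth_ratio(list(u = prof), "u")
  expect_lte(min(abs(c(time_grid()[which.max(res2$smooth)] - 3,
                       time_grid()[which.max(res2$smooth)] - 3 + 24))),
             0.5)

  empty_prof <- profile_from_counts(list(Other = rep(1L, 96)))
  expect_error(smooth_ratio(list(u = empty_prof), "u"), "undefined")
})

test_that("susceptibility times are the bins strictly above Q3", {
  expect_equal(length(susceptibility_times(rep(0.3, 96))), 0)

  inc <- seq(0.01, 0.96, length.out = 96)
  bins <- susceptibility_times(inc)
  expect_equal(bins, 73:96, ignore_attr = TRUE)   # exactly the top quartile
  expect_equal(attr(bins, "hours"), time_grid()[73:96])

  out <- rep(0.2, 96); out[40] <- 0.9
  expect_equal(susceptibility_times(out), 40, ignore_attr = TRUE)
  expect_error(susceptibility_times(c(rep(NA, 96))), "defined")
})

test_that("posts-vs-ratio correlation is Spearman over users", {
  mk_user <- function(total, disinfo) {
    profile_from_counts(list(
      Political = { v <- integer(96); v[1] <- disinfo; v },
      "Mainstream Media" = { v <- integer(96); v[1] <- total - disinfo; v }))
  }
  profs <- list(a = mk_user(10, 1), b = mk_user(20, 4), c = mk_user(30, 9),
                d = mk_user(40, 16))
  res <- posts_vs_ratio_correlation(profs)
  expect_equal(unname(res$statistic["rho"]), 1)

  anti <- list(a = mk_user(10, 5), b = mk_user(20, 6), c = mk_user(30, 6))
  expect_equal(unname(posts_vs_ratio_correlation(anti)$statistic["rho"]), -1)

  expect_error(posts_vs_ratio_correlation(profs[1:2]), "at least 3")
})

test_that("activity-ratio correlation handles NAs and constants", {
  act <- seq(0.001, 0.02, length.out = 96)
  ratio <- act^2                         # monotone transform
  expect_equal(unname(activity_ratio_correlation(act, ratio)$statistic), 1)

  r2 <- ratio; r2[c(4, 9)] <- NA
  res <- activity_ratio_correlation(act, r2)
  expect_equal(res$n1, 94)

  res_const <- activity_ratio_correlation(rep(0.01, 96), ratio)
  expect_true(is.na(res_const$p))
  expect_match(res_const$note, "constant")
})

test_that("night boost elevates the smoothed night ratio across seeds", {
  night_hit <- logical(20)
  for (s in 1:20) {
    cfg <- tiny_config(n_users = 15, seed = 100 + s, days = 45,
                       night_disinfo_boost = 2)
    posts <- generate_posts(generate_users(cfg), cfg)
    profiles <- user_profiles(posts)
    res <- smooth_ratio(profiles, names(profiles))
    mid <- time_grid() + 0.125
    night <- mid >= 22.5 | mid < 6.5
    night_hit[s] <- mean(res$smooth[night]) > mean(res$smooth[!night])
  }
  expect_gte(mean(night_hit), 0.9)
})
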