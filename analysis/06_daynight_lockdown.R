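#!/usr/bin/env Rscript
# Day/night comparisons under the three definitions (clock, daylight,
# inferred waking) with a 1-h safety margin, the content-type-by-cluster
# association, and the lockdown comparison (percent changes in posting rates
# and disinformative ratios).

library(chronospread)

posts <- read_posts("results/data/posts.csv")
assignments <- with(read.csv("results/tables/assignments.csv"),
                    setNames(cluster, user_id))
ratio_curves <- read.csv("results/tables/ratio_curves.csv")
windows <- read.csv("results/tables/waking_windows.csv")
clusters <- c("morning", "intermediate", "evening", "infrequent")

borders <- clock_day_borders()
cat(sprintf("clock-day borders: %05.2f - %05.2f\n", borders[1], borders[2]))
part_clock <- day_night_partition("clock", s = 1, borders = borders)
part_light <- day_night_partition("daylight", s = 1, year = 2020)
monthly <- monthly_ratio_matrix(posts, assignments)

profiles <- user_profiles(posts)
dn_rows <- list()
for (cn in clusters) {
  cc <- ratio_curves$coarse[ratio_curves$cluster == cn]
  w <- windows[windows$cluster == cn, ]
  aw <- structure(list(onset = w$onset, end = w$end, n = 16,
                       window_bins = integer(), complement = c(w$end, w$onset)),
                  class = "activity_window")
  part_wake <- day_night_partition("waking", s = 1, window = aw)
  for (def in c("clock", "daylight", "waking")) {
    res <- switch(def,
      clock = day_night_test(cc, part_clock, "less"),
      daylight = day_night_test(monthly[[cn]], part_light, "less"),
      waking = day_night_test(cc, part_wake, "less"))
    dn_rows[[paste(cn, def)]] <- data.frame(
      cluster = cn, definition = def, U = res$statistic[["U"]], p = res$p,
      note = res$note)
    cat(sprintf("%-13s %-9s U = %8.1f  p = %.3g  (%s)\n", cn, def,
                res$statistic[["U"]], res$p, res$note))
  }
}
write.csv(do.call(rbind, dn_rows), "results/tables/daynight_tests.csv",
          row.names = FALSE)

cat_tab <- table(assignments[posts$user_id], posts$category)
chi <- chi_square(as.matrix(cat_tab))
cat(sprintf("content type x cluster: chi^2 = %.1f (df = %d, p = %.3g)\n",
            chi$statistic[["chisq"]], chi$statistic[["df"]], chi$p))

ld <- lockdown_compare(posts, assignments,
                       as.Date(c("2020-03-09", "2020-05-18")),
                       as.Date(c("2020-01-22", "2022-08-01")))
write.csv(ld$table, "results/tables/lockdown_changes.csv", row.names = FALSE)
print(reshape(ld$table[, c("cluster", "metric", "pct_change")],
              idvar = "metric", timevar = "cluster", direction = "wide"))
if (!is.null(ld$chisq)) {
  cat(sprintf("disinfo posts vs lockdown period: chi^2 = %.1f (p = %.3g)\n",
              ld$chisq$statistic[["chisq"]], ld$chisq$p))
}
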