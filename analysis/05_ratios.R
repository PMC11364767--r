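#!/usr/bin/env Rscript
# Disinformative content ratios: per-cluster coarse and smoothed ratio
# curves, top-quartile susceptibility times, correlation of post volume with
# the disinformative share, and correlation of diurnal activity with the
# diurnal ratio (coarse and smooth variants).

library(chronospread)

posts <- read_posts("results/data/posts.csv")
assignments <- with(read.csv("results/tables/assignments.csv"),
                    setNames(cluster, user_id))
curves <- read.csv("results/tables/cluster_curves.csv")
profiles <- user_profiles(posts)
clusters <- c("morning", "intermediate", "evening", "infrequent")
grid <- time_grid()

ratio_rows <- list(); susc_rows <- list(); cor_rows <- list()
ratio_curves <- list()
for (cn in clusters) {
  members <- names(assignments)[assignments == cn]
  r <- smooth_ratio(profiles, members)
  ratio_curves[[cn]] <- r
  ratio_rows[[cn]] <- data.frame(cluster = cn, bin_start_hour = grid,
                                 coarse = curve_values(r$coarse),
                                 smooth = r$smooth)
  bins <- susceptibility_times(r$smooth)
  susc_rows[[cn]] <- data.frame(cluster = cn, hour = attr(bins, "hours"))

  pv <- posts_vs_ratio_correlation(profiles[members])
  co <- activity_ratio_correlation(curves$coarse[curves$cluster == cn],
                                   r$coarse)
  sm <- activity_ratio_correlation(curves$smooth[curves$cluster == cn],
                                   r$smooth)
  cor_rows[[cn]] <- data.frame(
    cluster = cn,
    posts_rho = pv$statistic[["rho"]], posts_p = pv$p,
    coarse_rho = co$statistic[["rho"]], coarse_p = co$p,
    smooth_rho = sm$statistic[["rho"]], smooth_p = sm$p)
  cat(sprintf(
    "%-13s mean ratio %.3f | susceptibility %2d bins | volume rho %+.3f | activity rho %+.3f\n",
    cn, mean(curve_values(r$coarse), na.rm = TRUE), length(bins),
    pv$statistic[["rho"]], co$statistic[["rho"]]))
}
pv_all <- posts_vs_ratio_correlation(profiles)
cat(sprintf("all users: volume vs ratio rho = %+.3f (p = %.2g, n = %d)\n",
            pv_all$statistic[["rho"]], pv_all$p, pv_all$n1))

write.csv(do.call(rbind, ratio_rows), "results/tables/ratio_curves.csv",
          row.names = FALSE)
write.csv(do.call(rbind, susc_rows),
          "results/tables/susceptibility_times.csv", row.names = FALSE)
write.csv(do.call(rbind, cor_rows), "results/tables/correlations.csv",
          row.names = FALSE)

# pairwise one-sided comparisons of the diurnal ratio distributions
pair_rows <- list()
for (a in clusters) for (b in clusters) {
  if (a == b) next
  for (variant in c("coarse", "smooth")) {
    ca <- if (variant == "coarse") ratio_curves[[a]]$coarse else ratio_curves[[a]]$smooth
    cb <- if (variant == "coarse") ratio_curves[[b]]$coarse else ratio_curves[[b]]$smooth
    res <- cluster_ratio_comparison(ca, cb, "less")
    pair_rows[[paste(a, b, variant)]] <- data.frame(
      smaller = a, larger = b, variant = variant,
      U = res$statistic[["U"]], p = res$p)
  }
}
write.csv(do.call(rbind, pair_rows),
          "results/tables/cluster_comparisons.csv", row.names = FALSE)
best <- do.call(rbind, pair_rows)
sig <- best[best$variant == "smooth" & best$p < 0.05, ]
cat("smooth-variant orderings significant at 0.05:",
    paste(sprintf("%s<%s", sig$smaller, sig$larger), collapse = " "), "\n")
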