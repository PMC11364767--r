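#!/usr/bin/env Rscript
# Cluster activity curves (equal user weights), Fourier decomposition, and
# reconstruction from the m largest harmonics, with m chosen per cluster by
# the multi-metric elbow rule over seven curve distances. Also computes the
# sigma = 6 smoothed disinformative activity curves.

library(chronospread)

posts <- read_posts("results/data/posts.csv")
assignments <- with(read.csv("results/tables/assignments.csv"),
                    setNames(cluster, user_id))
profiles <- user_profiles(posts)
act <- lapply(profiles, user_activity)
clusters <- c("morning", "intermediate", "evening", "infrequent")
grid <- time_grid()

rows <- list(); dist_rows <- list(); m_rows <- list()
for (cn in clusters) {
  members <- names(assignments)[assignments == cn]
  coarse <- cluster_activity(act, members)
  sel <- select_m(curve_values(coarse))
  smooth <- reconstruct_top_m(dft(curve_values(coarse)), sel$m)
  rows[[cn]] <- data.frame(cluster = cn, bin_start_hour = grid,
                           coarse = curve_values(coarse), smooth = smooth)
  dist_rows[[cn]] <- cbind(cluster = cn, sel$distances)
  m_rows[[cn]] <- data.frame(cluster = cn, m = sel$m,
                             votes = paste(sel$votes, collapse = ";"))
  cat(sprintf("%-13s m = %d (votes: %s)\n", cn, sel$m,
              paste(names(sel$votes), sel$votes, sep = "=", collapse = " ")))

  dis <- disinformative_activity(profiles, members)   # sigma = 6 smoothing
  seld <- select_m(curve_values(dis))
  rows[[paste0(cn, "_H")]] <- data.frame(
    cluster = paste0(cn, "_disinfo"), bin_start_hour = grid,
    coarse = curve_values(dis),
    smooth = reconstruct_top_m(dft(curve_values(dis)), seld$m))
}

write.csv(do.call(rbind, rows), "results/tables/cluster_curves.csv",
          row.names = FALSE)
write.csv(do.call(rbind, dist_rows), "results/tables/distance_table.csv",
          row.names = FALSE)
write.csv(do.call(rbind, m_rows), "results/tables/harmonic_m.csv",
          row.names = FALSE)
cat("wrote cluster_curves.csv, distance_table.csv, harmonic_m.csv\n")
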