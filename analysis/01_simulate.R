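#!/usr/bin/env Rscript
# Simulate the study's post stream: four diurnal archetypes (morning,
# intermediate, evening, infrequent) posting over the span 2020-01-22 to
# 2022-08-01, with Italy's first lockdown (2020-03-09 to 2020-05-18) at an
# elevated rate and a night-time elevation of disinformative categories.
#
# Desk scale: 400 users (about 130k posts) keeps every later stage
# interactive while preserving the planted structure.

library(chronospread)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- synthetic_config(seed = 20260927L)
users <- generate_users(cfg)
posts <- generate_posts(users, cfg)

write.csv(users, file.path(out, "users.csv"), row.names = FALSE)
write_posts(posts, file.path(out, "posts.csv"))

dates <- as.Date(format(posts$timestamp, "%Y-%m-%d"))
cat(sprintf("simulated %d posts by %d users (%s .. %s)\n", nrow(posts),
            nrow(users), min(dates), max(dates)))
print(table(users$archetype))
dis <- posts$category %in% disinformative_categories()
cls <- posts$category %in% classifiable_categories()
cat(sprintf("overall disinformative share of classified posts: %.3f\n",
            sum(dis) / sum(cls)))
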