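make_profiles <- function(totals) {
  out <- lapply(seq_along(totals), function(i) {
    profile_from_counts(list("Mainstream Media" = {
      v <- integer(96); v[1] <- totals[i]; v
    }), user = paste0("u", i))
  })
  names(out) <- sprintf("u%d", seq_along(totals))
  out
}

test_that("the infrequent split uses a strict < threshold and partitions", {
  pr <- make_profiles(c(239, 240, 241))
  sp <- split_infrequent(pr, 240)
  expect_equal(sp$infrequent, "u1")
  expect_setequal(sp$frequent, c("u2", "u3"))

  all_freq <- split_infrequent(make_profiles(c(240, 500)), 240)
  expect_equal(all_freq$infrequent, character())

  none <- split_infrequent(make_profiles(integer()), 240)
  expect_equal(none$frequent, character())
  expect_equal(none$infrequent, character())
  expect_error(split_infrequent(pr, 0), "threshold")
})

test_that("k-means separates zero-variance indicator groups perfectly", {
  curves <- c(
    setNames(replicate(4, indicator_curve(1), simplify = FALSE),
             paste0("a", 1:4)),
    setNames(replicate(4, indicator_curve(33), simplify = FALSE),
             paste0("b", 1:4)),
    setNames(replicate(4, indicator_curve(65), simplify = FALSE),
             paste0("c", 1:4)))
  model <- fit_archetypes(curves, 3, seed = 1)
  truth <- rep(1:3, each = 4)
  expect_equal(adjusted_rand_index(model$assignments, truth), 1)
  expect_equal(model$tot_withinss, 0)
  expect_true(all(sort(apply(model$centroids, 1, which.max)) == c(1, 33, 65)))

  expect_error(fit_archetypes(curves, 1), "k must be >= 2")
  expect_error(fit_archetypes(curves, 13), "exceeds")
})

test_that("fit is deterministic for a fixed seed", {
  set.seed(99)
  X <- matrix(runif(40 * 96), 40)
  rownames(X) <- paste0("u", 1:40)
  m1 <- fit_archetypes(X, 3, seed = 7)
  m2 <- fit_archetypes(X, 3, seed = 7)
  expect_identical(m1$assignments, m2$assignments)
})

test_that("planted generator archetypes are recovered with high ARI", {
  cfg <- tiny_config(
    n_users = 90, seed = 4, days = 60,
    cluster_proportions = c(morning = 1 / 3, intermediate = 1 / 3,
                            evening = 1 / 3, infrequent = 0),
    peaks = list(morning = data.frame(time = 4, sd = 1.5, weight = 1),
                 intermediate = data.frame(time = 12, sd = 1.5, weight = 1),
                 evening = data.frame(time = 20, sd = 1.5, weight = 1),
                 infrequent = default_peaks()$infrequent))
  users <- generate_users(cfg)
  posts <- generate_posts(users, cfg)
  profiles <- user_profiles(posts)
  smoothed <- lapply(lapply(profiles, user_activity), smooth_circular)
  model <- fit_archetypes(smoothed, 3, seed = 1)
  planted <- users$archetype[match(names(model$assignments), users$user_id)]
  expect_gte(adjusted_rand_index(model$assignments, planted), 0.9)
})

test_that("validity indices match brute-force formulas on a 2-D toy set", {
  X <- matrix(c(0, 0, 1, 0, 0, 1, 10, 10, 11, 10, 10, 11,
                20, 0, 21, 0, 20, 1, 21, 1), ncol = 2, byrow = TRUE)
  labels <- c(1, 1, 1, 2, 2, 2, 3, 3, 3, 3)
  idx <- validity_indices(X, labels)

  n <- nrow(X); k <- 3
  cents <- rbind(colMeans(X[1:3, ]), colMeans(X[4:6, ]), colMeans(X[7:10, ]))
  mu <- colMeans(X)
  wss <- sum((X - cents[labels, ])^2)
  bss <- sum(table(labels) * rowSums((cents - rep(mu, each = 3))^2))
  expect_equal(idx$calinski_harabasz, (bss / (k - 1)) / (wss / (n - k)))

  S <- sapply(1:3, function(c) mean(sqrt(rowSums(
    (X[labels == c, , drop = FALSE] - rep(cents[c, ], each = sum(labels == c)))^2))))
  M <- as.matrix(dist(cents))
  db <- mean(sapply(1:3, function(i) max((S[i] + S[-i]) / M[i, -i])))
  expect_equal(idx$davies_bouldin, db)

  dunn <- min(M[upper.tri(M)]) / max(2 * S)
  expect_equal(idx$generalized_dunn, dunn)

  sil <- mean(cluster::silhouette(labels, dist(X))[, "sil_width"])
  expect_equal(idx$silhouette, sil)
})

test_that("degenerate clusterings are guarded, not fatal", {
  # identical-point clusters, far apart: silhouette attains its optimum
  X <- rbind(matrix(0, 3, 2), matrix(10, 3, 2))
  idx <- validity_indices(X, rep(1:2, each = 3))
  expect_equal(idx$silhouette, 1)
  expect_equal(idx$generalized_dunn, Inf)

  # coincident centroids: Davies-Bouldin flagged as NA with a warning
  Xc <- rbind(matrix(c(0, 0, 1, 1), 2, byrow = TRUE),
              matrix(c(0, 0, 1, 1), 2, byrow = TRUE))
  expect_warning(idx2 <- validity_indices(Xc, c(1, 1, 2, 2)),
                 "Davies-Bouldin")
  expect_true(is.na(idx2$davies_bouldin))
})

test_that("validity score table is oriented so higher is better", {
  set.seed(2)
  X <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 6), 30))
  rownames(X) <- paste0("u", 1:60)
  vs <- validity_scores(X, 2:3, seed = 1, n_restarts = 3)
  expect_setequal(unique(vs$index),
                  c("calinski_harabasz", "davies_bouldin",
                    "generalized_dunn", "silhouette", "cop"))
  db <- vs[vs$index == "davies_bouldin", ]
  expect_equal(db$oriented, -db$score)
  sil2 <- vs$score[vs$index == "silhouette" & vs$k == 2]
  sil3 <- vs$score[vs$index == "silhouette" & vs$k == 3]
  expect_gt(sil2, sil3)   # two well-separated blobs prefer k = 2
  expect_error(validity_scores(X, c(1, 2)), "k_range")
})

test_that("clusters are named after their peak activity times", {
  mk <- function(hour) {
    v <- exp(-((seq(0, 23.75, 0.25) - hour)^2) / 4); v / sum(v)
  }
  cents <- rbind(mk(9.5), mk(23.25), mk(12))
  names <- name_clusters(cents)
  expect_equal(names, c("morning", "evening", "intermediate"),
               ignore_attr = TRUE)
  expect_equal(attr(names, "peak"), c(9.5, 23.25, 12))

  expect_error(name_clusters(rbind(mk(9), mk(10))), "disambiguate")
})

test_that("adjusted Rand index agrees with mclust's implementation", {
  skip_if_not_installed("mclust")
  set.seed(8)
  for (i in 1:20) {
    a <- sample(3, 30, replace = TRUE)
    b <- sample(4, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(1:10, rep(1:5, 2) * 7), 1 - 1)
  expect_equal(adjusted_rand_index(rep(1:2, 5), rep(1:2, 5)), 1)
})
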