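# Archetype clustering of smoothed per-user activity curves.
#
# Infrequent posters (< 240 posts by default) are set aside as their own
# cluster; the remaining users are clustered by k-means on their 96-bin
# smoothed activity curves (Euclidean metric, k-means++ seeding, several
# restarts), and clusters are named after their peak activity times.

#' Separate infrequent posters
#'
#' A user is infrequent iff their total post count is strictly below the
#' threshold. The split is an exhaustive, disjoint partition of the input.
#'
#' @param profiles Named list of `user_profile`s.
#' @param threshold Post-count threshold (default 240).
#' @return List with character vectors `frequent` and `infrequent`.
#' @export
split_infrequent <- function(profiles, threshold = 240) {
  if (threshold <= 0) stop("threshold must be > 0")
  totals <- vapply(profiles, function(p) p$total_posts, numeric(1))
  list(frequent = names(profiles)[totals >= threshold],
       infrequent = names(profiles)[totals < threshold])
}

curves_matrix <- function(curves) {
  if (is.matrix(curves)) return(curves)
  t(vapply(curves, curve_values, numeric(N_BINS)))
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  first <- sample.int(n, 1)
  centers[1, ] <- X[first, ]
  d2 <- colSums((t(X) - centers[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    d2[d2 < 0] <- 0
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    nxt <- sample.int(n, 1, prob = probs)
    centers[j, ] <- X[nxt, ]
    d2 <- pmin(d2, colSums((t(X) - centers[j, ])^2))
  }
  centers
}

#' K-means clustering of smoothed activity curves
#'
#' Lloyd iterations from k-means++ seedings, repeated over `n_restarts`
#' restarts; the solution with the lowest total within-cluster sum of squares
#' is kept. Deterministic given `seed`.
#'
#' @param curves Named list of smoothed user curves, or a user x 96 matrix.
#' @param k Number of clusters (>= 2).
#' @param seed Integer seed.
#' @param n_restarts Number of k-means++ restarts (default 10).
#' @return A `cluster_model`: list with `assignments` (named integer vector),
#'   `centroids` (k x 96 matrix, row = mean of member curves), `k`,
#'   `tot_withinss`, `seed`.
#' @export
fit_archetypes <- function(curves, k, seed = 1L, n_restarts = 10L) {
  X <- curves_matrix(curves)
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(X)) stop("k (", k, ") exceeds the number of users (", nrow(X), ")")
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      init <- kmeanspp_init(X, k)
      fit <- suppressWarnings(
        stats::kmeans(X, centers = init, iter.max = 100, algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    assignments <- best$cluster
    names(assignments) <- rownames(X)
    structure(list(assignments = assignments, centroids = best$centers,
                   k = k, tot_withinss = best$tot.withinss, seed = seed),
              class = "cluster_model")
  })
}

#' Internal validity indices for one clustering
#'
#' Calinski-Harabasz, Davies-Bouldin, a generalized Dunn index (centroid
#' separation over twice the mean within-cluster centroid distance), mean
#' Silhouette width, and the COP index (within-cluster cohesion over
#' min-max separation). Degenerate configurations (zero centroid distances,
#' singleton clusters) yield `NA` with a warning rather than an error.
#'
#' @param X Observation matrix (rows = points).
#' @param labels Integer cluster labels.
#' @return One-row data.frame with the five indices.
#' @export
validity_indices <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  ks <- sort(unique(labels))
  k <- length(ks)
  if (k < 2) stop("validity indices need at least 2 clusters")
  mu <- colMeans(X)
  cents <- t(vapply(ks, function(c) colMeans(X[labels == c, , drop = FALSE]),
                    numeric(ncol(X))))
  sizes <- vapply(ks, function(c) sum(labels == c), numeric(1))
  wss <- sum(vapply(seq_along(ks), function(i) {
    sum(sweep(X[labels == ks[i], , drop = FALSE], 2, cents[i, ])^2)
  }, numeric(1)))
  bss <- sum(sizes * rowSums(sweep(cents, 2, mu)^2))
  ch <- if (wss == 0) Inf else (bss / (k - 1)) / (wss / (n - k))

  S <- vapply(seq_along(ks), function(i) {
    mean(sqrt(rowSums(sweep(X[labels == ks[i], , drop = FALSE], 2,
                            cents[i, ])^2)))
  }, numeric(1))
  M <- as.matrix(stats::dist(cents))
  db <- {
    ratios <- vapply(seq_len(k), function(i) {
      r <- (S[i] + S[-i]) / M[i, -i]
      if (any(!is.finite(r))) NA_real_ else max(r)
    }, numeric(1))
    if (anyNA(ratios)) {
      warning("Davies-Bouldin undefined: coincident centroids")
      NA_real_
    } else mean(ratios)
  }

  diam <- 2 * S
  min_sep <- min(M[upper.tri(M)])
  dunn <- if (max(diam) == 0) Inf else min_sep / max(diam)

  sil <- if (any(sizes == 1)) {
    warning("silhouette flagged: singleton cluster present")
    sw <- cluster::silhouette(labels, stats::dist(X))
    if (is.matrix(sw)) mean(sw[, "sil_width"]) else NA_real_
  } else {
    mean(cluster::silhouette(labels, stats::dist(X))[, "sil_width"])
  }

  D <- as.matrix(stats::dist(X))
  cop <- mean(vapply(seq_along(ks), function(i) {
    inside <- labels == ks[i]
    coh <- mean(sqrt(rowSums(sweep(X[inside, , drop = FALSE], 2,
                                   cents[i, ])^2)))
    sep <- min(apply(D[!inside, inside, drop = FALSE], 1, max))
    if (sep == 0) return(NA_real_)
    sizes[i] * coh / sep
  }, numeric(1))) * k / n

  data.frame(calinski_harabasz = ch, davies_bouldin = db,
             generalized_dunn = dunn, silhouette = sil, cop = cop)
}

#' Validity-score table across a range of cluster counts
#'
#' Fits k-means for each k in `k_range` and evaluates the validity indices.
#' Davies-Bouldin and COP are lower-is-better; the `oriented` column negates
#' them so that higher is uniformly better.
#'
#' @param curves Named list of smoothed user curves or a matrix.
#' @param k_range Integer vector of candidate k (within `[2, n-1]`).
#' @param seed,n_restarts Passed to [fit_archetypes()].
#' @return Long data.frame `k, index, score, higher_is_better, oriented`.
#' @export
validity_scores <- function(curves, k_range = 2:6, seed = 1L, n_restarts = 10L) {
  X <- curves_matrix(curves)
  if (min(k_range) < 2 || max(k_range) > nrow(X) - 1) {
    stop("k_range must lie within [2, n - 1]")
  }
  higher <- c(calinski_harabasz = TRUE, davies_bouldin = FALSE,
              generalized_dunn = TRUE, silhouette = TRUE, cop = FALSE)
  rows <- lapply(k_range, function(k) {
    model <- fit_archetypes(X, k, seed = seed, n_restarts = n_restarts)
    idx <- validity_indices(X, model$assignments)
    data.frame(k = k, index = names(idx), score = as.numeric(idx[1, ]),
               higher_is_better = unname(higher[names(idx)]),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$oriented <- ifelse(out$higher_is_better, out$score, -out$score)
  out
}

#' Name archetype clusters after their peak activity times
#'
#' The cluster whose smoothed curve peaks before 12:00 is the morning type;
#' a peak after 20:00 marks the evening type; anything else is intermediate.
#' Two clusters mapping to the same name raise a disambiguation error
#' reporting the peak times.
#'
#' @param centroids k x 96 matrix (or list of curves) of smoothed cluster
#'   activity.
#' @param morning_before Peak-hour threshold for "morning" (default 12).
#' @param evening_after Peak-hour threshold for "evening" (default 20).
#' @return Character vector of names, one per cluster, with the peak hour as
#'   the `peak` attribute.
#' @export
name_clusters <- function(centroids, morning_before = 12, evening_after = 20) {
  M <- curves_matrix(centroids)
  peaks <- time_grid()[apply(M, 1, which.max)]
  names <- ifelse(peaks < morning_before, "morning",
                  ifelse(peaks > evening_after, "evening", "intermediate"))
  dup <- names[duplicated(names)]
  if (length(dup)) {
    stop("cannot disambiguate clusters: ",
         paste(sprintf("%s (peak %s)", names, format_hour(peaks)),
               collapse = ", "))
  }
  attr(names, "peak") <- peaks
  names
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b Label vectors of equal length.
#' @return ARI in `[-1, 1]`; 1 iff the partitions coincide.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}
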