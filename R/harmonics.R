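# Fourier decomposition of diurnal curves and reconstruction from the m
# largest-amplitude harmonics, plus the curve-distance metrics used to pick m.

#' Discrete Fourier decomposition of a diurnal curve
#'
#' Computes the DFT of the 96 bin values and the amplitude/phase of each
#' harmonic over the 24-h period. Amplitudes follow the real-signal
#' convention: `2|X_n|/N` for `1 <= n < N/2`, `|X_n|/N` for the DC and
#' Nyquist terms. The inverse transform of the full coefficient set
#' reproduces the curve to machine precision.
#'
#' @param curve A `diurnal_curve` or numeric vector of length 96 (finite).
#' @return A `harmonic_model`: list with `coefficients` (96 complex values),
#'   `dc` (mean level), `amplitude` and `phase` (indexed by harmonic
#'   `n = 1..48`), `period = 24`, `n_bins = 96` and the original `values`.
#' @export
dft <- function(curve) {
  v <- curve_values(curve)
  if (!all(is.finite(v))) stop("dft requires 96 finite values")
  X <- stats::fft(v)
  N <- N_BINS
  half <- N / 2                      # 48: Nyquist harmonic
  amp <- c(2 * Mod(X[2:half]) / N, Mod(X[half + 1]) / N)
  phase <- c(Arg(X[2:half]), Arg(X[half + 1]))
  structure(list(coefficients = X, dc = Re(X[1]) / N,
                 amplitude = amp, phase = phase,
                 period = 24, n_bins = N, values = v),
            class = "harmonic_model")
}

#' Indices of the m largest-amplitude harmonics
#'
#' The DC term is always retained and does not count towards `m`. Amplitude
#' ties are broken towards the lower frequency.
#' @keywords internal
kept_harmonics <- function(model, m) {
  ord <- order(-model$amplitude, seq_along(model$amplitude))
  sort(ord[seq_len(m)])
}

#' Reconstruct a curve from its m largest harmonics
#'
#' Evaluates `dc + sum of h(n, t)` over the kept set at the bin-start times,
#' where `h(n, t) = A_n cos(2 pi n t / 24 + phase_n)`. The mean of the output
#' equals the mean of the input, since the DC term is always kept.
#'
#' @param model A `harmonic_model` from [dft()].
#' @param m Number of non-DC harmonics to keep (`0 <= m <= 48`; `m = 48` is
#'   the full set and reproduces the input to machine precision).
#' @return Numeric vector of 96 reconstructed values.
#' @export
reconstruct_top_m <- function(model, m) {
  if (!inherits(model, "harmonic_model")) stop("not a harmonic_model")
  if (!is.numeric(m) || length(m) != 1 || m != round(m) || m < 0 || m > 48) {
    stop("m must be an integer in [0, 48]")
  }
  t <- time_grid()
  out <- rep(model$dc, N_BINS)
  if (m > 0) {
    for (n in kept_harmonics(model, m)) {
      out <- out + model$amplitude[n] *
        cos(2 * pi * n * t / model$period + model$phase[n])
    }
  }
  out
}

curve_metrics <- function() {
  c("pcm", "area", "frechet", "curve_length", "dtw", "mae", "mse")
}

as_curve_points <- function(v, x = NULL) {
  if (is.null(x)) {
    x <- if (length(v) == N_BINS) time_grid() else seq_along(v) - 1
  }
  cbind(x = x, y = as.numeric(v))
}

#' Distance between two curves
#'
#' Seven metrics over equal-length curves viewed as 2-D polylines
#' (time, value): Partial Curve Mapping (`"pcm"`, mean pointwise distance
#' after normalized arc-length reparameterization), the area method
#' (`"area"`, trapezoidal integral of the absolute difference over the shared
#' abscissae), discrete Frechet distance (`"frechet"`), curve length
#' (`"curve_length"`, absolute difference of the two arc lengths), Dynamic
#' Time Warping (`"dtw"`, cumulative Euclidean cost along the optimal
#' monotone alignment), mean absolute error (`"mae"`) and mean squared error
#' (`"mse"`). All metrics are 0 on identical curves.
#'
#' @param a,b Numeric vectors of equal length.
#' @param metric One of [curve_metrics()].
#' @param x Optional shared abscissae (defaults to the diurnal grid for
#'   96-point curves, else `0, 1, ...`).
#' @return Non-negative scalar distance.
#' @export
curve_distance <- function(a, b, metric, x = NULL) {
  if (length(a) != length(b)) stop("curves must have equal length")
  metric <- as.character(metric)
  if (!metric %in% curve_metrics()) {
    stop("unknown metric '", metric, "'; available: ",
         paste(curve_metrics(), collapse = ", "))
  }
  A <- as_curve_points(a, x); B <- as_curve_points(b, x)
  switch(metric,
    mae = mean(abs(A[, "y"] - B[, "y"])),
    mse = mean((A[, "y"] - B[, "y"])^2),
    area = {
      d <- abs(A[, "y"] - B[, "y"])
      xs <- A[, "x"]
      sum(diff(xs) * (d[-1] + d[-length(d)]) / 2)
    },
    curve_length = abs(polyline_length(A) - polyline_length(B)),
    frechet = frechet_distance(A, B),
    dtw = dtw_distance(A, B),
    pcm = pcm_distance(A, B)
  )
}

polyline_length <- function(P) {
  sum(sqrt(diff(P[, 1])^2 + diff(P[, 2])^2))
}

point_cost <- function(A, B) {
  # |A| x |B| matrix of Euclidean distances between polyline vertices
  outer(seq_len(nrow(A)), seq_len(nrow(B)), function(i, j) {
    sqrt((A[i, 1] - B[j, 1])^2 + (A[i, 2] - B[j, 2])^2)
  })
}

frechet_distance <- function(A, B) {
  cost <- point_cost(A, B)
  n <- nrow(A); m <- nrow(B)
  d <- matrix(NA_real_, n, m)
  d[1, 1] <- cost[1, 1]
  for (i in 2:max(n, 2)) if (n > 1) d[i, 1] <- max(d[i - 1, 1], cost[i, 1])
  for (j in 2:max(m, 2)) if (m > 1) d[1, j] <- max(d[1, j - 1], cost[1, j])
  if (n > 1 && m > 1) {
    for (i in 2:n) for (j in 2:m) {
      d[i, j] <- max(min(d[i - 1, j], d[i, j - 1], d[i - 1, j - 1]),
                     cost[i, j])
    }
  }
  d[n, m]
}

dtw_distance <- function(A, B) {
  cost <- point_cost(A, B)
  n <- nrow(A); m <- nrow(B)
  acc <- matrix(Inf, n, m)
  acc[1, 1] <- cost[1, 1]
  for (i in 2:max(n, 2)) if (n > 1) acc[i, 1] <- acc[i - 1, 1] + cost[i, 1]
  for (j in 2:max(m, 2)) if (m > 1) acc[1, j] <- acc[1, j - 1] + cost[1, j]
  if (n > 1 && m > 1) {
    for (i in 2:n) for (j in 2:m) {
      acc[i, j] <- cost[i, j] + min(acc[i - 1, j], acc[i, j - 1],
                                    acc[i - 1, j - 1])
    }
  }
  acc[n, m]
}

resample_by_arclength <- function(P, k) {
  s <- c(0, cumsum(sqrt(diff(P[, 1])^2 + diff(P[, 2])^2)))
  if (s[length(s)] == 0) {
    return(cbind(rep(P[1, 1], k), rep(P[1, 2], k)))
  }
  s <- s / s[length(s)]
  at <- seq(0, 1, length.out = k)
  cbind(stats::approx(s, P[, 1], xout = at, ties = "ordered")$y,
        stats::approx(s, P[, 2], xout = at, ties = "ordered")$y)
}

pcm_distance <- function(A, B, k = 200) {
  RA <- resample_by_arclength(A, k)
  RB <- resample_by_arclength(B, k)
  mean(sqrt(rowSums((RA - RB)^2)))
}

#' Distance table between a curve and its harmonic truncations
#'
#' @param curve Numeric 96-bin curve.
#' @param m_values Integer vector of m values.
#' @param metrics Metric names (default all seven).
#' @return data.frame `metric, m, distance`.
#' @export
distance_table <- function(curve, m_values, metrics = curve_metrics()) {
  model <- dft(curve)
  recons <- lapply(m_values, function(m) reconstruct_top_m(model, m))
  out <- expand.grid(metric = metrics, m = m_values, stringsAsFactors = FALSE)
  out$distance <- mapply(function(u, mi) {
    curve_distance(recons[[match(mi, m_values)]], curve_values(curve), u)
  }, out$metric, out$m)
  out
}

#' Select the number of harmonics by the multi-metric elbow rule
#'
#' For each distance metric, improvements `delta(m) = D(m-1) - D(m)` are
#' computed over the candidate range (with `D(0)` the DC-only
#' reconstruction); the metric votes for the smallest m whose following
#' improvement is smaller (`delta(m+1) < delta(m)`), i.e. the point where the
#' gain from one more harmonic starts shrinking. The final m is the minimum
#' of the most common votes, so a tie between equally supported values
#' resolves to the smaller one.
#'
#' @param curve Numeric 96-bin curve.
#' @param m_range Candidate range (default `1:4`; must lie within `[1, 47]`).
#' @param metrics Metric names to poll (default all seven).
#' @return List with `m` (chosen value), `votes` (named integer vector, one
#'   per metric) and `distances` (the full metric x m distance table).
#' @export
select_m <- function(curve, m_range = 1:4, metrics = curve_metrics()) {
  m_range <- sort(unique(as.integer(m_range)))
  if (length(m_range) == 0 || min(m_range) < 1 || max(m_range) > 47) {
    stop("m_range must lie within [1, 47]")
  }
  m_all <- c(0L, seq_len(min(max(m_range) + 1L, 48L)))
  tab <- distance_table(curve, m_all, metrics)
  select_m_from_distances(tab, m_range)
}

#' @describeIn select_m the elbow rule applied to a precomputed distance
#'   table (columns `metric, m, distance`, including `m = 0` and one value
#'   beyond the top of `m_range` where available).
#' @param distances data.frame `metric, m, distance`.
#' @export
select_m_from_distances <- function(distances, m_range = 1:4) {
  m_range <- sort(unique(as.integer(m_range)))
  metrics <- unique(distances$metric)
  votes <- vapply(metrics, function(u) {
    sub <- distances[distances$metric == u, ]
    D <- sub$distance[order(sub$m)]
    names(D) <- sort(sub$m)
    eps <- 1e-9 * max(abs(D), 1)        # guard strict < against round-off
    delta <- function(m) D[as.character(m - 1)] - D[as.character(m)]
    for (m in m_range) {
      nxt <- m + 1L
      if (!as.character(nxt) %in% names(D)) break
      if (delta(nxt) < delta(m) - eps) return(m)
    }
    max(m_range)
  }, integer(1))
  counts <- table(votes)
  mode_set <- as.integer(names(counts)[counts == max(counts)])
  list(m = min(mode_set), votes = votes, distances = distances)
}
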