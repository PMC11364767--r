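# Shared fixtures and independent brute-force oracles.

# posts at given local wall times (Europe/Rome) for one or more users
posts_at <- function(times, user = "u1", category = "Mainstream Media",
                     date = "2020-02-10") {
  data.frame(user_id = rep(user, length.out = length(times)),
             timestamp = as.POSIXct(paste(date, times), tz = "Europe/Rome"),
             category = rep(category, length.out = length(times)),
             lat = NA_real_, lon = NA_real_, stringsAsFactors = FALSE)
}

# a user_profile with prescribed bin-by-category counts
profile_from_counts <- function(counts_list, user = "u1") {
  cats <- content_categories()
  m <- matrix(0L, 96, length(cats), dimnames = list(NULL, cats))
  for (cat in names(counts_list)) {
    m[, cat] <- counts_list[[cat]]
  }
  structure(list(user_id = user, counts = m, total_posts = sum(m)),
            class = "user_profile")
}

indicator_curve <- function(bin) {
  v <- numeric(96); v[bin] <- 1
  diurnal_curve(v, kind = "activity", normalized = TRUE)
}

# small fast generator config (overlaps Italy's first lockdown)
tiny_config <- function(n_users = 20, seed = 1, days = 90, ...) {
  span <- as.Date("2020-03-01") + c(0, days - 1)
  synthetic_config(
    n_users = n_users,
    date_span = span,
    lockdown = list(start = as.Date("2020-03-09"),
                    end = min(span[2], as.Date("2020-05-18")),
                    rate_multiplier = 1.8),
    seed = seed, ...)
}

# ---- independent oracles -------------------------------------------------

# discrete Frechet by exhaustive enumeration of monotone couplings
frechet_brute <- function(A, B) {
  n <- nrow(A); m <- nrow(B)
  d <- function(i, j) sqrt(sum((A[i, ] - B[j, ])^2))
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- max(acc, d(i, j))
    if (acc >= best) return()
    if (i == n && j == m) { best <<- min(best, acc); return() }
    if (i < n) walk(i + 1, j, acc)
    if (j < m) walk(i, j + 1, acc)
    if (i < n && j < m) walk(i + 1, j + 1, acc)
  }
  walk(1, 1, 0)
  best
}

# DTW by exhaustive enumeration of monotone paths
dtw_brute <- function(A, B) {
  n <- nrow(A); m <- nrow(B)
  d <- function(i, j) sqrt(sum((A[i, ] - B[j, ])^2))
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + d(i, j)
    if (acc >= best) return()
    if (i == n && j == m) { best <<- min(best, acc); return() }
    if (i < n) walk(i + 1, j, acc)
    if (j < m) walk(i, j + 1, acc)
    if (i < n && j < m) walk(i + 1, j + 1, acc)
  }
  walk(1, 1, 0)
  best
}

# exhaustive heightened-onset scan
onset_brute <- function(v, n = 16) {
  w <- 4 * n
  ext <- c(v, v)
  sums <- sapply(1:96, function(b) sum(ext[b:(b + w - 1)]))
  (which.max(sums) - 1) / 4
}

# dip by bisection over unimodal CDF envelopes: per candidate mode, convex /
# concave band feasibility via chord-enumeration hulls plus the coupling
# bounds (minimal left limit vs maximal post-atom value)
dip_brute <- function(x, tol = 1e-9) {
  x <- sort(x); n <- length(x); vx <- unique(x); K <- length(vx)
  if (K == 1) return(0)
  cum <- cumsum(tabulate(match(x, vx), K)) / n
  lo <- cum; up <- c(0, cum[-K])
  hull_lo <- function(xs, ys) {       # lower convex hull values by chords
    sapply(seq_along(xs), function(i) {
      best <- ys[i]
      for (a in seq_len(i)) for (b in i:length(xs)) {
        if (a == b) next
        val <- ys[a] + (ys[b] - ys[a]) * (xs[i] - xs[a]) / (xs[b] - xs[a])
        best <- min(best, val)
      }
      best
    })
  }
  feas_mode <- function(k, d) {
    A <- pmax(lo - d, 0); B <- pmin(up + d, 1)
    ell_min <- -Inf
    if (k >= 2) {
      iL <- 1:(k - 1)
      if (any(A[iL] > hull_lo(vx[iL], B[iL]) + 1e-12)) return(FALSE)
      ell_min <- A[k - 1]
      if (k >= 3) for (j in 2:(k - 1)) for (i in 1:(j - 1)) {
        s <- (A[j] - B[i]) / (vx[j] - vx[i])
        if (s > 0) ell_min <- max(ell_min, A[j] + s * (vx[k] - vx[j]))
      }
    }
    iR <- k:K
    Ar <- A[iR]; Br <- B[iR]
    Ar[1] <- max(lo[k] - d, 0); Br[1] <- min(lo[k] + d, 1)
    Hu <- -hull_lo(vx[iR], -Ar)       # upper concave hull of the lower boxes
    if (any(Hu > Br + 1e-12)) return(FALSE)
    r_max <- Br[1]
    if (K >= k + 1) for (i in (k + 1):K) {
      r_max <- min(r_max, B[i])
      if (K >= i + 1) for (j in (i + 1):K) {
        s <- max(0, (A[j] - B[i]) / (vx[j] - vx[i]))
        r_max <- min(r_max, B[i] - s * (vx[i] - vx[k]))
      }
    }
    if (r_max < max(lo[k] - d, 0) - 1e-12) return(FALSE)
    k < 2 || (ell_min <= min(up[k] + d, 1) + 1e-12 &&
                ell_min <= r_max + 1e-12)
  }
  feas <- function(d) any(sapply(1:K, feas_mode, d = d))
  loD <- 0; hiD <- 0.5
  while (hiD - loD > tol) {
    mid <- (loD + hiD) / 2
    if (feas(mid)) hiD <- mid else loD <- mid
  }
  (loD + hiD) / 2
}

# Mann-Whitney U and exact p by full enumeration of group assignments
mw_brute <- function(x, y, alternative = "two") {
  n1 <- length(x); n2 <- length(y)
  U <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  obs <- U(x, y)
  pooled <- c(x, y)
  idx <- utils::combn(n1 + n2, n1)
  Us <- apply(idx, 2, function(i) U(pooled[i], pooled[-i]))
  p_less <- mean(Us <= obs + 1e-9)
  p_greater <- mean(Us >= obs - 1e-9)
  p <- switch(alternative, less = p_less, greater = p_greater,
              two = min(1, 2 * min(p_less, p_greater)))
  list(U = obs, p = p)
}

# second, independently coded sunrise algorithm (Almanac for Computers)
almanac_sun <- function(lat, lon, date, rising = TRUE) {
  d <- as.POSIXlt(as.Date(date))
  N <- d$yday + 1
  lngHour <- lon / 15
  t <- if (rising) N + (6 - lngHour) / 24 else N + (18 - lngHour) / 24
  M <- 0.9856 * t - 3.289
  L <- (M + 1.916 * sin(M * pi / 180) + 0.020 * sin(2 * M * pi / 180) +
          282.634) %% 360
  RA <- (atan(0.91764 * tan(L * pi / 180)) * 180 / pi) %% 360
  RA <- (RA + (floor(L / 90) * 90 - floor(RA / 90) * 90)) / 15
  sinDec <- 0.39782 * sin(L * pi / 180)
  cosDec <- cos(asin(sinDec))
  cosH <- (cos(90.8333 * pi / 180) - sinDec * sin(lat * pi / 180)) /
    (cosDec * cos(lat * pi / 180))
  if (abs(cosH) > 1) return(NA_real_)
  H <- if (rising) 360 - acos(cosH) * 180 / pi else acos(cosH) * 180 / pi
  TT <- H / 15 + RA - 0.06571 * t - 6.622
  (TT - lngHour) %% 24     # UTC hours
}
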