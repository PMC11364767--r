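# Nonparametric statistics used across the pipeline, with exact small-sample
# behaviour where enumeration is feasible.

#' Construct a statistical test result
#'
#' @param test Test name.
#' @param statistic Named numeric statistic(s).
#' @param p p-value (may be NA when the statistic is undefined).
#' @param sided One of "two", "less", "greater".
#' @param n1,n2 Sample sizes (n2 may be NA for one-sample tests).
#' @param note Optional free-text flag (e.g. "exact", "undefined: ...").
#' @return A `stat_result` list.
#' @export
stat_result <- function(test, statistic, p, sided = "two", n1 = NA, n2 = NA,
                        note = NULL) {
  if (!is.na(p) && (p < 0 || p > 1)) stop("p must be in [0, 1]")
  structure(list(test = test, statistic = statistic, p = p, sided = sided,
                 n1 = n1, n2 = n2, note = note),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<%s: %s p=%.4g (%s-sided, n=%s%s)%s>\n", x$test,
              paste(sprintf("%s=%.6g", names(x$statistic), x$statistic),
                    collapse = ", "),
              x$p, x$sided, x$n1,
              if (!is.na(x$n2)) paste0("/", x$n2) else "",
              if (!is.null(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

mw_u <- function(x, y) {
  # U = #(x_i > y_j) + half-ties: small when x sits below y
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test
#'
#' `U` counts pairs with `x_i > y_j` (ties counting one half), so a small U
#' means the `x` sample sits below `y`; the one-sided alternative `"less"`
#' states that `x` is stochastically smaller. The p-value is exact (full
#' enumeration of group assignments, ties included) when `n1 + n2 <= 12`,
#' and uses the normal approximation with tie correction and continuity
#' correction otherwise.
#'
#' @param x,y Numeric samples (nonempty).
#' @param alternative `"two"`, `"less"` or `"greater"`.
#' @param exact_limit Enumerate exactly when `n1 + n2` is at most this
#'   (default 12).
#' @return A [stat_result()] with statistic `U`.
#' @export
mann_whitney <- function(x, y, alternative = c("two", "less", "greater"),
                         exact_limit = 12L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  U <- mw_u(x, y)
  if (N <= exact_limit) {
    pooled <- c(x, y)
    idx <- utils::combn(N, n1)
    Us <- apply(idx, 2, function(i) mw_u(pooled[i], pooled[-i]))
    p_less <- mean(Us <= U + 1e-9)
    p_greater <- mean(Us >= U - 1e-9)
    p <- switch(alternative, less = p_less, greater = p_greater,
                two = min(1, 2 * min(p_less, p_greater)))
    return(stat_result("mann_whitney", c(U = U), p, alternative, n1, n2,
                       note = "exact"))
  }
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
  if (sigma == 0) stop("all pooled values identical; U test degenerate")
  p <- switch(alternative,
    less = stats::pnorm((U - mu + 0.5) / sigma),
    greater = stats::pnorm(-(U - mu - 0.5) / sigma),
    two = {
      z <- (U - mu - sign(U - mu) * 0.5) / sigma
      min(1, 2 * stats::pnorm(-abs(z)))
    })
  stat_result("mann_whitney", c(U = U), p, alternative, n1, n2,
              note = "normal approximation")
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks; p via the t approximation with `n - 2`
#' degrees of freedom. Constant input leaves the correlation undefined,
#' returned as `NA` with a note (not an error).
#'
#' @param x,y Paired numeric samples, `n >= 3`.
#' @return A [stat_result()] with statistic `rho`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("spearman needs at least 3 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(stat_result("spearman", c(rho = NA_real_), NA_real_, "two", n,
                       note = "undefined: constant input"))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), n - 2)
  }
  stat_result("spearman", c(rho = rho), p, "two", n)
}

#' Pearson chi-squared test on a contingency table
#'
#' @param tab Matrix of nonnegative counts, at least 2 x 2, without zero
#'   margins.
#' @return A [stat_result()] with `chisq` and `df`.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2 x 2")
  if (any(tab < 0)) stop("counts must be nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero row or column margin; chi-squared undefined")
  }
  fit <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  stat_result("chi_square",
              c(chisq = unname(fit$statistic), df = unname(fit$parameter)),
              fit$p.value, "two", sum(tab))
}

#' Shapiro-Wilk normality test
#'
#' @param x Numeric sample with `3 <= n <= 5000`.
#' @return A [stat_result()] with statistic `W`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000) {
    stop("shapiro_wilk requires 3 <= n <= 5000")
  }
  fit <- stats::shapiro.test(x)
  stat_result("shapiro_wilk", c(W = unname(fit$statistic)), fit$p.value,
              "two", length(x))
}

# ---- Hartigan's dip statistic -------------------------------------------
#
# dip(F_n) = min over unimodal distribution functions G of sup |F_n - G|,
# where G is convex up to its mode, concave after it, with an atom permitted
# at the mode. Computed exactly in C (src/dip.cpp) by bisection on the band
# half-width d: for each candidate mode, feasibility reduces to convex /
# concave hull conditions on the band boxes plus pair-extrapolation coupling
# bounds at the mode.

#' Hartigan's dip statistic
#'
#' Maximum distance between the empirical CDF and the closest unimodal
#' distribution function. Equally spaced (perfectly "uniform") samples give
#' exactly `1/(2n)`; two separated equal point masses give the supremum 1/4.
#' The statistic is location/scale invariant but - like the underlying
#' convexity notion - not invariant under general monotone transformations.
#'
#' @param x Numeric sample (`n >= 1`).
#' @return The dip statistic (scalar in `[0, 1/4]`).
#' @export
dip_stat <- function(x) {
  x <- sort(as.numeric(x[!is.na(x)]))
  n <- length(x)
  if (n < 1) stop("empty sample")
  vx <- unique(x)
  if (length(vx) == 1) return(0)
  cum <- cumsum(tabulate(match(x, vx), length(vx))) / n
  .dip_stat_c(vx, cum)
}

.dip_null_cache <- new.env(parent = emptyenv())

dip_null_table <- function(n, B, seed, null_bins) {
  key <- paste(n, B, seed, null_bins, sep = "|")
  if (!is.null(.dip_null_cache[[key]])) return(.dip_null_cache[[key]])
  tab <- with_seed(seed, {
    vapply(seq_len(B), function(i) {
      u <- stats::runif(n)
      if (is.finite(null_bins)) u <- (ceiling(u * null_bins) - 0.5) / null_bins
      dip_stat(u)
    }, numeric(1))
  })
  .dip_null_cache[[key]] <- tab
  tab
}

#' Dip test of unimodality
#'
#' Tests the null of a unimodal distribution with Hartigan's dip statistic;
#' the p-value is Monte-Carlo against same-size samples from the uniform
#' null (the conventional least-favourable unimodal null). When the observed
#' sample is discrete (few distinct values, e.g. a binned pseudo-sample),
#' the null draws are binned onto the same number of equal-width cells so
#' that null and observed dips live on the same support structure. The null
#' table is seeded and memoised per configuration.
#'
#' @param x Numeric sample, `n >= 4`.
#' @param B Number of null resamples (default 2000).
#' @param seed Seed for the null table (default 1).
#' @param null_bins Number of cells the uniform null is discretized into;
#'   default: the number of distinct values of `x` when that is <= 512,
#'   otherwise continuous.
#' @return A [stat_result()] with statistic `dip`.
#' @export
dip_test <- function(x, B = 2000L, seed = 1L, null_bins = NULL) {
  x <- as.numeric(x[!is.na(x)])
  if (length(x) < 4) stop("dip test requires n >= 4")
  if (is.null(null_bins)) {
    kd <- length(unique(x))
    null_bins <- if (kd <= 512) kd else Inf
  }
  dip <- dip_stat(x)
  null_tab <- dip_null_table(length(x), B, seed, null_bins)
  p <- (1 + sum(null_tab >= dip - 1e-12)) / (B + 1)
  stat_result("dip", c(dip = dip), p, "greater", length(x),
              note = sprintf("Monte-Carlo null, B=%d, seed=%d", B, seed))
}

#' Expand a binned diurnal curve into a pseudo-sample
#'
#' The dip test needs raw samples; a 96-bin activity curve is expanded by
#' drawing bin midpoints (in hours) with probability proportional to the bin
#' mass.
#'
#' @param curve Nonnegative 96-bin curve.
#' @param draws Resolution of the pseudo-sample (default 10000).
#' @param seed Seed.
#' @return Numeric vector of `draws` hours in `[0, 24)`.
#' @export
expand_curve_sample <- function(curve, draws = 10000L, seed = 1L) {
  v <- curve_values(curve)
  if (any(v < 0) || all(v == 0)) stop("curve must be nonnegative with mass")
  mid <- time_grid() + 0.125
  with_seed(seed, sample(mid, draws, replace = TRUE, prob = v / sum(v)))
}
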