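#' Probability-density histogram with linear or logarithmic bins
#'
#' Each bin's height is its raw count divided by the total count and by the
#' bin width *on the original axis*, so the area under the histogram
#' integrates to 1 regardless of the bin scale. Log-scale bins are
#' geometrically spaced, the representation of choice for right-skewed
#' morphometric features.
#'
#' @param x positive sample (strictly positive when `scale = "log"`).
#' @param n_bins number of bins.
#' @param scale `"log"` or `"linear"`.
#' @return list of class `density_histogram`: `edges` (length n_bins + 1),
#'   `density`, `counts`, `scale`.
#' @export
density_histogram <- function(x, n_bins = 30, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("empty sample")
  if (scale == "log" && any(x <= 0))
    stop("log-scale histogram requires strictly positive data")
  rng <- range(x)
  if (rng[1] == rng[2]) { # single value: give it one sensible bin
    pad <- if (scale == "log") c(0.99, 1.01) else rng[1] * 0 + c(-0.5, 0.5)
    rng <- if (scale == "log") rng * pad else rng + pad
  }
  edges <- if (scale == "log")
    exp(seq(log(rng[1]), log(rng[2]), length.out = n_bins + 1))
  else seq(rng[1], rng[2], length.out = n_bins + 1)
  edges[1] <- edges[1] - abs(edges[1]) * 1e-12 - 1e-300
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  widths <- diff(edges)
  dens <- counts / (sum(counts) * widths)
  structure(list(edges = edges, density = dens, counts = counts,
                 scale = scale),
            class = "density_histogram")
}

#' Mann-Whitney U rank test
#'
#' U statistic on midranks. For small samples (`n_x + n_y <= 16`) the
#' two-sided p-value is exact, from the full permutation distribution of U
#' over group assignments (computed by a subset-sum count, so ties are
#' handled exactly); larger samples use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param x,y numeric samples.
#' @return list of class `spinemorph_test`: `name`, `statistic` (U of `x`),
#'   `p_value`, `n` (c(nx, ny)), `method` ("exact"/"normal"), `direction`
#'   (sign of the median shift x vs y).
#' @export
mann_whitney <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  m <- length(x); n <- length(y)
  if (m < 1 || n < 1) stop("both samples must be non-empty")
  r <- rank(c(x, y))   # midranks
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (m + n <= 16) {
    p <- mw_exact_p(r, m, u)
    method <- "exact"
  } else {
    N <- m + n
    mu <- m * n / 2
    ties <- table(r)
    tiecor <- sum(ties^3 - ties) / (N * (N - 1))
    sig <- sqrt(m * n / 12 * ((N + 1) - tiecor))
    z <- (abs(u - mu) - 0.5) / sig
    p <- 2 * stats::pnorm(-max(z, 0))
    method <- "normal"
  }
  structure(list(name = "Mann-Whitney U", statistic = u,
                 p_value = min(p, 1), n = c(m, n), method = method,
                 direction = sign(stats::median(x) - stats::median(y))),
            class = "spinemorph_test")
}

# Exact permutation p-value of U via the distribution of the doubled rank
# sum of a random size-m subset (doubling makes midranks integral).
mw_exact_p <- function(r, m, u_obs) {
  r2 <- as.integer(round(2 * r))
  N <- length(r2)
  total <- sum(r2)
  # dp[k+1, s+1] = number of size-k subsets with doubled rank sum s
  dp <- matrix(0, nrow = m + 1, ncol = total + 1)
  dp[1, 1] <- 1
  for (v in r2) {
    kmax <- m
    for (k in kmax:1) {
      nz <- which(dp[k, ] > 0)
      if (length(nz)) dp[k + 1, nz + v] <- dp[k + 1, nz + v] + dp[k, nz]
    }
  }
  counts <- dp[m + 1, ]
  sums2 <- which(counts > 0) - 1
  us <- sums2 / 2 - m * (m + 1) / 2
  mu <- m * (N - m) / 2
  dev <- abs(u_obs - mu)
  sum(counts[counts > 0][abs(us - mu) >= dev - 1e-9]) / sum(counts)
}

#' Hartigan's dip statistic
#'
#' Maximum distance between the empirical CDF and the closest unimodal CDF,
#' computed by greatest-convex-minorant / least-concave-majorant refinement
#' of the modal interval. Lies in `[1/(2n), 1/4]` for samples of distinct
#' values.
#'
#' @param x numeric sample, `n >= 2` (any order; sorted internally).
#' @return the dip statistic.
#' @export
dip_statistic <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("dip requires at least 2 observations")
  .dip_stat_cpp(sort(x))
}

#' Dip test of unimodality
#'
#' Bootstrap p-value against the uniform(0,1) null, the conventional
#' conservative reference: p is the fraction of `n_boot` uniform samples of
#' the same size whose dip is at least the observed dip.
#'
#' @param x numeric sample, `n >= 4`.
#' @param n_boot bootstrap replicates (a warning flag is set below 100).
#' @param seed integer seed for the bootstrap.
#' @return list of class `dip_result`: `statistic`, `p_value`, `n`,
#'   `n_boot`, `seed`, `low_boot` flag.
#' @export
dip_test <- function(x, n_boot = 2000, seed = 1L) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) stop("dip test requires n >= 4")
  stat <- dip_statistic(x)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  boots <- .dip_unif_boot_cpp(as.integer(n), as.integer(n_boot))
  structure(list(statistic = stat, p_value = mean(boots >= stat),
                 n = n, n_boot = n_boot, seed = as.integer(seed),
                 low_boot = n_boot < 100),
            class = "dip_result")
}

#' @exportS3Method base::print
print.dip_result <- function(x, ...) {
  cat(sprintf("Hartigan dip test: D = %.5f, p = %.4f (n = %d, %d boots%s)\n",
              x$statistic, x$p_value, x$n, x$n_boot,
              if (!is.null(x$projection_info)) ", projected" else ""))
  invisible(x)
}

# deterministic direction grids
directions_2d <- function(m) {
  th <- (seq_len(m) - 1) * pi / m
  cbind(cos(th), sin(th))
}

directions_3d <- function(m) {
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(m) - 1
  z <- (i + 0.5) / m          # hemisphere suffices: directions are axial
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(golden * i), r * sin(golden * i), z)
}

#' Projection-based dip test in 2D/3D
#'
#' The multidimensional extension used for joint unimodality screening of
#' morphometric feature pairs/triples: the statistic is the maximum 1D dip
#' over projections of the standardized sample onto a fixed direction grid
#' (half-turn angles in 2D, a Fibonacci hemisphere in 3D). The p-value is
#' calibrated by applying the identical max-over-directions procedure to
#' reference samples drawn from a unimodal multivariate Gaussian with the
#' data's mean and covariance, which absorbs the max-induced multiplicity.
#'
#' @param points n x 2 or n x 3 matrix, `n >= 10`.
#' @param n_directions number of projection directions (default 36 in 2D,
#'   64 in 3D).
#' @param n_boot reference replicates.
#' @param seed integer seed.
#' @return a `dip_result` with `projection_info` (directions, per-direction
#'   dips, `ridged` flag for a regularized covariance).
#' @export
dip_test_nd <- function(points, n_directions = NULL, n_boot = 2000,
                        seed = 1L) {
  P <- as.matrix(points)
  d <- ncol(P)
  if (!d %in% 2:3) stop("points must have 2 or 3 columns")
  P <- P[stats::complete.cases(P), , drop = FALSE]
  n <- nrow(P)
  if (n < 10) stop("dip_test_nd requires n >= 10")
  if (is.null(n_directions)) n_directions <- if (d == 2) 36 else 64
  dirs <- if (d == 2) directions_2d(n_directions) else
    directions_3d(n_directions)
  Z <- scale(P)
  Z[, !is.finite(colSums(Z))] <- 0
  max_dip <- function(M) max(apply(M %*% t(dirs), 2,
                                   function(p) .dip_stat_cpp(sort(p))))
  stat <- max_dip(Z)
  S <- stats::cov(Z)
  ridged <- FALSE
  if (!all(is.finite(S)) || det(S) < 1e-12) {
    S[!is.finite(S)] <- 0
    S <- S + diag(1e-6, d)
    ridged <- TRUE
  }
  ch <- chol(S)
  mu <- colMeans(Z)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null_stats <- vapply(seq_len(n_boot), function(b) {
    M <- matrix(stats::rnorm(n * d), n, d) %*% ch
    max_dip(sweep(M, 2, mu, "+"))
  }, numeric(1))
  per_dir <- apply(Z %*% t(dirs), 2, function(p) .dip_stat_cpp(sort(p)))
  structure(list(statistic = stat, p_value = mean(null_stats >= stat),
                 n = n, n_boot = n_boot, seed = as.integer(seed),
                 low_boot = n_boot < 100,
                 projection_info = list(directions = dirs,
                                        dips = per_dir, ridged = ridged)),
            class = "dip_result")
}

#' Spearman correlation with a Wald slope test
#'
#' Spearman's rho on midranks; the two-sided p-value is the Wald t-test for
#' zero slope of the rank-on-rank least-squares regression (t with n - 2
#' degrees of freedom).
#'
#' @param x,y paired samples, `n >= 3`.
#' @return `spinemorph_test` with `statistic` = rho.
#' @export
spearman_with_wald <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("correlation undefined for constant input")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  fit <- stats::lm.fit(cbind(1, rx), ry)
  se <- sqrt(sum(fit$residuals^2) / (n - 2) / sum((rx - mean(rx))^2))
  tstat <- fit$coefficients[2] / se
  p <- if (!is.finite(tstat)) 0 else 2 * stats::pt(-abs(tstat), n - 2)
  structure(list(name = "Spearman rho (Wald slope test)", statistic = rho,
                 p_value = p, n = n, method = "t", direction = sign(rho)),
            class = "spinemorph_test")
}

#' @exportS3Method base::print
print.spinemorph_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (%s)\n",
              x$name, x$statistic, x$p_value, x$method))
  invisible(x)
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "n.s.")))
}

#' Compare feature distributions between groups
#'
#' Per feature and pair of groups: medians, means, ranges, the Mann-Whitney
#' two-sided p, and the conventional significance stars (* / ** / *** at
#' 0.05 / 0.01 / 0.001).
#'
#' @param table data.frame of per-spine records.
#' @param grouping name of the factor column.
#' @param features character vector of numeric feature columns.
#' @return list with `summary` (per group x feature) and `tests`
#'   (per feature x group pair).
#' @export
compare_populations <- function(table, grouping, features) {
  if (!grouping %in% names(table)) stop("missing grouping column: ", grouping)
  miss <- setdiff(features, names(table))
  if (length(miss)) stop("missing feature column(s): ",
                         paste(miss, collapse = ", "))
  g <- factor(table[[grouping]])
  lev <- levels(droplevels(g))
  if (length(lev) < 2) stop("need at least 2 groups")
  summ <- do.call(rbind, lapply(features, function(f) {
    do.call(rbind, lapply(lev, function(l) {
      v <- table[[f]][g == l]
      v <- v[is.finite(v)]
      data.frame(feature = f, group = l, n = length(v),
                 median = stats::median(v), mean = mean(v),
                 min = min(v), max = max(v), stringsAsFactors = FALSE)
    }))
  }))
  prs <- utils::combn(lev, 2)
  tests <- do.call(rbind, lapply(features, function(f) {
    do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
      a <- table[[f]][g == prs[1, k]]
      b <- table[[f]][g == prs[2, k]]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) < 2 || length(b) < 2)
        stop("each group needs >= 2 observations for ", f)
      mw <- mann_whitney(a, b)
      data.frame(feature = f, group_a = prs[1, k], group_b = prs[2, k],
                 U = mw$statistic, p_value = mw$p_value,
                 stars = significance_stars(mw$p_value),
                 direction = mw$direction, stringsAsFactors = FALSE)
    }))
  }))
  list(summary = summ, tests = tests)
}
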