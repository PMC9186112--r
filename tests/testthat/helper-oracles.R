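# Brute-force oracle for Hartigan's dip statistic, independent of the
# package implementation.
#
# dip(x) = min t such that some unimodal CDF G stays within t of the ECDF.
# For a fixed mode placement the existence of G is a band-feasibility
# question over the distinct values v_i with ECDF corners lo_i (left limit)
# and hi_i: a continuous G needs G(v_i) in [hi_i - t, lo_i + t]; G is convex
# left of the mode, concave right of it, with a possible atom exactly at the
# mode. Three config families are enumerated: mode in the open gap between
# v_j and v_{j+1} (slope-coupled crossing), mode before/after all data, and
# an atom exactly at a data value (band at that value relaxes to the
# one-sided constraints). Each family's minimal t is found by bisection on
# the feasibility predicate; inner extremal values (minimal convex end
# value, minimal convex linear extension, and their concave mirrors) are
# themselves bisections. Everything rests on two hull facts: a convex
# function fitting below u and above l exists iff the greatest convex
# minorant of u dominates l, and appending a virtual point caps an end value
# or an extension.

.oracle_eps <- 1e-12

# greatest convex minorant of points (x, y), evaluated at every x
oracle_gcm <- function(x, y) {
  n <- length(x)
  hull <- 1L
  for (k in seq_len(n)[-1]) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      if ((x[k] - x[a]) * (y[b] - y[a]) - (y[k] - y[a]) * (x[b] - x[a]) >= 0)
        hull <- hull[-length(hull)]
      else break
    }
    hull <- c(hull, k)
  }
  out <- numeric(n)
  for (s in seq_len(length(hull) - 1)) {
    a <- hull[s]; b <- hull[s + 1]
    sl <- (y[b] - y[a]) / (x[b] - x[a])
    idx <- a:b
    out[idx] <- y[a] + sl * (x[idx] - x[a])
  }
  if (length(hull) == 1) out[1] <- y[1]
  out
}

oracle_lcm <- function(x, y) -oracle_gcm(x, -y)

# exists convex nondecreasing g with l <= g <= u on knots x?
convex_feasible <- function(x, l, u) {
  if (any(l > u + .oracle_eps)) return(FALSE)
  all(oracle_gcm(x, u) >= l - .oracle_eps)
}

concave_feasible <- function(x, l, u) convex_feasible(-rev(x), rev(1 - u), rev(1 - l))

# minimal achievable end value g(x_last) over feasible convex g
convex_min_end <- function(x, l, u) {
  if (!convex_feasible(x, l, u)) return(Inf)
  lo <- l[length(l)]; hi <- u[length(u)]
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    u2 <- u; u2[length(u2)] <- min(u2[length(u2)], mid)
    if (convex_feasible(x, l, u2)) hi <- mid else lo <- mid
  }
  hi
}

# minimal achievable linear extension of g's last segment to x_ext
convex_min_ext <- function(x, l, u, x_ext) {
  if (!convex_feasible(x, l, u)) return(Inf)
  lo <- 0; hi <- 2
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    x2 <- c(x, x_ext); u2 <- c(u, mid); l2 <- c(l, -Inf)
    if (convex_feasible(x2, l2, u2)) hi <- mid else lo <- mid
  }
  hi
}

concave_max_start <- function(x, l, u) {
  v <- convex_min_end(-rev(x), rev(1 - u), rev(1 - l))
  1 - v
}

concave_max_ext <- function(x, l, u, x_ext) {
  v <- convex_min_ext(-rev(x), rev(1 - u), rev(1 - l), -x_ext)
  1 - v
}

# feasibility of dip-band width t for one sample (distinct values + corners)
dip_bands_feasible <- function(v, lo_c, hi_c, t) {
  m <- length(v)
  l <- pmax(0, hi_c - t)
  u <- pmin(1, lo_c + t)
  # mode in the open gap after index j (0 = before all, m = after all)
  for (j in 0:m) {
    left_ok <- j == 0 || convex_feasible(v[1:j], l[1:j], u[1:j])
    right_ok <- j == m ||
      concave_feasible(v[(j + 1):m], l[(j + 1):m], u[(j + 1):m])
    if (!left_ok || !right_ok) next
    if (j == 0 || j == m) return(TRUE)
    # crossing: rise must cover the smaller of the two boundary slopes
    # extended across the gap (an atom at the mode can only add rise)
    g_ext <- if (j == 1) l[1] else
      convex_min_ext(v[1:j], l[1:j], u[1:j], v[j + 1])
    h_max <- concave_max_start(v[(j + 1):m], l[(j + 1):m], u[(j + 1):m])
    if (g_ext <= h_max + .oracle_eps) return(TRUE)
    h_ext <- if (j == m - 1) u[m] else
      concave_max_ext(v[(j + 1):m], l[(j + 1):m], u[(j + 1):m], v[j])
    g_min <- convex_min_end(v[1:j], l[1:j], u[1:j])
    if (h_ext >= g_min - .oracle_eps) return(TRUE)
  }
  # atom exactly at value j: one-sided bands at the mode knot
  for (j in 1:m) {
    ll <- l; uu <- u
    lL <- c(if (j > 1) l[seq_len(j - 1)] else numeric(0), max(0, lo_c[j] - t))
    uL <- c(if (j > 1) u[seq_len(j - 1)] else numeric(0), min(1, lo_c[j] + t))
    lR <- c(max(0, hi_c[j] - t), if (j < m) l[(j + 1):m] else numeric(0))
    uR <- c(min(1, hi_c[j] + t), if (j < m) u[(j + 1):m] else numeric(0))
    if (!convex_feasible(v[1:j], lL, uL)) next
    if (!concave_feasible(v[j:m], lR, uR)) next
    gmin <- convex_min_end(v[1:j], lL, uL)
    hmax <- concave_max_start(v[j:m], lR, uR)
    if (gmin <= hmax + .oracle_eps) return(TRUE)
  }
  FALSE
}

# the oracle itself
dip_oracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  v <- unique(x)
  m <- length(v)
  if (m == 1) return(0.5 / n)
  cnt <- as.numeric(table(match(x, v)))
  hi_c <- cumsum(cnt) / n
  lo_c <- c(0, hi_c[-m])
  lo <- 0; hi <- 0.5
  for (it in 1:48) {
    mid <- (lo + hi) / 2
    if (dip_bands_feasible(v, lo_c, hi_c, mid)) hi <- mid else lo <- mid
  }
  hi
}
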