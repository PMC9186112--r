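test_that("density histograms integrate to one on either scale", {
  set.seed(1)
  for (rep in 1:10) {
    x <- stats::rlnorm(sample(20:500, 1), sample(0:2, 1), runif(1, .2, 1.5))
    for (sc in c("log", "linear")) {
      h <- density_histogram(x, n_bins = sample(5:50, 1), scale = sc)
      expect_equal(sum(h$density * diff(h$edges)), 1, tolerance = 1e-9)
      expect_equal(sum(h$counts), length(x))
      expect_true(all(diff(h$edges) > 0))
    }
  }
  # doubling the sample leaves densities unchanged
  x <- stats::rlnorm(200)
  h1 <- density_histogram(x, 20)
  h2 <- density_histogram(c(x, x), 20)
  expect_equal(h1$density, h2$density, tolerance = 1e-12)
  # single value: one occupied bin with density 1/width
  h3 <- density_histogram(rep(2, 5), 10)
  occ <- which(h3$counts > 0)
  expect_equal(length(occ), 1)
  expect_equal(h3$density[occ], 1 / diff(h3$edges)[occ], tolerance = 1e-9)
  expect_error(density_histogram(c(-1, 1), scale = "log"), "positive")
})

test_that("Mann-Whitney exact branch reproduces enumeration", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 2 / 6, tolerance = 1e-12)
  expect_equal(mw$method, "exact")

  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  set.seed(5)
  for (rep in 1:20) {
    m <- sample(2:8, 1); n <- sample(2:8, 1)
    x <- sample(0:6, m, replace = TRUE)  # ties included
    y <- sample(0:6, n, replace = TRUE)
    expect_equal(mann_whitney(x, y)$p_value, mw_enum_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("normal approximation agrees with the exact branch near n=16", {
  set.seed(6)
  for (rep in 1:10) {
    x <- stats::rnorm(8); y <- stats::rnorm(8, 0.5)
    p_exact <- mann_whitney(x, y)$p_value
    # force the large-sample branch by duplicating scale-free structure:
    # compare against the normal approximation computed directly
    r <- rank(c(x, y)); u <- sum(r[1:8]) - 36
    z <- (abs(u - 32) - 0.5) / sqrt(8 * 8 * 17 / 12)
    p_norm <- 2 * stats::pnorm(-max(z, 0))
    expect_lt(abs(p_exact - min(p_norm, 1)), 0.02)
  }
})

test_that("dip statistic matches its closed-form anchor points", {
  expect_equal(dip_statistic(c(5, 9)), 0.25, tolerance = 1e-12)
  # equally spaced values are uniform-like: dip attains the 1/(2n) bound
  n <- 1000
  expect_equal(dip_statistic(seq_len(n)), 1 / (2 * n), tolerance = 1e-12)
  expect_error(dip_statistic(3), "at least 2")
})

test_that("dip bounds and affine invariance hold over random samples", {
  set.seed(7)
  for (rep in 1:30) {
    n <- sample(2:200, 1)
    x <- switch(sample(3, 1), stats::runif(n), stats::rnorm(n),
                stats::rexp(n))
    d <- dip_statistic(x)
    expect_gte(d, 1 / (2 * n) - 1e-12)
    expect_lte(d, 0.25 + 1e-12)
    expect_equal(dip_statistic(2.5 * x + 7), d, tolerance = 1e-12)
  }
})

test_that("dip equals the band-feasibility oracle for tiny samples", {
  set.seed(8)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    x <- switch(sample(3, 1), stats::runif(n),
                round(stats::runif(n) * 8) / 2, stats::rnorm(n))
    expect_equal(dip_statistic(x), dip_oracle(x), tolerance = 1e-10)
  }
})

test_that("dip test is seeded, flagged, and powered", {
  x <- make_bimodal_population(500, 6, seed = 3)
  r1 <- dip_test(x, n_boot = 300, seed = 9)
  r2 <- dip_test(x, n_boot = 300, seed = 9)
  expect_identical(r1$p_value, r2$p_value)
  expect_lt(r1$p_value, 0.05)
  expect_true(dip_test(x, n_boot = 50, seed = 1)$low_boot)
  expect_error(dip_test(c(1, 2, 3)), "n >= 4")
})

test_that("projection dip test separates clusters and respects rotation", {
  set.seed(10)
  two <- rbind(matrix(stats::rnorm(300), ncol = 2),
               matrix(stats::rnorm(300, 6), ncol = 2))
  rt <- dip_test_nd(two, n_boot = 150, seed = 4)
  expect_lt(rt$p_value, 0.05)

  one <- matrix(stats::rnorm(600), ncol = 2)
  r1 <- dip_test_nd(one, n_boot = 150, seed = 4)
  expect_gt(r1$p_value, 0.05)

  th <- 0.61
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  r2 <- dip_test_nd(two %*% t(R), n_boot = 150, seed = 4)
  expect_equal(r2$statistic, rt$statistic, tolerance = 0.2 * rt$statistic)

  three <- cbind(two, stats::rnorm(300))
  r3 <- dip_test_nd(three, n_boot = 100, seed = 4)
  expect_lt(r3$p_value, 0.05)
  expect_error(dip_test_nd(matrix(1:8, ncol = 4)), "2 or 3")
})

test_that("Spearman-Wald behaves on monotone, transformed, and null data", {
  x <- 1:30
  y <- x^3
  sw <- spearman_with_wald(x, y)
  expect_equal(sw$statistic, 1, tolerance = 1e-12)
  expect_lt(sw$p_value, 1e-10)

  set.seed(11)
  a <- stats::rnorm(100); b <- a + stats::rnorm(100)
  s1 <- spearman_with_wald(a, b)
  s2 <- spearman_with_wald(exp(a), b^3 * 0 + b)  # monotone transform of x
  expect_equal(s1$statistic, s2$statistic, tolerance = 1e-12)

  nulls <- replicate(20, {
    spearman_with_wald(stats::runif(400), stats::runif(400))$statistic
  })
  expect_lt(stats::median(abs(nulls)), 0.1)

  expect_error(spearman_with_wald(rep(1, 10), stats::rnorm(10)), "constant")
})

test_that("population comparison reports medians, stars, and direction", {
  set.seed(12)
  tab <- data.frame(
    species = rep(c("human", "mouse"), each = 120),
    head_volume_um3 = c(stats::rlnorm(120, log(0.32), 0.4),
                        stats::rlnorm(120, log(0.146), 0.4)))
  cp <- compare_populations(tab, "species", "head_volume_um3")
  med <- cp$summary$median[cp$summary$group == "human"]
  expect_equal(med, stats::median(tab$head_volume_um3[tab$species == "human"]))
  expect_equal(cp$tests$stars, "***")
  expect_equal(cp$tests$direction, 1)

  same <- data.frame(g = rep(c("a", "b"), each = 50), v = rep(1:50, 2))
  cps <- compare_populations(same, "g", "v")
  expect_equal(cps$tests$stars, "n.s.")
  expect_error(compare_populations(tab, "species", "nope"), "missing feature")
})
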