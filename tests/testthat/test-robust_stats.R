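# independent evaluation of the Beta-weight formula for the HD estimator
hd_oracle <- function(x, q) {
  n <- length(x)
  i <- seq_len(n)
  w <- pbeta(i / n, (n + 1) * q, (n + 1) * (1 - q)) -
    pbeta((i - 1) / n, (n + 1) * q, (n + 1) * (1 - q))
  sum(w * sort(x))
}

test_that("Harrell-Davis estimator matches the Beta-weight formula", {
  expect_equal(harrell_davis(c(1, 2, 3), 0.5), 2, tolerance = 1e-12)
  expect_equal(harrell_davis(c(5, 5, 5, 5), 0.2), 5, tolerance = 1e-12)
  expect_equal(harrell_davis(c(1, 2, 3, 4), 0.5), 2.5, tolerance = 1e-12)
  set.seed(401)
  for (r in 1:20) {
    x <- rnorm(sample(5:60, 1))
    q <- runif(1, 0.05, 0.95)
    expect_equal(harrell_davis(x, q), hd_oracle(x, q), tolerance = 1e-12)
  }
  expect_error(harrell_davis(1:5, 0), "strictly in")
  expect_error(harrell_davis(1:5, 1), "strictly in")
})

test_that("HD weights sum to one; estimator is monotone and equivariant", {
  set.seed(402)
  for (n in c(4L, 11L, 50L)) {
    for (q in c(0.1, 0.5, 0.9)) {
      expect_equal(sum(hd_weights(n, q)), 1, tolerance = 1e-12)
    }
  }
  x <- rnorm(40)
  qs <- seq(0.1, 0.9, by = 0.1)
  est <- vapply(qs, function(q) harrell_davis(x, q), numeric(1))
  expect_true(all(diff(est) >= 0))
  # location-scale equivariance
  expect_equal(harrell_davis(3 * x + 7, 0.3),
               3 * harrell_davis(x, 0.3) + 7, tolerance = 1e-10)
})

test_that("Bayesian bootstrap HDI is deterministic and degenerates correctly", {
  x <- c(0.3, -1.2, 0.5, 2.1, -0.4, 0.9, -0.7, 1.4)
  a <- bayes_boot_hdi(x, n_draws = 400, seed = 21)
  b <- bayes_boot_hdi(x, n_draws = 400, seed = 21)
  expect_identical(a, b)
  expect_lte(a$lower, a$estimate)
  expect_gte(a$upper, a$estimate)
  const <- bayes_boot_hdi(rep(2.5, 10), n_draws = 200, seed = 1)
  expect_equal(const$lower, 2.5)
  expect_equal(const$upper, 2.5)
  expect_equal(const$estimate, 2.5)
  expect_warning(bayes_boot_hdi(rnorm(10), n_draws = 50, seed = 1),
                 "unstable")
  expect_error(bayes_boot_hdi(rnorm(10), level = 1.2), "level")
})

test_that("Bayesian bootstrap HDI covers the population median", {
  set.seed(403)
  covered <- replicate(200, {
    x <- rnorm(60)
    h <- bayes_boot_hdi(x, n_draws = 300, seed = sample.int(1e6, 1))
    h$lower <= 0 && h$upper >= 0
  })
  expect_gte(mean(covered), 0.9)  # nominal 0.95
})

test_that("shift function differences follow HD location equivariance", {
  x <- rnorm(50, sd = 2)
  # identical samples: all nine differences exactly zero
  sf0 <- shift_function(x, x, n_boot = 100, seed = 2)
  expect_identical(sf0$difference, rep(0, 9))
  expect_true(all(sf0$lower <= sf0$difference & sf0$difference <= sf0$upper))
  # pure location shift: every decile difference is exactly -1 (x - y)
  sf1 <- shift_function(x, x + 1, n_boot = 100, seed = 2)
  expect_equal(sf1$difference, rep(-1, 9), tolerance = 1e-10)
  # determinism
  expect_identical(shift_function(x, x + 1, n_boot = 100, seed = 2), sf1)
  expect_error(shift_function(rnorm(5), rnorm(50)), "at least 10")
})

test_that("KS statistic equals the ECDF supremum and its invariances", {
  expect_identical(ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(ks_statistic(1:5, 6:10), 1)
  expect_equal(ks_statistic(c(1, 3), c(2, 4)), 0.5)
  set.seed(404)
  for (r in 1:10) {
    x <- rnorm(30)
    y <- rnorm(45, mean = 0.5)
    # cross-check against the base two-sample test statistic
    expect_equal(ks_statistic(x, y),
                 unname(suppressWarnings(stats::ks.test(x, y)$statistic)),
                 tolerance = 1e-12)
    # invariance under a common strictly increasing transform
    expect_equal(ks_statistic(exp(x), exp(y)), ks_statistic(x, y))
  }
})

test_that("KS critical value reproduces its closed form and monotonicity", {
  expect_equal(round(ks_critical(0.001, 49, 50), 2), 0.39)
  n <- 80
  expect_equal(ks_critical(0.05, n, n),
               sqrt(-log(0.025) / 2) * sqrt(2 / n), tolerance = 1e-12)
  expect_lt(ks_critical(0.05, 40, 40), ks_critical(0.001, 40, 40))
  expect_error(ks_critical(0, 10, 10), "alpha")
  expect_error(ks_critical(0.05, 0, 10), "sizes")
})

test_that("Holm adjustment dominates raw p-values and preserves order", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  p <- c(0.5, 0.6, 0.9)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p) && all(adj <= 1))
  expect_identical(order(adj), order(p))
  expect_error(holm_adjust(c(0.1, 1.2)), "within")
})

test_that("covariate-adjusted group test keeps its type-I level and power", {
  set.seed(405)
  # null: permuted groups, moderate simulation count for the module test
  rej <- replicate(300, {
    y <- rnorm(60)
    g <- sample(rep(c("a", "b"), 30))
    covs <- data.frame(age = runif(60, 20, 60))
    group_covariate_test(y, g, covs) < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
  # strong injected shift
  y <- c(rnorm(30), rnorm(30, mean = 3))
  g <- rep(c("a", "b"), each = 30)
  expect_lt(group_covariate_test(y, g), 0.001)
  # covariate collinear with group
  covs <- data.frame(bad = as.numeric(g == "a"))
  expect_error(group_covariate_test(y, g, covs), "collinear")
})

test_that("omnibus multivariate variant accepts a matrix response", {
  set.seed(406)
  y <- matrix(rnorm(60 * 3), ncol = 3)
  g <- rep(c("a", "b"), each = 30)
  y[g == "b", 2] <- y[g == "b", 2] + 2
  p <- group_covariate_test(y, g, data.frame(age = rnorm(60)),
                            type = "pillai")
  expect_lt(p, 0.001)
  expect_error(group_covariate_test(rnorm(10), rep(c("a", "b"), 5),
                                    type = "pillai"), "matrix response")
})

test_that("pairwise-distance outlier rule flags gross points only", {
  expect_identical(flag_outliers(rep(3, 6)), rep(FALSE, 6))
  flags <- flag_outliers(c(0, 0.1, 0.2, 0.15, 100))
  expect_identical(flags, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # affine invariance
  x <- c(rnorm(20), 15)
  expect_identical(flag_outliers(5 * x - 3), flag_outliers(x))
  expect_error(flag_outliers(c(1, 2, 3)), "at least 4")
  # MAD-median alternative agrees on the gross case
  expect_identical(flag_outliers(c(0, 0.1, 0.2, 0.15, 100), method = "mad"),
                   c(FALSE, FALSE, FALSE, FALSE, TRUE))
})
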