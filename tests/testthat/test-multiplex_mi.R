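test_that("build_multiplex maps columns to layers in order", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(3, 1, 2, 4), c = c(1, 2, 3, 4))
  mvg <- build_multiplex(x, method = "natural",
                         network_labels = c("N1", "N1", "N2"))
  expect_s3_class(mvg, "multiplex_vg")
  expect_length(mvg$layers, 3L)
  expect_identical(mvg$layers[[1L]]$edges, nvg_naive(x[, 1L])$edges)
  expect_identical(mvg$layers[[2L]]$edges, nvg_naive(x[, 2L])$edges)
  # identical columns give identical layers
  expect_identical(mvg$layers[[1L]]$edges, mvg$layers[[3L]]$edges)
  # T = 2: every layer is the single chain edge
  tiny <- build_multiplex(matrix(rnorm(4), nrow = 2), method = "horizontal")
  expect_identical(unname(tiny$layers[[1L]]$edges), cbind(1L, 2L))
})

test_that("build_multiplex validates its inputs", {
  expect_error(build_multiplex(matrix(c(1, NA, 3, 4), 2)), "non-finite")
  expect_error(build_multiplex(matrix(1, 1, 3)), "at least 2 time points")
  expect_error(build_multiplex(matrix(rnorm(8), 4), roi_labels = "one"),
               "one entry per column")
  expect_error(build_multiplex("no"), "numeric matrix")
})

test_that("degree_pmf is the exact plug-in distribution", {
  pmf <- degree_pmf(nvg_naive(c(1, 2, 1, 2)))  # chain-like degrees
  expect_equal(sum(pmf$prob), 1, tolerance = 1e-12)
  expect_identical(pmf$degree, sort(unique(degree_sequence(nvg_naive(c(1, 2, 1, 2))))))
  pmf2 <- degree_pmf(hvg(c(1, 3, 2, 4)))
  expect_equal(pmf2$prob[match(c(1L, 2L, 3L), pmf2$degree)],
               c(0.25, 0.5, 0.25))
  # complete graph on 3 nodes: single support point
  pmf3 <- degree_pmf(nvg_naive(c(0, 1, 4)))
  expect_identical(pmf3$degree, 2L)
  expect_equal(pmf3$prob, 1)
})

test_that("interlayer MI matches the displayed double-sum on paired degrees", {
  set.seed(201)
  for (r in 1:20) {
    a <- visibility_graph(rnorm(60), sample(c("natural", "horizontal"), 1L))
    b <- visibility_graph(rnorm(60), sample(c("natural", "horizontal"), 1L))
    expect_equal(interlayer_mi(a, b),
                 mi_brute(degree_sequence(a), degree_sequence(b)),
                 tolerance = 1e-12)
    # symmetry and non-negativity
    expect_gte(interlayer_mi(a, b), 0)
    expect_equal(interlayer_mi(a, b), interlayer_mi(b, a))
  }
})

test_that("MI of a layer with itself is its degree entropy", {
  # chain degrees (1, 2, 2, 1): PMF {1: 1/2, 2: 1/2}, entropy ln 2
  chain <- nvg_naive(c(1, 2, 3, 4))
  expect_equal(interlayer_mi(chain, chain), log(2), tolerance = 1e-12)
  set.seed(202)
  for (r in 1:10) {
    g <- nvg_fast(rnorm(100))
    expect_equal(interlayer_mi(g, g), pmf_entropy(degree_pmf(g)),
                 tolerance = 1e-12)
  }
})

test_that("degenerate (constant-degree) layers carry zero information", {
  complete <- nvg_naive(c(0, 1, 4, 9))   # all degrees 3
  other <- nvg_naive(c(3, 1, 2, 5))
  expect_identical(interlayer_mi(complete, other), 0)
  expect_identical(interlayer_mi(complete, complete), 0)
  # paired degree sequences whose joint factorizes: chain vs itself is
  # dependent, but a hand-built independent pairing gives exactly 0
  expect_identical(mi_brute(c(1, 2, 2, 1), c(1, 2, 1, 2)), 0)
})

test_that("MI respects the requested logarithm base", {
  g <- hvg(c(1, 3, 2, 4))
  expect_equal(interlayer_mi(g, g, base = 2),
               interlayer_mi(g, g) / log(2), tolerance = 1e-12)
})

test_that("mi_matrix is symmetric with entropies on the diagonal", {
  set.seed(203)
  x <- matrix(rnorm(150 * 6), ncol = 6)
  mvg <- build_multiplex(x, network_labels = rep(c("A", "B"), each = 3))
  m <- mi_matrix(mvg)
  expect_identical(unclass(m), t(unclass(m)))
  for (j in 1:6) {
    expect_equal(m[j, j], pmf_entropy(degree_pmf(mvg$layers[[j]])),
                 tolerance = 1e-12)
  }
  expect_true(all(m >= 0))
})

test_that("layer-size mismatch is refused", {
  expect_error(interlayer_mi(hvg(rnorm(10)), hvg(rnorm(12))),
               "different node counts")
})

test_that("network averages use unordered off-diagonal pairs only", {
  # three identical layers: every off-diagonal entry equals the shared
  # entropy, so the network average does too
  x <- matrix(rep(c(3, 1, 4, 1, 5, 9, 2, 6), 3), ncol = 3)
  m <- mi_matrix(build_multiplex(x, network_labels = rep("net", 3)))
  expect_equal(network_avg_mi(m, "net"), m[1, 1], tolerance = 1e-12)

  # hand-built matrix: mean of the three upper-triangle entries
  fake <- matrix(c(9, 0.1, 0.2, 0.1, 9, 0.3, 0.2, 0.3, 9), 3, 3)
  fake <- structure(fake, network_labels = rep("g", 3),
                    method = "natural", log_base = exp(1), n_time = 10,
                    class = c("mi_matrix", "matrix", "array"))
  expect_equal(network_avg_mi(fake, "g"), 0.2, tolerance = 1e-12)
  # agreement with direct summation over the strictly-upper block
  block <- unclass(fake)
  expect_equal(network_avg_mi(fake, "g"),
               sum(block[upper.tri(block)]) / 3, tolerance = 1e-12)

  # two-ROI network: the single off-diagonal entry
  two <- structure(matrix(c(1, 0.4, 0.4, 1), 2),
                   network_labels = c("h", "h"), method = "natural",
                   log_base = exp(1), n_time = 10,
                   class = c("mi_matrix", "matrix", "array"))
  expect_equal(network_avg_mi(two, "h"), 0.4)

  expect_error(network_avg_mi(fake, "nope"), "unknown network")
  singleton <- structure(diag(2), network_labels = c("a", "b"),
                         method = "natural", log_base = exp(1), n_time = 5,
                         class = c("mi_matrix", "matrix", "array"))
  expect_error(network_avg_mi(singleton, "a"), "single ROI")
})

test_that("independent long layers share less information than a layer with itself", {
  set.seed(204)
  x <- matrix(rnorm(2 * 10000), ncol = 2)
  m <- mi_matrix(build_multiplex(x, method = "horizontal"))
  expect_lt(m[1, 2], m[1, 1])
  expect_lt(m[1, 2], m[2, 2])
})

test_that("network_mi_profile covers exactly the networks with >= 2 ROIs", {
  x <- matrix(rnorm(100 * 5), ncol = 5)
  mvg <- build_multiplex(x, network_labels = c("A", "A", "B", "B", "C"))
  prof <- network_mi_profile(mi_matrix(mvg))
  expect_identical(names(prof), c("A", "B"))  # C is a singleton
  expect_equal(prof[["A"]], network_avg_mi(mi_matrix(mvg), "A"))
})
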