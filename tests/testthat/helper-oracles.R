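# Independent brute-force oracles: both evaluate the visibility criteria
# literally, pair by pair, checking every intermediate point. Deliberately
# naive (O(N^3)) and independent of the package's constructions.

nvg_brute_edges <- function(y) {
  n <- length(y)
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ks <- if (j - i > 1L) (i + 1L):(j - 1L) else integer(0)
      if (!length(ks) ||
          all(y[ks] < y[i] + (y[j] - y[i]) * (ks - i) / (j - i))) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  do.call(rbind, out)
}

hvg_brute_edges <- function(y) {
  n <- length(y)
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ks <- if (j - i > 1L) (i + 1L):(j - 1L) else integer(0)
      if (!length(ks) || all(y[ks] < min(y[i], y[j]))) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  do.call(rbind, out)
}

edge_keys <- function(g) {
  paste(g$edges[, 1L], g$edges[, 2L], sep = "-")
}

# random series of assorted shapes, incl. the degenerate ones that
# stress tie handling
random_series <- function(n, kind = c("gaussian", "uniform", "constant",
                                      "monotone", "tied")) {
  kind <- match.arg(kind)
  switch(kind,
         gaussian = rnorm(n),
         uniform = runif(n),
         constant = rep(runif(1), n),
         monotone = sort(rnorm(n)),
         tied = sample(1:3, n, replace = TRUE))
}

series_kinds <- c("gaussian", "uniform", "constant", "monotone", "tied")

expect_same_edges <- function(a, b) {
  expect_identical(a$edges, b$edges)
}

# interlayer MI evaluated straight from the displayed double sum over the
# joint/marginal plug-in distributions (independent of the package kernel)
mi_brute <- function(ka, kb) {
  n <- length(ka)
  total <- 0
  for (u in unique(ka)) {
    for (v in unique(kb)) {
      pj <- sum(ka == u & kb == v) / n
      if (pj > 0) {
        total <- total + pj * log(pj / ((sum(ka == u) / n) * (sum(kb == v) / n)))
      }
    }
  }
  total
}
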