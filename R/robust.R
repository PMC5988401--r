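check_sample <- function(x, min_n = 1L, name = "sample") {
  if (!is.numeric(x) || length(x) < min_n) {
    stop(name, " must be numeric with at least ", min_n, " observation(s)",
         call. = FALSE)
  }
  if (any(!is.finite(x))) stop("non-finite values in ", name, call. = FALSE)
  as.double(x)
}

#' Harrell-Davis quantile weights
#'
#' Weight of the i-th order statistic (i = 1..n) for the q-th quantile:
#' w_i = I(i/n; a, b) - I((i-1)/n; a, b), with I the regularized
#' incomplete beta function, a = (n+1) q and b = (n+1)(1-q). The weights
#' are a proper convex combination (they sum to 1).
#'
#' @param n sample size.
#' @param q quantile in (0, 1).
#' @return numeric vector of n weights.
#' @export
hd_weights <- function(n, q) {
  if (q <= 0 || q >= 1) stop("q must lie strictly in (0, 1)", call. = FALSE)
  a <- (n + 1) * q
  b <- (n + 1) * (1 - q)
  diff(pbeta((0:n) / n, a, b))
}

#' Harrell-Davis quantile estimator
#'
#' Distribution-free quantile estimate as a Beta-weighted linear
#' combination of all order statistics (see [hd_weights()]). Smooth in
#' the data, location-scale equivariant, and monotone in q.
#'
#' @param x numeric sample (n >= 1, finite).
#' @param q quantile in (0, 1); default 0.5 (the HD median).
#' @return scalar estimate.
#' @examples
#' harrell_davis(c(1, 2, 3, 4), 0.5) # 2.5
#' @export
harrell_davis <- function(x, q = 0.5) {
  x <- check_sample(x)
  sum(hd_weights(length(x), q) * sort(x))
}

# HD deciles of many samples at once: rows of `sorted` are sorted samples,
# W is the 9 x n decile-weight matrix; returns 9 x nrow matrix
hd_decile_matrix <- function(n) {
  t(vapply(seq(0.1, 0.9, by = 0.1), function(q) hd_weights(n, q),
           numeric(n)))
}

# weighted HD quantile: observation weights w (a probability vector over
# the sorted sample) replace the uniform 1/n steps in the Beta integral
hd_weighted <- function(x_sorted, w, q) {
  a <- (length(x_sorted) + 1) * q
  b <- (length(x_sorted) + 1) * (1 - q)
  s <- cumsum(w)
  s[length(s)] <- 1  # guard rounding
  sum(diff(pbeta(c(0, s), a, b)) * x_sorted)
}

#' Bayesian bootstrap highest-density interval for the HD median
#'
#' Each draw reweights the observations with flat-Dirichlet weights and
#' evaluates the weighted Harrell-Davis median; the interval is the
#' narrowest one containing `level` of the draws (highest-density
#' interval). The point estimate is the HD median of the original sample.
#' Deterministic given `seed`.
#'
#' @param x numeric sample, n >= 2.
#' @param level interval mass in (0, 1); default 0.95.
#' @param n_draws number of Dirichlet draws; default 2000 (a warning is
#'   signaled below 100, where the HDI is unstable).
#' @param seed integer seed.
#' @param q quantile whose HD estimate is bootstrapped; default 0.5.
#' @return list with `estimate`, `lower`, `upper`, `level`, `n_draws`,
#'   `seed`.
#' @export
bayes_boot_hdi <- function(x, level = 0.95, n_draws = 2000L, seed = 1L,
                           q = 0.5) {
  x <- check_sample(x, min_n = 2L)
  if (level <= 0 || level >= 1) {
    stop("level must lie strictly in (0, 1)", call. = FALSE)
  }
  if (n_draws < 100L) {
    warning("n_draws < 100: highest-density interval will be unstable")
  }
  xs <- sort(x)
  n <- length(xs)
  set.seed(seed)
  draws <- vapply(seq_len(n_draws), function(d) {
    g <- rexp(n)
    hd_weighted(xs, g / sum(g), q)
  }, numeric(1))
  sorted <- sort(draws)
  k <- ceiling(level * n_draws)
  if (k >= n_draws) {
    lo <- sorted[1L]
    hi <- sorted[n_draws]
  } else {
    width <- sorted[(k + 1L):n_draws] - sorted[seq_len(n_draws - k)]
    at <- which.min(width)
    lo <- sorted[at]
    hi <- sorted[at + k]
  }
  list(estimate = harrell_davis(x, q), lower = lo, upper = hi,
       level = level, n_draws = as.integer(n_draws), seed = as.integer(seed))
}

#' Shift function between two independent samples
#'
#' For each decile q in 0.1..0.9 the difference of the Harrell-Davis
#' decile estimates (convention: x - y) with simultaneous confidence
#' bounds: difference +/- c * sqrt(SE_x^2 + SE_y^2), where the SEs are
#' bootstrap standard errors of each group's HD deciles and
#' c = 80.1/min(n_x, n_y)^2 + 2.73 is Wilcox's calibration keeping the
#' familywise type-I error of the nine intervals near 0.05 for
#' independent groups. Deterministic given `seed`.
#'
#' @param x,y numeric samples, each n >= 10.
#' @param n_boot bootstrap replicates per group; default 2000.
#' @param seed integer seed.
#' @return object of class `shift_function`: data.frame with columns
#'   `q`, `decile_x`, `decile_y`, `difference`, `lower`, `upper`, plus
#'   attributes `n_x`, `n_y`, `n_boot`, `seed`, `crit`.
#' @export
shift_function <- function(x, y, n_boot = 2000L, seed = 1L) {
  x <- check_sample(x, min_n = 10L, "x")
  y <- check_sample(y, min_n = 10L, "y")
  qs <- seq(0.1, 0.9, by = 0.1)
  dx <- vapply(qs, function(q) harrell_davis(x, q), numeric(1))
  dy <- vapply(qs, function(q) harrell_davis(y, q), numeric(1))
  seeds <- derive_seeds(seed, 2L)
  se_x <- boot_decile_se(x, n_boot, seeds[1L])
  se_y <- boot_decile_se(y, n_boot, seeds[2L])
  crit <- 80.1 / min(length(x), length(y))^2 + 2.73
  se <- sqrt(se_x^2 + se_y^2)
  out <- data.frame(q = qs, decile_x = dx, decile_y = dy,
                    difference = dx - dy,
                    lower = dx - dy - crit * se,
                    upper = dx - dy + crit * se)
  structure(out, n_x = length(x), n_y = length(y),
            n_boot = as.integer(n_boot), seed = as.integer(seed),
            crit = crit, class = c("shift_function", "data.frame"))
}

# bootstrap SE of the nine HD deciles of one sample (rows resampled,
# sorted, pushed through the decile weight matrix in one product)
boot_decile_se <- function(x, n_boot, seed) {
  n <- length(x)
  w <- hd_decile_matrix(n)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  sorted <- apply(matrix(x[idx], nrow = n_boot), 1L, sort)  # n x n_boot
  boots <- w %*% sorted                                     # 9 x n_boot
  apply(boots, 1L, sd)
}

#' @export
print.shift_function <- function(x, ...) {
  cat(sprintf("shift function (x - y), n_x = %d, n_y = %d, %d bootstraps, crit = %.3f\n",
              attr(x, "n_x"), attr(x, "n_y"), attr(x, "n_boot"),
              attr(x, "crit")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Supremum over thresholds of the absolute difference between the two
#' empirical CDFs. Purely the statistic (no p-value); ties are handled
#' exactly by evaluating both ECDFs on the pooled support.
#'
#' @param x,y numeric samples, each n >= 1.
#' @return scalar in `[0, 1]`.
#' @examples
#' ks_statistic(c(1, 3), c(2, 4)) # 0.5
#' @export
ks_statistic <- function(x, y) {
  x <- check_sample(x, 1L, "x")
  y <- check_sample(y, 1L, "y")
  pooled <- sort(unique(c(x, y)))
  max(abs(ecdf(x)(pooled) - ecdf(y)(pooled)))
}

#' Asymptotic two-sample Kolmogorov-Smirnov critical value
#'
#' c(alpha) * sqrt((n1 + n2)/(n1 n2)) with
#' c(alpha) = sqrt(-log(alpha/2)/2): the KS distance beyond which the
#' null of a common distribution is rejected at level alpha
#' (large-sample approximation).
#'
#' @param alpha significance level in (0, 1).
#' @param n1,n2 group sizes (>= 1).
#' @return scalar critical value.
#' @examples
#' round(ks_critical(0.001, 49, 50), 2) # 0.39
#' @export
ks_critical <- function(alpha, n1, n2) {
  if (alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly in (0, 1)", call. = FALSE)
  }
  if (n1 < 1 || n2 < 1) stop("group sizes must be >= 1", call. = FALSE)
  sqrt(-log(alpha / 2) / 2) * sqrt((n1 + n2) / (n1 * n2))
}

#' Holm step-down multiplicity adjustment
#'
#' Wrapper over [stats::p.adjust()] with input validation: adjusted
#' p-values dominate the raw ones, preserve their order, and are capped
#' at 1.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values, same length and names.
#' @examples
#' holm_adjust(c(0.01, 0.04)) # 0.02 0.04
#' @export
holm_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || any(!is.finite(pvalues)) ||
      any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must be finite and within [0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "holm")
}

#' Covariate-adjusted group test on a per-subject scalar
#'
#' F-test of the group factor on the response after adjusting for
#' nuisance covariates (e.g., age and framewise displacement), via
#' nested linear models. With a matrix response and
#' `type = "pillai"`, the omnibus multivariate test (Pillai trace over
#' all columns jointly) is used instead.
#'
#' @param values numeric vector (or matrix for `type = "pillai"`), one
#'   row/entry per subject.
#' @param group_labels factor or character vector of group memberships
#'   (>= 2 levels).
#' @param covariates optional data.frame of numeric covariates aligned
#'   with `values`.
#' @param type `"univariate"` (default) or `"pillai"`.
#' @return the p-value of the group term.
#' @export
group_covariate_test <- function(values, group_labels, covariates = NULL,
                                 type = c("univariate", "pillai")) {
  type <- match.arg(type)
  group <- factor(group_labels)
  if (nlevels(group) < 2L) stop("need at least 2 groups", call. = FALSE)
  n <- if (is.matrix(values)) nrow(values) else length(values)
  if (length(group) != n) {
    stop("group_labels not aligned with values", call. = FALSE)
  }
  dat <- data.frame(.group = group)
  cov_terms <- "1"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) {
      stop("covariate table not aligned with values", call. = FALSE)
    }
    dat <- cbind(dat, covariates)
    cov_terms <- paste(names(covariates), collapse = " + ")
  }
  dat$.y <- values
  full <- lm(as.formula(paste(".y ~", cov_terms, "+ .group")), data = dat)
  if (any(is.na(coef(full)))) {
    stop("rank-deficient design: a covariate is collinear with the group factor",
         call. = FALSE)
  }
  if (type == "pillai") {
    if (!is.matrix(values)) {
      stop("type = 'pillai' needs a matrix response (subjects x networks)",
           call. = FALSE)
    }
    tab <- anova(full, test = "Pillai")
    return(tab[".group", "Pr(>F)"])
  }
  reduced <- lm(as.formula(paste(".y ~", cov_terms)), data = dat)
  tab <- anova(reduced, full)
  tab[["Pr(>F)"]][2L]
}

#' Flag outliers by pairwise distances
#'
#' Distribution-shape-free rule: observation i is flagged when the median
#' of its absolute distances to all other points exceeds `cut` times the
#' overall median of all pairwise distances. No symmetry of the
#' underlying distribution is assumed, and the rule is invariant under
#' affine rescaling of the sample. A MAD-median alternative
#' (|x - median| / MAD > cut) is available.
#'
#' @param x numeric sample, n >= 4.
#' @param cut multiplier on the reference scale; default 2.24
#'   (approximately sqrt of the 0.975 chi-square quantile on 1 df).
#' @param method `"pairwise"` (default) or `"mad"`.
#' @return logical vector of flags, one per observation.
#' @export
flag_outliers <- function(x, cut = 2.24, method = c("pairwise", "mad")) {
  method <- match.arg(method)
  x <- check_sample(x, min_n = 4L)
  if (method == "mad") {
    s <- stats::mad(x)
    if (s == 0) return(rep(FALSE, length(x)))
    return(abs(x - median(x)) / s > cut)
  }
  d <- abs(outer(x, x, `-`))
  per_point <- vapply(seq_along(x), function(i) median(d[i, -i]), numeric(1))
  overall <- median(d[upper.tri(d)])
  if (overall == 0) return(rep(FALSE, length(x)))
  per_point > cut * overall
}
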