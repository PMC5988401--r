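#' Specification of a synthetic multivariate cohort
#'
#' Describes a cohort of band-limited, network-structured multivariate
#' Gaussian signals emulating preprocessed resting-state BOLD ROI tables:
#' M ROIs assigned to labeled networks, T uniformly sampled time points at
#' interval `dt`, signals band-pass filtered to `passband` and
#' standardized per ROI. Within each network, ROIs share a latent factor
#' with coupling rho, giving direct ground-truth control over the
#' within-network dependence that the interlayer-MI analysis is meant to
#' detect.
#'
#' Defaults mirror a typical resting-state acquisition and its
#' preprocessing (dt = 2 s, passband 0.01-0.08 Hz, nine networks) at desk
#' scale (M = 27 ROIs, three per network, T = 150 time points).
#'
#' @param n_subjects named integer vector: subjects per group; names are
#'   the group labels.
#' @param M number of ROIs.
#' @param T_len time points per subject (>= 32).
#' @param dt sampling interval in seconds.
#' @param passband analog band (low, high) in Hz; must satisfy
#'   0 < low < high < Nyquist = 1/(2 dt).
#' @param networks character vector of length M assigning ROIs to
#'   networks; default: nine canonical resting-state network labels in
#'   contiguous blocks.
#' @param coupling within-network coupling rho in `[0, 1]`: a scalar, a
#'   named per-network vector, or a groups x networks matrix (rownames =
#'   group labels) for group-specific effects.
#' @param noise_sd standard deviation of the ROI-private noise before
#'   filtering.
#' @param age_range uniform range for the synthetic age covariate (years).
#' @param fd_meanlog,fd_sdlog log-normal parameters of the synthetic
#'   framewise-displacement covariate (mm).
#' @param fd_group_shift additive per-group shift of mean log FD
#'   (recycled over groups) to inject covariate-group confounding for
#'   testing covariate adjustment.
#' @param seed master seed; all randomness flows from it through
#'   documented sub-seed derivation.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = c(control = 30L, patient = 30L),
                        M = 27L, T_len = 150L, dt = 2,
                        passband = c(0.01, 0.08), networks = NULL,
                        coupling = 0.3, noise_sd = 1,
                        age_range = c(21, 50), fd_meanlog = log(0.15),
                        fd_sdlog = 0.4, fd_group_shift = 0, seed = 1L) {
  if (is.null(names(n_subjects))) {
    names(n_subjects) <- paste0("group", seq_along(n_subjects))
  }
  if (any(n_subjects < 1L)) stop("empty group in n_subjects", call. = FALSE)
  if (T_len < 32L) stop("T_len must be >= 32", call. = FALSE)
  if (M < 1L) stop("M must be >= 1", call. = FALSE)
  nyq <- 1 / (2 * dt)
  if (!(passband[1L] > 0 && passband[1L] < passband[2L] &&
        passband[2L] < nyq)) {
    stop("passband must satisfy 0 < low < high < Nyquist (",
         format(nyq), " Hz)", call. = FALSE)
  }
  if (is.null(networks)) networks <- default_networks(M)
  if (length(networks) != M) {
    stop("networks must assign all ", M, " ROIs", call. = FALSE)
  }
  net_names <- unique(networks)
  rho <- resolve_coupling(coupling, names(n_subjects), net_names)
  if (any(rho < 0 | rho > 1)) {
    stop("coupling must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_subjects = n_subjects, M = as.integer(M),
                 T_len = as.integer(T_len), dt = dt, passband = passband,
                 networks = as.character(networks), coupling = rho,
                 noise_sd = noise_sd, age_range = age_range,
                 fd_meanlog = fd_meanlog, fd_sdlog = fd_sdlog,
                 fd_group_shift = rep_len(fd_group_shift,
                                          length(n_subjects)),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# nine canonical resting-state network labels, contiguous blocks
default_networks <- function(M) {
  rsn <- c("Visual", "Somatomotor", "DorsalAttention", "VentralAttention",
           "Limbic", "Frontoparietal", "Default", "Subcortical",
           "Cerebellum")
  rsn[ceiling(seq_len(M) / ceiling(M / length(rsn)))]
}

# normalize coupling to a groups x networks matrix
resolve_coupling <- function(coupling, groups, networks) {
  if (is.matrix(coupling)) {
    if (is.null(rownames(coupling))) rownames(coupling) <- groups
    if (is.null(colnames(coupling))) colnames(coupling) <- networks
    return(coupling[groups, networks, drop = FALSE])
  }
  if (!is.null(names(coupling))) {
    row <- coupling[networks]
    if (any(is.na(row))) {
      stop("coupling names do not cover all networks", call. = FALSE)
    }
  } else {
    row <- rep_len(coupling, length(networks))
  }
  out <- matrix(rep(row, each = length(groups)), nrow = length(groups),
                dimnames = list(groups, networks))
  out
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("cohort spec: %s; M = %d ROIs over %d networks, T = %d, dt = %gs, band %g-%g Hz, seed %d\n",
              paste(sprintf("%s n=%d", names(x$n_subjects), x$n_subjects),
                    collapse = ", "),
              x$M, length(unique(x$networks)), x$T_len, x$dt,
              x$passband[1L], x$passband[2L], x$seed))
  invisible(x)
}

# samples dropped at each end before standardization, absorbing
# zero-phase filter edge transients
EDGE_TRIM <- 8L

band_limit <- function(mat, dt, passband) {
  w <- passband / (1 / (2 * dt))  # normalized to Nyquist
  bf <- signal::butter(4, w, type = "pass")
  apply(mat, 2L, function(col) signal::filtfilt(bf, col))
}

#' Generate one synthetic subject
#'
#' For ROI i in network g: x_i = sqrt(rho_g) z_g + sqrt(1 - rho_g) e_i,
#' with z_g a latent Gaussian series shared by the network and e_i
#' ROI-private Gaussian noise; the mixture is band-pass filtered
#' (zero-phase, forward-backward Butterworth), edge-trimmed, and
#' standardized per ROI. Deterministic given the spec and
#' `subject_seed`.
#'
#' @param spec a [cohort_spec()].
#' @param subject_seed integer seed for this subject.
#' @param group group label (row of the coupling matrix); default the
#'   first group.
#' @return list with `data` (T x M matrix, columns named by ROI),
#'   `roi_labels`, `networks`, `group`, `seed`.
#' @export
generate_subject <- function(spec, subject_seed = 1L,
                             group = names(spec$n_subjects)[1L]) {
  stopifnot(inherits(spec, "cohort_spec"))
  t_raw <- spec$T_len + 2L * EDGE_TRIM
  set.seed(as.integer(subject_seed))
  latent <- matrix(rnorm(t_raw * ncol(spec$coupling)), nrow = t_raw,
                   dimnames = list(NULL, colnames(spec$coupling)))
  noise <- matrix(rnorm(t_raw * spec$M, sd = spec$noise_sd), nrow = t_raw)
  rho <- spec$coupling[group, spec$networks]
  raw <- latent[, spec$networks, drop = FALSE] *
    rep(sqrt(rho), each = t_raw) +
    noise * rep(sqrt(1 - rho), each = t_raw)
  filtered <- band_limit(raw, spec$dt, spec$passband)
  keep <- (EDGE_TRIM + 1L):(t_raw - EDGE_TRIM)
  out <- scale(filtered[keep, , drop = FALSE])
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  roi <- sprintf("%s_%02d", spec$networks, stats::ave(
    rep(1L, spec$M), spec$networks, FUN = seq_along))
  colnames(out) <- roi
  list(data = out, roi_labels = roi, networks = spec$networks,
       group = group, seed = as.integer(subject_seed))
}

#' Generate a full synthetic cohort
#'
#' One subject matrix per row of the design, plus a participants table
#' with group membership and synthetic covariates (age; framewise
#' displacement, optionally confounded with group via
#' `fd_group_shift`). Per-group coupling parameters induce a known
#' ordering of expected within-network interlayer MI, giving the
#' downstream statistics a ground truth.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `cohort`: list with `subjects` (named list of
#'   [generate_subject()] results), `participants` (data.frame:
#'   subject_id, group, age, fd), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- rep(names(spec$n_subjects), spec$n_subjects)
  n_total <- length(groups)
  seeds <- derive_seeds(spec$seed, n_total + 1L)
  ids <- sprintf("sub-%03d", seq_len(n_total))
  subjects <- lapply(seq_len(n_total), function(s) {
    generate_subject(spec, subject_seed = seeds[s], group = groups[s])
  })
  names(subjects) <- ids
  set.seed(seeds[n_total + 1L])
  shift <- spec$fd_group_shift[match(groups, names(spec$n_subjects))]
  participants <- data.frame(
    subject_id = ids,
    group = groups,
    age = round(runif(n_total, spec$age_range[1L], spec$age_range[2L]), 1),
    fd = rlnorm(n_total, meanlog = spec$fd_meanlog + shift,
                sdlog = spec$fd_sdlog))
  structure(list(subjects = subjects, participants = participants,
                 spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d subjects (%s), %d ROIs x %d time points each\n",
              nrow(x$participants),
              paste(sprintf("%s n=%d", names(x$spec$n_subjects),
                            x$spec$n_subjects), collapse = ", "),
              x$spec$M, x$spec$T_len))
  invisible(x)
}
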