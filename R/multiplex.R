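#' Assemble a multiplex visibility graph from a time x ROI matrix
#'
#' Each column (one ROI's signal) is mapped to its own visibility-graph
#' layer. All layers share the same node set because node t is time stamp
#' t in every layer — the natural alignment induced by the time arrow —
#' which is what makes the collection a multiplex rather than a generic
#' multilayer graph.
#'
#' @param data numeric matrix, rows = time points (T >= 2), columns =
#'   ROIs/signals (M >= 1); all entries finite.
#' @param method `"natural"` or `"horizontal"` visibility.
#' @param roi_labels character vector of length M; defaults to column
#'   names or `roi_1 ... roi_M`.
#' @param network_labels character vector of length M assigning each ROI
#'   to a labeled group (e.g., a resting-state network); defaults to a
#'   single group `"all"`.
#' @return an object of class `multiplex_vg`: list with `layers` (list of
#'   `visibility_graph`), `n_nodes`, `roi_labels`, `network_labels`,
#'   `method`.
#' @examples
#' x <- cbind(a = c(1, 2, 3, 4), b = c(3, 1, 2, 4))
#' build_multiplex(x, method = "natural")
#' @export
build_multiplex <- function(data, method = c("natural", "horizontal"),
                            roi_labels = NULL, network_labels = NULL) {
  method <- match.arg(method)
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("data must be a numeric matrix (rows = time, columns = ROIs)",
         call. = FALSE)
  }
  if (nrow(data) < 2L || ncol(data) < 1L) {
    stop("need at least 2 time points and 1 ROI, got ", nrow(data), " x ",
         ncol(data), call. = FALSE)
  }
  if (any(!is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)[1L, ]
    stop("non-finite value at time ", bad[1L], ", ROI column ", bad[2L],
         call. = FALSE)
  }
  m <- ncol(data)
  if (is.null(roi_labels)) {
    roi_labels <- colnames(data)
    if (is.null(roi_labels)) roi_labels <- paste0("roi_", seq_len(m))
  }
  if (is.null(network_labels)) network_labels <- rep("all", m)
  if (length(roi_labels) != m || length(network_labels) != m) {
    stop("roi_labels and network_labels must have one entry per column (",
         m, ")", call. = FALSE)
  }
  build <- if (method == "natural") nvg_fast else hvg
  layers <- lapply(seq_len(m), function(j) build(data[, j]))
  structure(list(layers = layers, n_nodes = nrow(data),
                 roi_labels = as.character(roi_labels),
                 network_labels = as.character(network_labels),
                 method = method),
            class = "multiplex_vg")
}

#' @export
print.multiplex_vg <- function(x, ...) {
  cat(sprintf("multiplex visibility graph (%s): M = %d layers, N = %d time points\n",
              x$method, length(x$layers), x$n_nodes))
  nets <- table(x$network_labels)
  cat("networks:", paste(sprintf("%s (%d)", names(nets), nets), collapse = ", "),
      "\n")
  invisible(x)
}

#' Empirical degree probability mass function of a layer
#'
#' Plug-in PMF over the exact integer degree values observed in the layer
#' (no binning, no smoothing).
#'
#' @param layer a `visibility_graph`.
#' @return a data.frame with columns `degree` (distinct values, ascending)
#'   and `prob` (relative frequencies summing to 1).
#' @examples
#' degree_pmf(hvg(c(1, 3, 2, 4)))
#' @export
degree_pmf <- function(layer) {
  k <- degree_sequence(layer)
  tab <- table(k)
  data.frame(degree = as.integer(names(tab)),
             prob = as.vector(tab) / length(k))
}

#' Shannon entropy of a degree PMF
#'
#' @param pmf as returned by [degree_pmf()].
#' @param base logarithm base; default `exp(1)` for nats.
#' @return entropy, non-negative.
#' @export
pmf_entropy <- function(pmf, base = exp(1)) {
  p <- pmf$prob[pmf$prob > 0]
  -sum(p * log(p)) / log(base)
}

# shared kernel: MI between two integer degree vectors paired by index.
# Degrees are >= 1 in any visibility graph (the chain guarantees it), so
# plain tabulate over 1..max(k) indexes the support directly.
mi_from_degrees <- function(ka, kb, base = exp(1)) {
  n <- length(ka)
  ma <- max(ka)
  mb <- max(kb)
  joint <- tabulate((ka - 1L) * mb + kb, nbins = ma * mb) / n
  pa <- tabulate(ka, nbins = ma) / n
  pb <- tabulate(kb, nbins = mb) / n
  pp <- rep(pa, each = mb) * rep.int(pb, ma)  # row-major outer product
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / pp[nz]))
  max(mi, 0) / log(base)  # clamp tiny negative rounding residue
}

#' Interlayer mutual information between two visibility-graph layers
#'
#' MI between the degree distributions of two layers of a multiplex,
#' using the joint distribution of the paired degrees (k of node t in
#' layer alpha, k of node t in layer beta) over the shared time-stamp
#' node set. Plug-in (empirical) estimator over exact degree values, no
#' bias correction; terms with zero joint probability contribute 0.
#'
#' `interlayer_mi(a, a)` equals the Shannon entropy of `a`'s degree PMF.
#' A layer with constant degree sequence yields 0 against anything.
#'
#' @param layer_a,layer_b `visibility_graph` layers with equal `n_nodes`.
#' @param base logarithm base; default natural log (result in nats).
#' @return non-negative scalar; symmetric in its arguments.
#' @export
interlayer_mi <- function(layer_a, layer_b, base = exp(1)) {
  stopifnot(inherits(layer_a, "visibility_graph"),
            inherits(layer_b, "visibility_graph"))
  if (layer_a$n_nodes != layer_b$n_nodes) {
    stop("layers have different node counts (", layer_a$n_nodes, " vs ",
         layer_b$n_nodes, "); interlayer MI needs the shared time axis",
         call. = FALSE)
  }
  mi_from_degrees(degree_sequence(layer_a), degree_sequence(layer_b), base)
}

#' Pairwise interlayer mutual information matrix of a multiplex
#'
#' Entry (alpha, beta) is [interlayer_mi()] of layers alpha and beta; the
#' diagonal holds each layer's degree-PMF entropy. Symmetric and
#' non-negative.
#'
#' @param mvg a `multiplex_vg`.
#' @param base logarithm base; default natural log (nats).
#' @return an object of class `mi_matrix`: an M x M numeric matrix with
#'   ROI labels as dimnames and attributes `network_labels`, `method`,
#'   `log_base`, `n_time`.
#' @export
mi_matrix <- function(mvg, base = exp(1)) {
  stopifnot(inherits(mvg, "multiplex_vg"))
  m <- length(mvg$layers)
  deg <- lapply(mvg$layers, degree_sequence)
  out <- matrix(0, m, m, dimnames = list(mvg$roi_labels, mvg$roi_labels))
  for (a in seq_len(m)) {
    for (b in a:m) {
      v <- mi_from_degrees(deg[[a]], deg[[b]], base)
      out[a, b] <- v
      out[b, a] <- v
    }
  }
  structure(out, network_labels = mvg$network_labels, method = mvg$method,
            log_base = base, n_time = mvg$n_nodes,
            class = c("mi_matrix", "matrix", "array"))
}

#' Mean interlayer MI within one labeled network
#'
#' Arithmetic mean of the interlayer MI over all unordered pairs of
#' distinct ROIs carrying the given network label; the diagonal
#' (layer entropies) is excluded. This is the per-subject scalar used in
#' group comparisons.
#'
#' @param mi an `mi_matrix`.
#' @param network network label; must tag at least 2 ROIs (a singleton
#'   network has no pairs, so the average is undefined).
#' @return scalar mean MI (same log base as `mi`).
#' @export
network_avg_mi <- function(mi, network) {
  stopifnot(inherits(mi, "mi_matrix"))
  labs <- attr(mi, "network_labels")
  idx <- which(labs == network)
  if (!length(idx)) {
    stop("unknown network '", network, "'; available: ",
         paste(unique(labs), collapse = ", "), call. = FALSE)
  }
  if (length(idx) < 2L) {
    stop("network '", network, "' has a single ROI; <MI> over pairs is undefined",
         call. = FALSE)
  }
  block <- mi[idx, idx, drop = FALSE]
  mean(block[upper.tri(block)])
}

#' Per-network mean interlayer MI for all eligible networks
#'
#' @param mi an `mi_matrix`.
#' @return named numeric vector of [network_avg_mi()] values, one per
#'   network with at least 2 ROIs, in first-appearance order.
#' @export
network_mi_profile <- function(mi) {
  stopifnot(inherits(mi, "mi_matrix"))
  labs <- attr(mi, "network_labels")
  nets <- unique(labs)
  nets <- nets[vapply(nets, function(g) sum(labs == g) >= 2L, logical(1))]
  vapply(nets, function(g) network_avg_mi(mi, g), numeric(1))
}

#' @export
print.mi_matrix <- function(x, ...) {
  cat(sprintf("interlayer MI matrix: %d ROIs, N = %d time points, %s visibility, log base %s\n",
              nrow(x), attr(x, "n_time"), attr(x, "method"),
              format(attr(x, "log_base"))))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))),
                   drop = FALSE], digits = 3)
  if (nrow(x) > 6L) cat("... (", nrow(x), "x", ncol(x), "total )\n")
  invisible(x)
}
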