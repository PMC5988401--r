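#' Validate a univariate series for visibility mapping
#'
#' Visibility graphs are defined on uniformly sampled scalar series with no
#' missing values: dropping a point would silently change the time axis, so
#' any non-finite value is a hard error naming the offending index.
#'
#' @param y numeric vector, length at least 2.
#' @return the series, invisibly, as a plain double vector.
#' @keywords internal
check_series <- function(y) {
  if (!is.numeric(y)) stop("series must be numeric", call. = FALSE)
  y <- as.double(y)
  if (length(y) < 2L) {
    stop("series must contain at least 2 time points, got ", length(y),
         call. = FALSE)
  }
  bad <- which(!is.finite(y))
  if (length(bad)) {
    stop("non-finite value(s) in series at time index ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "", call. = FALSE)
  }
  y
}

new_visibility_graph <- function(n, edges, method) {
  # canonical form: i < j, rows sorted by (i, j), 1-based node ids
  storage.mode(edges) <- "integer"
  if (nrow(edges)) {
    swap <- edges[, 1L] > edges[, 2L]
    if (any(swap)) edges[swap, ] <- edges[swap, c(2L, 1L)]
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  dimnames(edges) <- list(NULL, c("i", "j"))
  structure(list(n_nodes = as.integer(n), edges = edges, method = method),
            class = "visibility_graph")
}

#' Natural visibility graph, quadratic-scan reference construction
#'
#' Connects time points i < j when the straight segment between
#' (i, y_i) and (j, y_j) passes strictly above every intermediate sample:
#' y_k < y_i + (y_j - y_i) (k - i)/(j - i) for all i < k < j. Equivalently,
#' the slope from i to j strictly exceeds the slope from i to every
#' intermediate point, which is what the scan checks with a running
#' maximum. Collinear points therefore block visibility, and a pure linear
#' trend maps to the bare chain.
#'
#' This is the reference implementation: [nvg_fast()] is contracted to
#' return the identical edge set on every input.
#'
#' @param y numeric vector (length >= 2, all finite); one sample per
#'   uniformly spaced time point.
#' @return an object of class `visibility_graph`: a list with `n_nodes`,
#'   `edges` (two-column integer matrix, `i < j`, 1-based) and `method`.
#' @examples
#' nvg_naive(c(3, 1, 2))$edges
#' @seealso [nvg_fast()], [hvg()], [degree_sequence()]
#' @export
nvg_naive <- function(y) {
  y <- check_series(y)
  n <- length(y)
  ei <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    slopes <- (y[js] - y[i]) / (js - i)
    prev <- c(-Inf, cummax(slopes[-length(slopes)]))
    vis <- js[slopes > prev]
    ei[[i]] <- cbind(rep.int(i, length(vis)), vis)
  }
  new_visibility_graph(n, do.call(rbind, ei), "natural")
}

#' Natural visibility graph, divide-and-conquer construction
#'
#' Same graph as [nvg_naive()] (exact edge-set equality is part of the
#' contract and enforced by the test suite on randomized inputs), built by
#' recursively splitting at the segment maximum: the maximum blocks every
#' line of sight across it, so all edges are either incident to it or
#' confined to one side. Average cost O(N log N).
#'
#' @inheritParams nvg_naive
#' @return an object of class `visibility_graph`.
#' @examples
#' identical(nvg_fast(rnorm(50))$edges, nvg_naive(rnorm(50))$edges) # FALSE:
#' # different random series; on the *same* series they agree exactly:
#' y <- rnorm(50)
#' identical(nvg_fast(y)$edges, nvg_naive(y)$edges)
#' @export
nvg_fast <- function(y) {
  y <- check_series(y)
  new_visibility_graph(length(y), .nvg_fast_edges(y), "natural")
}

#' Horizontal visibility graph
#'
#' Connects i < j when every intermediate sample is strictly smaller than
#' both endpoints: y_k < min(y_i, y_j) for all i < k < j. Ties block
#' visibility. The result is always a subgraph of the natural visibility
#' graph of the same series, and is invariant under any strictly
#' increasing transform of the values (it is an order statistic of the
#' series). Built with an O(N) monotone-stack sweep.
#'
#' @inheritParams nvg_naive
#' @return an object of class `visibility_graph`.
#' @examples
#' hvg(c(1, 3, 2, 4))$edges
#' @export
hvg <- function(y) {
  y <- check_series(y)
  new_visibility_graph(length(y), .hvg_edges(y), "horizontal")
}

#' Build a visibility graph with a chosen criterion
#'
#' @inheritParams nvg_naive
#' @param method `"natural"` (default; convexity criterion) or
#'   `"horizontal"` (ordering criterion).
#' @return an object of class `visibility_graph`.
#' @export
visibility_graph <- function(y, method = c("natural", "horizontal")) {
  method <- match.arg(method)
  if (method == "natural") nvg_fast(y) else hvg(y)
}

#' Degree sequence of a visibility graph
#'
#' @param graph a `visibility_graph`.
#' @return integer vector of length `n_nodes`; entry t is the degree of
#'   time point t. Sums to twice the edge count.
#' @examples
#' degree_sequence(hvg(c(1, 3, 2, 4))) # 1 3 2 2
#' @export
degree_sequence <- function(graph) {
  stopifnot(inherits(graph, "visibility_graph"))
  tabulate(c(graph$edges[, 1L], graph$edges[, 2L]), nbins = graph$n_nodes)
}

#' Dense 0/1 adjacency matrix view of a visibility graph
#'
#' The canonical storage is the edge list; this view exists for
#' interoperability with adjacency-matrix consumers.
#'
#' @param graph a `visibility_graph`.
#' @return symmetric integer matrix with zero diagonal.
#' @export
as_adjacency <- function(graph) {
  stopifnot(inherits(graph, "visibility_graph"))
  a <- matrix(0L, graph$n_nodes, graph$n_nodes)
  a[graph$edges] <- 1L
  a[graph$edges[, c(2L, 1L)]] <- 1L
  a
}

#' Convert a visibility graph to an igraph object
#'
#' @param graph a `visibility_graph`.
#' @return an undirected [igraph::graph] on `n_nodes` vertices.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "visibility_graph"))
  g <- igraph::make_empty_graph(n = graph$n_nodes, directed = FALSE)
  igraph::add_edges(g, t(graph$edges))
}

#' @export
print.visibility_graph <- function(x, ...) {
  cat(sprintf("%s visibility graph: %d nodes (time points), %d edges\n",
              x$method, x$n_nodes, nrow(x$edges)))
  invisible(x)
}

#' @export
format.visibility_graph <- function(x, ...) {
  sprintf("<visibility_graph/%s: N=%d, |E|=%d>", x$method, x$n_nodes,
          nrow(x$edges))
}
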