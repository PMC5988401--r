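#' Read an ROI time-series table
#'
#' CSV/TSV with a header row of ROI labels and one row per time point, in
#' temporal order. Square matrices are ambiguous (time could run either
#' way) and are rejected unless the orientation is forced.
#'
#' @param path file path; delimiter inferred from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma).
#' @param transpose set `TRUE` when the file stores rows = ROIs.
#' @param allow_square set `TRUE` to accept a square matrix as rows =
#'   time.
#' @return list with `data` (T x M numeric matrix) and `roi_labels`.
#' @export
read_timeseries <- function(path, transpose = FALSE, allow_square = FALSE) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE)
  mat <- as.matrix(df)
  if (!is.numeric(mat)) stop("non-numeric cells in ", path, call. = FALSE)
  if (transpose) mat <- t(mat)
  labels <- colnames(mat)
  if (transpose) labels <- rownames(mat) %||% paste0("roi_", seq_len(ncol(mat)))
  if (anyDuplicated(labels)) {
    stop("duplicate ROI labels in ", path, ": ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)[1L, ]
    stop("non-finite value in ", path, " at time row ", bad[1L],
         ", ROI '", labels[bad[2L]], "'", call. = FALSE)
  }
  if (nrow(mat) == ncol(mat) && !allow_square && !transpose) {
    stop("square matrix in ", path,
         ": orientation is ambiguous; pass allow_square = TRUE ",
         "(rows = time) or transpose = TRUE (rows = ROIs)", call. = FALSE)
  }
  colnames(mat) <- labels
  list(data = mat, roi_labels = labels)
}

#' Write an ROI time-series table
#'
#' @param data T x M numeric matrix with ROI column names.
#' @param path output CSV path.
#' @export
write_timeseries <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Read an ROI-to-network map
#'
#' Two-column CSV `roi_label, network_name`. The map must cover every ROI
#' in `roi_labels` exactly once with a non-empty network name.
#'
#' @param path file path.
#' @param roi_labels ROI labels the map must cover (e.g., from
#'   [read_timeseries()]); optional.
#' @return named character vector network-per-ROI (names = ROI labels,
#'   ordered as `roi_labels` when given).
#' @export
read_network_map <- function(path, roi_labels = NULL) {
  df <- read.csv(path, check.names = FALSE,
                 colClasses = c("character", "character"))
  if (ncol(df) < 2L) stop("network map needs two columns", call. = FALSE)
  roi <- trimws(df[[1L]])
  net <- trimws(df[[2L]])
  if (any(net == "")) {
    stop("empty network name for ROI(s): ",
         paste(roi[net == ""], collapse = ", "), call. = FALSE)
  }
  dup <- unique(roi[duplicated(roi)])
  for (d in dup) {
    if (length(unique(net[roi == d])) > 1L) {
      stop("ROI '", d, "' mapped to conflicting networks", call. = FALSE)
    }
  }
  keep <- !duplicated(roi)
  map <- stats::setNames(net[keep], roi[keep])
  if (!is.null(roi_labels)) {
    missing <- setdiff(roi_labels, names(map))
    if (length(missing)) {
      stop("network map is missing ROI(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    unknown <- setdiff(names(map), roi_labels)
    if (length(unknown)) {
      stop("network map lists unknown ROI(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    map <- map[roi_labels]
  }
  map
}

#' Write a visibility graph as an edge-list CSV
#'
#' Two integer columns `i, j` with `i < j`, 0-based node ids, one header
#' line.
#'
#' @param graph a `visibility_graph`.
#' @param path output path.
#' @export
write_edgelist <- function(graph, path) {
  stopifnot(inherits(graph, "visibility_graph"))
  df <- data.frame(i = graph$edges[, 1L] - 1L, j = graph$edges[, 2L] - 1L)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an edge-list CSV back into a visibility graph
#'
#' @param path edge-list path (0-based ids as written by
#'   [write_edgelist()]).
#' @param n_nodes node count (needed because trailing isolated nodes are
#'   not representable in an edge list); default `max(id) + 1`.
#' @param method method tag to attach.
#' @return a `visibility_graph`.
#' @export
read_edgelist <- function(path, n_nodes = NULL,
                          method = c("natural", "horizontal")) {
  method <- match.arg(method)
  df <- read.csv(path)
  edges <- cbind(df$i, df$j) + 1L
  new_visibility_graph(n_nodes %||% max(edges), edges, method)
}

#' Write the dense adjacency-matrix view of a visibility graph
#'
#' Dense 0/1 CSV without header, for adjacency-matrix consumers.
#'
#' @param graph a `visibility_graph`.
#' @param path output path.
#' @export
write_adjacency <- function(graph, path) {
  utils::write.table(as_adjacency(graph), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an interlayer MI matrix with its sidecar metadata
#'
#' Labeled CSV (header row and column = ROI labels) plus
#' `<path>.json` recording method, log base, time-point count, and the
#' network labels, so the units (nats by default) travel with the data.
#'
#' @param mi an `mi_matrix`.
#' @param path output CSV path.
#' @export
write_mi_matrix <- function(mi, path) {
  stopifnot(inherits(mi, "mi_matrix"))
  write.csv(unclass(mi), path, row.names = TRUE)
  meta <- list(method = attr(mi, "method"),
               log_base = attr(mi, "log_base"),
               units = if (isTRUE(all.equal(attr(mi, "log_base"), exp(1))))
                 "nats" else "bits",
               n_time = attr(mi, "n_time"),
               roi_labels = rownames(mi),
               network_labels = attr(mi, "network_labels"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an interlayer MI matrix written by [write_mi_matrix()]
#'
#' @param path CSV path (the `<path>.json` sidecar must sit beside it).
#' @return an `mi_matrix`.
#' @export
read_mi_matrix <- function(path) {
  mat <- as.matrix(read.csv(path, row.names = 1L, check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(mat, network_labels = meta$network_labels,
            method = meta$method, log_base = meta$log_base,
            n_time = meta$n_time,
            class = c("mi_matrix", "matrix", "array"))
}

#' Write a partition as a node/module CSV
#'
#' Columns `node, module`, both 0-based.
#'
#' @param p a `vg_partition`.
#' @param path output path.
#' @export
write_partition <- function(p, path) {
  l <- partition_labels(p)
  write.csv(data.frame(node = seq_along(l) - 1L, module = l - 1L), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
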