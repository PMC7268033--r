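#' Multivariate node-by-time signal matrix
#'
#' Container for the raw signals (e.g. parcellated resting-state time
#' series) from which time-varying connectivity is estimated. Rows are
#' nodes, columns are time points.
#'
#' @param values Numeric matrix, `N` nodes by `T` time points. All values
#'   must be finite, with `N >= 2` and `T >= 2`.
#' @param node_ids Character vector of unique node identifiers. Defaults to
#'   existing rownames or `"n0" ... "n(N-1)"`.
#' @return An object of class `node_timeseries`: the numeric matrix with
#'   node identifiers as rownames.
#' @examples
#' x <- node_timeseries(matrix(rnorm(20), nrow = 4))
#' n_nodes(x); n_time(x)
#' @export
node_timeseries <- function(values, node_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(node_ids)) {
    node_ids <- rownames(values)
    if (is.null(node_ids)) node_ids <- paste0("n", seq_len(nrow(values)) - 1L)
  }
  node_ids <- as.character(node_ids)
  if (nrow(values) < 2L) stop("node_timeseries needs at least 2 nodes", call. = FALSE)
  if (ncol(values) < 2L) stop("node_timeseries needs at least 2 time points", call. = FALSE)
  if (!all(is.finite(values))) stop("node_timeseries values must all be finite", call. = FALSE)
  if (length(node_ids) != nrow(values)) {
    stop("node_ids length does not match number of rows", call. = FALSE)
  }
  if (anyDuplicated(node_ids)) {
    stop("duplicate node ids: ", paste(unique(node_ids[duplicated(node_ids)]), collapse = ", "),
         call. = FALSE)
  }
  rownames(values) <- node_ids
  colnames(values) <- NULL
  structure(values, class = c("node_timeseries", "matrix", "array"))
}

#' Weighted temporal network (stack of connectivity snapshots)
#'
#' An `N x N x T` array of symmetric weighted adjacency matrices with zero
#' diagonals: one connectivity "snapshot" per time point. Undirected only;
#' an asymmetric slice is rejected. The `thresholded` flag records whether
#' negative edges have been removed (see [threshold_negative_edges()]),
#' which downstream community detection and participation measures require.
#'
#' @param weights Numeric array `N x N x T` (an `N x N` matrix is promoted
#'   to `T = 1`).
#' @param node_ids Character vector of unique node identifiers.
#' @param thresholded Logical; if `TRUE` all weights must be nonnegative.
#' @return An object of class `temporal_network`.
#' @export
temporal_network <- function(weights, node_ids = NULL, thresholded = FALSE) {
  if (is.matrix(weights)) weights <- array(weights, dim = c(dim(weights), 1L))
  if (length(dim(weights)) != 3L || dim(weights)[1] != dim(weights)[2]) {
    stop("weights must be an N x N x T array", call. = FALSE)
  }
  storage.mode(weights) <- "double"
  n <- dim(weights)[1]
  tt <- dim(weights)[3]
  if (is.null(node_ids)) {
    node_ids <- dimnames(weights)[[1]]
    if (is.null(node_ids)) node_ids <- paste0("n", seq_len(n) - 1L)
  }
  node_ids <- as.character(node_ids)
  if (length(node_ids) != n || anyDuplicated(node_ids)) {
    stop("node_ids must be unique and match the array dimension", call. = FALSE)
  }
  if (!all(is.finite(weights))) stop("temporal_network weights must be finite", call. = FALSE)
  for (t in seq_len(tt)) {
    w <- weights[, , t]
    if (!isTRUE(all.equal(w, t(w), tolerance = 1e-12, check.attributes = FALSE))) {
      stop("slice ", t, " is not symmetric; only undirected networks are supported",
           call. = FALSE)
    }
    if (any(diag(w) != 0)) stop("slice ", t, " has a nonzero diagonal", call. = FALSE)
  }
  if (isTRUE(thresholded) && any(weights < 0)) {
    stop("thresholded network contains negative weights", call. = FALSE)
  }
  dimnames(weights) <- list(node_ids, node_ids, NULL)
  structure(weights,
            thresholded = isTRUE(thresholded),
            class = c("temporal_network", "array"))
}

#' Community partitions
#'
#' `static_partition()` holds one community label per node;
#' `partition_sequence()` holds an `N x T` matrix of labels, the community
#' of node `i` at time `t`. Labels are nonnegative integers; any label
#' alphabet read from disk is densified to `0..K-1` in order of first
#' appearance ([read_partition()]). After [temporal_consensus()] a label
#' denotes the "same" community across time (the `consensus` attribute
#' records this).
#'
#' @param labels For `static_partition` an integer vector; for
#'   `partition_sequence` an integer `N x T` matrix.
#' @param consensus Logical, whether labels are comparable across time.
#' @return A `static_partition` or `partition_sequence` object.
#' @export
static_partition <- function(labels) {
  labels <- check_labels(labels)
  structure(as.integer(labels), class = "static_partition")
}

#' @rdname static_partition
#' @export
partition_sequence <- function(labels, consensus = FALSE) {
  labels <- as.matrix(labels)
  lab <- check_labels(labels)
  m <- matrix(as.integer(lab), nrow = nrow(labels), ncol = ncol(labels))
  rownames(m) <- rownames(labels)
  structure(m, consensus = isTRUE(consensus),
            class = c("partition_sequence", "matrix", "array"))
}

check_labels <- function(labels) {
  if (length(labels) == 0L) stop("partition has no labels", call. = FALSE)
  if (anyNA(labels)) stop("every node must be labeled (no missing labels)", call. = FALSE)
  if (!is.numeric(labels) || any(labels != floor(labels)) || any(labels < 0)) {
    stop("labels must be nonnegative integers", call. = FALSE)
  }
  labels
}

#' @export
print.node_timeseries <- function(x, ...) {
  cat("<node_timeseries> ", nrow(x), " nodes x ", ncol(x), " time points\n", sep = "")
  invisible(x)
}

#' @export
print.temporal_network <- function(x, ...) {
  cat("<temporal_network> ", dim(x)[1], " nodes x ", dim(x)[3], " slices",
      if (attr(x, "thresholded")) " (thresholded)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
print.partition_sequence <- function(x, ...) {
  cat("<partition_sequence> ", nrow(x), " nodes x ", ncol(x), " time points; ",
      length(unique(as.vector(x))), " labels",
      if (attr(x, "consensus")) " (consensus-relabeled)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
print.static_partition <- function(x, ...) {
  cat("<static_partition> ", length(x), " nodes, ",
      length(unique(unclass(x))), " communities\n", sep = "")
  invisible(x)
}

#' Node-by-time series of one nodal measure
#'
#' Result container used by [pc_s()], [pc_t()], [tpc()] and
#' [module_degree_zscore()]: an `N x T` matrix of per-node, per-time values
#' plus the measure name and a provenance note describing the network and
#' partition(s) that produced it.
#'
#' @param values Numeric `N x T` matrix.
#' @param measure_name One of `"PC_S"`, `"PC_T"`, `"TPC"`, `"z_S"`, `"z_T"`,
#'   or `"static_PC"`.
#' @param provenance Character note on inputs (free form).
#' @return An object of class `nodal_measure_series`.
#' @export
nodal_measure_series <- function(values, measure_name, provenance = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stop("measure values must be finite", call. = FALSE)
  if (grepl("^(PC|TPC|static)", measure_name) &&
      (any(values < 0) || any(values >= 1))) {
    stop("participation-type values must lie in [0, 1)", call. = FALSE)
  }
  structure(values, measure_name = measure_name, provenance = provenance,
            class = c("nodal_measure_series", "matrix", "array"))
}

#' @export
print.nodal_measure_series <- function(x, ...) {
  cat("<nodal_measure_series: ", attr(x, "measure_name"), "> ",
      nrow(x), " nodes x ", ncol(x), " time points\n", sep = "")
  invisible(x)
}

# Accessors ------------------------------------------------------------

#' Dimensions of temporal objects
#'
#' @param x A `node_timeseries`, `temporal_network`, `partition_sequence`
#'   or `nodal_measure_series`.
#' @return Integer scalar.
#' @export
n_nodes <- function(x) {
  if (inherits(x, "temporal_network")) dim(x)[1]
  else if (inherits(x, "static_partition")) length(x)
  else nrow(x)
}

#' @rdname n_nodes
#' @export
n_time <- function(x) {
  if (inherits(x, "temporal_network")) dim(x)[3] else ncol(x)
}

#' @rdname n_nodes
#' @export
node_ids <- function(x) {
  if (inherits(x, "temporal_network")) dimnames(x)[[1]] else rownames(x)
}

#' @rdname n_nodes
#' @export
is_thresholded <- function(x) isTRUE(attr(x, "thresholded"))

#' Set all negative edges to zero
#'
#' Standard preprocessing before modularity community detection and
#' participation measures on correlation-based networks: every strictly
#' negative weight is replaced by 0. Idempotent; the input is not modified.
#'
#' @param net A [temporal_network()].
#' @return A `temporal_network` with `thresholded = TRUE`.
#' @examples
#' w <- array(0, c(2, 2, 1)); w[1, 2, 1] <- w[2, 1, 1] <- -0.3
#' threshold_negative_edges(temporal_network(w))
#' @export
threshold_negative_edges <- function(net) {
  stopifnot(inherits(net, "temporal_network"))
  w <- unclass(net)
  w[w < 0] <- 0
  temporal_network(w, node_ids = node_ids(net), thresholded = TRUE)
}

#' Per-node community strength profile
#'
#' For every node, time point and community of the given partition, the
#' within-community strength `k_its` (sum of the node's edge weights to
#' members of community `s` at time `t`) and the total strength `k_it`.
#' For any full partition the within-community strengths of a node sum
#' exactly to its total strength.
#'
#' @param net A thresholded [temporal_network()].
#' @param partition A [static_partition()] (applied at every slice) or a
#'   [partition_sequence()] (slice `t` uses its own labels).
#' @return A tibble with columns `node`, `time`, `community`,
#'   `within_strength`, `total_strength`.
#' @export
community_strength_profile <- function(net, partition) {
  stopifnot(inherits(net, "temporal_network"))
  tt <- n_time(net)
  labs <- partition_at_times(partition, n_nodes(net), tt)
  out <- purrr::map_dfr(seq_len(tt), function(t) {
    w <- net[, , t]
    ks <- strength_by_community(w, labs[, t])
    tibble::tibble(
      node = rep(node_ids(net), times = ncol(ks)),
      time = t,
      community = rep(as.integer(colnames(ks)), each = nrow(ks)),
      within_strength = as.vector(ks),
      total_strength = rep(rowSums(w), times = ncol(ks))
    )
  })
  out
}

# labels for every slice as an N x T matrix
partition_at_times <- function(partition, n, tt) {
  if (inherits(partition, "static_partition")) {
    if (length(partition) != n) stop("partition length does not match network", call. = FALSE)
    matrix(rep(as.integer(partition), tt), nrow = n)
  } else if (inherits(partition, "partition_sequence")) {
    if (nrow(partition) != n || ncol(partition) != tt) {
      stop("partition sequence shape does not match network", call. = FALSE)
    }
    unclass(partition)
  } else stop("partition must be a static_partition or partition_sequence", call. = FALSE)
}

# matrix of within-community strengths: rows nodes, cols sorted unique labels
strength_by_community <- function(w, labels) {
  labs <- sort(unique(labels))
  ind <- outer(labels, labs, "==") + 0   # N x S indicator
  ks <- w %*% ind
  colnames(ks) <- labs
  ks
}
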