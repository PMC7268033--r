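#' Read and write node-by-time signal matrices
#'
#' Plain-text format: one row per node, first column the node id, remaining
#' columns the signal at successive time points. A header row of 0-based
#' time indices is optional on read and always written. Lines starting with
#' `#` are comments; writers emit a `# temporalpc timeseries v1` header.
#'
#' @param path File path.
#' @param format `"csv"` or `"tsv"`; on read, guessed from the extension
#'   when missing.
#' @return `read_timeseries()` returns a [node_timeseries()];
#'   `write_timeseries()` returns `path` invisibly. Round trips preserve
#'   values to full double precision.
#' @export
read_timeseries <- function(path, format = NULL) {
  sep <- io_sep(path, format)
  rows <- io_read_rows(path, sep)
  cells <- rows$cells
  if (length(cells) == 0L) stop("no data rows in ", path, call. = FALSE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stop("ragged row at line ", rows$lines[bad], " of ", path, call. = FALSE)
  }
  # optional header row of time indices: first cell non-numeric ("node", "")
  first <- cells[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(first[2])))
  if (has_header) cells <- cells[-1]
  ids <- vapply(cells, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    bad <- which(duplicated(ids))[1]
    stop("duplicate node id '", ids[bad], "' at line ",
         rows$lines[bad + has_header], call. = FALSE)
  }
  vals <- t(vapply(cells, function(r) {
    v <- suppressWarnings(as.numeric(r[-1]))
    v
  }, numeric(widths[1] - 1L)))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1, any))[1]
    stop("non-numeric cell at line ", rows$lines[bad + has_header], " of ", path,
         call. = FALSE)
  }
  node_timeseries(vals, node_ids = ids)
}

#' @rdname read_timeseries
#' @param x Object to write.
#' @export
write_timeseries <- function(x, path, format = NULL) {
  stopifnot(inherits(x, "node_timeseries"))
  sep <- io_sep(path, format)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# temporalpc timeseries v1", con)
  writeLines(paste(c("node", paste0("t", seq_len(ncol(x)) - 1L)), collapse = sep), con)
  for (i in seq_len(nrow(x))) {
    writeLines(paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = sep), con)
  }
  invisible(path)
}

#' Read and write temporal networks as weighted temporal edge lists
#'
#' Tab-separated columns `i`, `j`, `t`, `weight` with 0-based node and time
#' indices. Networks are undirected: each edge is stored once, in either
#' orientation; a duplicate with equal weight is deduplicated and a
#' conflicting duplicate is an error. Absent `(i, j, t)` triples are weight
#' 0. Self-loops are rejected.
#'
#' @param path File path.
#' @param n_nodes,n_time Optional dimensions; inferred from the largest
#'   index when `NULL`. Explicit values allow trailing all-zero slices or
#'   isolated high-index nodes.
#' @return `read_temporal_edgelist()` returns a [temporal_network()];
#'   the writer returns `path` invisibly. Round trips preserve every
#'   nonzero weight exactly.
#' @export
read_temporal_edgelist <- function(path, n_nodes = NULL, n_time = NULL) {
  rows <- io_read_rows(path, "\t")
  cells <- rows$cells
  if (any(lengths(cells) != 4L)) {
    bad <- which(lengths(cells) != 4L)[1]
    stop("expected 4 columns (i, j, t, weight) at line ", rows$lines[bad], call. = FALSE)
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(cells))), ncol = 4, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    stop("non-numeric cell at line ", rows$lines[bad], call. = FALSE)
  }
  i <- m[, 1]; j <- m[, 2]; t <- m[, 3]; wt <- m[, 4]
  if (any(i != floor(i) | j != floor(j) | t != floor(t) | i < 0 | j < 0 | t < 0)) {
    stop("node and time indices must be nonnegative integers (0-based)", call. = FALSE)
  }
  if (any(i == j)) {
    stop("self-loop at line ", rows$lines[which(i == j)[1]], call. = FALSE)
  }
  n <- if (is.null(n_nodes)) max(i, j) + 1L else as.integer(n_nodes)
  tt <- if (is.null(n_time)) max(t) + 1L else as.integer(n_time)
  if (any(i >= n | j >= n | t >= tt)) {
    bad <- which(i >= n | j >= n | t >= tt)[1]
    stop("index out of range at line ", rows$lines[bad], call. = FALSE)
  }
  w <- array(0, c(n, n, tt))
  key <- paste(pmin(i, j), pmax(i, j), t)
  dup <- duplicated(key)
  if (any(dup)) {
    for (k in which(dup)) {
      prev <- match(key[k], key)
      if (wt[k] != wt[prev]) {
        stop("conflicting weights for edge (", i[k], ",", j[k], ") at time ", t[k],
             ": ", wt[prev], " vs ", wt[k], call. = FALSE)
      }
    }
  }
  w[cbind(i + 1L, j + 1L, t + 1L)] <- wt
  w[cbind(j + 1L, i + 1L, t + 1L)] <- wt
  temporal_network(w)
}

#' @rdname read_temporal_edgelist
#' @param net A [temporal_network()].
#' @export
write_temporal_edgelist <- function(net, path) {
  stopifnot(inherits(net, "temporal_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# temporalpc temporal-edgelist v1 (i\tj\tt\tweight, 0-based)", con)
  n <- n_nodes(net)
  for (t in seq_len(n_time(net))) {
    w <- net[, , t]
    idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    writeLines(sprintf("%d\t%d\t%d\t%.17g",
                       idx[, 1] - 1L, idx[, 2] - 1L, t - 1L, w[idx]), con)
  }
  invisible(path)
}

#' Read and write community partitions
#'
#' CSV with one row per node and one column per time point; a single
#' column yields a [static_partition()], several a [partition_sequence()].
#' Labels may be arbitrary strings or integers on disk; they are
#' re-encoded to dense nonnegative integers `0..K-1` in order of first
#' appearance (scanning time point by time point), so equal on-disk labels
#' stay equal and output is deterministic regardless of the source label
#' alphabet.
#'
#' @param path File path.
#' @return `read_partition()` returns a partition object; the writer
#'   returns `path` invisibly.
#' @export
read_partition <- function(path) {
  rows <- io_read_rows(path, ",")
  cells <- rows$cells
  if (length(cells) == 0L) stop("no rows in ", path, call. = FALSE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L) {
    stop("ragged row at line ", rows$lines[which(widths != widths[1])[1]], call. = FALSE)
  }
  raw <- matrix(unlist(cells), nrow = length(cells), byrow = TRUE)
  if (any(raw == "" | is.na(raw))) {
    stop("missing cell at line ",
         rows$lines[which(apply(raw == "" | is.na(raw), 1, any))[1]], call. = FALSE)
  }
  dense <- matrix(match(as.vector(raw), unique(as.vector(raw))) - 1L, nrow = nrow(raw))
  if (ncol(dense) == 1L) static_partition(dense[, 1]) else partition_sequence(dense)
}

#' @rdname read_partition
#' @param part A [static_partition()] or [partition_sequence()].
#' @export
write_partition <- function(part, path) {
  m <- if (inherits(part, "static_partition")) matrix(unclass(part), ncol = 1)
       else unclass(part)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# temporalpc partition v1 (rows nodes, columns time)", con)
  utils::write.table(m, con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Write one nodal measure as node x time CSV (node id first column).
#' Write a nodal measure series as CSV
#'
#' @param x A [nodal_measure_series()].
#' @param path File path.
#' @export
write_measure <- function(x, path) {
  stopifnot(inherits(x, "nodal_measure_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# temporalpc measure v1 (", attr(x, "measure_name"), ")"), con)
  writeLines(paste(c("node", paste0("t", seq_len(ncol(x)) - 1L)), collapse = ","), con)
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("n", seq_len(nrow(x)) - 1L)
  for (i in seq_len(nrow(x))) {
    writeLines(paste(c(ids[i], sprintf("%.17g", x[i, ])), collapse = ","), con)
  }
  invisible(path)
}

io_sep <- function(path, format) {
  if (!is.null(format)) {
    return(switch(match.arg(format, c("csv", "tsv")), csv = ",", tsv = "\t"))
  }
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

# split non-comment, non-blank lines into cells, keeping 1-based line numbers
io_read_rows <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  list(cells = strsplit(trimws(raw[keep]), sep, fixed = TRUE),
       lines = which(keep))
}
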