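#' Static community detection by modularity maximization
#'
#' Louvain modularity communities on a single weighted, nonnegative,
#' symmetric connectivity matrix (typically the time-averaged or static
#' Pearson connectivity, negative edges removed). Deterministic for a
#' given seed; labels are densified to `0..K-1` in order of first
#' appearance across nodes.
#'
#' @param mean_net Symmetric nonnegative `N x N` matrix with zero diagonal.
#' @param resolution Modularity resolution parameter (default 1).
#' @param seed Integer seed for the stochastic optimizer.
#' @return A [static_partition()].
#' @export
detect_static_communities <- function(mean_net, resolution = 1, seed = 1L) {
  mean_net <- as.matrix(mean_net)
  check_slice(mean_net)
  if (all(mean_net == 0)) stop("empty graph: all edge weights are zero", call. = FALSE)
  static_partition(louvain_membership(mean_net, resolution, seed))
}

#' Per-slice community detection on a temporal network
#'
#' Runs Louvain modularity maximization independently on every slice of a
#' thresholded temporal network. Labels are arbitrary per slice (dense
#' `0..K-1` within each slice) and not comparable across time until
#' [temporal_consensus()] is applied. An all-zero slice gets each node its
#' own singleton community, with a warning.
#'
#' @param net A thresholded [temporal_network()].
#' @param resolution Modularity resolution parameter (default 1).
#' @param seed Integer seed; per-slice seeds are derived deterministically
#'   from it.
#' @return A [partition_sequence()] (not consensus-relabeled).
#' @export
detect_slice_communities <- function(net, resolution = 1, seed = 1L) {
  stopifnot(inherits(net, "temporal_network"))
  if (!is_thresholded(net)) {
    stop("network must be thresholded (see threshold_negative_edges())", call. = FALSE)
  }
  n <- n_nodes(net)
  tt <- n_time(net)
  labs <- matrix(0L, n, tt, dimnames = list(node_ids(net), NULL))
  zero_slices <- integer(0)
  for (t in seq_len(tt)) {
    w <- net[, , t]
    if (all(w == 0)) {
      labs[, t] <- seq_len(n) - 1L
      zero_slices <- c(zero_slices, t)
    } else {
      labs[, t] <- louvain_membership(w, resolution, (seed * 1009L + t) %% .Machine$integer.max)
    }
  }
  if (length(zero_slices) > 0L) {
    warning("all-zero slice(s) ", paste(zero_slices, collapse = ", "),
            ": assigned singleton communities", call. = FALSE)
  }
  partition_sequence(labs)
}

louvain_membership <- function(w, resolution, seed) {
  check_slice(w)
  if (any(w < 0)) stop("community detection requires nonnegative weights", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  memb <- igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
  match(memb, unique(memb)) - 1L
}

check_slice <- function(w) {
  if (!is.matrix(w) || nrow(w) != ncol(w)) stop("slice must be square", call. = FALSE)
  if (!all(is.finite(w))) stop("slice must be finite", call. = FALSE)
  if (!isTRUE(all.equal(w, t(w), tolerance = 1e-12, check.attributes = FALSE))) {
    stop("slice is not symmetric", call. = FALSE)
  }
  if (any(diag(w) != 0)) stop("slice must have a zero diagonal", call. = FALSE)
  invisible(w)
}

#' Jaccard temporal consensus relabeling
#'
#' Relabels slice-wise community partitions so that corresponding
#' communities carry the same label through time: sweeping forward from
#' the second slice, each community at `t` is matched one-to-one with the
#' community at the already-relabeled `t - 1` whose node set has the
#' smallest Jaccard distance, and inherits its label. Matching is greedy
#' in ascending distance, accepting a pair only if the sets share at least
#' one node; ties are broken by the smallest member node index of the
#' community at `t`, then by the smallest candidate label. Unmatched
#' communities receive fresh labels never used before. Node membership is
#' never altered: per slice the output partition is identical to the
#' input up to relabeling, and the operation is idempotent.
#'
#' @param parts A [partition_sequence()].
#' @return A [partition_sequence()] with `consensus = TRUE`.
#' @export
temporal_consensus <- function(parts) {
  stopifnot(inherits(parts, "partition_sequence"))
  labs <- unclass(parts)
  n <- nrow(labs)
  tt <- ncol(labs)
  out <- matrix(0L, n, tt, dimnames = dimnames(labs))
  out[, 1] <- match(labs[, 1], unique(labs[, 1])) - 1L
  next_label <- max(out[, 1]) + 1L
  for (t in seq_len(tt)[-1]) {
    prev_sets <- split(seq_len(n), out[, t - 1])          # names are labels
    cur_sets <- split(seq_len(n), labs[, t])
    # order current communities by smallest member for deterministic ties
    cur_sets <- cur_sets[order(vapply(cur_sets, min, 0L))]
    cand <- expand.grid(cur = seq_along(cur_sets), prev = seq_along(prev_sets))
    cand$dist <- mapply(function(a, b) {
      jaccard_distance(cur_sets[[a]], prev_sets[[b]])
    }, cand$cur, cand$prev)
    cand <- cand[cand$dist < 1, , drop = FALSE]
    prev_labels <- as.integer(names(prev_sets))
    ord <- order(cand$dist,
                 vapply(cand$cur, function(a) min(cur_sets[[a]]), 0L),
                 prev_labels[cand$prev])
    cand <- cand[ord, , drop = FALSE]
    cur_taken <- logical(length(cur_sets))
    prev_taken <- logical(length(prev_sets))
    assigned <- rep(NA_integer_, length(cur_sets))
    for (k in seq_len(nrow(cand))) {
      a <- cand$cur[k]; b <- cand$prev[k]
      if (!cur_taken[a] && !prev_taken[b]) {
        assigned[a] <- prev_labels[b]
        cur_taken[a] <- TRUE
        prev_taken[b] <- TRUE
      }
    }
    for (a in seq_along(cur_sets)) {             # fresh labels, smallest member first
      if (is.na(assigned[a])) {
        assigned[a] <- next_label
        next_label <- next_label + 1L
      }
    }
    for (a in seq_along(cur_sets)) out[cur_sets[[a]], t] <- assigned[a]
  }
  partition_sequence(out, consensus = TRUE)
}

jaccard_distance <- function(a, b) {
  1 - length(intersect(a, b)) / length(union(a, b))
}
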