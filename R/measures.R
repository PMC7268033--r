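#' Static participation coefficient
#'
#' For one weighted, nonnegative connectivity matrix and one community
#' partition: `P_i = 1 - sum_s (k_is / k_i)^2`, where `k_is` is node `i`'s
#' strength into community `s` and `k_i` its total strength. `P_i` is 0
#' when all of a node's strength lies in one community and approaches 1
#' when spread evenly over many. A node with zero strength is assigned 0
#' ("no participation").
#'
#' @param net_slice Symmetric nonnegative `N x N` matrix, zero diagonal.
#' @param part A [static_partition()] of length `N`.
#' @return Numeric vector of length `N`, values in `[0, 1)`.
#' @examples
#' w <- matrix(0, 4, 4); w[1, 2] <- w[2, 1] <- 1; w[1, 3] <- w[3, 1] <- 1
#' static_pc(w, static_partition(c(0, 0, 1, 1)))
#' @export
static_pc <- function(net_slice, part) {
  net_slice <- as.matrix(net_slice)
  check_slice(net_slice)
  if (any(net_slice < 0)) stop("participation requires a thresholded (nonnegative) network",
                               call. = FALSE)
  if (!inherits(part, "static_partition")) part <- static_partition(part)
  if (length(part) != nrow(net_slice)) {
    stop("partition length (", length(part), ") does not match network size (",
         nrow(net_slice), ")", call. = FALSE)
  }
  pc_from_slice(net_slice, as.integer(part))
}

pc_from_slice <- function(w, labels) {
  ks <- strength_by_community(w, labels)
  k <- rowSums(w)
  p <- numeric(nrow(w))
  pos <- k > 0
  p[pos] <- 1 - rowSums((ks[pos, , drop = FALSE] / k[pos])^2)
  pmax(p, 0)
}

#' Participation coefficient through time with a static partition (PC_S)
#'
#' Applies [static_pc()] at every slice of a temporal network using one
#' community partition for all time points:
#' `P_it = 1 - sum_s (k_its / k_it)^2` over the static communities. Values
#' at different time points share the same community context and are
#' directly comparable.
#'
#' @param net A thresholded [temporal_network()].
#' @param part A [static_partition()].
#' @return A [nodal_measure_series()] (`N x T`), measure `"PC_S"`.
#' @export
pc_s <- function(net, part) {
  check_measure_inputs(net)
  labs <- partition_at_times(part, n_nodes(net), n_time(net))
  vals <- vapply(seq_len(n_time(net)),
                 function(t) pc_from_slice(net[, , t], labs[, t]),
                 numeric(n_nodes(net)))
  vals <- matrix(vals, nrow = n_nodes(net), dimnames = list(node_ids(net), NULL))
  nodal_measure_series(vals, "PC_S", provenance = "static partition at every slice")
}

#' Participation coefficient through time with temporal partitions (PC_T)
#'
#' `P_it = 1 - sum_s (k_its / k_it)^2` where the sum runs over the
#' communities of the partition at time `t` only. Each value is correct in
#' isolation, but because the community context changes from slice to
#' slice, values at different time points are generally not comparable —
#' see [tpc()] for the variant that restores comparability.
#'
#' @param net A thresholded [temporal_network()].
#' @param parts A [partition_sequence()] aligned with `net`.
#' @return A [nodal_measure_series()] (`N x T`), measure `"PC_T"`.
#' @export
pc_t <- function(net, parts) {
  check_measure_inputs(net)
  if (!inherits(parts, "partition_sequence")) {
    stop("parts must be a partition_sequence", call. = FALSE)
  }
  labs <- partition_at_times(parts, n_nodes(net), n_time(net))
  vals <- vapply(seq_len(n_time(net)),
                 function(t) pc_from_slice(net[, , t], labs[, t]),
                 numeric(n_nodes(net)))
  vals <- matrix(vals, nrow = n_nodes(net), dimnames = list(node_ids(net), NULL))
  nodal_measure_series(vals, "PC_T", provenance = "slice t partition at slice t")
}

#' Temporal participation coefficient (TPC)
#'
#' For each slice `t`, the participation of node `i` is evaluated against
#' the community partition of *every* time point and averaged:
#' `P_it = 1 - (1/T) sum_u sum_{s in partition u} (k_its(u) / k_it)^2`,
#' where `k_its(u)` is node `i`'s strength at time `t` into community `s`
#' of the partition at time `u`. Every slice is thus scored against the
#' same set of community contexts, so TPC values are comparable across
#' time while still using the temporal community information. Partitions
#' that recur at several time points are counted with their multiplicity,
#' weighting recurrent community configurations by their prevalence.
#'
#' @param net A thresholded [temporal_network()].
#' @param parts A [partition_sequence()] aligned with `net`.
#' @return A [nodal_measure_series()] (`N x T`), measure `"TPC"`.
#' @export
tpc <- function(net, parts) {
  check_measure_inputs(net)
  if (!inherits(parts, "partition_sequence")) {
    stop("parts must be a partition_sequence", call. = FALSE)
  }
  n <- n_nodes(net)
  tt <- n_time(net)
  labs <- partition_at_times(parts, n, tt)
  # group identical partitions: algebraically identical to looping u = 1..T,
  # each unique partition weighted by the number of slices carrying it
  key <- apply(labs, 2, paste, collapse = "\r")
  uniq <- !duplicated(key)
  mult <- as.vector(table(factor(key, levels = key[uniq])))
  sumsq <- matrix(0, n, tt)
  k <- vapply(seq_len(tt), function(t) rowSums(net[, , t]), numeric(n))
  ui <- 0L
  for (u in which(uniq)) {
    ui <- ui + 1L
    lab_u <- labs[, u]
    labset <- sort(unique(lab_u))
    ind <- outer(lab_u, labset, "==") + 0
    for (t in seq_len(tt)) {
      ks <- net[, , t] %*% ind
      pos <- k[, t] > 0
      sq <- numeric(n)
      sq[pos] <- rowSums((ks[pos, , drop = FALSE] / k[pos, t])^2)
      sq[!pos] <- 1       # zero-strength convention: contributes P = 0
      sumsq[, t] <- sumsq[, t] + mult[ui] * sq
    }
  }
  vals <- 1 - sumsq / tt
  vals <- pmin(pmax(vals, 0), 1 - 1e-15)
  dimnames(vals) <- list(node_ids(net), NULL)
  nodal_measure_series(vals, "TPC",
                       provenance = "all temporal partitions averaged per slice")
}

#' Node flexibility
#'
#' Fraction of consecutive time steps at which a node changes its
#' community label: `f_i = #{t : label_it != label_i(t-1)} / (T - 1)`.
#' Labels must be comparable across time, i.e. the sequence should be
#' consensus-relabeled (see [temporal_consensus()]); a warning is issued
#' otherwise.
#'
#' @param parts A [partition_sequence()].
#' @return Numeric vector of length `N`, values in `[0, 1]`.
#' @export
flexibility <- function(parts) {
  stopifnot(inherits(parts, "partition_sequence"))
  if (ncol(parts) < 2L) stop("flexibility needs at least 2 time points", call. = FALSE)
  if (!isTRUE(attr(parts, "consensus"))) {
    warning("partition sequence is not consensus-relabeled; ",
            "labels may not be comparable across time", call. = FALSE)
  }
  labs <- unclass(parts)
  changes <- labs[, -1, drop = FALSE] != labs[, -ncol(labs), drop = FALSE]
  f <- rowMeans(changes)
  names(f) <- rownames(labs)
  f
}

#' Within-module degree z-score through time
#'
#' For each slice, the z-score of a node's within-community strength
#' relative to the other members of its community:
#' `z_it = (k_i,si,t - mean_j k_j,si,t) / sd_j k_j,si,t` over members `j`
#' of node `i`'s community `si` at `t`. With a [static_partition()] the
#' same communities are used at every slice (`z_S`); with a
#' [partition_sequence()] slice `t` uses its own partition (`z_T`). The
#' standard deviation is the population (N-denominator) form; members of a
#' singleton or zero-variance community get `z = 0`.
#'
#' @param net A thresholded [temporal_network()].
#' @param partition A [static_partition()] or [partition_sequence()].
#' @return A [nodal_measure_series()] (`N x T`), measure `"z_S"` or
#'   `"z_T"`.
#' @export
module_degree_zscore <- function(net, partition) {
  check_measure_inputs(net)
  n <- n_nodes(net)
  tt <- n_time(net)
  labs <- partition_at_times(partition, n, tt)
  vals <- matrix(0, n, tt, dimnames = list(node_ids(net), NULL))
  for (t in seq_len(tt)) {
    w <- net[, , t]
    lab <- labs[, t]
    for (s in unique(lab)) {
      members <- which(lab == s)
      if (length(members) < 2L) next
      kin <- rowSums(w[members, members, drop = FALSE])
      sd_pop <- sqrt(mean((kin - mean(kin))^2))
      if (sd_pop > 0) vals[members, t] <- (kin - mean(kin)) / sd_pop
    }
  }
  name <- if (inherits(partition, "static_partition")) "z_S" else "z_T"
  nodal_measure_series(vals, name,
                       provenance = if (name == "z_S") "static partition at every slice"
                                    else "slice t partition at slice t")
}

check_measure_inputs <- function(net) {
  if (!inherits(net, "temporal_network")) stop("net must be a temporal_network", call. = FALSE)
  if (!is_thresholded(net)) {
    stop("network must be thresholded (see threshold_negative_edges())", call. = FALSE)
  }
  invisible(net)
}
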