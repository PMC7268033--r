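#' Hand-constructed two-slice toy scenarios
#'
#' Small weighted temporal networks (T = 2) with planted community
#' partitions that isolate the ways a node's participation can change
#' between snapshots:
#'
#' * `"fig1b"` — constant communities; the focal node's edges spread
#'   evenly over all communities at the second slice (all PC variants
#'   rise).
#' * `"fig1c"` — the focal node strengthens an edge toward another
#'   community and is absorbed into it; its per-slice temporal PC *falls*
#'   even though the edge grew.
#' * `"fig1d"` — the focal node's own edges are identical at both slices,
#'   but edges elsewhere merge the two communities; per-slice temporal PC
#'   changes with no change in the node's connectivity (PC_S and TPC are
#'   flat).
#' * `"fig2_split"` — the focal node's community splits because internal
#'   edges weaken; PC_T rises (suggesting integration) while PC_S and TPC
#'   fall.
#' * `"fig2_extend"` — the community extends because edges strengthen;
#'   PC_T falls while PC_S and TPC rise.
#' * `"fig3"` — a single bridge edge merges two communities at the second
#'   slice and only that edge differs between slices; TPC assigns the
#'   merged slice at least the split slice's participation.
#'
#' Weights use two base levels (strong 1.0, weak 0.5) except where the
#' scenario requires a graded bridge; only the *signs* of the focal node's
#' measure changes are meaningful, which `expected_signs` records.
#'
#' @param name Scenario name (see above).
#' @param seed Optional integer; for `"fig3"` draws the weight
#'   configuration at random from the ranges that realize the
#'   construction (within edges 0.8-1.2, merged bridge 0.8-1.6, split
#'   bridge 0.05-0.3, cross edge 0.2-0.5). Ignored by other scenarios.
#' @return An object of class `toy_scenario`: a list with elements
#'   `name`, `network` (thresholded [temporal_network()]),
#'   `planted_partitions` ([partition_sequence()]), `static_partition`,
#'   `focal_node` (1-based index), and `expected_signs`, a named character
#'   vector over `pc_s`, `pc_t`, `tpc` with values `"+"`, `"-"` or `"0"`
#'   for the focal node's change from slice 1 to slice 2.
#' @examples
#' toy <- make_toy("fig2_split")
#' pc_t(toy$network, toy$planted_partitions)[toy$focal_node, ]
#' @export
make_toy <- function(name = c("fig1b", "fig1c", "fig1d", "fig2_split",
                              "fig2_extend", "fig3"),
                     seed = NULL) {
  name <- match.arg(name)
  scen <- switch(name,
    fig1b = toy_fig1b(),
    fig1c = toy_fig1c(),
    fig1d = toy_fig1d(),
    fig2_split = toy_fig2(split = TRUE),
    fig2_extend = toy_fig2(split = FALSE),
    fig3 = toy_fig3(seed)
  )
  scen$name <- name
  class(scen) <- "toy_scenario"
  scen
}

#' @export
print.toy_scenario <- function(x, ...) {
  cat("<toy_scenario: ", x$name, "> ", n_nodes(x$network), " nodes, 2 slices; focal node ",
      x$focal_node, "\n expected signs (t1 -> t2): ",
      paste(names(x$expected_signs), x$expected_signs, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# symmetric slice from (i, j, w) rows
toy_slice <- function(n, edges) {
  w <- matrix(0, n, n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    w[i, j] <- w[j, i] <- edges[k, 3]
  }
  w
}

# all within-community pairs among `members`, excluding pairs touching `skip`
clique_edges <- function(members, weight = 1, skip = integer(0)) {
  members <- setdiff(members, skip)
  if (length(members) < 2) return(matrix(numeric(0), ncol = 3))
  p <- t(utils::combn(members, 2))
  cbind(p, weight)
}

toy_network <- function(n, edges1, edges2) {
  w <- array(0, c(n, n, 2))
  w[, , 1] <- toy_slice(n, edges1)
  w[, , 2] <- toy_slice(n, edges2)
  temporal_network(w, thresholded = TRUE)
}

toy_fig1b <- function() {
  A <- 1:4; B <- 5:8; C <- 9:12
  bg <- rbind(clique_edges(A, skip = 1), clique_edges(B), clique_edges(C))
  e1 <- rbind(bg, cbind(1, c(2, 3, 4), 1))
  e2 <- rbind(bg, cbind(1, c(2, 5, 9), 1))
  lab <- rep(0:2, each = 4)
  list(network = toy_network(12, e1, e2),
       planted_partitions = partition_sequence(cbind(lab, lab), consensus = TRUE),
       static_partition = static_partition(lab),
       focal_node = 1L,
       expected_signs = c(pc_s = "+", pc_t = "+", tpc = "+"))
}

toy_fig1c <- function() {
  A <- 1:4; B <- 5:8
  bg <- rbind(clique_edges(A, skip = 1), clique_edges(B))
  focal1 <- cbind(1, c(2, 5, 6), c(0.5, 1.0, 1.0))
  focal2 <- cbind(1, c(2, 5, 6), c(0.5, 2.0, 1.0))
  lab1 <- c(0, 0, 0, 0, 1, 1, 1, 1)
  lab2 <- c(1, 0, 0, 0, 1, 1, 1, 1)   # focal absorbed into community it strengthened
  list(network = toy_network(8, rbind(bg, focal1), rbind(bg, focal2)),
       planted_partitions = partition_sequence(cbind(lab1, lab2), consensus = TRUE),
       static_partition = static_partition(lab1),
       focal_node = 1L,
       expected_signs = c(pc_s = "-", pc_t = "-", tpc = "-"))
}

toy_fig1d <- function() {
  A <- 1:4; B <- 5:8
  bg <- rbind(clique_edges(A, skip = 1), clique_edges(B))
  focal <- cbind(1, c(2, 5), c(1.0, 1.0))
  merge_edges <- cbind(c(3, 4), c(6, 7), c(2.0, 2.0))  # do not touch the focal node
  lab1 <- c(0, 0, 0, 0, 1, 1, 1, 1)
  lab2 <- rep(0, 8)
  list(network = toy_network(8, rbind(bg, focal), rbind(bg, focal, merge_edges)),
       planted_partitions = partition_sequence(cbind(lab1, lab2), consensus = TRUE),
       static_partition = static_partition(lab1),
       focal_node = 1L,
       expected_signs = c(pc_s = "0", pc_t = "-", tpc = "0"))
}

toy_fig2 <- function(split) {
  A <- 1:4; B <- 5:8; C <- 9:12
  bg <- rbind(clique_edges(A, skip = 1), clique_edges(B), clique_edges(C))
  focal_within <- cbind(1, c(2, 3, 4), 1)
  cross <- cbind(1, 9, 0.5)
  bridge_strong <- cbind(1, c(5, 6), 0.5)
  bridge_weak <- cbind(1, c(5, 6), 0.25)
  # additional inter-block support edges away from the focal node, so the
  # planted merge/split is also what modularity detection finds per slice;
  # they never touch node 1, so no focal measure value depends on them
  pairs_ab <- as.matrix(expand.grid(c(2, 3, 4), c(6, 7, 8)))
  support_strong <- cbind(pairs_ab, 1.0)
  support_weak <- cbind(pairs_ab, 0.1)
  merged <- c(rep(0, 8), rep(1, 4))
  apart <- rep(0:2, each = 4)
  if (split) {
    e1 <- rbind(bg, focal_within, cross, bridge_strong, support_strong)
    e2 <- rbind(bg, focal_within, cross, bridge_weak, support_weak)
    labs <- cbind(merged, apart)
    signs <- c(pc_s = "-", pc_t = "+", tpc = "-")
  } else {
    e1 <- rbind(bg, focal_within, cross, bridge_weak, support_weak)
    e2 <- rbind(bg, focal_within, cross, bridge_strong, support_strong)
    labs <- cbind(apart, merged)
    signs <- c(pc_s = "+", pc_t = "-", tpc = "+")
  }
  list(network = toy_network(12, e1, e2),
       planted_partitions = partition_sequence(labs, consensus = TRUE),
       static_partition = static_partition(apart),
       focal_node = 1L,
       expected_signs = signs)
}

toy_fig3 <- function(seed = NULL) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    within <- stats::runif(2, 0.8, 1.2)
    b_merge <- stats::runif(1, 0.8, 1.6)
    b_split <- stats::runif(1, 0.05, 0.3)
    cross <- stats::runif(1, 0.2, 0.5)
  } else {
    within <- c(1, 1); b_merge <- 1.2; b_split <- 0.2; cross <- 0.35
  }
  A <- 1:3; B <- 4:6; C <- 7:9
  bg <- rbind(clique_edges(A, skip = 1), clique_edges(B), clique_edges(C))
  focal_within <- cbind(1, c(2, 3), within)
  e_split <- rbind(bg, focal_within, cbind(1, 4, b_split), cbind(1, 7, cross))
  e_merge <- rbind(bg, focal_within, cbind(1, 4, b_merge), cbind(1, 7, cross))
  apart <- rep(0:2, each = 3)
  merged <- c(rep(0, 6), rep(1, 3))
  list(network = toy_network(9, e_split, e_merge),   # slice 1 split, slice 2 merged
       planted_partitions = partition_sequence(cbind(apart, merged), consensus = TRUE),
       static_partition = static_partition(apart),
       focal_node = 1L,
       expected_signs = c(pc_s = "+", pc_t = "-", tpc = "+"))
}

#' Specification for the recurring-state synthetic generator
#'
#' Describes a piecewise-stationary multivariate signal: time is tiled by
#' epochs, each epoch draws from a zero-mean multivariate normal whose
#' correlation matrix has a block (community) structure given by that
#' epoch's state, and the states cycle so every community configuration
#' recurs. This realizes the recurrence assumption the temporal
#' participation coefficient relies on.
#'
#' @param n_nodes,n_time Dimensions (defaults 40 nodes, 200 time points).
#' @param states List of integer label vectors of length `n_nodes`, one
#'   block partition per state. Default: two states of four 10-node
#'   blocks, the second a 5-node rotation of the first, so communities
#'   overlap but differ.
#' @param epoch_length Time points per epoch (default 50); must tile
#'   `n_time` and leave every state at least two epochs.
#' @param within,between Target correlations inside and between blocks
#'   (defaults 0.6 and 0.05; must satisfy `within > between`, both in
#'   (-1, 1)).
#' @param noise_sd Standard deviation of white measurement noise added on
#'   top of the unit-variance signal (default 0.2).
#' @param seed Integer seed.
#' @return A `recurring_state_spec` list, validated.
#' @export
recurring_state_spec <- function(n_nodes = 40L, n_time = 200L, states = NULL,
                                 epoch_length = 50L, within = 0.6, between = 0.05,
                                 noise_sd = 0.2, seed = 1L) {
  n_nodes <- as.integer(n_nodes); n_time <- as.integer(n_time)
  epoch_length <- as.integer(epoch_length)
  if (is.null(states)) {
    if (n_nodes %% 4L != 0L) stop("default states need n_nodes divisible by 4", call. = FALSE)
    block <- n_nodes %/% 4L
    s1 <- rep(0:3, each = block)
    s2 <- s1[(seq_len(n_nodes) + block %/% 2L - 1L) %% n_nodes + 1L]
    states <- list(s1, s2)
  }
  k <- length(states)
  if (k < 1L || !all(lengths(states) == n_nodes)) {
    stop("each state must label all ", n_nodes, " nodes", call. = FALSE)
  }
  if (n_time %% epoch_length != 0L) stop("epochs must tile n_time exactly", call. = FALSE)
  n_epochs <- n_time %/% epoch_length
  if (n_epochs < 2L * k) {
    stop("each state must recur at least twice (need >= ", 2L * k, " epochs)", call. = FALSE)
  }
  if (!(within > between) || abs(within) >= 1 || abs(between) >= 1) {
    stop("need -1 < between < within < 1", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(n_nodes = n_nodes, n_time = n_time, states = states,
                 epoch_length = epoch_length, within = within, between = between,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "recurring_state_spec")
}

#' Generate a recurring-state multivariate time series
#'
#' Samples the signal described by a [recurring_state_spec()]: epochs
#' cycle through the states in order (`1, 2, ..., K, 1, 2, ...`), each
#' epoch drawing from a multivariate normal with the state's block
#' correlation structure, plus independent Gaussian measurement noise.
#' Bit-for-bit deterministic given the spec (including its seed).
#'
#' @param spec A [recurring_state_spec()].
#' @return A [node_timeseries()] with attribute `state_sequence` (the
#'   state index of every time point) and `spec`.
#' @export
generate_recurring_timeseries <- function(spec) {
  stopifnot(inherits(spec, "recurring_state_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  sigmas <- lapply(spec$states, function(lab) {
    s <- outer(lab, lab, "==") * (spec$within - spec$between) + spec$between
    diag(s) <- 1
    ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) {
      stop("target correlation matrix is not positive definite; ",
           "reduce the within/between contrast", call. = FALSE)
    }
    s
  })
  n_epochs <- spec$n_time %/% spec$epoch_length
  state_seq_epoch <- rep_len(seq_along(spec$states), n_epochs)
  x <- matrix(0, spec$n_nodes, spec$n_time)
  for (e in seq_len(n_epochs)) {
    cols <- ((e - 1L) * spec$epoch_length + 1L):(e * spec$epoch_length)
    x[, cols] <- t(MASS::mvrnorm(spec$epoch_length, mu = rep(0, spec$n_nodes),
                                 Sigma = sigmas[[state_seq_epoch[e]]]))
  }
  if (spec$noise_sd > 0) {
    x <- x + matrix(stats::rnorm(length(x), sd = spec$noise_sd), nrow = nrow(x))
  }
  out <- node_timeseries(x)
  attr(out, "state_sequence") <- rep(state_seq_epoch, each = spec$epoch_length)
  attr(out, "spec") <- spec
  out
}

#' Random nonnegative temporal network
#'
#' Independent Erdos-Renyi-style slices for property-based testing: each
#' unordered node pair is an edge with probability `density`, with weight
#' drawn uniformly from (0, 1).
#'
#' @param n_nodes,n_time Dimensions.
#' @param density Edge probability in (0, 1].
#' @param seed Integer seed.
#' @return A thresholded [temporal_network()].
#' @export
generate_random_temporal_network <- function(n_nodes, n_time, density = 0.5, seed = 1L) {
  if (density <= 0 || density > 1) stop("density must be in (0, 1]", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  n <- as.integer(n_nodes); tt <- as.integer(n_time)
  w <- array(0, c(n, n, tt))
  ut <- upper.tri(matrix(0, n, n))
  for (t in seq_len(tt)) {
    m <- matrix(0, n, n)
    on_edge <- stats::runif(sum(ut)) < density
    wt <- stats::runif(sum(ut))
    m[ut] <- on_edge * wt
    w[, , t] <- m + t(m)
  }
  temporal_network(w, thresholded = TRUE)
}
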