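test_that("toy scenarios satisfy their construction constraints", {
  expect_error(make_toy("nope"), "arg")

  # fig1d: the focal node's connectivity is identical at both slices
  toy <- make_toy("fig1d")
  expect_identical(toy$network[toy$focal_node, , 1],
                   toy$network[toy$focal_node, , 2])
  # ... and the slices differ elsewhere
  expect_false(identical(unclass(toy$network)[, , 1], unclass(toy$network)[, , 2]))

  # fig2_split: partitions differ between slices only within the split community
  toy <- make_toy("fig2_split")
  p <- toy$planted_partitions
  merged_comm <- which(p[, 1] == p[toy$focal_node, 1])
  outside <- setdiff(seq_len(nrow(p)), merged_comm)
  expect_same_partition_structure(p[outside, 1], p[outside, 2])
  expect_gt(length(unique(p[merged_comm, 2])), length(unique(p[merged_comm, 1])))

  # every scenario: valid thresholded network, planted partitions aligned
  for (nm in c("fig1b", "fig1c", "fig1d", "fig2_split", "fig2_extend", "fig3")) {
    toy <- make_toy(nm)
    expect_s3_class(toy$network, "temporal_network")
    expect_true(is_thresholded(toy$network))
    expect_equal(n_time(toy$network), 2)
    expect_equal(dim(toy$planted_partitions), c(n_nodes(toy$network), 2))
    expect_true(all(toy$expected_signs %in% c("+", "-", "0")))
  }
})

test_that("every toy reproduces its expected sign pattern across all measures", {
  sgn <- function(v) if (abs(v) < 1e-12) "0" else if (v > 0) "+" else "-"
  for (nm in c("fig1b", "fig1c", "fig1d", "fig2_split", "fig2_extend", "fig3")) {
    toy <- make_toy(nm)
    i <- toy$focal_node
    got <- c(
      pc_s = sgn(diff(pc_s(toy$network, toy$static_partition)[i, ])),
      pc_t = sgn(diff(pc_t(toy$network, toy$planted_partitions)[i, ])),
      tpc = sgn(diff(tpc(toy$network, toy$planted_partitions)[i, ]))
    )
    expect_equal(got, toy$expected_signs, label = nm)
  }
})

test_that("recurring-state spec validates its fields", {
  expect_error(recurring_state_spec(n_time = 130), "tile")
  expect_error(recurring_state_spec(n_time = 100), "recur at least twice")
  expect_error(recurring_state_spec(within = 0.05, between = 0.6), "within")
  expect_error(recurring_state_spec(states = list(0:1)), "label all")
  expect_error(generate_recurring_timeseries(
    recurring_state_spec(n_nodes = 8, n_time = 40, epoch_length = 10,
                         states = list(rep(0:1, each = 4), rep(0:1, 4)),
                         within = -0.9, between = -0.95)),
    "positive definite")
})

test_that("the generator is deterministic and plants the block correlations", {
  spec <- recurring_state_spec(n_nodes = 16, n_time = 120, epoch_length = 30,
                               states = list(rep(0:1, each = 8), rep(0:1, 8)),
                               seed = 81)
  a <- generate_recurring_timeseries(spec)
  b <- generate_recurring_timeseries(spec)
  expect_identical(unclass(a), unclass(b))

  # empirical within/between correlations approach the targets in each epoch
  x <- unclass(a)
  s1 <- spec$states[[1]]
  cc <- cor(t(x[, 1:30]))      # first epoch carries state 1
  within <- mean(cc[outer(s1, s1, "==") & upper.tri(cc)])
  between <- mean(cc[outer(s1, s1, "!=") & upper.tri(cc)])
  # noise_sd = 0.2 attenuates the target 0.6 to about 0.58
  expect_gt(within, 0.45)
  expect_lt(abs(between), 0.15)
  expect_gt(within - between, 0.3)

  expect_equal(attr(a, "state_sequence"), rep(rep(1:2, 2), each = 30))
})

test_that("no community structure emerges when within equals between", {
  spec <- recurring_state_spec(n_nodes = 16, n_time = 60, epoch_length = 15,
                               states = list(rep(0:1, each = 8), rep(0:1, 8)),
                               within = 0.2, between = 0.19, seed = 82)
  ts <- generate_recurring_timeseries(spec)
  net <- threshold_negative_edges(estimate_tvc_weighted_pearson(ts))
  parts <- suppressWarnings(detect_slice_communities(net, seed = 82))
  states <- attr(ts, "state_sequence")
  aris <- sapply(seq_len(ncol(parts)), function(t)
    ari(parts[, t], spec$states[[states[t]]]))
  expect_lt(mean(aris), 0.2)   # chance-level agreement with planted blocks
})

test_that("strong contrast yields informative slice partitions; state-pure estimates recover blocks exactly", {
  spec <- recurring_state_spec(seed = 7)
  ts <- generate_recurring_timeseries(spec)
  states <- attr(ts, "state_sequence")

  # through the distance-weighted estimator: far above chance at every slice
  net <- threshold_negative_edges(estimate_tvc_weighted_pearson(ts))
  parts <- suppressWarnings(detect_slice_communities(net, seed = 7))
  aris <- sapply(seq_len(ncol(parts)), function(t)
    ari(parts[, t], spec$states[[states[t]]]))
  expect_gt(mean(aris), 0.4)
  expect_gt(mean(aris > 0.2), 0.9)

  # with weights restricted to same-state time points, recovery is exact:
  # the mixture of states in the distance weights, not the contrast or the
  # detector, is what limits per-slice recovery above
  arr <- array(0, dim(unclass(net)))
  for (t in seq_len(dim(arr)[3])) {
    arr[, , t] <- weighted_pearson_slice(ts, as.numeric(states == states[t]))
  }
  pure <- threshold_negative_edges(temporal_network(arr))
  pparts <- detect_slice_communities(pure, seed = 7)
  paris <- sapply(seq_len(ncol(pparts)), function(t)
    ari(pparts[, t], spec$states[[states[t]]]))
  expect_gte(mean(paris == 1), 0.9)
})

test_that("random temporal networks are valid, dense as requested, deterministic", {
  net <- generate_random_temporal_network(10, 5, density = 1, seed = 91)
  for (t in 1:5) {
    w <- net[, , t]
    expect_equal(sum(w[upper.tri(w)] > 0), 45)   # complete graph
  }
  expect_identical(unclass(generate_random_temporal_network(6, 3, 0.4, seed = 9)),
                   unclass(generate_random_temporal_network(6, 3, 0.4, seed = 9)))

  # edge count concentrates around density * N(N-1)/2
  counts <- sapply(1:100, function(s) {
    w <- generate_random_temporal_network(8, 1, density = 0.3, seed = s)[, , 1]
    sum(w[upper.tri(w)] > 0)
  })
  expect_gt(mean(counts), 0.3 * 28 - 2 * sqrt(28 * 0.3 * 0.7 / 100) - 1)
  expect_lt(mean(counts), 0.3 * 28 + 2 * sqrt(28 * 0.3 * 0.7 / 100) + 1)
  expect_error(generate_random_temporal_network(5, 2, density = 0), "density")
})
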