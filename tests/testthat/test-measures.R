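# node 1 with one unit edge into each of m communities (plus filler nodes)
equal_split_slice <- function(m) {
  n <- 1 + 2 * m
  w <- matrix(0, n, n)
  targets <- 1 + seq_len(m)
  w[1, targets] <- 1; w[targets, 1] <- 1
  lab <- c(0L, rep(seq_len(m) - 1L, 2))   # focal in community 0, 2 nodes per community
  list(w = w, part = static_partition(lab))
}

test_that("static PC follows its closed forms and the brute-force oracle", {
  # all strength inside one community
  w <- matrix(0, 4, 4); w[1, 2] <- w[2, 1] <- 1; w[3, 4] <- w[4, 3] <- 0.5
  p <- static_pc(w, static_partition(c(0, 0, 1, 1)))
  expect_equal(p[1], 0)

  # equal split over M communities: PC = 1 - 1/M
  for (m in 2:8) {
    es <- equal_split_slice(m)
    expect_equal(static_pc(es$w, es$part)[1], 1 - 1 / m, tolerance = 1e-14)
  }

  # two distinct edge weights across 3 communities vs explicit oracle
  w <- matrix(0, 6, 6)
  w[1, 2] <- 1; w[1, 3] <- 0.5; w[1, 5] <- 0.5; w[2, 3] <- 1; w[5, 6] <- 1
  w <- w + t(w)
  lab <- c(0, 0, 1, 1, 2, 2)
  expect_equal(static_pc(w, static_partition(lab)), oracle_pc_slice(w, lab),
               tolerance = 1e-12)

  expect_error(static_pc(w, static_partition(c(0, 1))), "does not match")
  wn <- w; wn[1, 2] <- wn[2, 1] <- -1
  expect_error(static_pc(wn, static_partition(lab)), "nonnegative")
})

test_that("PC_S applies the static partition slice-wise, zero strength gives 0", {
  set.seed(61)
  net <- generate_random_temporal_network(7, 4, density = 0.8, seed = 61)
  part <- static_partition(c(0, 0, 0, 1, 1, 2, 2))
  ps <- pc_s(net, part)
  for (t in 1:4) {
    expect_equal(unname(ps[, t]), oracle_pc_slice(net[, , t], unclass(part)),
                 tolerance = 1e-12)
  }

  # constant network: every column identical
  w <- array(rep(net[, , 1], 3), c(7, 7, 3))
  cnet <- temporal_network(w, thresholded = TRUE)
  psc <- pc_s(cnet, part)
  expect_equal(psc[, 2], psc[, 1])
  expect_equal(psc[, 3], psc[, 1])

  # isolated node at a slice
  w0 <- unclass(net); w0[1, , 2] <- 0; w0[, 1, 2] <- 0
  p0 <- pc_s(temporal_network(w0, thresholded = TRUE), part)
  expect_equal(unname(p0[1, 2]), 0)
})

test_that("a node spreading its edges over all communities raises PC_S", {
  toy <- make_toy("fig1b")
  ps <- pc_s(toy$network, toy$static_partition)
  expect_equal(unname(ps[1, 1]), oracle_pc_slice(toy$network[, , 1],
                                                 unclass(toy$static_partition))[1])
  expect_gt(ps[1, 2], ps[1, 1])
})

test_that("PC_T uses each slice's own partition", {
  set.seed(62)
  net <- generate_random_temporal_network(8, 5, density = 0.7, seed = 62)
  parts <- random_partition_sequence(8, 5, seed = 63)
  pt <- pc_t(net, parts)
  for (t in 1:5) {
    expect_equal(unname(pt[, t]), oracle_pc_slice(net[, , t], parts[, t]),
                 tolerance = 1e-12)
  }

  # constant partition sequence: pc_t equals pc_s elementwise
  const <- partition_sequence(matrix(rep(c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L), 5), ncol = 5))
  expect_equal(unclass(pc_t(net, const)),
               unclass(pc_s(net, static_partition(const[, 1]))),
               tolerance = 1e-14, ignore_attr = TRUE)

  # singleton communities: node with m equal edges has PC 1 - 1/m
  es <- equal_split_slice(3)
  netl <- temporal_network(array(es$w, c(7, 7, 1)), thresholded = TRUE)
  singl <- partition_sequence(matrix(0:6, ncol = 1))
  expect_equal(unname(pc_t(netl, singl)[1, 1]), 1 - 1 / 3, tolerance = 1e-14)

  expect_error(pc_t(net, random_partition_sequence(8, 4, seed = 1)), "shape")
})

test_that("a node absorbed into the community it strengthened loses PC_T", {
  toy <- make_toy("fig1c")
  pt <- pc_t(toy$network, toy$planted_partitions)
  # the strengthened edge grew from slice 1 to slice 2
  expect_gt(toy$network[1, 5, 2], toy$network[1, 5, 1])
  expect_lt(pt[1, 2], pt[1, 1])
})

test_that("TPC equals the literal double-sum oracle and its identities", {
  for (seed in 1:10) {
    net <- generate_random_temporal_network(6, 4, density = 0.6, seed = seed)
    parts <- random_partition_sequence(6, 4, seed = seed + 100)
    tp <- tpc(net, parts)
    expect_equal(unclass(tp), oracle_tpc(unclass(net), unclass(parts)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }

  # identical partitions at all times: tpc == pc_t == pc_s
  net <- generate_random_temporal_network(6, 4, density = 0.8, seed = 7)
  const <- partition_sequence(matrix(rep(c(0L, 0L, 1L, 1L, 2L, 2L), 4), ncol = 4))
  tp <- tpc(net, const)
  expect_equal(unclass(tp), unclass(pc_t(net, const)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unclass(tp), unclass(pc_s(net, static_partition(const[, 1]))),
               tolerance = 1e-12, ignore_attr = TRUE)

  # T = 2 toy: TPC at each slice is the mean of the two per-partition PC values
  toy <- make_toy("fig3")
  tp <- tpc(toy$network, toy$planted_partitions)
  for (t in 1:2) {
    per_u <- sapply(1:2, function(u) {
      oracle_pc_slice(toy$network[, , t], toy$planted_partitions[, u])
    })
    expect_equal(unname(tp[, t]), rowMeans(per_u), tolerance = 1e-12)
  }
})

test_that("duplicate partitions count with multiplicity in TPC", {
  net <- generate_random_temporal_network(5, 3, density = 0.9, seed = 8)
  labs <- cbind(c(0, 0, 1, 1, 1), c(0, 0, 1, 1, 1), c(0, 1, 0, 1, 0))
  tp <- tpc(net, partition_sequence(labs))
  expect_equal(unclass(tp), oracle_tpc(unclass(net), labs), tolerance = 1e-12,
               ignore_attr = TRUE)
  # the repeated partition is weighted 2/3, not 1/2 as deduplication would give
  weighted <- sapply(1:3, function(t) {
    (2 * oracle_pc_slice(net[, , t], labs[, 1]) +
     oracle_pc_slice(net[, , t], labs[, 3])) / 3
  })
  dedup <- sapply(1:3, function(t) {
    (oracle_pc_slice(net[, , t], labs[, 1]) +
     oracle_pc_slice(net[, , t], labs[, 3])) / 2
  })
  expect_equal(unclass(tp), weighted, tolerance = 1e-12, ignore_attr = TRUE)
  expect_false(isTRUE(all.equal(unclass(tp), dedup, check.attributes = FALSE,
                                tolerance = 1e-8)))
})

test_that("scaling a node's edges at one slice leaves its PC variants unchanged", {
  set.seed(64)
  for (trial in 1:10) {
    net <- generate_random_temporal_network(7, 3, density = 0.9, seed = 200 + trial)
    parts <- random_partition_sequence(7, 3, seed = 300 + trial)
    i <- sample(7, 1); t <- sample(3, 1); c0 <- sample(c(0.1, 2, 10), 1)
    w2 <- unclass(net)
    w2[i, , t] <- w2[i, , t] * c0
    w2[, i, t] <- w2[, i, t] * c0
    net2 <- temporal_network(w2, thresholded = TRUE)
    sp <- static_partition(parts[, 1])
    expect_equal(pc_s(net2, sp)[i, t], pc_s(net, sp)[i, t], tolerance = 1e-12)
    expect_equal(pc_t(net2, parts)[i, t], pc_t(net, parts)[i, t], tolerance = 1e-12)
    expect_equal(tpc(net2, parts)[i, t], tpc(net, parts)[i, t], tolerance = 1e-12)
  }
})

test_that("flexibility counts label changes over consecutive steps", {
  p <- partition_sequence(rbind(c(0, 0, 1, 1, 0),
                                c(0, 0, 0, 0, 0),
                                c(0, 1, 0, 1, 0)), consensus = TRUE)
  f <- unname(flexibility(p))
  expect_equal(f, c(0.5, 0, 1))
  expect_error(flexibility(partition_sequence(matrix(0L, 3, 1), consensus = TRUE)),
               "2 time points")
  expect_warning(flexibility(partition_sequence(matrix(0L, 3, 4))), "consensus")
})

test_that("within-module degree z-score matches hand computation and conventions", {
  # community {1,2,3} engineered to have unequal within-strengths
  w <- matrix(0, 5, 5)
  w[1, 2] <- 0.5; w[1, 3] <- 1.5; w[2, 3] <- 1.5
  w[4, 5] <- 1
  w <- w + t(w)
  lab <- c(0, 0, 0, 1, 1)
  net <- temporal_network(array(w, c(5, 5, 1)), thresholded = TRUE)
  z <- module_degree_zscore(net, static_partition(lab))
  kin <- c(2, 2, 3)
  zref <- (kin - mean(kin)) / sqrt(mean((kin - mean(kin))^2))
  expect_equal(unname(z[1:3, 1]), zref, tolerance = 1e-12)
  # equal within-strength community: z = 0 for members
  expect_equal(unname(z[4:5, 1]), c(0, 0))
  expect_equal(attr(z, "measure_name"), "z_S")

  # the population-z formula on the strength profile (2, 2, 5)
  kin <- c(2, 2, 5)
  zv <- (kin - mean(kin)) / sqrt(mean((kin - mean(kin))^2))
  expect_equal(zv, c(-1 / sqrt(2), -1 / sqrt(2), 2 / sqrt(2)), tolerance = 1e-12)

  # singleton community convention
  zs <- module_degree_zscore(net, static_partition(c(0, 0, 0, 1, 2)))
  expect_equal(unname(zs[4, 1]), 0)
  expect_equal(unname(zs[5, 1]), 0)

  # temporal partition gives z_T
  parts <- partition_sequence(matrix(lab, ncol = 1))
  expect_equal(attr(module_degree_zscore(net, parts), "measure_name"), "z_T")
})

test_that("PC variants stay in [0, 1) and below 1 - 1/K_max", {
  for (seed in 1:5) {
    net <- generate_random_temporal_network(10, 4, density = 0.8, seed = seed)
    parts <- random_partition_sequence(10, 4, k_max = 5, seed = seed + 40)
    vals <- list(pc_t(net, parts), tpc(net, parts),
                 pc_s(net, static_partition(parts[, 1])))
    kmax <- max(apply(unclass(parts), 2, function(x) length(unique(x))))
    for (v in vals) {
      expect_true(all(v >= 0 & v < 1))
      expect_lte(max(v), 1 - 1 / kmax + 1e-12)
    }
  }
})
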