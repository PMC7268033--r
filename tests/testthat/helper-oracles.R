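# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementation.

# participation of every node on one slice, explicit sum over communities
oracle_pc_slice <- function(w, labels) {
  n <- nrow(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    k_i <- sum(w[i, ])
    if (k_i == 0) { out[i] <- 0; next }
    acc <- 0
    for (s in unique(labels)) {
      k_is <- 0
      for (j in seq_len(n)) if (labels[j] == s) k_is <- k_is + w[i, j]
      acc <- acc + (k_is / k_i)^2
    }
    out[i] <- 1 - acc
  }
  out
}

# TPC by the literal double sum over partition times u and communities s
oracle_tpc <- function(net, labs) {
  n <- dim(net)[1]; tt <- dim(net)[3]
  out <- matrix(0, n, tt)
  for (t in seq_len(tt)) {
    w <- net[, , t]
    for (i in seq_len(n)) {
      k_it <- sum(w[i, ])
      total <- 0
      for (u in seq_len(tt)) {
        if (k_it == 0) { total <- total + 1; next }
        for (s in unique(labs[, u])) {
          k_its <- sum(w[i, labs[, u] == s])
          total <- total + (k_its / k_it)^2
        }
      }
      out[i, t] <- 1 - total / tt
    }
  }
  out
}

# weighted Pearson by direct summation
oracle_weighted_pearson <- function(x, w) {
  n <- nrow(x)
  r <- matrix(0, n, n)
  sw <- sum(w)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    mi <- sum(w * x[i, ]) / sw
    mj <- sum(w * x[j, ]) / sw
    cij <- sum(w * (x[i, ] - mi) * (x[j, ] - mj)) / sw
    vi <- sum(w * (x[i, ] - mi)^2) / sw
    vj <- sum(w * (x[j, ] - mj)^2) / sw
    r[i, j] <- cij / sqrt(vi * vj)
  }
  diag(r) <- 0
  r
}

# distance -> similarity -> [0,1] row weights by explicit per-pair loops
oracle_distance_weights <- function(x) {
  tt <- ncol(x)
  d <- matrix(0, tt, tt)
  for (u in seq_len(tt)) for (v in seq_len(tt)) {
    d[u, v] <- sqrt(sum((x[, u] - x[, v])^2))
  }
  w <- matrix(0, tt, tt)
  for (t in seq_len(tt)) {
    sc <- (d[t, ] - min(d[t, ])) / (max(d[t, ]) - min(d[t, ]))
    w[t, ] <- 1 - sc
  }
  w
}

# MTD with explicit truncated sliding-window means
oracle_mtd <- function(x, hw) {
  dx <- t(diff(t(x)))
  s <- sqrt(apply(dx^2, 1, mean))
  n <- nrow(x); tt <- ncol(dx)
  raw <- array(0, c(n, n, tt))
  for (t in seq_len(tt)) for (i in seq_len(n)) for (j in seq_len(n)) {
    raw[i, j, t] <- dx[i, t] * dx[j, t] / (s[i] * s[j])
  }
  out <- array(0, c(n, n, tt))
  for (t in seq_len(tt)) {
    lo <- max(1, t - hw); hi <- min(tt, t + hw)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      out[i, j, t] <- mean(raw[i, j, lo:hi])
    }
    diag(out[, , t]) <- 0
  }
  out
}

# rank-transform then Pearson (average ranks for ties)
oracle_spearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# random generators for property-style tests -------------------------------

random_partition_sequence <- function(n, tt, k_max = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labs <- matrix(0L, n, tt)
  for (t in seq_len(tt)) {
    k <- sample(1:k_max, 1)
    labs[, t] <- sample(0:(k - 1), n, replace = TRUE)
  }
  partition_sequence(labs)
}

# adjusted Rand index via mclust (independent of package code)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

expect_same_partition_structure <- function(a, b) {
  expect_equal(ari(a, b), 1)
}
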