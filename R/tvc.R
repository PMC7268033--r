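#' Temporal distance weights for per-time-point connectivity
#'
#' For each time point `t`, the Euclidean distance between the length-`N`
#' signal vectors at `t` and every other time point is computed, converted
#' to a similarity and scaled into `[0, 1]`: within a row the distances are
#' first min-max scaled (the self-distance 0 maps to 0) and the weight is
#' one minus the scaled distance, so the time point itself gets weight 1,
#' the farthest time point weight 0, and "spatially nearby" time points
#' support the estimate at `t` the most.
#'
#' @param ts A [node_timeseries()] with at least 3 time points.
#' @return A `T x T` numeric matrix; row `t` is the weight vector used for
#'   the connectivity estimate at `t`.
#' @export
temporal_distance_weights <- function(ts) {
  stopifnot(inherits(ts, "node_timeseries"))
  tt <- ncol(ts)
  if (tt < 3L) stop("need at least 3 time points for distance weights", call. = FALSE)
  d <- as.matrix(stats::dist(t(unclass(ts))))
  if (all(d == 0)) {
    stop("all time points are identical (all distances 0); ",
         "use an ordinary (unweighted) Pearson correlation instead", call. = FALSE)
  }
  w <- matrix(0, tt, tt)
  for (t in seq_len(tt)) {
    row <- d[t, ]
    rng <- range(row)
    if (rng[2] == rng[1]) {
      # all other time points coincide with t; every weight is maximal
      w[t, ] <- 1
    } else {
      w[t, ] <- 1 - (row - rng[1]) / (rng[2] - rng[1])
    }
  }
  w
}

#' Weighted Pearson correlation matrix for one time point
#'
#' Correlation between every pair of node signals under observation
#' weights `w`: `r_ij = cov_w(x_i, x_j) / sqrt(var_w(x_i) var_w(x_j))`
#' with weighted mean `mu_i = sum(w * x_i) / sum(w)` and the
#' frequency-weight convention (denominator `sum(w)`). The diagonal of the
#' returned slice is 0.
#'
#' @param ts A [node_timeseries()].
#' @param w Nonnegative weight vector of length `T` with at least two
#'   strictly positive entries.
#' @return Symmetric `N x N` matrix with zero diagonal, values in
#'   `[-1, 1]`.
#' @export
weighted_pearson_slice <- function(ts, w) {
  stopifnot(inherits(ts, "node_timeseries"))
  x <- unclass(ts)
  if (length(w) != ncol(x)) stop("weight vector length must equal T", call. = FALSE)
  if (any(w < 0) || sum(w > 0) < 2L) {
    stop("weights must be nonnegative with at least two positive entries", call. = FALSE)
  }
  sw <- sum(w)
  mu <- as.vector(x %*% w) / sw
  xc <- x - mu
  cv <- (xc %*% (w * t(xc))) / sw
  v <- diag(cv)
  if (any(v <= 0)) {
    stop("zero weighted variance for node ", rownames(x)[which(v <= 0)[1]], call. = FALSE)
  }
  r <- cv / sqrt(outer(v, v))
  r <- (r + t(r)) / 2
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 0
  r
}

#' Estimate time-varying connectivity by distance-weighted Pearson correlation
#'
#' Produces one connectivity snapshot per time point: slice `t` is the
#' weighted Pearson correlation matrix of the node signals under row `t`
#' of [temporal_distance_weights()]. The result is *not* thresholded;
#' apply [threshold_negative_edges()] before community detection and
#' participation measures.
#'
#' @param ts A [node_timeseries()].
#' @return A [temporal_network()] with `T` slices (`thresholded = FALSE`).
#' @examples
#' ts <- node_timeseries(matrix(rnorm(60), nrow = 4))
#' net <- estimate_tvc_weighted_pearson(ts)
#' @export
estimate_tvc_weighted_pearson <- function(ts) {
  stopifnot(inherits(ts, "node_timeseries"))
  w <- temporal_distance_weights(ts)
  tt <- ncol(ts)
  out <- array(0, c(nrow(ts), nrow(ts), tt))
  for (t in seq_len(tt)) out[, , t] <- weighted_pearson_slice(ts, w[t, ])
  temporal_network(out, node_ids = rownames(ts))
}

#' Estimate time-varying connectivity by multiplication of temporal derivatives
#'
#' The coupling between nodes `i` and `j` at derivative step `t` is
#' `dx_it * dx_jt / (s_i * s_j)` where `dx` is the first difference of the
#' signals and `s_i` is the root mean square of `dx_i` (so a node's
#' self-coupling averages exactly 1 over the series). Each coupling series
#' is smoothed with a moving average over `t - half_window .. t +
#' half_window`, truncated at the series boundaries, giving `T - 1`
#' slices.
#'
#' @param ts A [node_timeseries()] with `T >= 2 * half_window + 2`.
#' @param half_window Smoothing half-width in time steps (default 4, i.e.
#'   averaging over +/- 4 points).
#' @return A [temporal_network()] with `T - 1` slices.
#' @export
estimate_tvc_mtd <- function(ts, half_window = 4L) {
  stopifnot(inherits(ts, "node_timeseries"))
  half_window <- as.integer(half_window)
  if (half_window < 0L) stop("half_window must be >= 0", call. = FALSE)
  x <- unclass(ts)
  if (ncol(x) < 2L * half_window + 2L) {
    stop("need T >= 2 * half_window + 2 time points", call. = FALSE)
  }
  dx <- x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE]   # N x (T-1)
  s <- sqrt(rowMeans(dx^2))
  if (any(s == 0)) {
    stop("zero derivative variance for node ", rownames(x)[which(s == 0)[1]], call. = FALSE)
  }
  dz <- dx / s
  tt <- ncol(dz)
  n <- nrow(dz)
  raw <- array(0, c(n, n, tt))
  for (t in seq_len(tt)) {
    m <- tcrossprod(dz[, t])
    raw[, , t] <- m
  }
  out <- array(0, c(n, n, tt))
  for (t in seq_len(tt)) {
    win <- max(1L, t - half_window):min(tt, t + half_window)
    out[, , t] <- apply(raw[, , win, drop = FALSE], c(1, 2), mean)
    diag(out[, , t]) <- 0
  }
  temporal_network(out, node_ids = rownames(ts))
}
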