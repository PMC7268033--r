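#' Per-node correlation between two measure time series
#'
#' Rank (Spearman, default) or Pearson correlation across time, computed
#' node by node, between two aligned nodal measure series. Ties receive
#' average ranks. A node whose series is constant in either measure has no
#' defined rank correlation and is reported as `NA`; summaries should
#' exclude these.
#'
#' @param a,b [nodal_measure_series()] objects of identical shape with at
#'   least 3 time points.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A tibble with columns `node` and `rho`.
#' @export
nodewise_correlation <- function(a, b, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  check_aligned(a, b)
  if (ncol(a) < 3L) stop("need at least 3 time points", call. = FALSE)
  rho <- vapply(seq_len(nrow(a)), function(i) {
    if (stats::sd(a[i, ]) == 0 || stats::sd(b[i, ]) == 0) return(NA_real_)
    stats::cor(a[i, ], b[i, ], method = method)
  }, numeric(1))
  tibble::tibble(node = series_node_ids(a), rho = rho)
}

#' Overlap of top-percentile "temporal hub" selections across methods
#'
#' For each measure series, the top `pct`% of values are selected either
#' per node (`mode = "per_node"`: the top time points of each node's
#' series, overlap then averaged over nodes) or pooled over all
#' `(node, time)` pairs (`mode = "pooled"`). For every pair and the triple
#' of methods, the fraction of the selection shared by all methods in the
#' subset is reported. The selection size is exactly `ceiling(pct/100 *
#' count)`; ties at the cutoff are broken by earliest time, then lowest
#' node index, so selections are deterministic.
#'
#' @param series_by_method Named list of two or more aligned
#'   [nodal_measure_series()].
#' @param pct Percentage in (0, 100).
#' @param mode `"per_node"` or `"pooled"`.
#' @return A tibble with columns `methods` (e.g. `"PC_S&TPC"`),
#'   `threshold_pct`, `mode`, `overlap`. The triple intersection never
#'   exceeds any pairwise intersection.
#' @export
hub_overlap <- function(series_by_method, pct = 10, mode = c("per_node", "pooled")) {
  mode <- match.arg(mode)
  if (!is.list(series_by_method) || length(series_by_method) < 2L ||
      is.null(names(series_by_method))) {
    stop("series_by_method must be a named list of >= 2 measure series", call. = FALSE)
  }
  if (pct <= 0 || pct >= 100) stop("pct must be in (0, 100)", call. = FALSE)
  for (s in series_by_method[-1]) check_aligned(series_by_method[[1]], s)
  methods <- names(series_by_method)
  subsets <- c(utils::combn(methods, 2, simplify = FALSE),
               if (length(methods) >= 3) utils::combn(methods, 3, simplify = FALSE))
  n <- nrow(series_by_method[[1]])
  tt <- ncol(series_by_method[[1]])

  if (mode == "pooled") {
    size <- ceiling(pct / 100 * n * tt)
    sel <- lapply(series_by_method, function(x) top_indices(as.vector(x), size,
                                                            time = rep(seq_len(tt), each = n),
                                                            node = rep(seq_len(n), tt)))
    overlap <- vapply(subsets, function(ms) {
      length(Reduce(intersect, sel[ms])) / size
    }, numeric(1))
  } else {
    size <- ceiling(pct / 100 * tt)
    per_node <- vapply(subsets, function(ms) {
      mean(vapply(seq_len(n), function(i) {
        sels <- lapply(series_by_method[ms], function(x) {
          top_indices(x[i, ], size, time = seq_len(tt), node = rep(i, tt))
        })
        length(Reduce(intersect, sels)) / size
      }, numeric(1)))
    }, numeric(1))
    overlap <- per_node
  }
  tibble::tibble(
    methods = vapply(subsets, paste, "", collapse = "&"),
    threshold_pct = pct,
    mode = mode,
    overlap = overlap
  )
}

# indices of the `size` largest values; ties by earliest time then lowest node
top_indices <- function(values, size, time, node) {
  ord <- order(-values, time, node)
  ord[seq_len(size)]
}

#' Quadrant analysis of static-vs-temporal measure differences
#'
#' Each `(node, time)` point is classified by the signs of
#' `dPC = PC_T - PC_S` and `dz = z_T - z_S`. The two opposite-sign
#' quadrants (`dPC < 0, dz > 0` and `dPC > 0, dz < 0`) are the
#' *discordant* points: there the static and temporal community contexts
#' yield opposite integration/segregation interpretations of the same
#' snapshot. Points lying exactly on an axis are excluded from the
#' quadrant fractions and reported separately.
#'
#' @param pc_s,pc_t,z_s,z_t Aligned [nodal_measure_series()] objects.
#' @return An object of class `quadrant_report`: a list with a `quadrants`
#'   tibble (fractions per quadrant), `discordant`, `on_axis` and `n`.
#' @export
quadrant_analysis <- function(pc_s, pc_t, z_s, z_t) {
  check_aligned(pc_s, pc_t); check_aligned(pc_s, z_s); check_aligned(pc_s, z_t)
  dpc <- as.vector(unclass(pc_t) - unclass(pc_s))
  dz <- as.vector(unclass(z_t) - unclass(z_s))
  n <- length(dpc)
  on_axis <- dpc == 0 | dz == 0
  quad <- tibble::tibble(
    quadrant = c("pc_up_z_up", "pc_up_z_down", "pc_down_z_up", "pc_down_z_down"),
    interpretation = c(
      "more integration and less segregation with temporal communities",
      "discordant: temporal says integration, static says segregation",
      "discordant: static says integration, temporal says segregation",
      "less integration and more segregation with temporal communities"),
    fraction = c(sum(dpc > 0 & dz > 0), sum(dpc > 0 & dz < 0),
                 sum(dpc < 0 & dz > 0), sum(dpc < 0 & dz < 0)) / n
  )
  structure(list(
    quadrants = quad,
    discordant = sum((dpc > 0 & dz < 0) | (dpc < 0 & dz > 0)) / n,
    on_axis = sum(on_axis) / n,
    n = n
  ), class = "quadrant_report")
}

#' @export
print.quadrant_report <- function(x, ...) {
  cat("<quadrant_report> ", x$n, " (node, time) points\n", sep = "")
  print(x$quadrants)
  cat(sprintf("discordant fraction: %.4f (on-axis: %.4f)\n", x$discordant, x$on_axis))
  invisible(x)
}

#' Bartlett heteroscedasticity diagnostic for a measure-vs-measure scatter
#'
#' Bins `y` by quantiles of `x` (deciles by default) and applies
#' Bartlett's test for equality of the `y` variances across bins. A large
#' statistic indicates that the spread of `y` changes along `x` — the
#' funnel-shaped relationship seen when two participation variants agree
#' only at the extremes. If a quantile bin would hold fewer than 2 points
#' the bin count is reduced with a warning; fewer than 2 usable bins is an
#' error.
#'
#' @param x,y Numeric vectors of equal length.
#' @param n_bins Number of quantile bins (default 10).
#' @return A tibble with columns `statistic`, `p_value`, `df`, `n_bins`.
#' @export
heteroscedasticity_test <- function(x, y, n_bins = 10) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  repeat {
    breaks <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
    ok <- length(breaks) >= 3L
    if (ok) {
      g <- cut(x, breaks = breaks, include.lowest = TRUE)
      sizes <- table(g)
      ok <- length(sizes) >= 2L && all(sizes >= 2L)
    }
    if (ok) break
    if (n_bins == 2L) stop("cannot form 2 bins with >= 2 points each", call. = FALSE)
    n_bins <- n_bins - 1L
    warning("reducing bin count to ", n_bins, " (bin with < 2 points)", call. = FALSE)
  }
  bt <- stats::bartlett.test(y, g)
  tibble::tibble(statistic = unname(bt$statistic),
                 p_value = bt$p.value,
                 df = unname(bt$parameter),
                 n_bins = length(levels(droplevels(g))))
}

#' Correlation of time-averaged participation across methods
#'
#' Averages each node's series over time, then correlates the per-node
#' means across nodes for every pair of methods (Pearson). High values
#' here with low [nodewise_correlation()] indicate that methods agree on
#' which nodes participate on average while disagreeing about when.
#'
#' @param series_by_method Named list of aligned [nodal_measure_series()].
#' @return A tibble with columns `method_a`, `method_b`, `r`.
#' @export
mean_over_time_correlation <- function(series_by_method) {
  if (!is.list(series_by_method) || length(series_by_method) < 2L ||
      is.null(names(series_by_method))) {
    stop("series_by_method must be a named list of >= 2 measure series", call. = FALSE)
  }
  for (s in series_by_method[-1]) check_aligned(series_by_method[[1]], s)
  if (nrow(series_by_method[[1]]) < 3L) stop("need at least 3 nodes", call. = FALSE)
  means <- vapply(series_by_method, rowMeans, numeric(nrow(series_by_method[[1]])))
  pairs <- utils::combn(names(series_by_method), 2, simplify = FALSE)
  tibble::tibble(
    method_a = vapply(pairs, `[[`, "", 1L),
    method_b = vapply(pairs, `[[`, "", 2L),
    r = vapply(pairs, function(p) stats::cor(means[, p[1]], means[, p[2]]), numeric(1))
  )
}

check_aligned <- function(a, b) {
  if (!is.matrix(unclass(a)) || !is.matrix(unclass(b)) ||
      nrow(a) != nrow(b) || ncol(a) != ncol(b)) {
    stop("measure series must have identical node x time shape", call. = FALSE)
  }
  invisible(NULL)
}

series_node_ids <- function(x) {
  ids <- rownames(x)
  if (is.null(ids)) paste0("n", seq_len(nrow(x)) - 1L) else ids
}
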