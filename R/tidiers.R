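#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a nodal measure series into long format
#'
#' @param x A [nodal_measure_series()].
#' @param ... Unused.
#' @return A tibble with columns `node`, `time` (0-based), `measure`,
#'   `value`.
#' @export
tidy.nodal_measure_series <- function(x, ...) {
  tibble::as_tibble(tidy_measure_df(x))
}

#' Tidy a temporal network into a long edge list
#'
#' @param x A [temporal_network()].
#' @param ... Unused.
#' @return A tibble with columns `i`, `j`, `time` (all 0-based) and
#'   `weight`, one row per nonzero undirected edge per slice.
#' @export
tidy.temporal_network <- function(x, ...) {
  purrr::map_dfr(seq_len(n_time(x)), function(t) {
    w <- x[, , t]
    idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
    tibble::tibble(i = idx[, 1] - 1L, j = idx[, 2] - 1L, time = t - 1L,
                   weight = w[idx])
  })
}

#' Tidy a partition sequence into long format
#'
#' @param x A [partition_sequence()].
#' @param ... Unused.
#' @return A tibble with columns `node`, `time` (0-based), `community`.
#' @export
tidy.partition_sequence <- function(x, ...) {
  tibble::tibble(node = rep(series_node_ids(x), ncol(x)),
                 time = rep(seq_len(ncol(x)) - 1L, each = nrow(x)),
                 community = as.vector(unclass(x)))
}

#' @rdname quadrant_analysis
#' @param x A `quadrant_report`.
#' @param ... Unused.
#' @export
tidy.quadrant_report <- function(x, ...) x$quadrants

#' @rdname quadrant_analysis
#' @export
glance.quadrant_report <- function(x, ...) {
  tibble::tibble(discordant = x$discordant, on_axis = x$on_axis, n = x$n)
}

#' Plot a nodal measure series over time
#'
#' One line per node; useful for eyeballing how participation or
#' within-module degree fluctuates.
#'
#' @param object A [nodal_measure_series()].
#' @param nodes Optional subset of node ids to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nodal_measure_series <- function(object, nodes = NULL, ...) {
  d <- tidy.nodal_measure_series(object)
  if (!is.null(nodes)) d <- dplyr::filter(d, .data$node %in% nodes)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value,
                                  group = .data$node, colour = .data$node)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "time", y = attr(object, "measure_name")) +
    ggplot2::theme_minimal()
}

#' Plot a quadrant report
#'
#' Bar chart of the fraction of (node, time) points per sign quadrant of
#' (PC_T - PC_S, z_T - z_S); the discordant quadrants are highlighted.
#'
#' @param object A `quadrant_report` from [quadrant_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quadrant_report <- function(object, ...) {
  d <- dplyr::mutate(object$quadrants,
                     discordant = grepl("discordant", .data$interpretation))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$quadrant, y = .data$fraction,
                                  fill = .data$discordant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                               guide = "none") +
    ggplot2::labs(y = "fraction of (node, time) points", x = NULL,
                  subtitle = sprintf("discordant fraction %.3f", object$discordant)) +
    ggplot2::theme_minimal()
}
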