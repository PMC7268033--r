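#' Default pipeline configuration
#'
#' @param input Path to a node-by-time signal file, or a
#'   [node_timeseries()] object.
#' @param out_dir Output directory (created if missing).
#' @param tvc_method `"weighted_pearson"` or `"mtd"`.
#' @param mtd_half_window Smoothing half-width for the MTD estimator.
#' @param resolution Modularity resolution for community detection.
#' @param seed Integer seed for every stochastic stage.
#' @param measures Character vector from `"pc_s"`, `"pc_t"`, `"tpc"`,
#'   `"flexibility"`, `"z_s"`, `"z_t"`.
#' @param compare Logical: also write the divergence report comparing the
#'   participation variants.
#' @param hub_pcts Hub-overlap thresholds (percent) for the report.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, out_dir,
                            tvc_method = c("weighted_pearson", "mtd"),
                            mtd_half_window = 4L,
                            resolution = 1, seed = 1L,
                            measures = c("pc_s", "pc_t", "tpc", "flexibility",
                                         "z_s", "z_t"),
                            compare = TRUE,
                            hub_pcts = c(5, 10, 20)) {
  tvc_method <- match.arg(tvc_method)
  measures <- match.arg(measures, several.ok = TRUE)
  structure(list(input = input, out_dir = out_dir, tvc_method = tvc_method,
                 mtd_half_window = as.integer(mtd_half_window),
                 resolution = resolution, seed = as.integer(seed),
                 measures = measures, compare = isTRUE(compare),
                 hub_pcts = hub_pcts),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML or JSON file
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path Config file path (`.json`, `.yaml`/`.yml`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml package required to read ", path, call. = FALSE)
    }
    yaml::read_yaml(path)
  }
  do.call(pipeline_config, cfg)
}

#' Run the full temporal-participation pipeline
#'
#' Orders the standard stages: estimate time-varying connectivity,
#' remove negative edges, detect static and per-slice communities,
#' consensus-relabel the temporal partitions, compute the requested nodal
#' measures, and (optionally) the divergence report between participation
#' variants. Outputs are written to `config$out_dir` as plain-text files,
#' and a JSON manifest records the package version, a configuration hash,
#' per-stage log lines and every file written. Runs are deterministic
#' given the configuration (including its seed): identical configs yield
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()] (or a path accepted by
#'   [read_pipeline_config()]).
#' @return The manifest, invisibly (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  log_lines <- character(0)
  note <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
    message(line)
    log_lines <<- c(log_lines, sprintf("%s: %s", stage, msg))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    files <<- c(files, name)
    path
  }

  ts <- if (inherits(config$input, "node_timeseries")) config$input
        else read_timeseries(config$input)
  note("input", sprintf("%d nodes x %d time points", nrow(ts), ncol(ts)))

  net <- switch(config$tvc_method,
    weighted_pearson = estimate_tvc_weighted_pearson(ts),
    mtd = estimate_tvc_mtd(ts, half_window = config$mtd_half_window))
  net <- threshold_negative_edges(net)
  note("tvc", sprintf("%s estimate, %d slices, thresholded", config$tvc_method,
                      n_time(net)))

  mean_net <- stats::cor(t(unclass(ts)))
  mean_net[mean_net < 0] <- 0
  diag(mean_net) <- 0
  static_part <- detect_static_communities(mean_net, resolution = config$resolution,
                                           seed = config$seed)
  parts <- detect_slice_communities(net, resolution = config$resolution,
                                    seed = config$seed)
  parts <- temporal_consensus(parts)
  note("communities", sprintf("static: %d communities; temporal: %d labels",
                              length(unique(unclass(static_part))),
                              length(unique(as.vector(parts)))))
  emit("static_partition.csv", function(p) write_partition(static_part, p))
  emit("temporal_partitions.csv", function(p) write_partition(parts, p))

  results <- list()
  for (m in config$measures) {
    results[[m]] <- switch(m,
      pc_s = pc_s(net, static_part),
      pc_t = pc_t(net, parts),
      tpc = tpc(net, parts),
      z_s = module_degree_zscore(net, static_part),
      z_t = module_degree_zscore(net, parts),
      flexibility = flexibility(parts))
    if (m == "flexibility") {
      emit("flexibility.csv", function(p) {
        utils::write.table(
          data.frame(node = names(results$flexibility),
                     flexibility = sprintf("%.17g", results$flexibility)),
          p, sep = ",", row.names = FALSE, quote = FALSE)
      })
    } else {
      emit(paste0(m, ".csv"), function(p) write_measure(results[[m]], p))
    }
    note("measures", m)
  }
  pc_names <- intersect(c("pc_s", "pc_t", "tpc"), names(results))
  if (length(pc_names) >= 2) {
    emit("measures_long.tsv", function(p) {
      long <- dplyr::bind_rows(lapply(results[setdiff(names(results), "flexibility")],
                                      tidy_measure_df))
      utils::write.table(long, p, sep = "\t", row.names = FALSE, quote = FALSE)
    })
  }

  if (config$compare && length(pc_names) >= 2) {
    series <- stats::setNames(results[pc_names], toupper(pc_names))
    report <- divergence_report(series,
                                z_s = results$z_s, z_t = results$z_t,
                                hub_pcts = config$hub_pcts)
    emit("compare_report.json", function(p) {
      jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
    note("compare", "divergence report written")
  }

  cfg_out <- unclass(config)
  if (!is.character(cfg_out$input)) cfg_out$input <- "<in-memory node_timeseries>"
  manifest <- list(
    package = "temporalpc",
    version = as.character(utils::packageVersion("temporalpc")),
    config_hash = rlang::hash(cfg_out),
    config = cfg_out,
    files = files,
    log = log_lines,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

tidy_measure_df <- function(x) {
  data.frame(node = rep(series_node_ids(x), ncol(x)),
             time = rep(seq_len(ncol(x)) - 1L, each = nrow(x)),
             measure = attr(x, "measure_name"),
             value = as.vector(x))
}

#' Divergence report between participation variants
#'
#' Bundles the comparison diagnostics into one JSON-serializable list:
#' per-node rank correlations between each pair of methods (with
#' medians), correlations of time-averaged participation, hub-overlap
#' fractions at the requested thresholds in both modes, the quadrant
#' analysis (when both z-score series are supplied), and the Bartlett
#' heteroscedasticity diagnostic for each method pair.
#'
#' @param series Named list of 2-3 aligned [nodal_measure_series()]
#'   participation series.
#' @param z_s,z_t Optional aligned z-score series for the quadrant
#'   analysis.
#' @param hub_pcts Hub-overlap thresholds (percent).
#' @return A nested list of tibbles and scalars.
#' @export
divergence_report <- function(series, z_s = NULL, z_t = NULL,
                              hub_pcts = c(5, 10, 20)) {
  pairs <- utils::combn(names(series), 2, simplify = FALSE)
  rho <- purrr::map_dfr(pairs, function(p) {
    r <- nodewise_correlation(series[[p[1]]], series[[p[2]]])
    tibble::tibble(method_a = p[1], method_b = p[2],
                   median_rho = stats::median(r$rho, na.rm = TRUE),
                   sd_rho = stats::sd(r$rho, na.rm = TRUE),
                   n_defined = sum(!is.na(r$rho)))
  })
  overlaps <- purrr::map_dfr(hub_pcts, function(p) {
    dplyr::bind_rows(hub_overlap(series, p, "per_node"),
                     hub_overlap(series, p, "pooled"))
  })
  bartlett <- purrr::map_dfr(pairs, function(p) {
    bt <- heteroscedasticity_test(as.vector(series[[p[1]]]),
                                  as.vector(series[[p[2]]]))
    dplyr::mutate(bt, method_a = p[1], method_b = p[2], .before = 1)
  })
  out <- list(nodewise_spearman = rho,
              mean_over_time = mean_over_time_correlation(series),
              hub_overlap = overlaps,
              bartlett = bartlett)
  if (!is.null(z_s) && !is.null(z_t) &&
      all(c("PC_S", "PC_T") %in% names(series))) {
    q <- quadrant_analysis(series$PC_S, series$PC_T, z_s, z_t)
    out$quadrants <- q$quadrants
    out$discordant_fraction <- q$discordant
    out$on_axis_fraction <- q$on_axis
  }
  out
}
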