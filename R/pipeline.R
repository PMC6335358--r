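pipeline_schema <- function() {
  list(
    top = c("seed", "out_dir", "sim_raster", "input_raster", "sim_calcium",
            "input_traces", "bursts", "graph", "calcium"),
    sim_raster = setdiff(names(formals(raster_sim_config)), "seed"),
    sim_calcium = setdiff(names(formals(calcium_sim_config)), "seed"),
    bursts = c("bin_width_ms", "threshold_coeff", "min_spikes",
               "min_electrodes", "gap_bins", "refine"),
    graph = c("velocity", "delta_ms", "fraction", "min_degree"),
    calcium = c("accuracy_coeff", "min_run", "min_duration")
  )
}

#' Assemble and validate a pipeline configuration
#'
#' A pipeline configuration is a plain named list (round-trippable through
#' YAML) describing which stages to run and with which parameters. Unknown
#' keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param seed integer master seed for all stochastic stages.
#' @param out_dir output directory for all artifacts.
#' @param sim_raster named list of [raster_sim_config()] arguments (without
#'   `seed`), or `NULL` to skip raster simulation.
#' @param input_raster path of a raster CSV to analyse instead of
#'   simulating.
#' @param sim_calcium named list of [calcium_sim_config()] arguments, or
#'   `NULL` to skip the calcium branch.
#' @param input_traces path of a traces CSV to analyse instead.
#' @param bursts,graph,calcium named lists of stage parameters (see
#'   [detect_network_bursts()], [delayed_synchrony()] /
#'   [significant_edges()] / [find_hubs()], [detect_transients()]).
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("meanet-run-"),
                            sim_raster = NULL, input_raster = NULL,
                            sim_calcium = NULL, input_traces = NULL,
                            bursts = list(), graph = list(),
                            calcium = list()) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              sim_raster = sim_raster, input_raster = input_raster,
              sim_calcium = sim_calcium, input_traces = input_traces,
              bursts = bursts, graph = graph, calcium = calcium)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  check_keys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra)) {
      stop_invalid("unknown configuration key(s) in %s: %s", where,
                   paste(extra, collapse = ", "))
    }
  }
  stopifnot(is.list(cfg))
  schema <- pipeline_schema()
  check_keys(cfg, schema$top, "top level")
  for (sec in c("sim_raster", "sim_calcium", "bursts", "graph", "calcium")) {
    if (!is.null(cfg[[sec]])) {
      check_keys(cfg[[sec]], schema[[sec]], sec)
    }
  }
  if (is.null(cfg$seed)) stop_invalid("configuration must carry a seed")
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_pipeline_config` returns a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  validate_pipeline_config(yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: raster simulation (or reading), TSR burst detection
#' and classification, functional-graph construction with hub metrics, and
#' the calcium branch (trace simulation or reading, transient detection,
#' population summary). All artifacts are written to `out_dir` as plain
#' text (CSV / JSON / GraphML) together with a run manifest carrying the
#' configuration, package version and per-file checksums. Identical
#' configuration and seed produce identical outputs.
#'
#' @param config a `pipeline_config`, or the path of a YAML file.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop_invalid("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  raster <- NULL
  if (!is.null(config$sim_raster)) {
    sim <- stage("simulate-raster", {
      rcfg <- do.call(raster_sim_config,
                      c(config$sim_raster, list(seed = config$seed)))
      simulate_raster(rcfg)
    })
    raster <- sim$raster
    files["raster"] <- write_raster(raster, file.path(out, "raster.csv"))
    files["ground_truth"] <- write_ground_truth(
      sim$ground_truth, file.path(out, "ground_truth.json"))
  } else if (!is.null(config$input_raster)) {
    raster <- stage("read-raster", read_raster(config$input_raster))
  }

  if (!is.null(raster)) {
    stage("detect-bursts", {
      bp <- config$bursts
      tsr <- compute_tsr(raster, bin_width_ms = bp$bin_width_ms %||% 50)
      bursts <- detect_network_bursts(
        tsr, raster,
        threshold_coeff = bp$threshold_coeff %||% 0.1,
        min_spikes = bp$min_spikes %||% 4,
        min_electrodes = bp$min_electrodes %||% 4,
        gap_bins = bp$gap_bins %||% 1,
        refine = bp$refine %||% TRUE)
      bursts <- classify_bursts(bursts)
      files["bursts"] <- write_bursts(bursts, file.path(out, "bursts.csv"))
      stats <- burst_statistics(bursts, raster$duration)
      jsonlite::write_json(stats, file.path(out, "burst_stats.json"),
                           auto_unbox = TRUE, digits = NA)
      files["burst_stats"] <- file.path(out, "burst_stats.json")
    })
    stage("build-graph", {
      gp <- config$graph
      cm <- delayed_synchrony(raster,
                              velocity = gp$velocity %||% 300,
                              delta_ms = gp$delta_ms %||% 2)
      g <- significant_edges(cm, fraction = gp$fraction %||% 0.05)
      hubs <- find_hubs(g, min_degree = gp$min_degree %||% 10)
      files["connectivity"] <- write_connectivity(
        cm, file.path(out, "connectivity.csv"),
        file.path(out, "connectivity_meta.json"))
      files["graph"] <- write_functional_graph(
        g, file.path(out, "graph.graphml"), file.path(out, "edges.csv"))
      jsonlite::write_json(
        list(n_hubs = hubs$n_hubs, mean_connections = hubs$mean_connections,
             hubs = hubs$hubs),
        file.path(out, "hubs.json"), auto_unbox = TRUE, digits = NA)
      files["hubs"] <- file.path(out, "hubs.json")
    })
  }

  traces <- NULL
  if (!is.null(config$sim_calcium)) {
    csim <- stage("simulate-calcium", {
      ccfg <- do.call(calcium_sim_config,
                      c(config$sim_calcium, list(seed = config$seed + 1L)))
      simulate_calcium(ccfg)
    })
    traces <- csim$traces
    files["traces"] <- write_traces(traces, file.path(out, "traces.csv"))
    files["calcium_ground_truth"] <- write_ground_truth(
      csim$ground_truth, file.path(out, "calcium_ground_truth.json"))
  } else if (!is.null(config$input_traces)) {
    traces <- stage("read-traces", read_traces(config$input_traces))
  }

  if (!is.null(traces)) {
    stage("analyze-calcium", {
      cp <- config$calcium
      tr <- detect_transients(traces,
                              accuracy_coeff = cp$accuracy_coeff %||% 2,
                              min_run = cp$min_run %||% 2,
                              min_duration = cp$min_duration %||% 1)
      write.csv(data.frame(roi_id = tr$roi_id, start_s = tr$start,
                           end_s = tr$end, duration_s = tr$duration),
                file.path(out, "transients.csv"), row.names = FALSE)
      files["transients"] <- file.path(out, "transients.csv")
      summ <- summarize_calcium(tr, n_cells = length(traces$roi_ids),
                                duration_s = traces$duration)
      jsonlite::write_json(summ, file.path(out, "calcium_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      files["calcium_summary"] <- file.path(out, "calcium_summary.json")
    })
  }

  manifest <- list(
    package = "meanet",
    version = as.character(packageVersion("meanet")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = unclass(config),
    files = lapply(stats::setNames(as.list(files), names(files)), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
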