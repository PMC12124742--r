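#' Read a scenario configuration file
#'
#' YAML with top-level keys `scenario` (`colony`/`biofilm`), `nutrient`
#' (mg/L), optional `resolver` (`type`, `alpha`, `tol`, `max_iters`,
#' `neighborhood`, `jitter_sigma`, `seed`), `growth`, `field` (`dx`, `D`,
#' `depth`), `timesteps` (`fast`, `slow`), `domain_scale`, `duration`,
#' `seed`, `metrics_every`, `stop_population`, `replicates` and `out`.
#'
#' @param path path to the YAML file.
#' @return list with elements `scenario` (a [build_scenario()] object),
#'   `replicates` and `out`.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenario) || is.null(cfg$nutrient))
    stop("config must set 'scenario' and 'nutrient'")
  resolver <- cfg$resolver %||% list()
  seed <- cfg$seed %||% resolver$seed
  resolver$seed <- NULL
  ov <- list(resolver = resolver, growth = cfg$growth %||% list(),
             field = cfg$field %||% list(),
             domain_scale = cfg$domain_scale, duration = cfg$duration,
             seed = seed, metrics_every = cfg$metrics_every,
             stop_population = cfg$stop_population,
             dt_fast = cfg$timesteps$fast, dt_slow = cfg$timesteps$slow)
  ov <- ov[!vapply(ov, is.null, logical(1))]
  list(scenario = build_scenario(cfg$scenario, cfg$nutrient, ov),
       replicates = cfg$replicates %||% 1L,
       out = cfg$out %||% ".")
}

#' Export / import grid matrices as delimited text
#'
#' Occupancy matrices, excess matrices and single motion-tensor layers are
#' plain `W x H` numeric matrices (first index x, second y); these helpers
#' write and read them as tab-separated text for debugging and external
#' analysis.
#'
#' @param m numeric matrix.
#' @param path file path.
#' @return `read_grid_matrix()` returns the matrix; `write_grid_matrix()`
#'   returns `path` invisibly.
#' @export
write_grid_matrix <- function(m, path) {
  utils::write.table(format(unclass(m), digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_grid_matrix
#' @export
read_grid_matrix <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                              colClasses = "numeric"))
}

#' Run a configured experiment, with replicates
#'
#' Executes the scenario to its stopping condition once per replicate,
#' deriving the replicate seed as `seed + replicate - 1`, and writes per
#' replicate a final cell snapshot (`cells_final_rep<k>.csv`) and a
#' metrics time series (`metrics_rep<k>.csv`), plus a cross-replicate
#' `summary.csv` (final population, final and maximum overlap ratio) and
#' a `manifest.json` echoing the configuration and seeds.  Identical
#' configuration and seed give byte-identical snapshot and metrics files.
#'
#' @param config path to a YAML config, or a [build_scenario()] object.
#' @param out output directory (created if missing).
#' @param replicates number of replicate runs (default from the config
#'   file, else 1).
#' @param quiet suppress progress output.
#' @return invisibly, the manifest list (with a `summary` data frame).
#' @export
run_experiment <- function(config, out = NULL, replicates = NULL,
                           quiet = TRUE) {
  if (is.character(config)) {
    cfg <- read_scenario_config(config)
    scenario <- cfg$scenario
    replicates <- replicates %||% cfg$replicates
    out <- out %||% cfg$out
  } else {
    scenario <- config
    replicates <- replicates %||% 1L
    out <- out %||% "."
  }
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  root_seed <- scenario$seed %||% 1L
  started <- format(Sys.time(), "%Y-%m-%d %H:%M:%S", tz = "UTC")

  rows <- vector("list", replicates)
  for (k in seq_len(replicates)) {
    sck <- scenario
    sck$seed <- root_seed + k - 1L
    st <- run_simulation(sck, quiet = quiet)
    write_cells(st$cells, file.path(out, sprintf("cells_final_rep%d.csv", k)))
    write.csv(st$metrics, file.path(out, sprintf("metrics_rep%d.csv", k)),
              row.names = FALSE)
    rows[[k]] <- data.frame(
      replicate = k, seed = sck$seed, time = st$time,
      population = nrow(st$cells),
      final_overlap_ratio = utils::tail(st$metrics$overlap_ratio, 1),
      max_overlap_ratio = if (nrow(st$metrics)) max(st$metrics$overlap_ratio)
                          else NA_real_,
      stopped = st$stopped)
  }
  summary <- do.call(rbind, rows)
  write.csv(summary, file.path(out, "summary.csv"), row.names = FALSE)

  manifest <- list(
    package = "dorasim", version = as.character(packageVersion("dorasim")),
    scenario = scenario$name, nutrient = scenario$nutrient,
    domain = scenario$domain, resolver = scenario$resolver$type,
    root_seed = root_seed, replicate_seeds = root_seed + seq_len(replicates) - 1L,
    started = started,
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    out = normalizePath(out))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$summary <- summary
  invisible(manifest)
}
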