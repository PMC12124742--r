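#' Build a colony or biofilm scenario
#'
#' Colony: a square domain (default 600 x 600 um) with periodic boundaries
#' on all sides and a single founding cell at the center.  Biofilm: a
#' default 800 x 200 um domain with a solid bottom edge (no-flux/Neumann
#' for the substrate), a Dirichlet top edge held at the bulk concentration
#' (an effectively infinite nutrient reservoir), periodic lateral edges,
#' and 40 founding cells uniformly spaced along the bottom.
#'
#' Time advances on two scales: substrate diffusion with a fast step
#' (default 5e-4 min) and growth, division and one overlap-resolver call
#' per slow step (default 0.01 min).  The fast step must divide the slow
#' step evenly and satisfy the FTCS stability bound, both checked here.
#'
#' @param name `"colony"` or `"biofilm"`.
#' @param nutrient bulk substrate concentration, mg/L (the regimes studied
#'   are 100, 10 and 1 mg/L; any non-negative value is accepted).
#' @param overrides named list of scenario fields to override.  Scalar
#'   fields (`duration`, `seed`, `dt_fast`, `dt_slow`, `metrics_every`,
#'   `stop_population`, `stall_stop`, `domain`) replace the default;
#'   `domain_scale` multiplies the domain (e.g. 0.25 gives a 150 x 150 um
#'   colony); `resolver`, `growth` and `field` take lists merged over the
#'   default parameter objects (`field` accepts `dx`, `D`, `depth`);
#'   `sink_spread` chooses how each cell's substrate uptake is debited
#'   from the field (`"center"`: the unit containing the cell center;
#'   `"area"`: spread over the footprint in proportion to overlap);
#'   `initial_cells` replaces the founding population.
#' @return an object of class `scenario`.
#' @examples
#' sc <- build_scenario("colony", 100, overrides = list(domain_scale = 0.25))
#' @export
build_scenario <- function(name = c("colony", "biofilm"), nutrient,
                           overrides = list()) {
  name <- match.arg(name)
  stopifnot(nutrient >= 0)
  ov <- as.list(overrides)

  domain <- ov[["domain"]] %||% switch(name, colony = c(600, 600),
                                  biofilm = c(800, 200))
  if (!is.null(ov[["domain_scale"]])) domain <- domain * ov[["domain_scale"]]

  growth <- do.call(growth_params,
                    utils::modifyList(list(), ov[["growth"]] %||% list()))
  resolver <- do.call(resolution_config,
                      utils::modifyList(list(), ov[["resolver"]] %||% list()))

  fld <- utils::modifyList(list(dx = 10, D = 4e4, depth = 20),
                           ov[["field"]] %||% list())
  dt_fast <- ov[["dt_fast"]] %||% 5e-4
  dt_slow <- ov[["dt_slow"]] %||% 0.01
  nsub <- dt_slow / dt_fast
  if (abs(nsub - round(nsub)) > 1e-9)
    stop("dt_fast must divide dt_slow evenly")

  w <- ov[["grid_unit"]] %||% 1
  W <- as.integer(round(domain[1] / w))
  H <- as.integer(round(domain[2] / w))
  nx <- as.integer(round(domain[1] / fld$dx))
  ny <- as.integer(round(domain[2] / fld$dx))

  if (name == "colony") {
    grid <- grid_spec(W, H, w, w, boundary = "periodic")
    field <- substrate_field(nx, ny, fld$dx, fld$D, S0 = nutrient,
                             boundary = "periodic", depth = fld$depth)
    r0 <- growth$initial_radius
    init <- make_cells(domain[1] / 2, domain[2] / 2, r0,
                       biomass = biomass_from_radius(r0, growth))
  } else {
    grid <- grid_spec(W, H, w, w,
                      boundary = list(bottom = "solid", top = "open",
                                      left = "periodic", right = "periodic"))
    field <- substrate_field(nx, ny, fld$dx, fld$D, S0 = nutrient,
                             boundary = list(bottom = "neumann",
                                             top = "dirichlet",
                                             left = "periodic",
                                             right = "periodic"),
                             depth = fld$depth)
    r0 <- growth$initial_radius
    n0 <- 40L
    init <- make_cells((seq_len(n0) - 0.5) * domain[1] / n0,
                       rep(r0, n0), r0,
                       biomass = biomass_from_radius(r0, growth))
  }
  if (!is.null(ov[["initial_cells"]])) init <- validate_cells(ov[["initial_cells"]])

  check_ftcs_stability(field, dt_fast)

  structure(list(
    name = name, nutrient = nutrient, domain = domain,
    grid = grid, field = field, growth = growth, resolver = resolver,
    dt_fast = dt_fast, dt_slow = dt_slow, nsub = as.integer(round(nsub)),
    duration = ov[["duration"]] %||% switch(name, colony = 1200, biofilm = 1000),
    metrics_every = as.integer(ov[["metrics_every"]] %||% 10),
    stop_population = ov[["stop_population"]] %||% NULL,
    sink_spread = match.arg(ov[["sink_spread"]] %||% "center",
                            c("center", "area")),
    stall_stop = ov[["stall_stop"]] %||% TRUE,
    seed = ov[["seed"]] %||% NULL,
    initial_cells = init,
    # pg of biomass-substrate <-> mg/L in one field unit of volume dx^2*depth
    conc_per_pg = 1e6 / (fld$dx^2 * fld$depth)
  ), class = "scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s, %g mg/L bulk nutrient\n", x$name, x$nutrient))
  cat(sprintf("  domain %g x %g um; resolver %s; dt %g/%g min; duration %g min\n",
              x$domain[1], x$domain[2], x$resolver$type, x$dt_fast,
              x$dt_slow, x$duration))
  cat(sprintf("  %d initial cell(s); mu_max %g/min, Ks %g mg/L\n",
              nrow(x$initial_cells), x$growth$mu_max, x$growth$Ks))
  invisible(x)
}

#' Initialize simulation state
#'
#' @param scenario a [build_scenario()] object.
#' @return an object of class `simulation_state` holding the clock, the
#'   population, the substrate field, the pending consumption sinks and
#'   the event/metrics log.
#' @export
init_simulation <- function(scenario) {
  cells <- scenario$initial_cells
  structure(list(
    time = 0, n_steps = 0L, cells = cells, field = scenario$field,
    sinks = NULL, next_id = if (nrow(cells)) max(cells$id) + 1L else 1L,
    divisions = 0L, metrics = list(), stopped = NA_character_
  ), class = "simulation_state")
}

#' @export
print.simulation_state <- function(x, ...) {
  cat(sprintf("<simulation_state> t = %g min, %d cells, %d division(s)\n",
              x$time, nrow(x$cells), x$divisions))
  invisible(x)
}

field_index <- function(cells, field) {
  nx <- nrow(field$S); ny <- ncol(field$S)
  ii <- pmin(pmax(floor(cells$x / field$dx), 0), nx - 1) + 1
  jj <- pmin(pmax(floor(cells$y / field$dx), 0), ny - 1) + 1
  cbind(ii, jj)
}

#' Advance the simulation by one slow step
#'
#' Per slow step: (1) the substrate field runs `dt_slow / dt_fast` FTCS
#' substeps with the consumption sinks recorded during the previous growth
#' phase (nearest-unit binning of each cell's uptake); (2) every cell
#' grows by Monod kinetics on its local concentration and cells reaching
#' the division radius divide; (3) the configured overlap resolver runs
#' once.  Metrics are sampled every `metrics_every` slow steps.
#'
#' @param state a [init_simulation()] state.
#' @param scenario the scenario being run.
#' @return the advanced state.
#' @export
step_simulation <- function(state, scenario) {
  sc <- scenario
  state$field <- ftcs_step(state$field, sc$dt_fast, sinks = state$sinks,
                           nsub = sc$nsub)
  cells <- state$cells
  if (nrow(cells) > 0) {
    idx <- field_index(cells, state$field)
    S_local <- state$field$S[idx]
    if (!is.null(sc$growth$lysis_conc)) {
      keep <- S_local >= sc$growth$lysis_conc
      cells <- cells[keep, , drop = FALSE]
      idx <- idx[keep, , drop = FALSE]
      S_local <- S_local[keep]
    }
  }
  if (nrow(cells) > 0) {
    gr <- grow_and_divide(cells, sc$dt_slow, S_local, sc$growth,
                          next_id = state$next_id)
    state$next_id <- gr$next_id
    state$divisions <- state$divisions + gr$divisions
    # pending sinks: concentration removed per field unit per fast substep
    if (sc$sink_spread == "area") {
      fb <- state$field$boundary
      dxf <- state$field$dx
      sinks <- cpp_rasterize_weighted(
        cells$x / dxf, cells$y / dxf, cells$r / dxf, cells$r / dxf,
        gr$consumed * sc$conc_per_pg / sc$nsub,
        nrow(state$field$S), ncol(state$field$S),
        fb$left == "periodic", fb$bottom == "periodic")
    } else {
      sinks <- matrix(0, nrow(state$field$S), ncol(state$field$S))
      add <- gr$consumed * sc$conc_per_pg / sc$nsub
      lin <- (idx[, 2] - 1) * nrow(sinks) + idx[, 1]
      tab <- rowsum(add, lin)
      sinks[as.integer(rownames(tab))] <- tab
    }
    state$sinks <- sinks
    cells <- wrap_clamp_cells(gr$cells, sc$grid)
    t0 <- proc.time()[[3]]
    # state cells are validated and id-sorted; use the direct pipeline
    cells <- if (sc$resolver$type == "dora")
      dora_core(cells, sc$grid, sc$resolver)
    else
      relaxation_shove(cells, sc$grid, tol = sc$resolver$shove_tol,
                       max_sweeps = sc$resolver$max_sweeps)
    state$resolver_seconds <- proc.time()[[3]] - t0
    state$resolver_iterations <-
      attr(cells, "iterations") %||% attr(cells, "sweeps") %||% NA_integer_
    attributes(cells)[c("iterations", "residual_excess",
                        "sweeps", "max_depth")] <- NULL
  }
  if (nrow(cells) == 0) state$sinks <- NULL   # no uptake to carry forward
  state$cells <- cells
  state$time <- state$time + sc$dt_slow
  state$n_steps <- state$n_steps + 1L
  if (state$n_steps %% sc$metrics_every == 0L)
    state$metrics[[length(state$metrics) + 1L]] <- sample_metrics(state, sc)
  state
}

sample_metrics <- function(state, scenario) {
  cells <- state$cells
  toa <- total_overlap_area(cells, scenario$grid)
  tca <- if (nrow(cells)) sum(pi * cells$r^2) else 0
  list(time = state$time,
       population = nrow(cells),
       overlap_ratio = if (tca > 0) toa / tca else 0,
       total_overlap_area = toa,
       total_cell_area = tca,
       resolver_iterations = state$resolver_iterations %||% NA_integer_,
       resolver_seconds = state$resolver_seconds %||% NA_real_,
       edge_roughness = if (nrow(cells) >= 10)
         edge_roughness(cells) else NA_real_)
}

#' Run a scenario to completion
#'
#' Steps the simulation until the configured duration is reached, the
#' target population (`stop_population`) is met, or — with `stall_stop` —
#' growth has effectively ceased because the substrate is exhausted
#' (largest local concentration below 0.5% of `Ks`, i.e. the Monod rate
#' everywhere below 0.5% of `mu_max`).
#'
#' @param scenario a [build_scenario()] object.
#' @param quiet suppress progress messages.
#' @return the final `simulation_state`; `$metrics` is a data frame of the
#'   sampled time series and `$stopped` records the stop reason.
#' @export
run_simulation <- function(scenario, quiet = TRUE) {
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  state <- init_simulation(scenario)
  steps_total <- ceiling(scenario$duration / scenario$dt_slow - 1e-9)
  stop_reason <- "duration"
  for (s in seq_len(steps_total)) {
    state <- step_simulation(state, scenario)
    if (!is.null(scenario$stop_population) &&
        nrow(state$cells) >= scenario$stop_population) {
      stop_reason <- "population"
      break
    }
    if (isTRUE(scenario$stall_stop) && scenario$nutrient > 0 &&
        max(state$field$S) < 0.005 * scenario$growth$Ks) {
      stop_reason <- "stalled"
      break
    }
    if (!quiet && s %% 1000 == 0)
      message(sprintf("t = %.1f min, %d cells", state$time,
                      nrow(state$cells)))
  }
  state$stopped <- stop_reason
  state$metrics <- metrics_frame(state$metrics)
  state
}

metrics_frame <- function(samples) {
  if (is.data.frame(samples)) return(samples)
  if (length(samples) == 0)
    return(data.frame(time = numeric(0), population = integer(0),
                      overlap_ratio = numeric(0),
                      total_overlap_area = numeric(0),
                      total_cell_area = numeric(0),
                      resolver_iterations = numeric(0),
                      resolver_seconds = numeric(0),
                      edge_roughness = numeric(0)))
  cols <- names(samples[[1]])
  out <- lapply(cols, function(cn)
    unlist(lapply(samples, function(s) s[[cn]] %||% NA), use.names = FALSE))
  names(out) <- cols
  as.data.frame(out)
}
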