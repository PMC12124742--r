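#' Resolver configuration
#'
#' Tuning constants for the overlap resolvers.  The grid-based resolver
#' iteratively redistributes excess occupancy with step size `alpha` (a
#' numerical diffusivity factor in `(0, 1]`) until the largest per-unit
#' occupancy change falls below `tol` or `max_iters` is reached.  The
#' kd-tree relaxation shover sweeps until the deepest pairwise overlap is
#' below `shove_tol` (um) or `max_sweeps` is reached.
#'
#' @param type `"dora"` (grid-based) or `"kdtree"` (relaxation shoving).
#' @param alpha numerical diffusivity factor in `(0, 1]`.
#' @param tol convergence threshold on the per-iteration occupancy change.
#' @param max_iters iteration cap for the excess-diffusion loop.
#' @param neighborhood `"von_neumann"` (4 neighbors, weight 1/4) or
#'   `"moore"` (8 neighbors, weight 1/8).
#' @param jitter_sigma std-dev (grid units) of an isotropic Gaussian
#'   pre-displacement applied before forward translation; 0 disables.
#' @param max_move cap on the displacement a cell may receive from one
#'   resolver call, in units of its own radius (`Inf` disables).  The
#'   motion accumulated while a deep local overlap relaxes can otherwise
#'   overshoot by several cell diameters and throw a cell onto a
#'   neighbor; the cap keeps the direction and limits the magnitude to
#'   the physical scale of one shoving event.
#' @param signed_motion if `TRUE`, motion-tensor layers accumulate signed
#'   flows instead of outflow-only (clamped) flows.
#' @param shove_tol kd-tree baseline: overlap-depth tolerance in um.
#' @param max_sweeps kd-tree baseline: sweep cap.
#' @return an object of class `resolution_config`.
#' @export
resolution_config <- function(type = c("dora", "kdtree"), alpha = 0.5,
                              tol = 1e-4, max_iters = 200,
                              neighborhood = c("von_neumann", "moore"),
                              jitter_sigma = 0, max_move = 1,
                              signed_motion = FALSE,
                              shove_tol = 1e-3, max_sweeps = 50) {
  type <- match.arg(type)
  neighborhood <- match.arg(neighborhood)
  stopifnot(alpha > 0, alpha <= 1, tol > 0, max_iters >= 1,
            jitter_sigma >= 0, max_move > 0, shove_tol > 0, max_sweeps >= 1)
  structure(list(type = type, alpha = alpha, tol = tol,
                 max_iters = as.integer(max_iters),
                 neighborhood = neighborhood, jitter_sigma = jitter_sigma,
                 max_move = max_move, signed_motion = isTRUE(signed_motion),
                 shove_tol = shove_tol, max_sweeps = as.integer(max_sweeps)),
            class = "resolution_config")
}

n_layers <- function(config) if (config$neighborhood == "moore") 8L else 4L

#' Excess occupancy
#'
#' `E[i][j] = max(0, Omega[i][j] - 1)`: the per-unit surplus that the
#' resolver redistributes.
#'
#' @param omega an occupancy matrix.
#' @return matrix of the same shape.
#' @export
compute_excess <- function(omega) {
  E <- pmax(omega - 1, 0)
  attributes(E) <- attributes(omega)
  E
}

#' Empty motion tensor
#'
#' A `W x H x L` array accumulating per-unit directional displacement in
#' grid units; layers are ordered down, right, up, left (then up-right,
#' up-left, down-left, down-right for the Moore neighborhood).
#'
#' @param grid a [grid_spec()].
#' @param config a [resolution_config()] (sets the number of layers).
#' @export
new_motion_tensor <- function(grid, config = resolution_config()) {
  array(0, dim = c(grid$W, grid$H, n_layers(config)))
}

# shifted copy of m holding the value at (i + di, j + dj); non-periodic
# axes pad with `fill`
shift_matrix <- function(m, di, dj, px, py, fill = 0) {
  W <- nrow(m); H <- ncol(m)
  ii <- seq_len(W) + di
  jj <- seq_len(H) + dj
  if (px) ii <- (ii - 1) %% W + 1
  if (py) jj <- (jj - 1) %% H + 1
  out <- matrix(fill, W, H)
  ok_i <- ii >= 1 & ii <= W
  ok_j <- jj >= 1 & jj <= H
  out[ok_i, ok_j] <- m[ii[ok_i], jj[ok_j]]
  out
}

direction_offsets <- function(L) {
  di <- c(0, 1, 0, -1, 1, -1, -1, 1)[seq_len(L)]
  dj <- c(-1, 0, 1, 0, 1, 1, -1, -1)[seq_len(L)]
  list(di = di, dj = dj)
}

#' One excess-diffusion step
#'
#' Reference (vectorized R) implementation of a single redistribution
#' iteration:
#' `Omega' = Omega - alpha * (E - wn * sum_{neighbors} E)` with
#' `wn = 1/4` for the von Neumann neighborhood and `1/8` for Moore, and a
#' motion-tensor update `M[i][j][d] += alpha * wn * max(0, E[i][j] - E[k][l])`
#' per direction `d` towards neighbor `(k, l)`.  On a fully periodic grid
#' the total occupancy is conserved exactly.  The iterated loop used by
#' [resolve_occupancy()] runs the same scheme in compiled code.
#'
#' @param omega occupancy matrix (attribute `"grid"` supplies boundaries,
#'   else `grid`).
#' @param config a [resolution_config()].
#' @param motion motion tensor to accumulate into (default: zeros).
#' @param grid a [grid_spec()].
#' @return list with elements `omega`, `motion` and `max_delta` (largest
#'   absolute per-unit occupancy change).
#' @export
diffuse_step <- function(omega, config = resolution_config(), motion = NULL,
                         grid = attr(omega, "grid")) {
  px <- if (is.null(grid)) TRUE else periodic_x(grid)
  py <- if (is.null(grid)) TRUE else periodic_y(grid)
  L <- n_layers(config)
  wn <- 1 / L
  off <- direction_offsets(L)
  if (is.null(motion)) motion <- array(0, dim = c(nrow(omega), ncol(omega), L))
  E <- pmax(unclass(omega) - 1, 0)
  EN <- 0
  for (d in seq_len(L)) {
    Ed <- shift_matrix(E, off$di[d], off$dj[d], px, py)
    EN <- EN + Ed
    flow <- config$alpha * wn * (E - Ed)
    if (!config$signed_motion) flow <- pmax(flow, 0)
    motion[, , d] <- motion[, , d] + flow
  }
  omega_new <- omega - config$alpha * (E - wn * EN)
  list(omega = omega_new, motion = motion,
       max_delta = max(abs(omega_new - omega)))
}

#' Iterate excess diffusion to convergence
#'
#' Repeats the redistribution step while excess occupancy exists, stopping
#' once the largest per-unit occupancy change drops below `config$tol` or
#' after `config$max_iters` iterations.  Residual excess after the
#' iteration cap is reported with a warning, not an error: minor residual
#' overlaps are expected and are resolved over subsequent resolver calls.
#'
#' @inheritParams diffuse_step
#' @return list with `motion` (accumulated motion tensor), `omega` (relaxed
#'   matrix), `iterations`, `max_delta` and `residual_excess`.
#' @export
resolve_occupancy <- function(omega, config = resolution_config(),
                              grid = attr(omega, "grid")) {
  px <- if (is.null(grid)) TRUE else periodic_x(grid)
  py <- if (is.null(grid)) TRUE else periodic_y(grid)
  res <- cpp_resolve(unclass(omega), config$alpha, config$tol,
                     config$max_iters, config$neighborhood == "moore",
                     px, py, config$signed_motion)
  if (res$iterations >= config$max_iters && res$max_delta >= config$tol)
    warning(sprintf(
      "resolver hit max_iters = %d with residual excess %.3g",
      config$max_iters, res$residual_excess))
  res
}

#' Per-unit movement vector
#'
#' `v_x = M[right] - M[left]`, `v_y = M[up] - M[down]`; Moore diagonal
#' layers contribute `1/sqrt(2)` of their magnitude to each adjacent
#' cardinal component.
#'
#' @param motion a motion tensor (`W x H x L`).
#' @param i,j 0-based grid-unit indices.
#' @return `c(v_x, v_y)` in grid units.
#' @export
unit_motion_vector <- function(motion, i, j) {
  v <- unit_motion_vectors(motion)
  c(v_x = v$vx[i + 1, j + 1], v_y = v$vy[i + 1, j + 1])
}

#' @rdname unit_motion_vector
#' @return `unit_motion_vectors()` returns the full per-unit fields as a
#'   list of two `W x H` matrices `vx`, `vy`.
#' @export
unit_motion_vectors <- function(motion) {
  s2 <- 1 / sqrt(2)
  Md <- motion[, , 1]; Mr <- motion[, , 2]
  Mu <- motion[, , 3]; Ml <- motion[, , 4]
  if (dim(motion)[3] == 8) {
    Mr <- Mr + s2 * (motion[, , 5] + motion[, , 8])
    Ml <- Ml + s2 * (motion[, , 6] + motion[, , 7])
    Mu <- Mu + s2 * (motion[, , 5] + motion[, , 6])
    Md <- Md + s2 * (motion[, , 7] + motion[, , 8])
  }
  list(vx = Mr - Ml, vy = Mu - Md)
}

#' Back-translate the motion tensor into per-cell movement vectors
#'
#' Grid units covered by exactly one cell contribute their per-unit vector
#' to that cell's sum.  Units covered by `N > 1` cells partition the
#' covering cells into positive/negative movers per axis: the number of
#' rightward movers is `round(N * M_right / (M_right + M_left))` (rounding
#' half away from zero; vertical analogously), the directional magnitude
#' is shared equally among the movers in that direction, and assignment is
#' by ascending cell id (lower ids take the positive direction), which
#' also breaks ties deterministically.  A zero directional denominator
#' assigns no movement on that axis.
#'
#' @param cells cells data frame (um coordinates).
#' @param motion accumulated motion tensor from [resolve_occupancy()].
#' @param grid a [grid_spec()].
#' @param config a [resolution_config()].
#' @return data frame with `id`, `vx`, `vy` (grid units), one row per cell
#'   in the input order.
#' @export
cell_movements <- function(cells, motion, grid, config = resolution_config()) {
  cells <- validate_cells(cells)
  ord <- order(cells$id)
  cs <- cells[ord, , drop = FALSE]
  V <- cpp_cell_movements(cs$x / grid$w, cs$y / grid$h,
                          cs$r / grid$w, cs$r / grid$h,
                          motion, grid$W, grid$H, dim(motion)[3],
                          periodic_x(grid), periodic_y(grid))
  out <- data.frame(id = cs$id, vx = V[, 1], vy = V[, 2])
  out[match(cells$id, out$id), , drop = FALSE]
}

#' Apply movement vectors to cell positions
#'
#' Displaces each cell by its movement vector (grid units, converted to um
#' through the unit size), wrapping on periodic edges and clamping at solid
#' edges so the cell center stays at least one radius inside the wall.
#' Open edges neither wrap nor clamp.
#'
#' @param cells cells data frame.
#' @param movements data frame from [cell_movements()] (`id`, `vx`, `vy`).
#' @param grid a [grid_spec()].
#' @return the displaced cells.
#' @export
apply_movements <- function(cells, movements, grid) {
  cells <- validate_cells(cells)
  m <- movements[match(cells$id, movements$id), , drop = FALSE]
  cells$x <- cells$x + m$vx * grid$w
  cells$y <- cells$y + m$vy * grid$h
  wrap_clamp_cells(cells, grid)
}

wrap_clamp_cells <- function(cells, grid) {
  Lx <- grid$W * grid$w
  Ly <- grid$H * grid$h
  b <- grid$boundary
  if (periodic_x(grid)) cells$x <- cells$x %% Lx
  if (periodic_y(grid)) cells$y <- cells$y %% Ly
  if (b$left == "solid") cells$x <- pmax(cells$x, cells$r)
  if (b$right == "solid") cells$x <- pmin(cells$x, Lx - cells$r)
  if (b$bottom == "solid") cells$y <- pmax(cells$y, cells$r)
  if (b$top == "solid") cells$y <- pmin(cells$y, Ly - cells$r)
  cells
}

#' Resolve overlaps with the grid-based resolver
#'
#' The full three-phase pipeline: optional Gaussian pre-displacement
#' (jitter), forward translation of the population to an occupancy matrix,
#' iterative excess redistribution with motion-tensor bookkeeping, and
#' back-translation of the accumulated displacements to the cells.  On a
#' population with no over-occupied grid unit the call returns the
#' positions unchanged (up to jitter).  The motion tensor is reset at the
#' start of every call.
#'
#' @param cells cells data frame (um coordinates).
#' @param grid a [grid_spec()].
#' @param config a [resolution_config()].
#' @return the adjusted cells, with attributes `iterations` and
#'   `residual_excess` describing the resolver pass.
#' @export
dora_resolve_overlaps <- function(cells, grid, config = resolution_config()) {
  cells <- validate_cells(cells)
  if (nrow(cells) == 0) return(cells)
  check_cell_scale(cells$r, grid)
  ord <- NULL
  if (is.unsorted(cells$id)) {
    ord <- order(cells$id)
    cells <- cells[ord, , drop = FALSE]
  }
  out <- dora_core(cells, grid, config)
  if (!is.null(ord)) {
    at <- attributes(out)[c("iterations", "residual_excess")]
    out <- out[order(ord), , drop = FALSE]
    rownames(out) <- NULL
    attributes(out)[names(at)] <- at
  }
  out
}

# validation-free pipeline; assumes a valid cells frame sorted by id
dora_core <- function(cells, grid, config) {
  px <- periodic_x(grid)
  py <- periodic_y(grid)
  if (config$jitter_sigma > 0) {
    cells$x <- cells$x + rnorm(nrow(cells), 0, config$jitter_sigma) * grid$w
    cells$y <- cells$y + rnorm(nrow(cells), 0, config$jitter_sigma) * grid$h
    cells <- wrap_clamp_cells(cells, grid)
  }
  res <- cpp_dora(cells$x / grid$w, cells$y / grid$h,
                  cells$r / grid$w, cells$r / grid$h,
                  grid$W, grid$H, px, py,
                  config$alpha, config$tol, config$max_iters,
                  config$neighborhood == "moore", config$signed_motion)
  if (res$iterations >= config$max_iters && res$max_delta >= config$tol)
    warning(sprintf("resolver hit max_iters = %d with residual excess %.3g",
                    config$max_iters, res$residual_excess))
  if (res$iterations > 1 || res$residual_excess > 0) {
    vx <- res$V[, 1]
    vy <- res$V[, 2]
    if (is.finite(config$max_move)) {
      # clamp each displacement to max_move cell radii (grid units)
      mag <- sqrt((vx * grid$w)^2 + (vy * grid$h)^2)
      cap <- config$max_move * cells$r
      f <- ifelse(mag > cap, cap / mag, 1)
      vx <- vx * f
      vy <- vy * f
    }
    cells$x <- cells$x + vx * grid$w
    cells$y <- cells$y + vy * grid$h
    cells <- wrap_clamp_cells(cells, grid)
  }
  attr(cells, "iterations") <- res$iterations
  attr(cells, "residual_excess") <- res$residual_excess
  cells
}

#' Dispatch to the configured overlap resolver
#'
#' @inheritParams dora_resolve_overlaps
#' @seealso [dora_resolve_overlaps()], [relaxation_shove()]
#' @export
resolve_overlaps <- function(cells, grid, config = resolution_config()) {
  if (config$type == "kdtree")
    relaxation_shove(cells, grid, tol = config$shove_tol,
                     max_sweeps = config$max_sweeps)
  else dora_resolve_overlaps(cells, grid, config)
}
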