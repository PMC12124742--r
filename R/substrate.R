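#' Monod specific growth rate
#'
#' `mu = mu_max * S / (Ks + S)`, the saturating dependence of the specific
#' growth rate on the local substrate concentration.
#'
#' @param S local substrate concentration, mg/L (vectorized, must be >= 0).
#' @param p a [growth_params()].
#' @return specific growth rate in 1/min, in `[0, mu_max]`.
#' @export
monod_rate <- function(S, p) {
  if (any(S < 0)) stop("substrate concentration must be non-negative")
  p$mu_max * S / (p$Ks + S)
}

#' Substrate concentration field
#'
#' Nutrient concentration on its own (coarser) grid, advanced by the
#' explicit Forward-Time Central-Space scheme.  The field is conceptually
#' a well-mixed nutrient layer of thickness `depth` above the cell plane;
#' `depth` only enters the biomass/substrate unit conversion.  Boundary
#' conditions per edge: `"periodic"`, `"neumann"` (zero flux) or
#' `"dirichlet"` (edge pinned to the bulk concentration `S0`).
#'
#' @param nx,ny field grid size in units.
#' @param dx field grid spacing, um.
#' @param D diffusion coefficient, um^2/min.
#' @param S0 initial (and bulk/Dirichlet) concentration, mg/L.
#' @param boundary single string or named list (`bottom`, `top`, `left`,
#'   `right`); periodic edges must be paired.
#' @param depth nutrient layer thickness, um.
#' @return an object of class `substrate_field`.
#' @export
substrate_field <- function(nx, ny, dx, D, S0 = 0, boundary = "periodic",
                            depth = 20) {
  stopifnot(nx >= 1, ny >= 1, dx > 0, D >= 0, S0 >= 0, depth > 0)
  edges <- c("bottom", "top", "left", "right")
  if (length(boundary) == 1 && is.null(names(boundary)))
    boundary <- stats::setNames(as.list(rep(boundary, 4)), edges)
  else {
    boundary <- as.list(boundary)[edges]
    if (any(vapply(boundary, is.null, logical(1))))
      stop("boundary must name all of: ", paste(edges, collapse = ", "))
  }
  ok <- vapply(boundary, function(b) b %in% c("periodic", "neumann", "dirichlet"),
               logical(1))
  if (!all(ok)) stop("boundary values must be 'periodic', 'neumann' or 'dirichlet'")
  if (xor(boundary$left == "periodic", boundary$right == "periodic") ||
      xor(boundary$bottom == "periodic", boundary$top == "periodic"))
    stop("periodic edges must be paired (left/right, bottom/top)")
  structure(list(S = matrix(S0, nx, ny), dx = dx, D = D, bulk = S0,
                 boundary = boundary, depth = depth, deficit = 0),
            class = "substrate_field")
}

#' @export
print.substrate_field <- function(x, ...) {
  cat(sprintf("<substrate_field> %d x %d units of %g um, D = %g um^2/min\n",
              nrow(x$S), ncol(x$S), x$dx, x$D))
  cat(sprintf("  S: mean %.4g, range [%.4g, %.4g] mg/L; bulk %g\n",
              mean(x$S), min(x$S), max(x$S), x$bulk))
  invisible(x)
}

bc_code <- function(b) c(periodic = 0L, neumann = 1L, dirichlet = 2L)[[b]]

#' Check the FTCS stability bound
#'
#' The explicit 2-D scheme is stable for `D * dt / dx^2 <= 1/4`.
#'
#' @param field a [substrate_field()].
#' @param dt time step, min.
#' @export
check_ftcs_stability <- function(field, dt) {
  crit <- field$D * dt / field$dx^2
  if (crit > 0.25)
    stop(sprintf(
      "FTCS unstable: D*dt/dx^2 = %.3g > 0.25 (reduce dt or coarsen dx)",
      crit))
  invisible(crit)
}

#' Advance the substrate field
#'
#' `nsub` Forward-Time Central-Space substeps of length `dt` each, using a
#' 5-point Laplacian; an optional per-substep sink matrix (concentration
#' consumed per unit per substep) is subtracted after each diffusion
#' update.  Negative concentrations are floored at zero and the floored
#' mass accumulates in the field's `deficit` log.  With periodic
#' boundaries and no sinks, total substrate is conserved.
#'
#' @param field a [substrate_field()].
#' @param dt substep length, min (must satisfy the stability bound).
#' @param sinks optional `nx x ny` matrix, mg/L removed per unit per substep.
#' @param nsub number of substeps.
#' @return the updated field.
#' @export
ftcs_step <- function(field, dt, sinks = NULL, nsub = 1) {
  check_ftcs_stability(field, dt)
  if (is.null(sinks)) sinks <- matrix(0, 0, 0)
  b <- field$boundary
  res <- cpp_ftcs(field$S, field$D, dt, field$dx, as.integer(nsub), sinks,
                  bc_code(b$left), bc_code(b$right),
                  bc_code(b$bottom), bc_code(b$top), field$bulk)
  field$S <- res$S
  field$deficit <- field$deficit + res$deficit
  field
}
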