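#' Growth and division parameters
#'
#' Monod kinetics plus the biomass-geometry link.  A cell of biomass `m`
#' (pg) has radius `r = sqrt(m / (pi * density))`, i.e. biomass is
#' proportional to the cell's area through the areal `density` constant.
#' Defaults are calibrated to heterotroph scales such that a closed
#' 600 x 600 um domain at 100 mg/L holds substrate for a population of a
#' few times 1e4 cells (see the package vignette for the budget).
#'
#' @param mu_max maximum specific growth rate, 1/min.
#' @param Ks half-saturation constant, mg/L.
#' @param yield biomass produced per substrate mass consumed (pg/pg).
#' @param division_radius radius triggering division, um.
#' @param density areal biomass density, pg/um^2.
#' @param initial_radius radius of founding cells, um.
#' @param division_noise half-width (as a fraction of `division_radius`) of
#'   the uniform per-cell randomization of the division threshold.  Each
#'   cell carries a persistent threshold drawn at birth from
#'   `division_radius * (1 +/- division_noise)`.  0 disables.
#' @param split_sd standard deviation of the biomass split fraction at
#'   division: the first daughter receives a fraction
#'   `0.5 + N(0, split_sd)` (truncated to `[0.35, 0.65]`) of the mother's
#'   biomass, the second the remainder.  This is what actually
#'   desynchronizes lineages: threshold noise alone telescopes out of the
#'   cumulative generation time (a late-dividing mother makes large,
#'   early-dividing daughters), so without split asymmetry every
#'   descendant of the founder divides in lockstep and the colony grows
#'   in artificial bursts.  0 restores exact halving.
#' @param lysis_conc optional starvation threshold (mg/L): cells whose
#'   local substrate concentration is below it are removed.  `NULL`
#'   (default) disables lysis.
#' @return an object of class `growth_params`.
#' @export
growth_params <- function(mu_max = 0.02, Ks = 2.5, yield = 0.5,
                          division_radius = 2, density = 1e-4,
                          initial_radius = 1, division_noise = 0.1,
                          split_sd = 0.05, lysis_conc = NULL) {
  stopifnot(mu_max > 0, Ks > 0, yield > 0, division_radius > 0,
            density > 0, initial_radius > 0,
            division_noise >= 0, division_noise < 1,
            split_sd >= 0, split_sd < 0.15)
  structure(list(mu_max = mu_max, Ks = Ks, yield = yield,
                 division_radius = division_radius, density = density,
                 initial_radius = initial_radius,
                 division_noise = division_noise, split_sd = split_sd,
                 lysis_conc = lysis_conc),
            class = "growth_params")
}

#' @rdname growth_params
#' @param m biomass, pg.
#' @param p a `growth_params` object.
#' @export
radius_from_biomass <- function(m, p) sqrt(m / (pi * p$density))

#' @rdname growth_params
#' @param r radius, um.
#' @export
biomass_from_radius <- function(r, p) pi * r^2 * p$density

#' Grow cells and divide those that reach the division radius
#'
#' Biomass grows exponentially over the step, `m' = m * exp(mu * dt)` with
#' `mu` the local Monod rate; the substrate consumed is
#' `(m' - m) / yield`.  Radii are updated through the density link.  A
#' cell whose radius reaches its division threshold splits into two
#' daughters sharing its biomass (an even split up to the `split_sd`
#' asymmetry), placed tangentially along a uniformly random axis with
#' their midpoint at the mother's position, so the siblings touch without
#' overlapping; the first daughter keeps the mother's id, the second
#' receives a fresh id.  With `division_noise > 0` every cell carries a
#' persistent threshold (column `r_div`, drawn at birth, assigned here on
#' first use for populations lacking it); thresholds are not written to
#' snapshots and are redrawn on resume.  All draws come from the session
#' RNG in ascending mother id order, keeping runs reproducible under a
#' fixed seed.
#'
#' @param cells cells data frame.
#' @param dt time step, min.
#' @param S_local per-cell substrate concentration, mg/L (recycled).
#' @param p a [growth_params()].
#' @param next_id first id to assign to new daughters (default: one past
#'   the current maximum).
#' @return list with `cells` (grown/divided population), `consumed` (total
#'   substrate mass consumed, pg, per original cell, named by id),
#'   `divisions` (count) and `next_id`.
#' @export
grow_and_divide <- function(cells, dt, S_local, p, next_id = NULL) {
  stopifnot(dt > 0)
  cells <- validate_cells(cells)
  if (is.null(next_id))
    next_id <- if (nrow(cells)) max(cells$id) + 1L else 1L
  if (nrow(cells) == 0)
    return(list(cells = cells, consumed = numeric(0), divisions = 0L,
                next_id = next_id))
  mu <- monod_rate(rep_len(S_local, nrow(cells)), p)
  m_new <- cells$biomass * exp(mu * dt)
  consumed <- (m_new - cells$biomass) / p$yield
  names(consumed) <- cells$id
  cells$biomass <- m_new
  cells$r <- radius_from_biomass(m_new, p)

  noise <- p$division_noise
  if (noise > 0 && is.null(cells$r_div))
    cells$r_div <- p$division_radius *
      (1 + runif(nrow(cells), -noise, noise))
  thr <- if (!is.null(cells$r_div)) cells$r_div else
    rep(p$division_radius, nrow(cells))

  div <- which(cells$r >= thr)
  div <- div[order(cells$id[div])]     # deterministic RNG consumption order
  if (length(div) > 0) {
    ang <- runif(length(div), 0, 2 * pi)
    mothers <- cells[div, , drop = FALSE]
    f <- rep(0.5, length(div))
    if (p$split_sd > 0)
      f <- 0.5 + pmin(pmax(rnorm(length(div), 0, p$split_sd), -0.15), 0.15)
    m1 <- mothers$biomass * f
    m2 <- mothers$biomass * (1 - f)
    r1 <- radius_from_biomass(m1, p)
    r2 <- radius_from_biomass(m2, p)
    # daughters touch (centers r1 + r2 apart, midpoint at the mother):
    # division itself introduces no overlap between the siblings
    sep <- (r1 + r2) / 2
    off_x <- sep * cos(ang)
    off_y <- sep * sin(ang)
    d1 <- data.frame(id = mothers$id,
                     x = mothers$x - off_x, y = mothers$y - off_y,
                     r = r1, biomass = m1)
    d2 <- data.frame(id = seq.int(next_id, length.out = length(div)),
                     x = mothers$x + off_x, y = mothers$y + off_y,
                     r = r2, biomass = m2)
    if (!is.null(cells$r_div)) {
      d1$r_div <- p$division_radius *
        (1 + runif(length(div), -noise, noise))
      d2$r_div <- p$division_radius *
        (1 + runif(length(div), -noise, noise))
    }
    next_id <- next_id + length(div)
    cells <- rbind(cells[-div, , drop = FALSE], d1, d2)
    cells <- cells[order(cells$id), , drop = FALSE]
    rownames(cells) <- NULL
  }
  list(cells = cells, consumed = consumed, divisions = length(div),
       next_id = as.integer(next_id))
}
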