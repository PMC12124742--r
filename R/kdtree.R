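#' Pairwise overlap test
#'
#' Two circular cells overlap when the sum of their radii exceeds the
#' distance between their centers.  On periodic axes the minimum-image
#' distance is used.
#'
#' @param c1,c2 one-row cells data frames, or numeric vectors `c(x, y, r)`.
#' @param grid optional [grid_spec()] supplying domain size and periodicity.
#' @return list with `depth` (`max(0, r1 + r2 - d)`, um) and `overlap`
#'   (logical, `d < r1 + r2`).
#' @export
overlapping_pair <- function(c1, c2, grid = NULL) {
  as_xyr <- function(c_) {
    if (is.data.frame(c_)) c(c_$x[1], c_$y[1], c_$r[1]) else as.numeric(c_[1:3])
  }
  a <- as_xyr(c1); b <- as_xyr(c2)
  dx <- a[1] - b[1]; dy <- a[2] - b[2]
  if (!is.null(grid)) {
    Lx <- grid$W * grid$w; Ly <- grid$H * grid$h
    if (periodic_x(grid)) dx <- dx - round(dx / Lx) * Lx
    if (periodic_y(grid)) dy <- dy - round(dy / Ly) * Ly
  }
  d <- sqrt(dx^2 + dy^2)
  list(depth = max(0, a[3] + b[3] - d), overlap = d < a[3] + b[3])
}

domain_of <- function(cells, grid) {
  if (!is.null(grid))
    return(list(Lx = grid$W * grid$w, Ly = grid$H * grid$h,
                px = periodic_x(grid), py = periodic_y(grid)))
  list(Lx = max(cells$x, 1) + 1, Ly = max(cells$y, 1) + 1,
       px = FALSE, py = FALSE)
}

#' kd-tree fixed-radius neighbor query
#'
#' Returns the row indices of the cells whose centers lie within `radius`
#' of the query point, located through a kd-tree over the cell centers
#' (minimum-image metric on periodic axes).
#'
#' @param cells cells data frame.
#' @param q query point `c(x, y)` in um.
#' @param radius query radius in um.
#' @param grid optional [grid_spec()] for domain size and periodicity.
#' @return integer vector of row indices (ascending).
#' @export
neighbors_within <- function(cells, q, radius, grid = NULL) {
  cells <- validate_cells(cells)
  if (nrow(cells) == 0) return(integer(0))
  d <- domain_of(cells, grid)
  sort(cpp_kd_query(cells$x, cells$y, q[1], q[2], radius,
                    d$Lx, d$Ly, d$px, d$py))
}

#' All overlapping pairs in a population
#'
#' Candidate pairs are found via the kd-tree (or, for verification, by the
#' quadratic brute-force scan) and reported with their center distances.
#'
#' @param cells cells data frame.
#' @param grid optional [grid_spec()].
#' @param method `"kdtree"` or `"brute"`.
#' @return data frame with row indices `i < j` and center distance `d` (um).
#' @export
overlap_pairs <- function(cells, grid = NULL, method = c("kdtree", "brute")) {
  method <- match.arg(method)
  cells <- validate_cells(cells)
  dm <- domain_of(cells, grid)
  if (nrow(cells) < 2)
    return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  if (method == "kdtree") {
    m <- cpp_kd_pairs(cells$x, cells$y, cells$r, dm$Lx, dm$Ly, dm$px, dm$py)
    out <- data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
                      d = m[, 3])
  } else {
    pr <- utils::combn(nrow(cells), 2)
    dx <- cells$x[pr[1, ]] - cells$x[pr[2, ]]
    dy <- cells$y[pr[1, ]] - cells$y[pr[2, ]]
    if (dm$px) dx <- dx - round(dx / dm$Lx) * dm$Lx
    if (dm$py) dy <- dy - round(dy / dm$Ly) * dm$Ly
    d <- sqrt(dx^2 + dy^2)
    keep <- d < cells$r[pr[1, ]] + cells$r[pr[2, ]]
    out <- data.frame(i = pr[1, keep], j = pr[2, keep], d = d[keep])
  }
  out[order(out$i, out$j), , drop = FALSE]
}

#' Relaxation shoving (kd-tree baseline)
#'
#' The classical pairwise comparator: repeated sweeps over the population
#' in ascending id order; for each focal cell, neighbors within
#' `r_focal + r_max` are fetched from a kd-tree rebuilt at the start of
#' every sweep, and each overlapping pair is displaced symmetrically by
#' half the overlap depth along the line joining the centers (a repulsive
#' contact force).  Sweeps stop when the deepest overlap encountered falls
#' below `tol` or after `max_sweeps`.  Coincident centers separate along a
#' direction drawn from the seeded RNG.
#'
#' @param cells cells data frame.
#' @param grid a [grid_spec()] (boundaries: periodic edges wrap, solid
#'   edges clamp the center one radius inside).
#' @param tol overlap-depth tolerance in um.
#' @param max_sweeps sweep cap.
#' @return the displaced cells, with attributes `sweeps` and `max_depth`.
#' @export
relaxation_shove <- function(cells, grid, tol = 1e-3, max_sweeps = 50) {
  cells <- validate_cells(cells)
  if (nrow(cells) == 0) return(cells)
  ord <- order(cells$id)
  cs <- cells[ord, , drop = FALSE]
  b <- grid$boundary
  res <- cpp_relax_shove(cs$x, cs$y, cs$r, grid$W * grid$w, grid$H * grid$h,
                         periodic_x(grid), periodic_y(grid),
                         b$bottom == "solid", b$top == "solid",
                         tol, max_sweeps, runif(nrow(cs), 0, 2 * pi))
  if (res$n_coincident > 0)
    message("separated ", res$n_coincident,
            " coincident pair(s) along random directions")
  cs$x <- res$x
  cs$y <- res$y
  out <- cs[match(cells$id, cs$id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sweeps") <- res$sweeps
  attr(out, "max_depth") <- res$max_depth
  out
}
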