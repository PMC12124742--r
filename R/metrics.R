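#' Circle-circle intersection (lens) area
#'
#' Exact area of the intersection of two discs: zero for `d >= r1 + r2`,
#' `pi * min(r1, r2)^2` when one disc contains the other, and the
#' two-segment lens formula otherwise.  Vectorized.
#'
#' @param r1,r2 radii (um).
#' @param d center distance (um).
#' @return intersection area in um^2.
#' @export
lens_area <- function(r1, r2, d) {
  n <- max(length(r1), length(r2), length(d))
  r1 <- rep_len(r1, n); r2 <- rep_len(r2, n); d <- rep_len(d, n)
  out <- numeric(n)
  contained <- d <= abs(r1 - r2)
  out[contained] <- pi * pmin(r1, r2)[contained]^2
  lens <- !contained & d < r1 + r2
  if (any(lens)) {
    a <- r1[lens]; b <- r2[lens]; dd <- d[lens]
    out[lens] <-
      a^2 * acos(pmin(1, pmax(-1, (dd^2 + a^2 - b^2) / (2 * dd * a)))) +
      b^2 * acos(pmin(1, pmax(-1, (dd^2 + b^2 - a^2) / (2 * dd * b)))) -
      0.5 * sqrt(pmax(0, (-dd + a + b) * (dd + a - b) *
                         (dd - a + b) * (dd + a + b)))
  }
  out
}

#' Residual overlap metrics
#'
#' The overlap ratio is the total pairwise lens area divided by the total
#' cell area `sum(pi * r^2)`; higher-order (triple) overlaps are counted
#' pairwise, making the ratio an upper bound on the true excess area.  An
#' empty population has ratio 0 by convention.
#'
#' @param cells cells data frame.
#' @param grid optional [grid_spec()] (periodicity for pair detection).
#' @param method pair search: `"kdtree"` (spatial index) or `"brute"`.
#' @return `overlap_ratio()`: a single fraction; `total_overlap_area()`:
#'   summed lens area in um^2.
#' @export
overlap_ratio <- function(cells, grid = NULL, method = c("kdtree", "brute")) {
  cells <- validate_cells(cells)
  if (nrow(cells) == 0) return(0)
  total_overlap_area(cells, grid, method) / sum(pi * cells$r^2)
}

#' @rdname overlap_ratio
#' @export
total_overlap_area <- function(cells, grid = NULL,
                               method = c("kdtree", "brute")) {
  cells <- validate_cells(cells)
  pr <- overlap_pairs(cells, grid, method)
  if (nrow(pr) == 0) return(0)
  sum(lens_area(cells$r[pr$i], cells$r[pr$j], pr$d))
}

#' Colony edge roughness
#'
#' Coefficient of variation of the radial distance of boundary cells from
#' the population centroid.  Boundary cells are, within each of `bins`
#' angular bins, the cells in the top decile of radial distance.  Cells on
#' a perfect circle give 0; rougher (e.g. branched) colony edges give
#' larger values.  Intended for colonies well inside the domain; periodic
#' wrapping is not unfolded.
#'
#' @param cells cells data frame (at least 10 cells).
#' @param bins number of angular bins.
#' @return dimensionless roughness statistic.
#' @export
edge_roughness <- function(cells, bins = 36) {
  cells <- validate_cells(cells)
  if (nrow(cells) < 10)
    stop("edge_roughness is undefined for fewer than 10 cells")
  cx <- mean(cells$x); cy <- mean(cells$y)
  dx <- cells$x - cx; dy <- cells$y - cy
  rad <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx)
  bin <- pmin(floor((ang + pi) / (2 * pi) * bins) + 1, bins)
  edge <- unlist(lapply(split(rad, bin), function(rs) {
    rs[rs >= quantile(rs, 0.9)]
  }), use.names = FALSE)
  if (mean(edge) == 0) return(0)
  sd(edge) / mean(edge)
}
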