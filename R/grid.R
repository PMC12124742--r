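#' Grid specification for the occupancy lattice
#'
#' Discretizes a rectangular domain into `W x H` grid units of physical size
#' `w x h` micrometres.  The unit size is chosen on the same scale as the
#' cell radius, typically around 1 um per grid unit.  Grid unit `(i, j)`
#' (0-based) spans the half-open box `[i, i+1) x [j, j+1)` in continuous
#' grid coordinates, with the origin at the bottom-left corner; `i` indexes
#' the x direction and `j` the y direction.
#'
#' @param W,H number of grid units along x and y.
#' @param w,h physical width and height of one unit (um per grid unit).
#' @param boundary either a single string applied to all edges or a named
#'   list/vector with entries `bottom`, `top`, `left`, `right`, each one of
#'   `"periodic"`, `"solid"` or `"open"`.  Periodic edges must come in
#'   opposing pairs.
#' @return an object of class `grid_spec`.
#' @examples
#' g <- grid_spec(150, 150)           # 150 x 150 um domain at 1 um per unit
#' g <- grid_spec(800, 200, boundary = list(bottom = "solid", top = "open",
#'                                          left = "periodic", right = "periodic"))
#' @export
grid_spec <- function(W, H, w = 1, h = 1, boundary = "periodic") {
  stopifnot(W >= 1, H >= 1, w > 0, h > 0)
  edges <- c("bottom", "top", "left", "right")
  if (length(boundary) == 1 && is.null(names(boundary))) {
    boundary <- stats::setNames(as.list(rep(boundary, 4)), edges)
  } else {
    boundary <- as.list(boundary)
    if (!all(edges %in% names(boundary)))
      stop("boundary must name all of: ", paste(edges, collapse = ", "))
    boundary <- boundary[edges]
  }
  ok <- vapply(boundary, function(b) b %in% c("periodic", "solid", "open"),
               logical(1))
  if (!all(ok)) stop("boundary values must be 'periodic', 'solid' or 'open'")
  if (xor(boundary$left == "periodic", boundary$right == "periodic") ||
      xor(boundary$bottom == "periodic", boundary$top == "periodic"))
    stop("periodic edges must be paired (left/right, bottom/top)")
  structure(list(W = as.integer(W), H = as.integer(H), w = w, h = h,
                 boundary = boundary),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d units of %g x %g um (domain %g x %g um)\n",
              x$W, x$H, x$w, x$h, x$W * x$w, x$H * x$h))
  cat("  boundary:", paste(names(x$boundary), unlist(x$boundary),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

periodic_x <- function(grid) grid$boundary$left == "periodic"
periodic_y <- function(grid) grid$boundary$bottom == "periodic"

#' Cell boundaries in continuous grid coordinates
#'
#' For a cell centered at `(xc, yc)` (grid units) with radius `r` (um), the
#' axis-aligned bounding square on the grid is
#' `x_left/right = xc -/+ r/w` and `y_bottom/top = yc -/+ r/h`.  The circular
#' cell is approximated by this square throughout the forward translation.
#'
#' @param xc,yc cell center coordinates in grid units (may be vectors).
#' @param r cell radius in um.
#' @param grid a [grid_spec()].
#' @return data frame with columns `x_left`, `x_right`, `y_bottom`, `y_top`.
#' @export
compute_cell_bounds <- function(xc, yc, r, grid) {
  if (any(!is.finite(r)) || any(r <= 0))
    stop("invalid cell: radius must be positive and finite")
  data.frame(x_left  = xc - r / grid$w, x_right = xc + r / grid$w,
             y_bottom = yc - r / grid$h, y_top   = yc + r / grid$h)
}

#' Rasterize a single cell onto the occupancy grid
#'
#' Computes, for every grid unit touched by the cell's bounding square, the
#' fractional overlap
#' `max(0, min(i+1, x_right) - max(i, x_left)) * max(0, min(j+1, y_top) - max(j, y_bottom))`.
#' In grid coordinates the normalization by the unit area `w x h` cancels,
#' since the bounds are already expressed in grid units.  For a cell fully
#' interior to the grid the fractions sum to `(2r/w) * (2r/h)`.
#'
#' @inheritParams compute_cell_bounds
#' @return data frame with 0-based unit indices `i`, `j` (wrapped on periodic
#'   axes) and the occupancy fraction `frac` in `[0, 1]`.  A cell entirely
#'   outside a non-periodic domain yields zero rows, with a warning.
#' @export
rasterize_cell <- function(xc, yc, r, grid) {
  stopifnot(length(xc) == 1, length(yc) == 1, length(r) == 1)
  check_cell_scale(r, grid)
  b <- compute_cell_bounds(xc, yc, r, grid)
  is <- seq.int(floor(b$x_left), ceiling(b$x_right) - 1)
  js <- seq.int(floor(b$y_bottom), ceiling(b$y_top) - 1)
  ox <- pmin(is + 1, b$x_right) - pmax(is, b$x_left)
  oy <- pmin(js + 1, b$y_top) - pmax(js, b$y_bottom)
  keep_i <- ox > 0
  keep_j <- oy > 0
  if (periodic_x(grid)) ii <- is %% grid$W
  else { keep_i <- keep_i & is >= 0 & is < grid$W; ii <- is }
  if (periodic_y(grid)) jj <- js %% grid$H
  else { keep_j <- keep_j & js >= 0 & js < grid$H; jj <- js }
  out <- expand.grid(i = ii[keep_i], j = jj[keep_j], KEEP.OUT.ATTRS = FALSE)
  out$frac <- as.vector(outer(ox[keep_i], oy[keep_j]))
  if (nrow(out) == 0)
    warning("cell lies entirely outside the (non-periodic) domain")
  out[order(out$j, out$i), , drop = FALSE]
}

check_cell_scale <- function(r, grid) {
  if (any(2 * r / grid$w > grid$W) || any(2 * r / grid$h > grid$H))
    stop("cell larger than the domain is not supported")
  if (any(r < 0.05 * min(grid$w, grid$h)))
    warning("cell radius below 0.05 * unit size; rasterization becomes noisy")
  invisible(TRUE)
}

#' Build the occupancy matrix for a population
#'
#' Sums the rasterized footprints of all cells: `Omega[i][j] = sum_k Omega_ij(k)`.
#' Values below one mark under-occupied units, exactly one fully occupied
#' units, and above one over-occupied units where cells overlap.
#'
#' @param cells a cells data frame (see [make_cells()]); coordinates in um.
#' @param grid a [grid_spec()].
#' @return a `W x H` numeric matrix, indexed `[i + 1, j + 1]` for unit
#'   `(i, j)`, with the grid attached as attribute `"grid"`.
#' @export
build_occupancy <- function(cells, grid) {
  cells <- validate_cells(cells)
  if (nrow(cells) > 0) check_cell_scale(cells$r, grid)
  omega <- cpp_build_occupancy(cells$x / grid$w, cells$y / grid$h,
                               cells$r / grid$w, cells$r / grid$h,
                               grid$W, grid$H,
                               periodic_x(grid), periodic_y(grid))
  attr(omega, "grid") <- grid
  omega
}
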