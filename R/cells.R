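#' Construct a population of circular cells
#'
#' Cells are stored as a plain data frame with one row per cell and columns
#' `id` (integer), `x`, `y` (center coordinates, um), `r` (radius, um) and
#' `biomass` (mass-like scalar, pg; used by the growth model and ignored by
#' the overlap resolvers).
#'
#' @param x,y center coordinates in um.
#' @param r radii in um (recycled).
#' @param biomass biomass per cell (recycled; default 0).
#' @param id integer ids (default `seq_along(x)`); must be unique.
#' @return a cells data frame.
#' @export
make_cells <- function(x, y, r, biomass = 0, id = seq_along(x)) {
  validate_cells(data.frame(id = as.integer(id), x = as.numeric(x),
                            y = as.numeric(y),
                            r = as.numeric(rep_len(r, length(x))),
                            biomass = as.numeric(rep_len(biomass, length(x)))))
}

validate_cells <- function(cells) {
  need <- c("id", "x", "y", "r", "biomass")
  if (!all(need %in% names(cells)))
    stop("cells must have columns: ", paste(need, collapse = ", "))
  cells <- as.data.frame(cells)
  # canonical columns first; extras (e.g. per-cell division thresholds)
  # ride along untouched
  cells <- cells[c(need, setdiff(names(cells), need))]
  if (nrow(cells) > 0) {
    if (anyDuplicated(cells$id)) stop("cell ids must be unique")
    if (any(!is.finite(cells$r)) || any(cells$r <= 0))
      stop("invalid cell: radius must be positive and finite")
  }
  cells
}

#' Read / write cell snapshots
#'
#' Plain delimited text with header `id,x,y,r,biomass`; coordinates in um.
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces the population exactly.
#'
#' @param path file path.
#' @return `read_cells()` returns a cells data frame; `write_cells()` returns
#'   `path` invisibly.
#' @export
read_cells <- function(path) {
  cells <- read.csv(path, colClasses = c(id = "integer", x = "numeric",
                                         y = "numeric", r = "numeric",
                                         biomass = "numeric"))
  validate_cells(cells)
}

#' @param cells a cells data frame.
#' @rdname read_cells
#' @export
write_cells <- function(cells, path) {
  cells <- validate_cells(cells)
  out <- data.frame(id = cells$id,
                    x = sprintf("%.17g", cells$x),
                    y = sprintf("%.17g", cells$y),
                    r = sprintf("%.17g", cells$r),
                    biomass = sprintf("%.17g", cells$biomass))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a random circle packing with controlled overlap
#'
#' Draws radii uniformly from `radius_range`, places the cells by rejection
#' sampling into a disjoint packing, and, for a positive target, contracts
#' the configuration towards the domain center until the brute-force
#' overlap ratio (pairwise lens area over total cell area) matches
#' `target_overlap_ratio`.  The contraction factor is found by bisection,
#' so the measured ratio lands well within +/-20% of the target.
#'
#' @param n number of cells.
#' @param domain `c(width, height)` in um.
#' @param radius_range `c(min, max)` radius in um.
#' @param target_overlap_ratio desired overlap ratio (0 gives a packing
#'   verified disjoint).
#' @param seed optional RNG seed for reproducibility.
#' @return a cells data frame.
#' @export
generate_packing <- function(n, domain = c(100, 100), radius_range = c(1, 2),
                             target_overlap_ratio = 0, seed = NULL) {
  stopifnot(n >= 1, target_overlap_ratio >= 0)
  if (!is.null(seed)) set.seed(seed)
  r <- sort(runif(n, radius_range[1], radius_range[2]), decreasing = TRUE)
  if (sum(pi * r^2) > 0.9 * prod(domain))
    stop("infeasible density: total cell area exceeds 0.9 x domain area")
  # largest cells are placed first; small late cells fit remaining gaps
  x <- numeric(n); y <- numeric(n)
  max_tries <- 5000L
  for (k in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      cx <- runif(1, r[k], domain[1] - r[k])
      cy <- runif(1, r[k], domain[2] - r[k])
      if (k == 1 || all((x[seq_len(k - 1)] - cx)^2 + (y[seq_len(k - 1)] - cy)^2 >=
                        (r[seq_len(k - 1)] + r[k])^2)) {
        x[k] <- cx; y[k] <- cy; placed <- TRUE; break
      }
    }
    if (!placed) stop("could not place cell ", k, ": packing too dense")
  }
  cells <- make_cells(x, y, r)
  if (target_overlap_ratio > 0) {
    ctr <- domain / 2
    contract <- function(s) {
      out <- cells
      out$x <- ctr[1] + s * (cells$x - ctr[1])
      out$y <- ctr[2] + s * (cells$y - ctr[2])
      out
    }
    lo <- 0.02; hi <- 1
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      ratio <- overlap_ratio(contract(mid), method = "brute")
      if (abs(ratio - target_overlap_ratio) < 0.02 * target_overlap_ratio) break
      if (ratio > target_overlap_ratio) lo <- mid else hi <- mid
    }
    cells <- contract(mid)
  }
  cells
}
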