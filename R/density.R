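#' Density map container
#'
#' A scalar mass-density field on a regular cubic grid.
#'
#' @param origin numeric 3-vector: position of voxel (1,1,1), Angstrom.
#' @param spacing voxel edge length, Angstrom.
#' @param values 3-D numeric array.
#' @return An object of class \code{"density_map"}.
#' @export
density_map <- function(origin, spacing, values) {
  stopifnot(length(origin) == 3, spacing > 0, length(dim(values)) == 3)
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 values = values), class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat("density_map:", paste(dim(x$values), collapse = " x "),
      "voxels, spacing", x$spacing, "A, origin",
      paste(signif(x$origin, 4), collapse = " "), "\n")
  invisible(x)
}

#' Build a Gaussian-sum density map from atom positions
#'
#' Each atom contributes \eqn{C m_i \exp(-D \|y - x_i\|^2)} with
#' \eqn{D = 1/(2 s^2)}, \eqn{s = \mathrm{resolution}/2} and
#' \eqn{C = (2\pi s^2)^{-3/2}}, so every atom integrates to its mass and
#' the total grid mass equals the total selected mass (away from edges).
#' Gaussians are truncated at \eqn{3.5s}, which retains 99.3 percent of each
#' atom's mass.
#'
#' @param positions Nx3 coordinate matrix, Angstrom.
#' @param masses numeric vector of atom masses, amu.
#' @param resolution map resolution parameter in Angstrom (default 4); the
#'   Gaussian width is \code{resolution/2}.
#' @param margin grid margin beyond the position bounding box (default 5 A).
#' @param spacing voxel edge, Angstrom (default 1).
#' @param grid optional list with \code{origin} and \code{dims} to force a
#'   specific grid (used when averaging over frames).
#' @return A [density_map()].
#' @export
build_density_map <- function(positions, masses, resolution = 4,
                              margin = 5, spacing = 1, grid = NULL) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  if (nrow(positions) == 0) stop("cannot build a density map from 0 atoms")
  stopifnot(resolution > 0, length(masses) == nrow(positions))
  s <- resolution / 2
  coefC <- (2 * pi * s^2)^(-3 / 2)
  if (is.null(grid)) {
    lo <- apply(positions, 2, min) - margin
    hi <- apply(positions, 2, max) + margin
    origin <- floor(lo / spacing) * spacing
    dims <- pmax(2L, as.integer(ceiling((hi - origin) / spacing)) + 1L)
  } else {
    origin <- grid$origin
    dims <- as.integer(grid$dims)
  }
  vals <- .density_sum_cpp(positions, as.numeric(masses),
                           as.numeric(origin), spacing, dims, s, coefC, 3.5)
  density_map(origin, spacing, array(vals, dim = dims))
}

#' Smooth a density map with a Gaussian low-pass filter
#'
#' @param map a [density_map()].
#' @param filter_width Gaussian standard deviation in Angstrom
#'   (0 = identity).
#' @return The smoothed [density_map()].
#' @export
smooth_density <- function(map, filter_width = 4) {
  stopifnot(filter_width >= 0)
  if (filter_width == 0) return(map)
  d <- dim(map$values)
  vals <- .blur3_cpp(as.numeric(map$values), as.integer(d),
                     filter_width / map$spacing)
  density_map(map$origin, map$spacing, array(vals, dim = d))
}

#' Trilinear interpolation of a density map
#'
#' @param map a [density_map()].
#' @param points 3-vector or Nx3 matrix of evaluation points. Points outside
#'   the grid evaluate to 0.
#' @return Numeric vector of interpolated values.
#' @export
interpolate_density <- function(map, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  .trilinear_cpp(as.numeric(map$values), as.integer(dim(map$values)),
                 map$origin, map$spacing, points)
}

#' Total mass of a density map
#' @param map a [density_map()].
#' @return Sum of voxel values times voxel volume.
#' @export
density_total_mass <- function(map) {
  sum(map$values) * map$spacing^3
}

#' Time-averaged density of a selection over trajectory frames
#'
#' Builds one Gaussian-sum map per used frame on a common grid and averages
#' them. For long trajectories a frame subset (stride) gives an essentially
#' identical average at a fraction of the cost.
#'
#' @param traj a [trajectory()] (already aligned).
#' @param expr selection string for the atoms to map.
#' @param resolution,margin,spacing as in [build_density_map()].
#' @param frames integer vector of frame indices to use (default: all).
#' @param grid optional list with \code{origin} and \code{dims} forcing a
#'   common grid (e.g. shared between the water and lipid maps).
#' @return A [density_map()].
#' @export
average_density <- function(traj, expr, resolution = 4, margin = 5,
                            spacing = 1, frames = NULL, grid = NULL) {
  idx <- select_atoms(traj$system, expr)
  if (length(idx) == 0) stop("selection matched no atoms: ", expr)
  if (is.null(frames)) frames <- seq_along(traj$frames)
  masses <- traj$system$atoms$mass[idx]
  if (is.null(grid)) {
    grid <- density_grid(traj, idx, margin = margin, spacing = spacing,
                         frames = frames)
  }
  origin <- grid$origin
  dims <- as.integer(grid$dims)
  spacing <- if (!is.null(grid$spacing)) grid$spacing else spacing
  acc <- NULL
  for (i in frames) {
    m <- build_density_map(traj$frames[[i]][idx, , drop = FALSE], masses,
                           resolution = resolution, spacing = spacing,
                           grid = grid)
    acc <- if (is.null(acc)) m$values else acc + m$values
  }
  density_map(origin, spacing, acc / length(frames))
}

#' Grid specification covering a selection over frames
#'
#' @param traj a [trajectory()].
#' @param idx atom indices (or a selection string).
#' @param margin,spacing grid margin and voxel edge, Angstrom.
#' @param frames frames to cover (default all).
#' @return A list with \code{origin}, \code{dims} and \code{spacing}.
#' @export
density_grid <- function(traj, idx, margin = 5, spacing = 1, frames = NULL) {
  if (is.character(idx)) idx <- select_atoms(traj$system, idx)
  if (is.null(frames)) frames <- seq_along(traj$frames)
  lo <- c(Inf, Inf, Inf); hi <- -lo
  for (i in frames) {
    p <- traj$frames[[i]][idx, , drop = FALSE]
    lo <- pmin(lo, apply(p, 2, min))
    hi <- pmax(hi, apply(p, 2, max))
  }
  origin <- floor((lo - margin) / spacing) * spacing
  dims <- pmax(2L, as.integer(ceiling((hi + margin - origin) / spacing)) + 1L)
  list(origin = origin, dims = dims, spacing = spacing)
}
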