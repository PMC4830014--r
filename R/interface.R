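#' Interface surface container
#'
#' A point cloud on the density mesh where the water and lipid densities are
#' equal, optionally carrying per-point outward (solvent-side) unit normals.
#'
#' @param points Nx3 matrix of surface points, Angstrom.
#' @param normals optional Nx3 matrix of unit normals.
#' @return An object of class \code{"interface_surface"}.
#' @export
interface_surface <- function(points, normals = NULL) {
  stopifnot(is.matrix(points), ncol(points) == 3)
  if (!is.null(normals)) {
    stopifnot(nrow(normals) == nrow(points))
    if (any(abs(sqrt(rowSums(normals^2)) - 1) > 1e-9))
      stop("normals must be unit length")
  }
  structure(list(points = points, normals = normals),
            class = "interface_surface")
}

#' @export
print.interface_surface <- function(x, ...) {
  cat("interface_surface:", nrow(x$points), "points",
      if (!is.null(x$normals)) "(with normals)" else "(no normals)", "\n")
  invisible(x)
}

#' Extract the equal-density water-lipid interface
#'
#' Finds, by linear interpolation along the edges of the density grid, the
#' points where \eqn{\rho_W - \rho_L} changes sign. Grid cells where both
#' densities are below a noise floor (a fraction of the global density
#' maximum) are excluded, which suppresses spurious "interface" in vacuum
#' or empty-margin regions.
#'
#' @param water_map,lipid_map [density_map()] objects on the same grid
#'   (typically from [average_density()]).
#' @param noise_floor fraction of the global density maximum below which
#'   voxels are ignored (default 0.01).
#' @return An [interface_surface()] (points only; see [compute_normals()]).
#' @export
extract_interface <- function(water_map, lipid_map, noise_floor = 0.01) {
  if (!isTRUE(all.equal(water_map$origin, lipid_map$origin)) ||
      water_map$spacing != lipid_map$spacing ||
      !all(dim(water_map$values) == dim(lipid_map$values)))
    stop("water and lipid maps must share the same grid")
  w <- water_map$values
  l <- lipid_map$values
  d <- w - l
  floor_val <- noise_floor * max(max(w), max(l))
  ok <- pmax(w, l) >= floor_val
  dims <- dim(d)
  sp <- water_map$spacing
  org <- water_map$origin
  pts <- list()
  axis_step <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (ax in 1:3) {
    n <- dims[ax]
    if (n < 2) next
    idx1 <- slice.index(d, ax) < n
    lead <- function(a) {
      # a shifted by one voxel along `ax` (drop first slice)
      if (ax == 1) a[c(2:n, 1), , , drop = FALSE]
      else if (ax == 2) a[, c(2:n, 1), , drop = FALSE]
      else a[, , c(2:n, 1), drop = FALSE]
    }
    d2 <- lead(d)
    ok2 <- lead(ok)
    cross <- idx1 & ok & ok2 & (d * d2 < 0)
    if (!any(cross)) next
    ijk <- which(cross, arr.ind = TRUE)
    t_frac <- d[cross] / (d[cross] - d2[cross])
    base <- sweep((ijk - 1) * sp, 2, org, "+")
    step <- matrix(axis_step[[ax]], nrow(ijk), 3, byrow = TRUE)
    pts[[ax]] <- base + step * (t_frac * sp)
  }
  zero <- ok & (d == 0)
  if (any(zero)) {
    ijk <- which(zero, arr.ind = TRUE)
    pts[[4]] <- sweep((ijk - 1) * sp, 2, org, "+")
  }
  pts <- do.call(rbind, pts)
  if (is.null(pts) || nrow(pts) == 0)
    stop("no interface found: densities never cross")
  colnames(pts) <- c("x", "y", "z")
  interface_surface(pts)
}

#' Attach best-fit-plane normals to an interface surface
#'
#' For each surface point, fits a least-squares plane through all surface
#' points within \code{fit_radius} and takes its normal, with the sign
#' chosen so the normal points toward the solvent side (increasing
#' \eqn{\rho_W - \rho_L}). Points with fewer than 3 neighbours are dropped
#' with a warning.
#'
#' @param surface an [interface_surface()].
#' @param water_map,lipid_map the density maps used to extract the surface
#'   (for normal orientation).
#' @param fit_radius plane-fit neighbourhood radius, Angstrom (default 10).
#' @return The [interface_surface()] with normals (possibly fewer points).
#' @export
compute_normals <- function(surface, water_map, lipid_map, fit_radius = 10) {
  pts <- surface$points
  fit <- .plane_normals_cpp(pts, fit_radius)
  normals <- fit$normals
  bad <- is.na(normals[, 1])
  if (any(bad)) {
    warning(sum(bad), " surface points dropped (< 3 neighbours within ",
            fit_radius, " A)")
    pts <- pts[!bad, , drop = FALSE]
    normals <- normals[!bad, , drop = FALSE]
  }
  delta <- water_map$spacing
  d_plus <- interpolate_density(water_map, pts + delta * normals) -
    interpolate_density(lipid_map, pts + delta * normals)
  d_minus <- interpolate_density(water_map, pts - delta * normals) -
    interpolate_density(lipid_map, pts - delta * normals)
  flip <- (d_plus - d_minus) < 0
  normals[flip, ] <- -normals[flip, , drop = FALSE]
  normals <- normalize_rows(normals)
  interface_surface(pts, normals)
}

#' Nearest interface point
#'
#' Exact nearest-neighbour query (grid-accelerated); ties are broken by the
#' lowest point index, matching an exhaustive scan.
#'
#' @param surface a non-empty [interface_surface()].
#' @param positions 3-vector or Nx3 matrix of query positions.
#' @return Integer vector of surface point indices.
#' @export
nearest_surface_point <- function(surface, positions) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  .nearest_point_cpp(surface$points, positions, bin = 5.0)
}

#' Write an interface surface as PDB pseudo-atoms plus a normal table
#'
#' @param surface an [interface_surface()] with normals.
#' @param pdb_file path for the pseudo-atom PDB.
#' @param normals_file path for the companion normal table (point index,
#'   position, normal), or \code{NULL} to skip.
#' @return \code{pdb_file}, invisibly.
#' @export
write_interface <- function(surface, pdb_file, normals_file = NULL) {
  n <- nrow(surface$points)
  sys <- molecular_system(atom_name = rep("SUR", n),
                          res_name = rep("SUR", n),
                          res_number = seq_len(n),
                          chain = rep("S", n),
                          mass = rep(1, n))
  write_pdb_system(pdb_file, sys, surface$points)
  if (!is.null(normals_file) && !is.null(surface$normals)) {
    tab <- cbind(seq_len(n), surface$points, surface$normals)
    colnames(tab) <- c("point", "x", "y", "z", "nx", "ny", "nz")
    write.table(tab, normals_file, row.names = FALSE, quote = FALSE)
  }
  invisible(pdb_file)
}
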