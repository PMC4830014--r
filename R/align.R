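#' Density-overlap alignment score
#'
#' Sum of the (smoothed) reference solvent density interpolated at the water
#' positions minus the sum at the lipid positions. Rigid alignment of a
#' frame maximizes this score: it rewards placing the frame's solvent where
#' the reference solvent was, and penalizes placing lipids there.
#'
#' @param map reference solvent [density_map()] (typically smoothed).
#' @param water_positions,lipid_positions Nx3 coordinate matrices.
#' @return Scalar score.
#' @export
alignment_score <- function(map, water_positions, lipid_positions) {
  sum(interpolate_density(map, water_positions)) -
    sum(interpolate_density(map, lipid_positions))
}

params_to_transform <- function(par, pivot) {
  r <- euler_zyx(par[1], par[2], par[3])
  rigid_transform(r, pivot - drop(r %*% pivot) + par[4:6])
}

#' Rigidly align one frame to a reference solvent density
#'
#' Derivative-free local maximization of [alignment_score()] over 3 Euler
#' angles (intrinsic z-y-x, about the frame centroid) and 3 translations,
#' warm-started from \code{initial}. Deterministic given its inputs.
#'
#' @param map smoothed reference solvent [density_map()].
#' @param water_positions,lipid_positions frame coordinates of the solvent
#'   and lipid selections.
#' @param initial starting [rigid_transform()] (default identity; during
#'   trajectory alignment the previous frame's solution is used).
#' @param maxit maximum optimizer iterations per restart.
#' @return A \code{rigid_transform} with attributes \code{score} and
#'   \code{converged}. Non-convergence gives a warning and the best-found
#'   transform.
#' @export
align_frame <- function(map, water_positions, lipid_positions,
                        initial = NULL, maxit = 2000) {
  pivot <- colMeans(rbind(water_positions, lipid_positions))
  start <- c(0, 0, 0, 0, 0, 0)
  if (!is.null(initial)) {
    r <- initial$rotation
    # recover z-y-x Euler angles: R = Rz(a) Ry(b) Rx(g)
    b <- asin(max(-1, min(1, -r[3, 1])))
    a <- atan2(r[2, 1], r[1, 1])
    g <- atan2(r[3, 2], r[3, 3])
    t_pivot <- drop(initial$rotation %*% pivot) - pivot +
      initial$translation
    start <- c(a, b, g, t_pivot)
  }
  neg_score <- function(par) {
    tr <- params_to_transform(par, pivot)
    -(sum(interpolate_density(map, apply_transform(tr, water_positions))) -
        sum(interpolate_density(map, apply_transform(tr, lipid_positions))))
  }
  # two deterministic starts (warm start and identity) guard against the
  # optimizer drifting along quasi-symmetric directions, e.g. rotations
  # about the axis of a cylindrical assembly
  starts <- unique(list(start, rep(0, 6)))
  opt <- NULL
  for (s0 in starts) {
    o <- optim(s0, neg_score, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-9))
    if (is.null(opt) || o$value < opt$value) opt <- o
  }
  # restarts from the winning optimum re-inflate the simplex; iterate until
  # the score stops improving, which walks out of near-degenerate valleys
  # (e.g. rotations about a cylinder axis) where a single run stalls
  for (k in 1:5) {
    opt2 <- optim(opt$par, neg_score, method = "Nelder-Mead",
                  control = list(maxit = maxit, reltol = 1e-11))
    improved <- opt$value - opt2$value
    if (opt2$value < opt$value) opt <- opt2
    if (improved < 1e-9 * (abs(opt$value) + 1)) break
  }
  converged <- opt$convergence == 0
  if (!converged)
    warning("frame alignment did not fully converge; returning best found")
  out <- params_to_transform(opt$par, pivot)
  attr(out, "score") <- -opt$value
  attr(out, "converged") <- converged
  out
}

#' Align every frame of a trajectory on its first frame
#'
#' Builds the solvent density map from frame 1, smooths it, and aligns each
#' frame by maximizing solvent-minus-lipid density overlap, warm-starting
#' each frame from the previous frame's transform. This is the general
#' (curved-geometry) alignment route; planar bilayers are better served by
#' the centre-of-mass route ([analyze_com_positions()] +
#' [translate_frames()]).
#'
#' @param traj a [trajectory()] with at least 1 frame.
#' @param water_expr selection string for the solvent used to build the
#'   reference density (typically all solvent copies of the extended
#'   system).
#' @param lipid_expr selection string for the lipids whose overlap is
#'   penalized.
#' @param align_water_expr selection whose overlap is maximized (default:
#'   \code{water_expr}).
#' @param resolution density resolution (A), see [build_density_map()].
#' @param filter_width low-pass Gaussian width (A), see [smooth_density()].
#' @param spacing voxel edge of the reference map (A). The default 0.5 is
#'   finer than the analysis default: the precision of the recovered
#'   transforms is limited by the trilinear discretization of the map.
#' @param outdir optional output directory: reference density (MRC), aligned
#'   trajectory (PDB + DCD) and transform table are written there.
#' @return A list with \code{trajectory} (aligned) and \code{transforms}
#'   (list of [rigid_transform()], one per frame; frame 1 is the identity).
#' @export
align_trajectory_on_first_frame <- function(traj, water_expr, lipid_expr,
                                            align_water_expr = water_expr,
                                            resolution = 4,
                                            filter_width = 4,
                                            spacing = 0.5,
                                            outdir = NULL) {
  widx <- select_atoms(traj$system, water_expr)
  if (length(widx) == 0) stop("empty water selection")
  lidx <- select_atoms(traj$system, lipid_expr)
  aidx <- if (identical(align_water_expr, water_expr)) widx
          else select_atoms(traj$system, align_water_expr)
  masses <- traj$system$atoms$mass[widx]
  ref <- build_density_map(traj$frames[[1]][widx, , drop = FALSE], masses,
                           resolution = resolution, spacing = spacing)
  ref <- smooth_density(ref, filter_width)
  nf <- length(traj$frames)
  transforms <- vector("list", nf)
  transforms[[1]] <- rigid_transform()
  new_frames <- traj$frames
  prev <- rigid_transform()
  if (nf > 1) for (i in 2:nf) {
    f <- traj$frames[[i]]
    tr <- align_frame(ref, f[aidx, , drop = FALSE],
                      f[lidx, , drop = FALSE], initial = prev)
    transforms[[i]] <- tr
    new_frames[[i]] <- apply_transform(tr, f)
    prev <- tr
  }
  aligned <- trajectory(traj$system, new_frames, traj$cell)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_mrc(ref, file.path(outdir, "reference_solvent_density.mrc"))
    write_pdb_system(file.path(outdir, "aligned.pdb"), aligned$system,
                     aligned$frames[[1]])
    write_dcd(file.path(outdir, "aligned.dcd"), aligned)
    write_transforms(file.path(outdir, "transforms.txt"), transforms)
  }
  list(trajectory = aligned, transforms = transforms)
}

#' Write rigid transforms as a plain-text table
#'
#' One row per frame: frame index, the 9 rotation-matrix entries in
#' row-major order, and the 3 translation components.
#'
#' @param file output path.
#' @param transforms list of [rigid_transform()].
#' @return The file path, invisibly.
#' @export
write_transforms <- function(file, transforms) {
  rows <- t(vapply(seq_along(transforms), function(i) {
    tr <- transforms[[i]]
    c(i, as.numeric(t(tr$rotation)), tr$translation)
  }, numeric(13)))
  colnames(rows) <- c("frame", paste0("r", rep(1:3, each = 3), rep(1:3, 3)),
                      c("tx", "ty", "tz"))
  write.table(rows, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a transform table written by [write_transforms()]
#' @param file path to the table.
#' @return List of [rigid_transform()].
#' @export
read_transforms <- function(file) {
  tab <- read.table(file, header = TRUE)
  lapply(seq_len(nrow(tab)), function(i) {
    r <- matrix(as.numeric(tab[i, 2:10]), 3, 3, byrow = TRUE)
    rigid_transform(r, as.numeric(tab[i, 11:13]))
  })
}
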