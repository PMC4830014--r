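#' Extend a trajectory to neighbouring unit cells
#'
#' Replicates the whole system once per lattice shift, so that downstream
#' analysis (interface extraction, splay pairs) never needs to treat
#' periodic boundaries explicitly. Replicated chains are renamed with an
#' integer suffix (\code{M} becomes \code{M1}, \code{M2}, ...; if a name is
#' already taken the next free integer is used) and all tilt/splay flags on
#' replicas are \code{FALSE}.
#'
#' @param traj a [trajectory()].
#' @param shifts list (or 3-column matrix) of integer triplets; each triplet
#'   \code{(i,j,k)} adds a replica translated by \code{i a + j b + k c}.
#'   \code{(0,0,0)} is the original cell and must not appear.
#' @param multipliers integer triplet; the extended cell vectors are the
#'   input vectors scaled by these factors.
#' @return The extended [trajectory()].
#' @export
extend_trajectory <- function(traj, shifts, multipliers = c(1, 1, 1)) {
  if (is.matrix(shifts))
    shifts <- lapply(seq_len(nrow(shifts)), function(i) shifts[i, ])
  stopifnot(all(multipliers >= 1), length(multipliers) == 3)
  for (s in shifts) {
    stopifnot(length(s) == 3)
    if (all(s == 0))
      stop("shift (0,0,0) would duplicate the original cell")
  }
  sys <- traj$system
  if (length(shifts) == 0) return(traj)

  taken <- unique(sys$residues$chain)
  res_blocks <- list(sys$residues)
  atom_blocks <- list(sys$atoms)
  n_res <- nrow(sys$residues)
  for (k in seq_along(shifts)) {
    res_k <- sys$residues
    orig_chains <- unique(res_k$chain)
    new_names <- character(length(orig_chains))
    for (ci in seq_along(orig_chains)) {
      suf <- k
      repeat {
        cand <- paste0(orig_chains[ci], suf)
        if (!cand %in% taken) break
        suf <- suf + 1
      }
      new_names[ci] <- cand
      taken <- c(taken, cand)
    }
    res_k$chain <- new_names[match(res_k$chain, orig_chains)]
    res_k$do_tilt <- FALSE
    res_k$do_splay <- FALSE
    res_blocks[[k + 1]] <- res_k
    at_k <- sys$atoms
    at_k$res <- at_k$res + k * n_res
    atom_blocks[[k + 1]] <- at_k
  }
  new_sys <- structure(list(atoms = do.call(rbind, atom_blocks),
                            residues = do.call(rbind, res_blocks)),
                       class = "molecular_system")
  rownames(new_sys$atoms) <- NULL
  rownames(new_sys$residues) <- NULL

  offsets <- t(vapply(shifts, function(s) drop(s %*% traj$cell),
                      numeric(3)))
  new_frames <- lapply(traj$frames, function(f) {
    blocks <- vector("list", length(shifts) + 1)
    blocks[[1]] <- f
    for (k in seq_along(shifts))
      blocks[[k + 1]] <- sweep(f, 2, offsets[k, ], "+")
    do.call(rbind, blocks)
  })
  trajectory(new_sys, new_frames, traj$cell * multipliers)
}

#' Wrap trajectory frames around per-frame centers
#'
#' Puts every atom (or every residue centre of mass, when
#' \code{group_by_residue}) inside the unit cell centered on the frame's
#' center, working in fractional coordinates so triclinic cells are handled.
#' With \code{group_by_residue} all atoms of a residue receive the same
#' lattice shift, keeping residues whole.
#'
#' @param traj a [trajectory()].
#' @param centers numeric 3-vector, or a matrix with one row per frame.
#' @param group_by_residue keep residues whole (default \code{TRUE}).
#' @return The wrapped [trajectory()].
#' @export
wrap_trajectory <- function(traj, centers, group_by_residue = TRUE) {
  nf <- length(traj$frames)
  if (is.null(dim(centers)))
    centers <- matrix(centers, nf, 3, byrow = TRUE)
  stopifnot(nrow(centers) == nf)
  inv <- tryCatch(solve(traj$cell),
                  error = function(e) stop("unit cell is not invertible"))
  res <- traj$system$atoms$res
  w <- traj$system$atoms$mass
  new_frames <- vector("list", nf)
  for (i in seq_len(nf)) {
    f <- traj$frames[[i]]
    frac <- sweep(f, 2, centers[i, ], "-") %*% inv
    if (group_by_residue) {
      mfrac <- rowsum(frac * w, res) / rowsum(matrix(w, ncol = 1), res)[, 1]
      shift <- floor(mfrac + 0.5)
      frac <- frac - shift[res, , drop = FALSE]
    } else {
      frac <- frac - floor(frac + 0.5)
    }
    new_frames[[i]] <- sweep(frac %*% traj$cell, 2, centers[i, ], "+")
  }
  trajectory(traj$system, new_frames, traj$cell)
}

#' Translate trajectory frames
#'
#' @param traj a [trajectory()].
#' @param offsets numeric 3-vector, or a matrix with one row per frame.
#'   Typical use: minus the per-frame membrane centre of mass, putting it at
#'   the origin (the fast alignment route for planar bilayers).
#' @return The translated [trajectory()].
#' @export
translate_frames <- function(traj, offsets) {
  nf <- length(traj$frames)
  if (is.null(dim(offsets)))
    offsets <- matrix(offsets, nf, 3, byrow = TRUE)
  stopifnot(nrow(offsets) == nf)
  new_frames <- lapply(seq_len(nf), function(i)
    sweep(traj$frames[[i]], 2, offsets[i, ], "+"))
  trajectory(traj$system, new_frames, traj$cell)
}

#' Per-frame centre of mass of a selection
#'
#' @param traj a [trajectory()].
#' @param expr selection string (see [select_atoms()]).
#' @return Matrix with one row per frame.
#' @export
analyze_com_positions <- function(traj, expr) {
  idx <- select_atoms(traj$system, expr)
  if (length(idx) == 0) stop("selection matched no atoms")
  t(vapply(traj$frames,
           function(f) center_of_mass(traj$system, idx, f), numeric(3)))
}
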