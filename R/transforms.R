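#' Rigid transform (rotation + translation)
#'
#' A proper rigid transform in 3-D: \code{y = R x + t} with \code{R} a
#' right-handed orthonormal matrix.
#'
#' @param rotation 3x3 rotation matrix (orthonormal, determinant +1).
#' @param translation numeric 3-vector, Angstrom.
#' @return An object of class \code{"rigid_transform"}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation matrix is not orthonormal")
  if (det(rotation) < 0)
    stop("rotation matrix is improper (determinant -1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Rotation matrix from intrinsic z-y-x Euler angles
#'
#' \code{R = Rz(alpha) Ry(beta) Rx(gamma)}, angles in radians. This is the
#' parameterization used by the density-based aligner and in transform files.
#'
#' @param alpha,beta,gamma Euler angles in radians.
#' @return 3x3 rotation matrix.
#' @export
euler_zyx <- function(alpha, beta, gamma) {
  ca <- cos(alpha); sa <- sin(alpha)
  cb <- cos(beta);  sb <- sin(beta)
  cg <- cos(gamma); sg <- sin(gamma)
  rz <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
  ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  rx <- matrix(c(1, 0, 0, 0, cg, sg, 0, -sg, cg), 3, 3)
  rz %*% ry %*% rx
}

#' Apply a rigid transform to coordinates
#'
#' @param tr A \code{rigid_transform}.
#' @param x Nx3 coordinate matrix (or a 3-vector).
#' @return Transformed coordinates, same shape as the input.
#' @export
apply_transform <- function(tr, x) {
  if (is.null(dim(x))) {
    drop(tr$rotation %*% x) + tr$translation
  } else {
    sweep(x %*% t(tr$rotation), 2, tr$translation, "+")
  }
}

#' Invert a rigid transform
#' @param tr A \code{rigid_transform}.
#' @return The inverse \code{rigid_transform}.
#' @export
invert_transform <- function(tr) {
  rt <- t(tr$rotation)
  rigid_transform(rt, -drop(rt %*% tr$translation))
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying \code{first}, then
#' \code{second}.
#' @param second,first \code{rigid_transform} objects.
#' @return A \code{rigid_transform}.
#' @export
compose_transforms <- function(second, first) {
  rigid_transform(second$rotation %*% first$rotation,
                  drop(second$rotation %*% first$translation) +
                    second$translation)
}

#' Rotation angle of a rotation matrix
#'
#' The geodesic angle (radians) of a rotation, used to measure how far two
#' recovered alignments differ.
#' @param r 3x3 rotation matrix.
#' @return Angle in radians in \code{[0, pi]}.
#' @export
rotation_angle <- function(r) {
  acos(max(-1, min(1, (sum(diag(r)) - 1) / 2)))
}

normalize_rows <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  x / nrm
}
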