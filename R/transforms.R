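#' Similarity transform (scale, rotation, translation)
#'
#' Maps a point `x` (mm) to `scale * rotation %*% x + translation`. Used for
#' phantom poses and Procrustes alignment maps.
#'
#' @param scale positive scalar.
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation numeric length-3 vector (mm).
#' @return An object of class `similarity_transform`.
#' @export
similarity_transform <- function(scale = 1, rotation = diag(3),
                                 translation = c(0, 0, 0)) {
  scale <- as.numeric(scale)
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("`scale` must be a positive scalar")
  check_rotation(rotation)
  if (length(translation) != 3L || any(!is.finite(translation)))
    stop("`translation` must be 3 finite values")
  structure(list(scale = scale, rotation = rotation,
                 translation = translation),
            class = "similarity_transform")
}

#' Rigid transform (rotation + translation)
#'
#' The 3D rigid-body model used for registration: a point `x` maps to
#' `A %*% x + b` with `A` a proper rotation (orthonormal, det +1) and `b` a
#' translation in mm.
#'
#' @param A 3x3 rotation matrix.
#' @param b numeric length-3 translation (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(A = diag(3), b = c(0, 0, 0)) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  check_rotation(A)
  if (length(b) != 3L || any(!is.finite(b)))
    stop("`b` must be 3 finite values")
  structure(list(A = A, b = b), class = "rigid_transform")
}

check_rotation <- function(A, tol = 1e-10) {
  if (!is.matrix(A) || any(dim(A) != c(3L, 3L)) || any(!is.finite(A)))
    stop("rotation must be a finite 3x3 matrix")
  if (max(abs(crossprod(A) - diag(3))) > tol)
    stop("rotation matrix is not orthonormal (A^T A != I)")
  if (abs(det(A) - 1) > tol)
    stop("rotation matrix must have determinant +1 (no reflection)")
  invisible(TRUE)
}

#' Apply a rigid transform to a set of points
#'
#' @param t a [rigid_transform()].
#' @param coords n x 3 matrix of mm coordinates (a length-3 vector is
#'   treated as one point).
#' @return n x 3 matrix of transformed coordinates.
#' @export
apply_rigid <- function(t, coords) {
  stopifnot(inherits(t, "rigid_transform"))
  coords <- as_points(coords)
  sweep(coords %*% t(t$A), 2, t$b, "+")
}

#' Apply a similarity transform to a set of points
#'
#' @param t a [similarity_transform()].
#' @param coords n x 3 matrix of mm coordinates.
#' @return n x 3 matrix of transformed coordinates.
#' @export
apply_similarity <- function(t, coords) {
  stopifnot(inherits(t, "similarity_transform"))
  coords <- as_points(coords)
  sweep(t$scale * (coords %*% t(t$rotation)), 2, t$translation, "+")
}

#' Invert a rigid or similarity transform
#'
#' @param t transform to invert.
#' @return A transform of the same class such that composing the two is the
#'   identity.
#' @export
invert_transform <- function(t) {
  if (inherits(t, "rigid_transform")) {
    rigid_transform(t(t$A), -t(t$A) %*% t$b)
  } else if (inherits(t, "similarity_transform")) {
    Ri <- t(t$rotation)
    similarity_transform(1 / t$scale, Ri,
                         -(Ri %*% t$translation) / t$scale)
  } else stop("not a transform")
}

#' Rotation matrix from intrinsic z-y-x Euler angles
#'
#' `R = Rz(rz) %*% Ry(ry) %*% Rx(rx)`; angles in radians.
#'
#' @param rx,ry,rz rotation angles about x, y, z (radians).
#' @return 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(rx, ry, rz) {
  cx <- cos(rx); sx <- sin(rx)
  cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Rotation angle between two rotation matrices
#'
#' The geodesic angle (radians) of `A %*% t(B)`; with `B` omitted, the
#' rotation angle of `A` itself.
#'
#' @param A,B 3x3 rotation matrices.
#' @return angle in radians, in `[0, pi]`.
#' @export
rotation_angle <- function(A, B = diag(3)) {
  R <- A %*% t(B)
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

as_points <- function(coords) {
  if (is.null(dim(coords))) {
    if (length(coords) != 3L) stop("points must be n x 3")
    coords <- matrix(coords, 1L, 3L)
  }
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("points must be n x 3")
  storage.mode(coords) <- "double"
  coords
}
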