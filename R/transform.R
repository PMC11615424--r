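#' Rigid transform
#'
#' A proper rigid-body transform: an orthonormal rotation matrix with
#' determinant +1 plus a translation vector, both in millimetres. Points map
#' as \code{R \%*\% p + t}.
#'
#' @param rotation 3x3 orthonormal matrix, det +1.
#' @param translation numeric length-3 translation (mm).
#' @param tol validation tolerance on orthonormality and determinant.
#' @return An object of class \code{rigid_transform} with elements
#'   \code{rotation} and \code{translation}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            tol = 1e-9) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3L)
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stop("rigid_transform: non-finite entries")
  if (max(abs(crossprod(rotation) - diag(3))) > tol)
    stop("rigid_transform: rotation is not orthonormal within tolerance")
  if (abs(det(rotation) - 1) > tol)
    stop("rigid_transform: rotation determinant is not +1 (reflection?)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Identity rigid transform
#' @return The identity \code{rigid_transform}.
#' @export
identity_transform <- function() rigid_transform()

#' Rotation about a coordinate axis
#'
#' @param axis one of "x", "y", "z".
#' @param angle_deg rotation angle in degrees (right-handed).
#' @return 3x3 rotation matrix.
#' @export
axis_rotation <- function(axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
}

#' Rotation about an arbitrary unit axis (Rodrigues)
#' @param axis length-3 direction (normalized internally).
#' @param angle_deg angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Compose two rigid transforms
#'
#' \code{compose_rigid(a, b)} is the transform applying \code{b} first and
#' then \code{a} (matrix convention: \code{a \%after\% b}).
#'
#' @param a,b \code{rigid_transform} objects.
#' @return The composed \code{rigid_transform}.
#' @export
compose_rigid <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation,
                  tol = 1e-6)
}

#' Invert a rigid transform
#' @param tr a \code{rigid_transform}.
#' @return The inverse \code{rigid_transform}.
#' @export
invert_rigid <- function(tr) {
  stopifnot(inherits(tr, "rigid_transform"))
  rt <- t(tr$rotation)
  rigid_transform(rt, -as.numeric(rt %*% tr$translation), tol = 1e-6)
}

#' Apply a rigid transform to points, a mesh or landmarks
#'
#' Every point p maps to \code{R p + t}; pairwise distances are preserved.
#'
#' @param x an N x 3 point matrix, a \code{triangle_mesh}, or a
#'   \code{landmark_set}.
#' @param tr a \code{rigid_transform}.
#' @return Object of the same kind as \code{x}, transformed.
#' @export
apply_rigid <- function(x, tr) {
  stopifnot(inherits(tr, "rigid_transform"))
  if (inherits(x, "triangle_mesh")) {
    x$vertices <- apply_rigid(x$vertices, tr)
    return(x)
  }
  if (inherits(x, "landmark_set")) {
    for (nm in names(x)) x[[nm]] <- as.numeric(tr$rotation %*% x[[nm]] +
                                               tr$translation)
    return(x)
  }
  p <- as.matrix(x)
  if (ncol(p) != 3) stop("apply_rigid: points must be N x 3")
  if (!all(is.finite(p))) stop("apply_rigid: non-finite points")
  out <- p %*% t(tr$rotation)
  out <- sweep(out, 2, tr$translation, "+")
  dimnames(out) <- dimnames(p)
  if (inherits(x, "corresponded_shape")) class(out) <-
      c("corresponded_shape", class(out))
  out
}

#' Serialize a rigid transform to a 4x4 homogeneous matrix JSON file
#' @param tr a \code{rigid_transform}.
#' @param path output JSON path.
#' @export
write_transform_json <- function(tr, path) {
  stopifnot(inherits(tr, "rigid_transform"))
  m <- rbind(cbind(tr$rotation, tr$translation), c(0, 0, 0, 1))
  jsonlite::write_json(list(matrix = m), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a rigid transform from a 4x4 homogeneous matrix JSON file
#' @param path JSON path written by \code{\link{write_transform_json}}.
#' @return A \code{rigid_transform}.
#' @export
read_transform_json <- function(path) {
  m <- jsonlite::fromJSON(path)$matrix
  rigid_transform(m[1:3, 1:3], m[1:3, 4], tol = 1e-6)
}
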