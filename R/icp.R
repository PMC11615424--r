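#' Least-squares rigid fit between paired point sets (Kabsch)
#'
#' The rotation and translation minimizing the sum of squared distances
#' between \code{R p_i + t} and \code{q_i}, via SVD of the cross-covariance
#' with a determinant correction so the result is a proper rotation.
#'
#' @param p,q N x 3 paired point matrices (N >= 3, non-collinear).
#' @return A \code{rigid_transform} mapping \code{p} onto \code{q}.
#' @export
kabsch_fit <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  stopifnot(ncol(p) == 3, ncol(q) == 3, nrow(p) == nrow(q), nrow(p) >= 3)
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  sv <- svd(crossprod(pc, qc))  # H = P^T Q
  s <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  r <- sv$v %*% s %*% t(sv$u)
  rigid_transform(r, cq - as.numeric(r %*% cp), tol = 1e-6)
}

# second singular value of the centered point set; ~0 means collinear
point_spread_rank2 <- function(p) {
  pc <- sweep(as.matrix(p), 2, colMeans(p))
  svd(pc, nu = 0, nv = 0)$d[2]
}

#' Rigid iterative-closest-point registration of points onto a mesh
#'
#' Alternates nearest-point correspondence (point-to-nearest-triangle) with
#' a least-squares rigid Kabsch fit, from an initial transform, until the
#' change in mean correspondence distance drops below \code{tol} or
#' \code{max_iter} is reached.
#'
#' @param source N x 3 point matrix (>= 3 non-collinear points).
#' @param target a \code{triangle_mesh}.
#' @param init initial \code{rigid_transform} (default identity).
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the change of mean distance (mm).
#' @param k_candidates see \code{\link{closest_points}}.
#' @return list with \code{transform} (a \code{rigid_transform} mapping
#'   source into target coordinates), \code{mean_distance} (final mean
#'   correspondence distance, mm), \code{history} (per-iteration mean
#'   distances), \code{iterations}, \code{converged}.
#' @export
icp_rigid <- function(source, target, init = identity_transform(),
                      max_iter = 50L, tol = 1e-3, k_candidates = 32L) {
  p <- as.matrix(source)
  stopifnot(ncol(p) == 3, inherits(target, "triangle_mesh"))
  if (nrow(p) < 3 || point_spread_rank2(p) < 1e-9 * max(1, max(abs(p))))
    stop("icp_rigid: source points are degenerate (collinear or < 3 points)")
  stopifnot(inherits(init, "rigid_transform"))

  tr <- init
  history <- numeric(0)
  prev <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    moved <- apply_rigid(p, tr)
    cp <- closest_points(moved, target, k_candidates)
    history <- c(history, mean(cp$distance))
    step <- kabsch_fit(moved, cp$points)
    tr <- compose_rigid(step, tr)
    if (abs(prev - history[it]) < tol) { converged <- TRUE; break }
    prev <- history[it]
  }
  list(transform = tr, mean_distance = history[length(history)],
       history = history, iterations = it, converged = converged)
}
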