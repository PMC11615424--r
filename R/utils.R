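#' @useDynLib canalssm, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif setNames
NULL

# Flatten an N x 3 shape into the (x0, y0, z0, x1, ...) vector convention
# used throughout the point-distribution model, and back.
flatten_shape <- function(m) as.vector(t(as.matrix(m)))

unflatten_shape <- function(v) {
  m <- matrix(v, ncol = 3, byrow = TRUE)
  class(m) <- c("corresponded_shape", class(m))
  m
}

#' Mark a point matrix as a corresponded shape
#'
#' A corresponded shape is a fixed-length ordered 3D point set whose row
#' indices are matched across a population (one row of the point
#' distribution model).
#'
#' @param points N x 3 numeric matrix (mm), finite.
#' @return The matrix with class \code{corresponded_shape}.
#' @export
corresponded_shape <- function(points) {
  m <- as.matrix(points)
  storage.mode(m) <- "double"
  if (ncol(m) != 3 || !all(is.finite(m)))
    stop("corresponded_shape: points must be a finite N x 3 matrix")
  if (!inherits(m, "corresponded_shape"))
    class(m) <- c("corresponded_shape", class(m))
  m
}

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Area-weighted outward vertex normals of a mesh.
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  vn <- matrix(0, nrow(v), 3)
  for (j in 1:3) {
    for (c_ in 1:3) {
      acc <- tapply(fn[, c_], f[, j], sum)
      vn[as.integer(names(acc)), c_] <- vn[as.integer(names(acc)), c_] + acc
    }
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}
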