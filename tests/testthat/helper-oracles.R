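# Independent oracles used to cross-check the package's geometry and PCA
# paths. These deliberately use different algorithms from the implementation.

# Exact point-to-triangle distance via candidate enumeration: the closest
# point is the in-plane projection (if its barycentrics are admissible),
# a clamped projection onto one of the three edges, or a vertex.
oracle_point_triangle <- function(p, v0, v1, v2) {
  cand <- list(v0, v1, v2)
  e0 <- v1 - v0
  e1 <- v2 - v0
  g <- matrix(c(sum(e0 * e0), sum(e0 * e1), sum(e0 * e1), sum(e1 * e1)), 2, 2)
  rhs <- c(sum(e0 * (p - v0)), sum(e1 * (p - v0)))
  if (abs(det(g)) > 1e-300) {
    st <- solve(g, rhs)
    if (st[1] >= 0 && st[2] >= 0 && sum(st) <= 1)
      cand <- c(cand, list(v0 + st[1] * e0 + st[2] * e1))
  }
  edge_pt <- function(a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab * ab)
    a + min(max(t, 0), 1) * ab
  }
  cand <- c(cand, list(edge_pt(v0, v1), edge_pt(v1, v2), edge_pt(v2, v0)))
  sqrt(min(vapply(cand, function(q) sum((p - q)^2), 0)))
}

# Exhaustive nearest-triangle distance from each point to a whole mesh.
oracle_mesh_distance <- function(points, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  apply(points, 1, function(p) {
    min(vapply(seq_len(nrow(f)), function(i)
      oracle_point_triangle(p, v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ]), 0))
  })
}

# Symmetric vertex-based RMSE via the exhaustive search above.
oracle_surface_rmse <- function(a, b) {
  d_ab <- oracle_mesh_distance(a$vertices, b)
  d_ba <- oracle_mesh_distance(b$vertices, a)
  sqrt(mean(c(d_ab^2, d_ba^2)))
}

# Horn's closed-form absolute orientation (unit quaternion from the largest
# eigenvector of the 4x4 cross-covariance form) — independent of the
# SVD/Kabsch path.
oracle_rigid_fit <- function(p, q) {
  cp <- colMeans(p)
  cq <- colMeans(q)
  s <- crossprod(sweep(p, 2, cp), sweep(q, 2, cq))
  n4 <- rbind(
    c(s[1,1]+s[2,2]+s[3,3], s[2,3]-s[3,2],        s[3,1]-s[1,3],        s[1,2]-s[2,1]),
    c(s[2,3]-s[3,2],        s[1,1]-s[2,2]-s[3,3], s[1,2]+s[2,1],        s[3,1]+s[1,3]),
    c(s[3,1]-s[1,3],        s[1,2]+s[2,1],        s[2,2]-s[1,1]-s[3,3], s[2,3]+s[3,2]),
    c(s[1,2]-s[2,1],        s[3,1]+s[1,3],        s[2,3]+s[3,2],        s[3,3]-s[1,1]-s[2,2]))
  qv <- eigen(n4, symmetric = TRUE)$vectors[, 1]
  w <- qv[1]; x <- qv[2]; y <- qv[3]; z <- qv[4]
  r <- rbind(
    c(w*w+x*x-y*y-z*z, 2*(x*y-w*z),     2*(x*z+w*y)),
    c(2*(x*y+w*z),     w*w-x*x+y*y-z*z, 2*(y*z-w*x)),
    c(2*(x*z-w*y),     2*(y*z+w*x),     w*w-x*x-y*y+z*z))
  list(rotation = r, translation = cq - as.numeric(r %*% cp))
}

# Brute-force PCA: explicitly form the (3N x 3N) sample covariance and
# eigendecompose it.
oracle_pca <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  ed <- eigen(crossprod(xc) / (nrow(x) - 1), symmetric = TRUE)
  list(eigenvalues = pmax(ed$values, 0), vectors = ed$vectors)
}

# angle (deg) between two rotation matrices
rotation_angle_deg <- function(r1, r2) {
  tr <- sum(diag(crossprod(r1, r2)))
  acos(min(1, max(-1, (tr - 1) / 2))) * 180 / pi
}

# flatten helper mirroring the package's layout convention
flat <- function(m) as.vector(t(as.matrix(m)))

# small deterministic test population (vector fidelity, default spectrum)
make_vector_population <- function(n = 64, seed = 1,
                                   variances = NULL, residual = NULL) {
  tpl <- canal_template()
  basis <- canal_mode_basis(tpl)
  cfg <- if (is.null(variances))
    population_config(n_samples = n, fidelity = "vector", seed = seed)
  else
    population_config(n_samples = n, mode_variances = variances,
                      residual_variance_total = residual,
                      fidelity = "vector", seed = seed)
  list(template = tpl, basis = basis,
       samples = sample_population(tpl, basis, cfg))
}
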