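#' Closest points on a mesh surface
#'
#' For each query point, the nearest point on the triangulated surface
#' (point-to-nearest-triangle, not nearest-vertex), its distance and the
#' face it lies on. Queries are pruned through the \code{k_candidates}
#' nearest face centroids; \code{k_candidates = 0} forces the exhaustive
#' search over every face (used by the test oracles). Meshes below 2048
#' faces are always searched exhaustively.
#'
#' @param points N x 3 query points.
#' @param mesh a \code{triangle_mesh}.
#' @param k_candidates centroid-pruning width (default 32; 0 = exhaustive).
#' @return list with \code{points} (N x 3 closest surface points),
#'   \code{distance} (N), \code{face} (N, 1-based face index).
#' @export
closest_points <- function(points, mesh, k_candidates = 32L) {
  stopifnot(inherits(mesh, "triangle_mesh"), nrow(mesh$faces) > 0)
  p <- as.matrix(points)
  storage.mode(p) <- "double"
  if (ncol(p) != 3) stop("closest_points: points must be N x 3")
  k <- as.integer(k_candidates)
  if (nrow(mesh$faces) < 2048L) k <- 0L
  cpp_closest_points(p, mesh$vertices, mesh$faces - 1L, k)
}

#' Symmetric surface RMSE between two meshes
#'
#' Root-mean-square of point-to-nearest-triangle distances, sampled on both
#' surfaces and pooled symmetrically. Zero iff the surfaces coincide at the
#' sampled resolution.
#'
#' @param a,b \code{triangle_mesh} objects (non-empty).
#' @param samples points sampled per surface (deterministic area-weighted
#'   sampling); \code{NULL} uses the mesh vertices directly.
#' @param k_candidates see \code{\link{closest_points}}.
#' @return RMSE in mm.
#' @export
surface_rmse <- function(a, b, samples = 2000L, k_candidates = 32L) {
  stopifnot(inherits(a, "triangle_mesh"), inherits(b, "triangle_mesh"))
  if (nrow(a$faces) == 0 || nrow(b$faces) == 0)
    stop("surface_rmse: empty mesh")
  if (!is.null(samples) && samples <= 0) stop("surface_rmse: samples must be > 0")
  pa <- if (is.null(samples)) a$vertices else sample_mesh_points(a, samples)
  pb <- if (is.null(samples)) b$vertices else sample_mesh_points(b, samples)
  d_ab <- closest_points(pa, b, k_candidates)$distance
  d_ba <- closest_points(pb, a, k_candidates)$distance
  sqrt(mean(c(d_ab^2, d_ba^2)))
}

# Shared voxel grid (origin + dims) covering one or two meshes with a
# one-voxel margin; voxel centers sit at half-spacing offsets from the
# minimum vertex coordinate (deterministic tie-breaking on lattice geometry).
voxel_grid_for <- function(spacing, vmin, vmax) {
  origin <- vmin - spacing
  dims <- pmax(1L, as.integer(ceiling((vmax + spacing - origin) / spacing)))
  list(origin = origin, dims = dims)
}

#' Voxelize a closed mesh into an occupancy image
#'
#' Marks voxel centers strictly inside the surface using axis-aligned
#' ray-casting parity along +z. The grid covers the mesh bounds plus a
#' one-voxel margin; centers are offset half a spacing from the minimum
#' vertex coordinate so lattice-aligned geometry cannot produce ties.
#'
#' @param mesh a closed \code{triangle_mesh}.
#' @param spacing voxel edge length (mm), scalar.
#' @param grid optional list(origin, dims) to force a shared grid.
#' @return A \code{voxel_image} with values in {0, 1}.
#' @export
voxelize <- function(mesh, spacing = 1, grid = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (spacing <= 0) stop("voxelize: spacing must be > 0")
  if (!is_closed_mesh(mesh))
    stop("voxelize: mesh must be closed (cap_mesh() open surfaces first)")
  v <- mesh$vertices
  if (is.null(grid))
    grid <- voxel_grid_for(spacing, apply(v, 2, min), apply(v, 2, max))
  origin <- grid$origin
  dims <- grid$dims
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  cx <- origin[1] + (seq_len(nx) - 0.5) * spacing
  cy <- origin[2] + (seq_len(ny) - 0.5) * spacing
  cz <- origin[3] + (seq_len(nz) - 0.5) * spacing

  f <- mesh$faces
  ax <- v[f[, 1], 1]; ay <- v[f[, 1], 2]; az <- v[f[, 1], 3]
  bx <- v[f[, 2], 1]; by <- v[f[, 2], 2]; bz <- v[f[, 2], 3]
  cx3 <- v[f[, 3], 1]; cy3 <- v[f[, 3], 2]; cz3 <- v[f[, 3], 3]

  # per-column crossing lists: crossings[[col]] = z values where the +z ray
  # through the column's (x, y) center pierces the surface
  crossings <- vector("list", nx * ny)
  for (t in seq_len(nrow(f))) {
    x1 <- ax[t]; y1 <- ay[t]; x2 <- bx[t]; y2 <- by[t]; x3 <- cx3[t]; y3 <- cy3[t]
    det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    if (abs(det) < 1e-300) next  # projected triangle degenerate: vertical face
    i_lo <- max(1L, ceiling((min(x1, x2, x3) - origin[1]) / spacing + 0.5))
    i_hi <- min(nx, floor((max(x1, x2, x3) - origin[1]) / spacing + 0.5))
    j_lo <- max(1L, ceiling((min(y1, y2, y3) - origin[2]) / spacing + 0.5))
    j_hi <- min(ny, floor((max(y1, y2, y3) - origin[2]) / spacing + 0.5))
    if (i_lo > i_hi || j_lo > j_hi) next
    px <- cx[i_lo:i_hi]
    py <- cy[j_lo:j_hi]
    pxg <- rep(px, times = length(py))
    pyg <- rep(py, each = length(px))
    l1 <- ((y2 - y3) * (pxg - x3) + (x3 - x2) * (pyg - y3)) / det
    l2 <- ((y3 - y1) * (pxg - x3) + (x1 - x3) * (pyg - y3)) / det
    l3 <- 1 - l1 - l2
    inside <- l1 >= 0 & l2 >= 0 & l3 >= 0
    if (!any(inside)) next
    zhit <- l1[inside] * az[t] + l2[inside] * bz[t] + l3[inside] * cz3[t]
    ii <- (i_lo:i_hi)[((which(inside) - 1L) %% length(px)) + 1L]
    jj <- (j_lo:j_hi)[((which(inside) - 1L) %/% length(px)) + 1L]
    cols <- ii + nx * (jj - 1L)
    for (q in seq_along(cols)) {
      cl <- cols[q]
      crossings[[cl]] <- c(crossings[[cl]], zhit[q])
    }
  }

  occ <- array(0L, dims)
  ztol <- 1e-7 * max(spacing, 1)
  for (cl in which(!vapply(crossings, is.null, TRUE))) {
    zx <- sort(crossings[[cl]])
    # collapse coincident crossings (coplanar faces sharing a diagonal)
    if (length(zx) > 1) zx <- zx[c(TRUE, diff(zx) > ztol)]
    if (length(zx) < 2) next
    i <- ((cl - 1L) %% nx) + 1L
    j <- ((cl - 1L) %/% nx) + 1L
    par <- findInterval(cz, zx) %% 2L
    occ[i, j, par == 1L] <- 1L
  }
  if (!any(occ == 1L))
    stop("voxelize: no voxel center falls inside the mesh (degenerate or empty interior)")
  voxel_image(occ, spacing = spacing, origin = origin)
}

#' Volumetric intersection-over-union of two closed meshes
#'
#' Voxelizes both meshes on one shared grid covering the union of their
#' bounds and returns |A intersect B| / |A union B|. Symmetric in its
#' arguments; 0 for disjoint bounding boxes, 1 for identical occupancy.
#'
#' @param a,b closed \code{triangle_mesh} objects.
#' @param spacing shared voxel edge length (mm), default 1 (sub-millimetre
#'   detail is below CT segmentation fidelity).
#' @return IoU fraction in [0, 1].
#' @export
mesh_iou <- function(a, b, spacing = 1) {
  stopifnot(inherits(a, "triangle_mesh"), inherits(b, "triangle_mesh"))
  lo_a <- apply(a$vertices, 2, min); hi_a <- apply(a$vertices, 2, max)
  lo_b <- apply(b$vertices, 2, min); hi_b <- apply(b$vertices, 2, max)
  if (any(hi_a < lo_b) || any(hi_b < lo_a)) return(0)
  grid <- voxel_grid_for(spacing, pmin(lo_a, lo_b), pmax(hi_a, hi_b))
  va <- voxelize(a, spacing, grid = grid)$values == 1L
  vb <- voxelize(b, spacing, grid = grid)$values == 1L
  inter <- sum(va & vb)
  uni <- sum(va | vb)
  if (uni == 0) return(0)
  inter / uni
}

#' Surface comparison report
#'
#' Bundles the two smoothing-fidelity metrics, RMSE and IoU, for a pair of
#' closed surfaces.
#'
#' @param rmse RMSE in mm (>= 0).
#' @param iou IoU fraction in [0, 1].
#' @return An object of class \code{comparison_report}.
#' @export
comparison_report <- function(rmse, iou) {
  stopifnot(is.finite(rmse), rmse >= 0, is.finite(iou), iou >= 0, iou <= 1)
  structure(list(rmse = rmse, iou = iou), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison_report: RMSE %.4f mm, IoU %.4f\n", x$rmse, x$iou))
  invisible(x)
}
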