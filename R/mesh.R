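#' Triangle mesh
#'
#' A triangulated 3D surface: an N x 3 vertex matrix (mm) and an M x 3
#' integer face matrix of 1-based vertex indices. Faces are oriented
#' counter-clockwise seen from outside for closed surfaces.
#'
#' @param vertices N x 3 numeric matrix (mm).
#' @param faces M x 3 integer matrix of vertex indices (1-based).
#' @return An object of class \code{triangle_mesh}.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3) stop("triangle_mesh: vertices must be N x 3")
  if (ncol(faces) != 3) stop("triangle_mesh: faces must be M x 3")
  if (!all(is.finite(vertices))) stop("triangle_mesh: non-finite vertices")
  if (nrow(faces) > 0) {
    if (min(faces) < 1 || max(faces) > nrow(vertices))
      stop("triangle_mesh: face index out of range")
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3]))
      stop("triangle_mesh: face repeats a vertex")
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces, %s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is_closed_mesh(x)) "closed" else "open"))
  invisible(x)
}

# Ordered edge table: one row per directed edge (a, b) of every face.
directed_edges <- function(mesh) {
  f <- mesh$faces
  cbind(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1]))
}

#' Boundary edges of a mesh
#'
#' Directed edges whose opposite edge is absent; empty for a closed,
#' consistently oriented surface.
#'
#' @param mesh a \code{triangle_mesh}.
#' @return 2-column matrix of directed boundary edges (may have 0 rows).
#' @export
boundary_edges <- function(mesh) {
  e <- directed_edges(mesh)
  key <- paste(e[, 1], e[, 2])
  rev_key <- paste(e[, 2], e[, 1])
  e[!(rev_key %in% key), , drop = FALSE]
}

#' Is a mesh closed (watertight and consistently oriented)?
#'
#' TRUE iff every edge is shared by exactly two faces with opposite
#' direction (consistent orientation) and no directed edge repeats.
#'
#' @param mesh a \code{triangle_mesh}.
#' @return logical.
#' @export
is_closed_mesh <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(FALSE)
  e <- directed_edges(mesh)
  key <- paste(e[, 1], e[, 2])
  if (anyDuplicated(key)) return(FALSE)
  all(paste(e[, 2], e[, 1]) %in% key)
}

# Split boundary edges into ordered loops (list of vertex index vectors).
boundary_loops <- function(mesh) {
  be <- boundary_edges(mesh)
  if (nrow(be) == 0) return(list())
  nxt <- be[, 2]
  names(nxt) <- as.character(be[, 1])
  loops <- list()
  remaining <- stats::setNames(rep(TRUE, nrow(be)), as.character(be[, 1]))
  while (any(remaining)) {
    start <- as.integer(names(remaining)[which(remaining)[1]])
    loop <- start
    remaining[as.character(start)] <- FALSE
    cur <- nxt[[as.character(start)]]
    guard <- 0L
    while (cur != start) {
      loop <- c(loop, cur)
      if (is.na(remaining[as.character(cur)]))
        stop("boundary_loops: boundary is not a set of simple loops")
      remaining[as.character(cur)] <- FALSE
      cur <- nxt[[as.character(cur)]]
      guard <- guard + 1L
      if (guard > nrow(be)) stop("boundary_loops: non-terminating loop walk")
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Cap the boundary loops of an open mesh
#'
#' Fan-triangulates each boundary loop about its centroid so that volume can
#' be computed for cropped (open-ended) surfaces. A closed mesh is returned
#' unchanged.
#'
#' @param mesh a \code{triangle_mesh}.
#' @return A closed \code{triangle_mesh}.
#' @export
cap_mesh <- function(mesh) {
  loops <- boundary_loops(mesh)
  if (length(loops) == 0) return(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  for (loop in loops) {
    cen <- colMeans(v[loop, , drop = FALSE])
    v <- rbind(v, cen)
    ci <- nrow(v)
    n <- length(loop)
    # boundary edge a->b has no partner; cap triangles run b->a->centroid
    a <- loop
    b <- loop[c(2:n, 1)]
    f <- rbind(f, cbind(b, a, ci))
  }
  triangle_mesh(v, f)
}

#' Enclosed volume of a closed mesh
#'
#' Signed-tetrahedron (divergence theorem) volume; the absolute value is
#' returned, so the result is orientation- and rigid-motion-invariant.
#'
#' @param mesh a \code{triangle_mesh}; must be closed. Cap open cropped
#'   meshes with \code{\link{cap_mesh}} first.
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (!is_closed_mesh(mesh)) {
    be <- boundary_edges(mesh)
    stop(sprintf(
      "mesh_volume: mesh is not closed (%d boundary edges, e.g. %s); cap it with cap_mesh()",
      nrow(be),
      paste(utils::head(apply(be, 1, paste, collapse = "-"), 3), collapse = ", ")))
  }
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  cross <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
                 b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
                 b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  abs(sum(a * cross) / 6)
}

#' Axis-aligned box mesh
#' @param lo,hi opposite corners (length-3).
#' @return A closed \code{triangle_mesh} with 8 vertices and 12 faces.
#' @export
make_box <- function(lo = c(0, 0, 0), hi = c(1, 1, 1)) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # vertex order: 1:(-,-,-) 2:(+,-,-) 3:(-,+,-) 4:(+,+,-) 5..8 top
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # bottom (z = lo), outward -z
    c(5, 6, 7), c(6, 8, 7),   # top, outward +z
    c(1, 2, 5), c(2, 6, 5),   # y = lo, outward -y
    c(3, 7, 4), c(4, 7, 8),   # y = hi, outward +y
    c(1, 5, 3), c(3, 5, 7),   # x = lo, outward -x
    c(2, 4, 6), c(4, 8, 6))   # x = hi, outward +x
  triangle_mesh(v, f)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere; a standard analytic test
#' shape (volume 4/3 pi r^3 in the subdivision limit).
#'
#' @param radius sphere radius (mm).
#' @param subdivisions number of 4-to-1 triangle subdivisions (>= 0).
#' @param center sphere center.
#' @return A closed \code{triangle_mesh}.
#' @export
make_icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    mid_cache <- new.env(hash = TRUE)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      v <<- rbind(v, (v[i, ] + v[j, ]) / 2)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[(4L * (k - 1L) + 1L):(4L * k), ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- newf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  v <- sweep(v, 2, center, "+")
  triangle_mesh(v, f)
}

# Per-face areas.
face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sqrt(rowSums(cr^2)) / 2
}

#' Deterministic surface point sampling
#'
#' Distributes \code{n} points over the surface proportionally to face area
#' (largest-remainder apportionment) and places them inside each face by a
#' fixed low-discrepancy barycentric sequence, so repeated calls are
#' bit-identical.
#'
#' @param mesh a \code{triangle_mesh}.
#' @param n number of points (> 0).
#' @return n x 3 matrix of surface points.
#' @export
sample_mesh_points <- function(mesh, n) {
  stopifnot(inherits(mesh, "triangle_mesh"), n > 0)
  ar <- face_areas(mesh)
  quota <- n * ar / sum(ar)
  cnt <- floor(quota)
  short <- n - sum(cnt)
  if (short > 0) {
    extra <- order(quota - cnt, decreasing = TRUE)[seq_len(short)]
    cnt[extra] <- cnt[extra] + 1
  }
  idx <- rep.int(seq_along(cnt), cnt)
  k <- seq_len(n)
  # Kronecker sequence folded into the unit triangle
  u <- (k * (sqrt(2) - 1)) %% 1
  w <- (k * (sqrt(3) - 1)) %% 1
  flip <- u + w > 1
  u[flip] <- 1 - u[flip]
  w[flip] <- 1 - w[flip]
  v <- mesh$vertices
  f <- mesh$faces[idx, , drop = FALSE]
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  a + u * (b - a) + w * (cc - a)
}
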