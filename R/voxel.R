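#' Voxel image
#'
#' A 3D scalar raster: intensities (HU-like) or occupancy in {0, 1}, with
#' per-axis voxel spacing (mm) and the position of the grid corner (mm).
#' Voxel (i, j, k) has its center at \code{origin + (c(i,j,k) - 0.5) * spacing}.
#'
#' @param values 3D numeric array.
#' @param spacing length-3 positive voxel edge lengths (mm); a scalar is
#'   recycled.
#' @param origin length-3 grid corner (mm).
#' @return An object of class \code{voxel_image}.
#' @export
voxel_image <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3) stop("voxel_image: values must be a 3D array")
  if (any(dim(values) < 1)) stop("voxel_image: each dimension must be >= 1")
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- as.numeric(origin)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel_image: spacing must be strictly positive")
  if (length(origin) != 3 || any(!is.finite(origin)))
    stop("voxel_image: origin must be a finite 3-vector")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  cat(sprintf("voxel_image: %s voxels, spacing %s mm, origin %s mm\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "/"),
              paste(signif(x$origin, 4), collapse = "/")))
  invisible(x)
}

# Voxel center coordinates along one axis (1 = x, 2 = y, 3 = z).
voxel_centers <- function(img, axis) {
  n <- dim(img$values)[axis]
  img$origin[axis] + (seq_len(n) - 0.5) * img$spacing[axis]
}

#' Extract the 0.5 iso-surface of a binary occupancy image
#'
#' Emits the boundary faces between occupied and empty voxels (the exact 0.5
#' level set under nearest-neighbour interpolation), producing a watertight,
#' consistently oriented triangle mesh whose enclosed volume equals
#' occupied-count x voxel volume exactly.
#'
#' @param img a \code{voxel_image} with occupancy values (> 0.5 = inside).
#' @param error_on_empty error (default) or return an empty mesh when the
#'   mask has no occupied voxel.
#' @return A closed \code{triangle_mesh} in world coordinates (mm).
#' @export
mask_to_mesh <- function(img, error_on_empty = TRUE) {
  stopifnot(inherits(img, "voxel_image"))
  occ <- img$values > 0.5
  d <- dim(occ)
  if (!any(occ)) {
    if (error_on_empty) stop("mask_to_mesh: mask is empty, no surface to extract")
    return(triangle_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3)))
  }
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  # pad with empty so border voxels emit faces
  pad <- array(FALSE, d + 2L)
  pad[2:(nx + 1), 2:(ny + 1), 2:(nz + 1)] <- occ

  # neighbour occupancy via sub-array indexing of the padded array
  nbr <- function(ax, s) {
    ix <- 2:(nx + 1); iy <- 2:(ny + 1); iz <- 2:(nz + 1)
    if (ax == 1) ix <- ix + s
    if (ax == 2) iy <- iy + s
    if (ax == 3) iz <- iz + s
    pad[ix, iy, iz, drop = FALSE]
  }

  # corner id for corner (i, j, k), i in 0..nx etc. (voxel corners)
  cid <- function(i, j, k) 1 + i + (nx + 1) * (j + (ny + 1) * k)

  face_list <- vector("list", 6)
  fi <- 0L
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      fi <- fi + 1L
      hit <- occ & !nbr(ax, s)
      if (!any(hit)) { face_list[[fi]] <- NULL; next }
      w <- which(hit, arr.ind = TRUE)
      i <- w[, 1] - 1L; j <- w[, 2] - 1L; k <- w[, 3] - 1L  # 0-based voxel
      # the face lies on the +s side of the voxel along ax
      if (ax == 1) {
        x0 <- i + (s + 1L) / 2L
        c00 <- cid(x0, j,      k);      c10 <- cid(x0, j + 1L, k)
        c11 <- cid(x0, j + 1L, k + 1L); c01 <- cid(x0, j,      k + 1L)
        # outward normal +x for s=1: order (c00, c10, c11, c01); flip for s=-1
        q <- if (s == 1L) cbind(c00, c10, c11, c01) else cbind(c00, c01, c11, c10)
      } else if (ax == 2) {
        y0 <- j + (s + 1L) / 2L
        c00 <- cid(i,      y0, k);      c10 <- cid(i + 1L, y0, k)
        c11 <- cid(i + 1L, y0, k + 1L); c01 <- cid(i,      y0, k + 1L)
        # outward +y for s=1: (c00, c01, c11, c10)
        q <- if (s == 1L) cbind(c00, c01, c11, c10) else cbind(c00, c10, c11, c01)
      } else {
        z0 <- k + (s + 1L) / 2L
        c00 <- cid(i,      j,      z0); c10 <- cid(i + 1L, j,      z0)
        c11 <- cid(i + 1L, j + 1L, z0); c01 <- cid(i,      j + 1L, z0)
        # outward +z for s=1: (c00, c10, c11, c01)
        q <- if (s == 1L) cbind(c00, c10, c11, c01) else cbind(c00, c01, c11, c10)
      }
      face_list[[fi]] <- q
    }
  }
  quads <- do.call(rbind, face_list[!vapply(face_list, is.null, TRUE)])
  tris <- rbind(quads[, c(1, 2, 3), drop = FALSE],
                quads[, c(1, 3, 4), drop = FALSE])
  used <- sort(unique(as.vector(tris)))
  remap <- integer(max(used))
  remap[used] <- seq_along(used)
  tris <- matrix(remap[tris], ncol = 3)
  u0 <- used - 1L
  ci <- u0 %% (nx + 1L)
  cj <- (u0 %/% (nx + 1L)) %% (ny + 1L)
  ck <- u0 %/% ((nx + 1L) * (ny + 1L))
  verts <- cbind(img$origin[1] + ci * img$spacing[1],
                 img$origin[2] + cj * img$spacing[2],
                 img$origin[3] + ck * img$spacing[3])
  triangle_mesh(verts, tris)
}
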