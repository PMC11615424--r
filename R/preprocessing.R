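#' Segmentation configuration
#'
#' @param bone_threshold HU window segmenting bone (default c(230, 3020),
#'   the standard bone window).
#' @param smoothing_sigma Gaussian smoothing SD in mm (default 1.5).
#' @param target_length standardized canal length in mm (default 150).
#' @return An object of class \code{segmentation_config}.
#' @export
segmentation_config <- function(bone_threshold = c(230, 3020),
                                smoothing_sigma = 1.5,
                                target_length = 150) {
  if (length(bone_threshold) != 2 || bone_threshold[1] >= bone_threshold[2])
    stop("segmentation_config: bone_threshold must be an increasing interval")
  if (target_length <= 0)
    stop("segmentation_config: target_length must be > 0")
  if (smoothing_sigma < 0)
    stop("segmentation_config: smoothing_sigma must be >= 0")
  structure(list(bone_threshold = as.numeric(bone_threshold),
                 smoothing_sigma = smoothing_sigma,
                 target_length = target_length),
            class = "segmentation_config")
}

#' Segment the canal from a CT-like image
#'
#' Reproduces the Boolean-subtraction segmentation: voxels inside the bone
#' HU window form the bone mask; flood-filling the complement from the image
#' border (6-connected, so the fill cannot leak diagonally through the
#' cortical shell) identifies the outside, and every unreached complement
#' voxel is an internal cavity. The "completely filled" bone minus the bone
#' itself is exactly that cavity — the canal. The canal surface is extracted
#' as the 0.5 iso-surface of the occupancy mask.
#'
#' @param image a \code{voxel_image} of intensities.
#' @param config a \code{segmentation_config}.
#' @return list with \code{mask} (occupancy \code{voxel_image}),
#'   \code{mesh} (closed \code{triangle_mesh}, or NULL when the canal is
#'   empty — then a warning is raised and mesh extraction from the empty
#'   mask errors).
#' @export
segment_canal <- function(image, config = segmentation_config()) {
  stopifnot(inherits(image, "voxel_image"),
            inherits(config, "segmentation_config"))
  vals <- image$values
  bone <- vals >= config$bone_threshold[1] & vals <= config$bone_threshold[2]
  if (!any(bone))
    stop("segment_canal: no voxel falls inside the bone threshold window")
  outside <- array(cpp_flood_outside(as.integer(bone), dim(bone)), dim(bone))
  canal <- !bone & !outside
  if (any(canal)) canal <- repair_mask_diagonals(canal)
  mask <- voxel_image(array(as.integer(canal), dim(canal)),
                      spacing = image$spacing, origin = image$origin)
  if (!any(canal)) {
    warning("segment_canal: bone has no internal cavity; canal mask is empty")
    return(list(mask = mask, mesh = NULL))
  }
  list(mask = mask, mesh = mask_to_mesh(mask))
}

# Resolve edge-diagonal voxel contacts (two occupied voxels sharing only an
# edge) by filling one of the two empty in-plane neighbours, so the 0.5
# iso-surface is a closed 2-manifold. Sub-voxel change; iterated to a fixed
# point.
repair_mask_diagonals <- function(occ) {
  d <- dim(occ)
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  sub <- function(x, a, ra, b, rb) {
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx[[a]] <- ra; idx[[b]] <- rb
    x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  repeat {
    changed <- FALSE
    for (p in pairs) {
      a <- p[1]; b <- p[2]
      if (d[a] < 2 || d[b] < 2) next
      lo_a <- seq_len(d[a] - 1L); hi_a <- 2:d[a]
      lo_b <- seq_len(d[b] - 1L); hi_b <- 2:d[b]
      x11 <- sub(occ, a, lo_a, b, lo_b); x22 <- sub(occ, a, hi_a, b, hi_b)
      x21 <- sub(occ, a, hi_a, b, lo_b); x12 <- sub(occ, a, lo_a, b, hi_b)
      fill1 <- x11 & x22 & !x21 & !x12   # fill the (hi_a, lo_b) neighbour
      fill2 <- x21 & x12 & !x11 & !x22   # fill the (lo_a, lo_b) neighbour
      if (any(fill1)) {
        idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
        idx[[a]] <- hi_a; idx[[b]] <- lo_b
        occ[idx[[1]], idx[[2]], idx[[3]]] <-
          occ[idx[[1]], idx[[2]], idx[[3]]] | fill1
        changed <- TRUE
      }
      if (any(fill2)) {
        idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
        idx[[a]] <- lo_a; idx[[b]] <- lo_b
        occ[idx[[1]], idx[[2]], idx[[3]]] <-
          occ[idx[[1]], idx[[2]], idx[[3]]] | fill2
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  occ
}

# zero-padded separable convolution of a 3D array along one axis
conv_axis <- function(arr, w, axis) {
  r <- (length(w) - 1L) %/% 2L
  out <- arr * w[r + 1L]
  if (r == 0L) return(out)
  d <- dim(arr)
  n <- d[axis]
  for (k in seq_len(min(r, n - 1L))) {  # shifts beyond the grid contribute 0
    src_lo <- 1:(n - k); dst_lo <- (1 + k):n   # shift +k
    src_hi <- (1 + k):n; dst_hi <- 1:(n - k)   # shift -k
    if (axis == 1) {
      out[dst_lo, , ] <- out[dst_lo, , ] + w[r + 1L + k] * arr[src_lo, , ]
      out[dst_hi, , ] <- out[dst_hi, , ] + w[r + 1L - k] * arr[src_hi, , ]
    } else if (axis == 2) {
      out[, dst_lo, ] <- out[, dst_lo, ] + w[r + 1L + k] * arr[, src_lo, ]
      out[, dst_hi, ] <- out[, dst_hi, ] + w[r + 1L - k] * arr[, src_hi, ]
    } else {
      out[, , dst_lo] <- out[, , dst_lo] + w[r + 1L + k] * arr[, , src_lo]
      out[, , dst_hi] <- out[, , dst_hi] + w[r + 1L - k] * arr[, , src_hi]
    }
  }
  out
}

#' Gaussian smoothing of an occupancy mask
#'
#' Exact separable Gaussian convolution of the occupancy (sigma given in mm
#' and converted per axis by the voxel spacing), re-thresholded at 0.5.
#' sigma = 0 is the identity. Protruding single-voxel features fall below
#' 0.5 and are removed; interiors of large uniform regions are unchanged.
#'
#' @param mask occupancy \code{voxel_image} (values in {0, 1}).
#' @param sigma Gaussian SD in mm (>= 0).
#' @return list with \code{mask} (smoothed occupancy \code{voxel_image})
#'   and \code{mesh} (its 0.5 iso-surface, NULL if empty).
#' @export
gaussian_smooth_mask <- function(mask, sigma) {
  stopifnot(inherits(mask, "voxel_image"))
  if (sigma < 0) stop("gaussian_smooth_mask: sigma must be >= 0")
  occ <- (mask$values > 0.5) * 1.0
  if (sigma > 0) {
    for (axis in 1:3) {
      sv <- sigma / mask$spacing[axis]
      r <- max(1L, as.integer(ceiling(3 * sv)))
      w <- exp(-((-r):r)^2 / (2 * sv^2))
      w <- w / sum(w)
      occ <- conv_axis(occ, w, axis)
    }
  }
  thr <- occ > 0.5
  if (sigma > 0 && any(thr)) thr <- repair_mask_diagonals(thr)
  out <- voxel_image(array(as.integer(thr), dim(thr)),
                     spacing = mask$spacing, origin = mask$origin)
  mesh <- if (any(out$values == 1L)) mask_to_mesh(out) else NULL
  list(mask = out, mesh = mesh)
}

#' Validate smoothing fidelity
#'
#' Compares the unsmoothed and smoothed surfaces with the two standard
#' fidelity metrics and applies the acceptance thresholds RMSE < 1 mm and
#' IoU > 0.5.
#'
#' @param original,smoothed closed \code{triangle_mesh} surfaces.
#' @param rmse_threshold,iou_threshold pass thresholds (defaults 1 and 0.5).
#' @param samples RMSE sampling density (see \code{\link{surface_rmse}}).
#' @param spacing IoU voxel spacing (mm).
#' @return list with \code{report} (a \code{comparison_report}) and
#'   \code{pass} (logical).
#' @export
validate_smoothing <- function(original, smoothed, rmse_threshold = 1,
                               iou_threshold = 0.5, samples = 2000L,
                               spacing = 1) {
  rmse <- surface_rmse(original, smoothed, samples = samples)
  iou <- mesh_iou(original, smoothed, spacing = spacing)
  rep <- comparison_report(rmse, iou)
  list(report = rep,
       pass = rmse < rmse_threshold && iou > iou_threshold)
}

#' Crop a canal mesh to the standard length
#'
#' Removes everything more than \code{target_length} distal to the proximal
#' extreme along the canonical long axis (z), re-triangulating faces cut by
#' the crop plane and capping the cut loop so the result stays closed.
#' Inputs shorter than the target length are rejected (mirroring the
#' exclusion of scans with insufficient field of view).
#'
#' @param mesh a \code{triangle_mesh} in the canonical frame, or any frame
#'   if \code{frame} is supplied.
#' @param frame optional \code{anatomical_frame} (or \code{rigid_transform})
#'   applied before cropping.
#' @param target_length standardized length in mm (default 150).
#' @param tol slack on the extent comparison (mm).
#' @return The cropped, closed \code{triangle_mesh} (vertex set unchanged
#'   when the input extent already equals the target).
#' @export
crop_to_length <- function(mesh, frame = NULL, target_length = 150,
                           tol = 1e-9) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (!is.null(frame)) {
    tr <- if (inherits(frame, "anatomical_frame")) frame$transform else frame
    mesh <- apply_rigid(mesh, tr)
  }
  z <- mesh$vertices[, 3]
  extent <- max(z) - min(z)
  if (extent < target_length - tol)
    stop(sprintf(
      "crop_to_length: axial extent %.3f mm < target %.3f mm; case excluded",
      extent, target_length))
  z_cut <- max(z) - target_length
  if (min(z) >= z_cut - tol) return(mesh)

  v <- mesh$vertices
  keep <- z >= z_cut
  f <- mesh$faces
  kf <- matrix(keep[f], ncol = 3)
  nkeep <- rowSums(kf)

  new_v <- v
  edge_cache <- new.env(hash = TRUE)
  cut_point <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    hit <- edge_cache[[key]]
    if (!is.null(hit)) return(hit)
    t <- (z_cut - v[i, 3]) / (v[j, 3] - v[i, 3])
    new_v <<- rbind(new_v, v[i, ] + t * (v[j, ] - v[i, ]))
    edge_cache[[key]] <- nrow(new_v)
    nrow(new_v)
  }

  out_f <- f[nkeep == 3L, , drop = FALSE]
  mixed <- which(nkeep == 1L | nkeep == 2L)
  add <- vector("list", length(mixed))
  for (m in seq_along(mixed)) {
    tri <- f[mixed[m], ]
    k <- keep[tri]
    # rotate so the pattern starts at vertex a
    if (sum(k) == 1L) {
      while (!k[1]) { tri <- tri[c(2, 3, 1)]; k <- k[c(2, 3, 1)] }
      a <- tri[1]; b <- tri[2]; cc <- tri[3]
      add[[m]] <- rbind(c(a, cut_point(a, b), cut_point(cc, a)))
    } else {
      while (k[3]) { tri <- tri[c(2, 3, 1)]; k <- k[c(2, 3, 1)] }
      a <- tri[1]; b <- tri[2]; cc <- tri[3]  # a, b kept; cc dropped
      i_bc <- cut_point(b, cc)
      i_ca <- cut_point(cc, a)
      add[[m]] <- rbind(c(a, b, i_bc), c(a, i_bc, i_ca))
    }
  }
  out_f <- rbind(out_f, do.call(rbind, add))
  # drop unreferenced vertices and re-index
  used <- sort(unique(as.vector(out_f)))
  remap <- integer(nrow(new_v))
  remap[used] <- seq_along(used)
  cropped <- triangle_mesh(new_v[used, , drop = FALSE],
                           matrix(remap[out_f], ncol = 3))
  cap_mesh(cropped)
}
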