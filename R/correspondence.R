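#' Anatomical landmark set
#'
#' The six named landmarks that define the canonical frame and the version
#' measurement: the two posterior condyles, the intertrochanteric crest, the
#' calcar point, and the femoral neck axis end points.
#'
#' @param medial_posterior_condyle,lateral_posterior_condyle,intertrochanteric_crest,calcar_point,neck_head_point,neck_base_point
#'   length-3 numeric positions (mm).
#' @return An object of class \code{landmark_set} (named list of points).
#' @export
landmark_set <- function(medial_posterior_condyle, lateral_posterior_condyle,
                         intertrochanteric_crest, calcar_point,
                         neck_head_point, neck_base_point) {
  lm <- list(medial_posterior_condyle = as.numeric(medial_posterior_condyle),
             lateral_posterior_condyle = as.numeric(lateral_posterior_condyle),
             intertrochanteric_crest = as.numeric(intertrochanteric_crest),
             calcar_point = as.numeric(calcar_point),
             neck_head_point = as.numeric(neck_head_point),
             neck_base_point = as.numeric(neck_base_point))
  if (any(vapply(lm, length, 1L) != 3) ||
      !all(vapply(lm, function(p) all(is.finite(p)), TRUE)))
    stop("landmark_set: each landmark must be a finite 3-vector")
  if (sqrt(sum((lm$medial_posterior_condyle -
                lm$lateral_posterior_condyle)^2)) < 1e-12)
    stop("landmark_set: condyle points must be distinct")
  if (sqrt(sum((lm$neck_head_point - lm$neck_base_point)^2)) < 1e-12)
    stop("landmark_set: neck axis points must be distinct")
  structure(lm, class = "landmark_set")
}

#' Write/read landmarks as CSV (name,x,y,z)
#' @param lm a \code{landmark_set}.
#' @param path CSV path.
#' @export
write_landmarks_csv <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  df <- data.frame(name = names(lm),
                   x = vapply(lm, `[`, 0, 1),
                   y = vapply(lm, `[`, 0, 2),
                   z = vapply(lm, `[`, 0, 3))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @return \code{read_landmarks_csv}: a \code{landmark_set}.
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path)
  pts <- lapply(seq_len(nrow(df)), function(i) as.numeric(df[i, c("x", "y", "z")]))
  names(pts) <- df$name
  do.call(landmark_set, pts)
}

#' Landmark-based anatomical frame
#'
#' Builds the canonical coordinate system from external landmarks: x along
#' the posterior condylar line (medial to lateral), z from the condylar
#' midpoint toward the intertrochanteric crest orthogonalized against x,
#' y = z x x, origin at the intertrochanteric crest. The returned transform
#' maps scanner coordinates into this canonical frame.
#'
#' @param landmarks a \code{landmark_set} in scanner coordinates.
#' @return An object of class \code{anatomical_frame} with element
#'   \code{transform} (a \code{rigid_transform}).
#' @export
anatomical_frame <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  med <- landmarks$medial_posterior_condyle
  lat <- landmarks$lateral_posterior_condyle
  crest <- landmarks$intertrochanteric_crest
  x <- lat - med
  x <- x / sqrt(sum(x^2))
  zt <- crest - (med + lat) / 2
  z <- zt - sum(zt * x) * x
  nz <- sqrt(sum(z^2))
  if (nz < 1e-9 * max(1, sqrt(sum(zt^2))))
    stop("anatomical_frame: condylar line is parallel to the crest direction (degenerate)")
  z <- z / nz
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  r_canonical_to_scanner <- cbind(x, y, z)
  r <- t(r_canonical_to_scanner)
  structure(list(transform = rigid_transform(r, -as.numeric(r %*% crest),
                                             tol = 1e-6)),
            class = "anatomical_frame")
}

#' Align a population of shapes into the canonical frame
#'
#' @param shapes list of \code{triangle_mesh} (or point matrices).
#' @param frames list of \code{anatomical_frame}, one per shape.
#' @return List of shapes expressed in the canonical frame.
#' @export
align_population <- function(shapes, frames) {
  if (length(shapes) != length(frames))
    stop("align_population: one frame is required per shape")
  Map(function(s, f) {
    stopifnot(inherits(f, "anatomical_frame"))
    apply_rigid(s, f$transform)
  }, shapes, frames)
}

#' Map template points onto a target surface
#'
#' Rigid ICP refines the template-to-target pose, then each registered
#' template point is projected onto its nearest point on the target
#' surface. The output is the projected points in the target's (canonical)
#' frame: pose standardization is the job of the anatomical-frame
#' alignment, and rotational anatomy — version, varus/valgus, torsion —
#' must stay in the coordinates or the model could never capture it. The
#' ICP step only carries the template into the target's pose so that
#' nearest-point projection assigns indices correctly. The output always
#' has the template's point count: this is what makes every shape "an
#' equal number of nodes" in the point distribution model.
#'
#' @param template a \code{corresponded_shape} (or N x 3 matrix).
#' @param target a closed \code{triangle_mesh}, roughly pre-aligned.
#' @param max_mean_distance divergence cap (mm): an ICP result whose mean
#'   correspondence distance exceeds this errors out, flagging the case.
#' @param max_iter,tol,k_candidates passed to \code{\link{icp_rigid}}.
#' @return A \code{corresponded_shape} of the same length as the template.
#' @export
map_points <- function(template, target, max_mean_distance = 25,
                       max_iter = 50L, tol = 1e-5, k_candidates = 32L) {
  p <- as.matrix(template)
  reg <- icp_rigid(p, target, max_iter = max_iter, tol = tol,
                   k_candidates = k_candidates)
  if (reg$mean_distance > max_mean_distance)
    stop(sprintf(
      "map_points: registration diverged (mean distance %.2f mm > cap %.2f mm)",
      reg$mean_distance, max_mean_distance))
  proj <- closest_points(apply_rigid(p, reg$transform), target,
                         k_candidates)$points
  corresponded_shape(proj)
}

#' Iterative mean shape and population correspondence
#'
#' Initializes the working template from one reference case, then
#' alternates mapping every target onto the current mean
#' (\code{\link{map_points}}) with index-wise averaging, until the mean's
#' vertex displacement falls below \code{tol} or \code{max_outer} rounds
#' are reached. The per-round displacement history is kept so
#' non-convergence is visible. The result depends weakly on the reference
#' case; fix \code{reference_index} (or supply \code{init_points}) for
#' reproducibility.
#'
#' For vector-fidelity populations (a list of corresponded point matrices)
#' no registration is needed and the mean is the index-wise average.
#'
#' @param targets list of closed \code{triangle_mesh} (canonical frame), or
#'   list of corresponded point matrices.
#' @param reference_index which target seeds the template (default 1).
#' @param max_outer outer iteration cap (default 5).
#' @param tol convergence tolerance on mean vertex displacement (mm,
#'   default 0.1).
#' @param init_points optional N x 3 matrix used as the initial template
#'   instead of sampling the reference target.
#' @param n_points template size when sampling the reference target
#'   (default 1002).
#' @param ... passed to \code{\link{map_points}}.
#' @return list with \code{mean} (list: \code{points}, a
#'   \code{corresponded_shape}; \code{history}, per-round mean displacement
#'   in mm; \code{converged}), and \code{shapes} (list of final
#'   \code{corresponded_shape}s).
#' @export
compute_mean_shape <- function(targets, reference_index = 1L, max_outer = 5L,
                               tol = 0.1, init_points = NULL,
                               n_points = 1002L, ...) {
  if (length(targets) < 1) stop("compute_mean_shape: no targets")
  if (!inherits(targets[[1]], "triangle_mesh")) {
    mats <- lapply(targets, as.matrix)
    ns <- vapply(mats, nrow, 1L)
    if (length(unique(ns)) != 1)
      stop("compute_mean_shape: corresponded shapes differ in length")
    mean_pts <- Reduce(`+`, mats) / length(mats)
    return(list(mean = list(points = corresponded_shape(mean_pts),
                            history = numeric(0), converged = TRUE),
                shapes = lapply(mats, corresponded_shape)))
  }
  if (is.null(init_points)) {
    ref <- targets[[reference_index]]
    init_points <- if (nrow(ref$vertices) <= n_points) ref$vertices
                   else sample_mesh_points(ref, n_points)
  }
  mean_pts <- as.matrix(init_points)
  history <- numeric(0)
  shapes <- NULL
  converged <- FALSE
  for (round in seq_len(max_outer)) {
    shapes <- vector("list", length(targets))
    for (i in seq_along(targets)) {
      shapes[[i]] <- tryCatch(
        map_points(mean_pts, targets[[i]], ...),
        error = function(e) stop(sprintf(
          "compute_mean_shape: mapping failed for case %d: %s", i,
          conditionMessage(e))))
    }
    new_mean <- Reduce(`+`, lapply(shapes, unclass)) / length(shapes)
    disp <- mean(sqrt(rowSums((new_mean - mean_pts)^2)))
    history <- c(history, disp)
    mean_pts <- new_mean
    if (disp < tol) { converged <- TRUE; break }
  }
  list(mean = list(points = corresponded_shape(mean_pts), history = history,
                   converged = converged),
       shapes = shapes)
}

#' Femoral version angle from landmarks
#'
#' The signed axial-plane angle between the femoral neck axis (base to
#' head) and the posterior condylar line, measured in the canonical frame
#' derived from the same landmarks (hence invariant under any common rigid
#' transform). Anteversion — neck pointing anteriorly — is positive;
#' retroversion negative.
#'
#' @param landmarks a \code{landmark_set}.
#' @return Version angle in degrees.
#' @export
measure_version <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  fr <- anatomical_frame(landmarks)
  lm <- apply_rigid(landmarks, fr$transform)
  n <- lm$neck_head_point - lm$neck_base_point
  axial <- sqrt(n[1]^2 + n[2]^2)
  if (axial < 1e-9 * max(1, sqrt(sum(n^2))))
    stop("measure_version: neck axis has no axial-plane projection")
  # angle to the (undirected) condylar line, sign from the anterior component
  deg <- atan2(abs(n[2]), abs(n[1])) * 180 / pi
  if (n[2] < 0) deg <- -deg
  deg
}
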