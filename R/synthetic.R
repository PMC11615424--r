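#' Canonical canal template
#'
#' Deterministic tubular template of the proximal femoral intramedullary
#' canal in the canonical anatomical frame: +z proximal along the canal
#' axis, +x medial-to-lateral (posterior condylar line), +y anterior, origin
#' at the intertrochanteric crest. The canal spans z in [-length, 0] with an
#' elliptical cross-section that flares proximally. Surface points are
#' arranged as rings plus two pole vertices ((point_count - 2) / points_per_ring
#' rings), triangulated into a closed surface; the point ordering is the
#' correspondence ground truth for synthetic populations.
#'
#' Landmarks (canonical positions, mm): posterior condyles at (+/-40, 0,
#' -380), intertrochanteric crest at the origin, calcar point at
#' (-8, -4, -30), femoral neck axis from (0, 0, -12) toward
#' medial-anterior-superior with 16 degrees of native anteversion.
#'
#' @param point_count total surface points (default 1002 = 40 rings x 25 + 2
#'   poles); must satisfy (point_count - 2) divisible by points_per_ring.
#' @param length axial canal length in mm (default 150).
#' @param flare_ratio proximal/distal radius ratio (> 1; default 2.5).
#' @param points_per_ring ring resolution (default 25).
#' @param distal_radius distal base radius in mm (default 6).
#' @return An object of class \code{canal_template}: list with
#'   \code{points} (corresponded_shape), \code{faces}, \code{axis}
#'   (ring z levels), \code{radii} (per-ring ellipse semi-axes),
#'   \code{landmarks}, \code{length}, \code{points_per_ring},
#'   \code{n_rings}.
#' @export
canal_template <- function(point_count = 1002L, length = 150,
                           flare_ratio = 2.5, points_per_ring = 25L,
                           distal_radius = 6) {
  if (point_count < 200) stop("canal_template: point_count must be >= 200")
  if (length <= 0) stop("canal_template: length must be > 0")
  if (flare_ratio < 1)
    stop("canal_template: flare_ratio must be >= 1 (the canal flares proximally)")
  n_ring_pts <- point_count - 2L
  if (n_ring_pts %% points_per_ring != 0)
    stop("canal_template: (point_count - 2) must be divisible by points_per_ring")
  n_rings <- n_ring_pts %/% points_per_ring

  z <- seq(-length, 0, length.out = n_rings)
  # proximal flare over the top third, smoothstep profile
  z_f <- -length / 3
  s <- ifelse(z <= z_f, 0, (z - z_f) / (0 - z_f))
  s <- s * s * (3 - 2 * s)
  r <- distal_radius * (1 + (flare_ratio - 1) * s)
  # medial-lateral semi-axis wider than anterior-posterior, as in the
  # metaphyseal canal; the marked ellipticity also makes axial rotation
  # geometrically observable on the surface
  a <- 1.20 * r
  b <- 0.85 * r

  th <- (seq_len(points_per_ring) - 1) / points_per_ring * 2 * pi
  pts <- matrix(0, n_ring_pts, 3)
  for (i in seq_len(n_rings)) {
    rows <- ((i - 1L) * points_per_ring + 1L):(i * points_per_ring)
    pts[rows, ] <- cbind(a[i] * cos(th), b[i] * sin(th), z[i])
  }
  pts <- rbind(pts, c(0, 0, -length), c(0, 0, 0))  # distal pole, proximal pole
  i_dpole <- n_ring_pts + 1L
  i_ppole <- n_ring_pts + 2L

  faces <- matrix(0L, 0L, 3L)
  ring_idx <- function(i) ((i - 1L) * points_per_ring + 1L):(i * points_per_ring)
  for (i in seq_len(n_rings - 1L)) {
    lo <- ring_idx(i)
    hi <- ring_idx(i + 1L)
    nxt <- c(2:points_per_ring, 1L)
    # outward-facing quads split into triangles (CCW from outside)
    faces <- rbind(faces,
                   cbind(lo, lo[nxt], hi[nxt]),
                   cbind(lo, hi[nxt], hi))
  }
  lo <- ring_idx(1L)
  hi <- ring_idx(n_rings)
  nxt <- c(2:points_per_ring, 1L)
  faces <- rbind(faces,
                 cbind(lo[nxt], lo, i_dpole),   # distal cap, outward -z
                 cbind(hi, hi[nxt], i_ppole))   # proximal cap, outward +z

  version_deg <- 16
  neck_base <- c(0, 0, -12)
  neck_dir <- c(-cos(version_deg * pi / 180) * cos(40 * pi / 180),
                sin(version_deg * pi / 180) * cos(40 * pi / 180),
                sin(40 * pi / 180))
  landmarks <- landmark_set(
    medial_posterior_condyle  = c(-40, 0, -380),
    lateral_posterior_condyle = c( 40, 0, -380),
    intertrochanteric_crest   = c(0, 0, 0),
    calcar_point              = c(-8, -4, -30),
    neck_head_point           = neck_base + 45 * neck_dir,
    neck_base_point           = neck_base)

  structure(list(points = corresponded_shape(pts), faces = faces,
                 axis = z, radii = cbind(a = a, b = b),
                 landmarks = landmarks, length = length,
                 points_per_ring = points_per_ring, n_rings = n_rings),
            class = "canal_template")
}

#' Template mesh
#' @param template a \code{canal_template}.
#' @return The template surface as a closed \code{triangle_mesh}.
#' @export
template_mesh <- function(template) {
  stopifnot(inherits(template, "canal_template"))
  triangle_mesh(template$points, template$faces)
}

#' Planted orthonormal mode basis
#'
#' Builds the five raw displacement fields that define the synthetic
#' population's ground-truth anatomy modes, then Gram-Schmidt
#' orthonormalizes them in construction order (size first, so size stays
#' the dominant interpretable direction):
#' \enumerate{
#'   \item size: uniform radial scaling about the canal axis;
#'   \item proximal_torsion: axial rotation ramping from its maximum at the
#'     proximal end to zero at the calcar level (no displacement distal to
#'     the calcar);
#'   \item anteversion: rigid-like axial rotation of every point about the
#'     long axis;
#'   \item varus_valgus: coronal-plane (x-z) tilt of the axis about the
#'     canal midpoint;
#'   \item distal_twist: axial rotation ramping from zero at mid-shaft to
#'     its maximum distally.
#' }
#'
#' @param template a \code{canal_template}.
#' @return An object of class \code{mode_basis}: list with \code{fields}
#'   (3N x 5 orthonormal matrix, columns in the order above), \code{raw}
#'   (the pre-orthonormalization fields), \code{labels}.
#' @export
canal_mode_basis <- function(template) {
  stopifnot(inherits(template, "canal_template"))
  p <- unclass(template$points)
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  z_calcar <- template$landmarks$calcar_point[3]
  z_mid <- -template$length / 2
  z_distal <- -template$length

  ramp_prox <- ifelse(z <= z_calcar, 0, (z - z_calcar) / (0 - z_calcar))
  ramp_dist <- ifelse(z >= z_mid, 0, (z_mid - z) / (z_mid - z_distal))

  raw <- cbind(
    size            = flatten_shape(cbind(x, y, 0)),
    proximal_torsion = flatten_shape(cbind(-ramp_prox * y, ramp_prox * x, 0)),
    anteversion     = flatten_shape(cbind(-y, x, 0)),
    varus_valgus    = flatten_shape(cbind(z - z_mid, 0, -x)),
    distal_twist    = flatten_shape(cbind(-ramp_dist * y, ramp_dist * x, 0)))

  fields <- raw
  for (k in 1:5) {
    v <- raw[, k]
    if (k > 1)
      v <- v - fields[, 1:(k - 1), drop = FALSE] %*%
        crossprod(fields[, 1:(k - 1), drop = FALSE], v)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-8 * sqrt(sum(raw[, k]^2)))
      stop("canal_mode_basis: raw fields are linearly dependent")
    fields[, k] <- v / nv
  }
  structure(list(fields = fields, raw = raw, labels = colnames(raw)),
            class = "mode_basis")
}

#' Synthetic population configuration
#'
#' Defaults encode the study conditions the generator emulates: 64 subjects;
#' a five-mode variance spectrum in the proportions 3.8 : 1.9 : 1.5 : 0.89 :
#' 0.61 with an isotropic residual of 1.66/8.7 of the planted total spread
#' over the orthogonal complement (so the planted modes are exactly the top
#' five population eigenvalues); 0.3 mm surface noise; scanner pose jitter
#' of up to 10 degrees / 5 mm. The absolute variance scale (mode 1 =
#' 1000 mm^2, about 1 mm radial standard deviation per point) is set so that
#' +/-3 SD shapes remain geometrically valid for a ~6 mm radius canal.
#'
#' @param n_samples population size (>= 2; default 64).
#' @param mode_variances five planted mode variances (mm^2), descending.
#' @param residual_variance_total total isotropic residual variance (mm^2)
#'   spread over the orthogonal complement of the planted modes.
#' @param noise_sd_surface per-vertex surface noise SD along the outward
#'   normal (mm), mesh fidelity only.
#' @param pose_jitter list(max_rotation_deg, max_translation) for the random
#'   rigid scanner pose, mesh fidelity only.
#' @param fidelity "vector" (corresponded point sets, no pose/noise) or
#'   "mesh" (posed noisy meshes with landmarks).
#' @param seed integer RNG seed.
#' @return An object of class \code{population_config}.
#' @export
population_config <- function(n_samples = 64L,
                              mode_variances = 1000 *
                                c(3.8e5, 1.9e5, 1.5e5, 8.9e4, 6.1e4) / 3.8e5,
                              residual_variance_total = 1000 * 1.66e5 / 3.8e5,
                              noise_sd_surface = 0.3,
                              pose_jitter = list(max_rotation_deg = 10,
                                                 max_translation = 5),
                              fidelity = c("vector", "mesh"),
                              seed = 1L) {
  fidelity <- match.arg(fidelity)
  if (n_samples < 2) stop("population_config: n_samples must be >= 2")
  if (length(mode_variances) != 5 || any(mode_variances < 0))
    stop("population_config: mode_variances must be five values >= 0")
  if (residual_variance_total < 0 || noise_sd_surface < 0)
    stop("population_config: variances must be >= 0")
  stopifnot(is.list(pose_jitter),
            all(c("max_rotation_deg", "max_translation") %in% names(pose_jitter)))
  structure(list(n_samples = as.integer(n_samples),
                 mode_variances = as.numeric(mode_variances),
                 residual_variance_total = residual_variance_total,
                 noise_sd_surface = noise_sd_surface,
                 pose_jitter = pose_jitter, fidelity = fidelity,
                 seed = as.integer(seed)),
            class = "population_config")
}

#' Sample a synthetic canal population
#'
#' Draws mode coefficients from zero-mean normals with the planted
#' variances, adds an isotropic residual confined to the orthogonal
#' complement of the planted fields, and (mesh fidelity) adds surface noise
#' along vertex normals plus a random rigid scanner pose applied to surface
#' and landmarks alike. Fully reproducible from the config seed.
#'
#' @param template a \code{canal_template}.
#' @param basis a \code{mode_basis} from \code{\link{canal_mode_basis}}.
#' @param config a \code{population_config}.
#' @return List of samples; each sample is a list with
#'   \code{true_coefficients} (five mode coefficients, mm) and
#'   \code{true_pose} (a \code{rigid_transform}), plus either \code{shape}
#'   (vector fidelity, a \code{corresponded_shape}) or \code{mesh} and
#'   \code{landmarks} (mesh fidelity, in scanner pose).
#' @export
sample_population <- function(template, basis, config) {
  stopifnot(inherits(template, "canal_template"),
            inherits(basis, "mode_basis"),
            inherits(config, "population_config"))
  n <- config$n_samples
  f <- basis$fields
  p3 <- nrow(f)
  t0 <- flatten_shape(template$points)
  sd_dir <- if (config$residual_variance_total > 0)
    sqrt(config$residual_variance_total / (p3 - ncol(f))) else 0

  with_seed(config$seed, {
    coefs <- matrix(rnorm(n * 5), n, 5) %*% diag(sqrt(config$mode_variances))
    samples <- vector("list", n)
    for (i in seq_len(n)) {
      xi <- t0 + as.numeric(f %*% coefs[i, ])
      if (sd_dir > 0) {
        g <- rnorm(p3, sd = sd_dir)
        xi <- xi + (g - as.numeric(f %*% crossprod(f, g)))
      }
      if (config$fidelity == "vector") {
        samples[[i]] <- list(shape = unflatten_shape(xi),
                             true_coefficients = coefs[i, ],
                             true_pose = identity_transform())
      } else {
        mesh <- triangle_mesh(unflatten_shape(xi), template$faces)
        if (config$noise_sd_surface > 0) {
          vn <- vertex_normals(mesh)
          mesh$vertices <- mesh$vertices +
            vn * rnorm(nrow(vn), sd = config$noise_sd_surface)
        }
        ax <- rnorm(3)
        ax <- ax / sqrt(sum(ax^2))
        ang <- runif(1, -config$pose_jitter$max_rotation_deg,
                     config$pose_jitter$max_rotation_deg)
        tr <- rigid_transform(rotation_about(ax, ang),
                              runif(3, -config$pose_jitter$max_translation,
                                    config$pose_jitter$max_translation),
                              tol = 1e-6)
        samples[[i]] <- list(mesh = apply_rigid(mesh, tr),
                             landmarks = apply_rigid(template$landmarks, tr),
                             true_coefficients = coefs[i, ],
                             true_pose = tr)
      }
    }
    samples
  })
}

# iterative 6-neighbour binary dilation by `rounds` voxels
dilate_mask <- function(occ, rounds) {
  d <- dim(occ)
  for (r in seq_len(rounds)) {
    out <- occ
    out[-1, , ] <- out[-1, , ] | occ[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | occ[-1, , ]
    out[, -1, ] <- out[, -1, ] | occ[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | occ[, -1, ]
    out[, , -1] <- out[, , -1] | occ[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | occ[, , -1]
    occ <- out
  }
  occ
}

#' CT-like phantom of a synthetic canal sample
#'
#' Rasterizes a mesh-fidelity sample into a three-label intensity image:
#' canal interior at the canal intensity, a dilated cortical shell of the
#' stated thickness around it at the cortex intensity, background elsewhere.
#' Default intensities put the cortex inside the standard bone segmentation
#' window [230, 3020] HU and the canal outside it.
#'
#' @param sample a mesh-fidelity sample from \code{\link{sample_population}}
#'   (or any list with a closed \code{mesh}).
#' @param cortex_thickness shell thickness in mm (> 0; default 3).
#' @param intensities named numeric: canal, cortex, background HU
#'   (defaults 80, 1200, -1000).
#' @param spacing voxel edge length in mm (default 1).
#' @return A \code{voxel_image} of intensities.
#' @export
make_ct_phantom <- function(sample, cortex_thickness = 3,
                            intensities = c(canal = 80, cortex = 1200,
                                            background = -1000),
                            spacing = 1) {
  if (is.null(sample$mesh))
    stop("make_ct_phantom: sample has no mesh (mesh-fidelity required)")
  if (cortex_thickness <= 0)
    stop("make_ct_phantom: cortex_thickness must be > 0")
  stopifnot(all(c("canal", "cortex", "background") %in% names(intensities)))
  mesh <- sample$mesh
  v <- mesh$vertices
  margin <- cortex_thickness + spacing
  grid <- list(origin = apply(v, 2, min) - margin - spacing,
               dims = as.integer(ceiling((apply(v, 2, max) + margin + spacing -
                                          (apply(v, 2, min) - margin - spacing)) /
                                         spacing)))
  canal <- voxelize(mesh, spacing, grid = grid)
  occ <- canal$values == 1L
  shell <- dilate_mask(occ, max(1L, as.integer(round(cortex_thickness / spacing)))) & !occ
  vals <- array(intensities[["background"]], dim(occ))
  vals[shell] <- intensities[["cortex"]]
  vals[occ] <- intensities[["canal"]]
  voxel_image(vals, spacing = canal$spacing, origin = canal$origin)
}
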