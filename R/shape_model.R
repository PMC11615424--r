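#' Fit a PCA shape model to corresponded shapes
#'
#' Stacks each shape as one row (x0, y0, z0, x1, ...), centers by the
#' column mean, and factorizes the centered matrix with a thin SVD (the
#' 3N x 3N covariance is never formed; n is much smaller than 3N).
#' Eigenvalues are singular values squared over (n - 1) — the unbiased
#' sample covariance spectrum — in strictly descending order, and modes are
#' the corresponding orthonormal eigenvectors. Mode signs are fixed so each
#' mode's largest-magnitude entry is positive, making +/- SD perturbations
#' reproducible. Modes with eigenvalue below 1e-9 times the leading one are
#' dropped; a population of identical shapes yields a zero-variance model
#' with no modes and \code{zero_variance = TRUE}.
#'
#' @param shapes list of \code{corresponded_shape} / N x 3 matrices of equal
#'   length, or an n x 3N numeric matrix (one shape per row).
#' @return An object of class \code{shape_model}: list with \code{mean}
#'   (3N), \code{modes} (3N x m, orthonormal columns), \code{eigenvalues}
#'   (m, mm^2), \code{n_samples}, \code{n_points}, \code{zero_variance}.
#' @export
fit_pca <- function(shapes) {
  if (is.list(shapes)) {
    ns <- vapply(shapes, function(s) nrow(as.matrix(s)), 1L)
    if (length(unique(ns)) != 1)
      stop("fit_pca: shapes have mismatched point counts")
    x <- do.call(rbind, lapply(shapes, flatten_shape))
  } else {
    x <- as.matrix(shapes)
  }
  n <- nrow(x)
  if (n < 2) stop("fit_pca: need at least two shapes")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc, nu = 0)
  ev <- sv$d^2 / (n - 1)
  if (ev[1] <= 0 || !any(ev > 1e-12 * max(ev[1], 1))) {
    return(structure(list(mean = mu,
                          modes = matrix(0, ncol(x), 0),
                          eigenvalues = numeric(0),
                          n_samples = n, n_points = ncol(x) / 3L,
                          zero_variance = TRUE),
                     class = "shape_model"))
  }
  keep <- which(ev > 1e-9 * ev[1])
  keep <- keep[keep <= n - 1L]
  modes <- sv$v[, keep, drop = FALSE]
  for (k in seq_len(ncol(modes))) {
    imax <- which.max(abs(modes[, k]))
    if (modes[imax, k] < 0) modes[, k] <- -modes[, k]
  }
  structure(list(mean = mu, modes = modes, eigenvalues = ev[keep],
                 n_samples = n, n_points = ncol(x) / 3L,
                 zero_variance = FALSE),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("shape_model: %d samples, %d points, %d modes\n",
              x$n_samples, x$n_points, ncol(x$modes)))
  if (length(x$eigenvalues))
    cat("  leading eigenvalues (mm^2):",
        paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Explained-variance report
#'
#' Per-mode explained-variance fractions, the running cumulative sum, a
#' scree table, and the smallest number of modes reaching a cumulative
#' threshold (default 80%).
#'
#' @param model a fitted \code{shape_model}.
#' @param threshold cumulative fraction defining "the majority of the
#'   variation" (default 0.80).
#' @return An object of class \code{variance_report}: list with
#'   \code{fractions}, \code{cumulative}, \code{scree} (data.frame: mode,
#'   eigenvalue, fraction, cumulative), \code{k_threshold},
#'   \code{threshold}.
#' @export
variance_report <- function(model, threshold = 0.80) {
  stopifnot(inherits(model, "shape_model"))
  ev <- model$eigenvalues
  if (length(ev) == 0 || sum(ev) <= 0)
    stop("variance_report: model has no variance (all eigenvalues zero)")
  fr <- ev / sum(ev)
  cum <- cumsum(fr)
  structure(list(fractions = fr, cumulative = cum,
                 scree = data.frame(mode = seq_along(ev), eigenvalue = ev,
                                    fraction = fr, cumulative = cum),
                 k_threshold = which(cum >= threshold)[1],
                 threshold = threshold),
            class = "variance_report")
}

#' Reconstruct a shape from mode weights
#'
#' mean + sum_k w_k sqrt(lambda_k) phi_k, with weights in SD units, so
#' w = +/-3 is the standard +/-3 SD perturbation.
#'
#' @param model a \code{shape_model}.
#' @param weights numeric weights (SD units), length <= number of modes.
#' @return A \code{corresponded_shape} (N x 3).
#' @export
reconstruct_shape <- function(model, weights) {
  stopifnot(inherits(model, "shape_model"))
  m <- ncol(model$modes)
  if (length(weights) > m)
    stop("reconstruct_shape: more weights than retained modes")
  x <- model$mean
  if (length(weights) > 0) {
    k <- seq_along(weights)
    x <- x + as.numeric(model$modes[, k, drop = FALSE] %*%
                        (weights * sqrt(model$eigenvalues[k])))
  }
  unflatten_shape(x)
}

#' Project a shape onto the model's modes
#'
#' w_k = phi_k^T (x - mean) / sqrt(lambda_k): the inverse of
#' \code{\link{reconstruct_shape}} for shapes inside the model span;
#' training-set weights are whitened (unit variance per mode).
#'
#' @param model a \code{shape_model}.
#' @param shape a \code{corresponded_shape} / N x 3 matrix with the model's
#'   point count.
#' @param n_modes how many leading modes to project on (default all).
#' @return Numeric weight vector in SD units.
#' @export
project_shape <- function(model, shape, n_modes = ncol(model$modes)) {
  stopifnot(inherits(model, "shape_model"))
  x <- flatten_shape(shape)
  if (length(x) != length(model$mean))
    stop("project_shape: shape length does not match the model")
  if (n_modes > ncol(model$modes))
    stop("project_shape: mode with zero eigenvalue requested")
  k <- seq_len(n_modes)
  lam <- model$eigenvalues[k]
  if (any(lam <= 0)) stop("project_shape: mode with zero eigenvalue requested")
  as.numeric(crossprod(model$modes[, k, drop = FALSE], x - model$mean)) /
    sqrt(lam)
}

#' Export +/- SD perturbation meshes for each mode
#'
#' Writes, for each retained mode, the reconstructed surface at weights
#' -sd_range ... +sd_range in steps of \code{step}, under systematic names
#' \code{mode{k}_w{+/-d}.ply}.
#'
#' @param model a \code{shape_model}.
#' @param faces triangulation (M x 3) valid for the model's points.
#' @param dir output directory (created if needed).
#' @param sd_range half-range in SD units (default 3).
#' @param step weight step (default 1).
#' @param n_modes how many leading modes to export (default up to 5).
#' @return Character vector of written file paths, invisibly.
#' @export
export_perturbations <- function(model, faces, dir, sd_range = 3, step = 1,
                                 n_modes = min(5L, ncol(model$modes))) {
  stopifnot(inherits(model, "shape_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  weights <- seq(-sd_range, sd_range, by = step)
  paths <- character(0)
  for (k in seq_len(n_modes)) {
    for (w in weights) {
      wv <- rep(0, k)
      wv[k] <- w
      mesh <- triangle_mesh(reconstruct_shape(model, wv), faces)
      p <- file.path(dir, sprintf("mode%d_w%+d.ply", k, as.integer(w)))
      write_ply(mesh, p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Volume trace of one mode
#'
#' Deforms the mean by -3 ... +3 SD along one mode (step 1 by default),
#' measures the enclosed volume of each reconstruction (capping open
#' surfaces), and attaches the closed-form least-squares slope of volume
#' against weight. The mode whose trace is steepest encodes size.
#'
#' @param model a \code{shape_model}.
#' @param faces triangulation for the model's points.
#' @param mode 1-based mode index (must be retained).
#' @param weights weight grid in SD units (default -3:3).
#' @return An object of class \code{mode_feature_trace}: list with
#'   \code{mode}, \code{weights}, \code{volumes} (mm^3), \code{slope}
#'   (mm^3 per SD).
#' @export
mode_volume_trace <- function(model, faces, mode, weights = -3:3) {
  stopifnot(inherits(model, "shape_model"))
  if (mode < 1 || mode > ncol(model$modes))
    stop("mode_volume_trace: mode not retained in the model")
  vols <- vapply(weights, function(w) {
    wv <- rep(0, mode)
    wv[mode] <- w
    mesh <- triangle_mesh(reconstruct_shape(model, wv), faces)
    if (!is_closed_mesh(mesh)) mesh <- cap_mesh(mesh)
    tryCatch(mesh_volume(mesh), error = function(e)
      stop(sprintf("mode_volume_trace: degenerate reconstruction at weight %+g: %s",
                   w, conditionMessage(e))))
  }, 0)
  wc <- weights - mean(weights)
  slope <- sum(wc * (vols - mean(vols))) / sum(wc^2)
  structure(list(mode = mode, weights = weights, volumes = vols,
                 slope = slope),
            class = "mode_feature_trace")
}

#' Identify the size mode from volume traces
#'
#' The mode whose volume-vs-weight line of best fit is steepest (largest
#' absolute slope). Ties are broken toward the lower mode index and
#' flagged.
#'
#' @param traces list of \code{mode_feature_trace}.
#' @param tie_tol relative slope difference treated as a tie (default 1e-9).
#' @return list with \code{mode} (index into the traces' mode labels),
#'   \code{tie} (logical), \code{slopes} (named by mode).
#' @export
identify_size_mode <- function(traces, tie_tol = 1e-9) {
  if (length(traces) == 0) stop("identify_size_mode: no traces supplied")
  slopes <- vapply(traces, function(t) t$slope, 0)
  modes <- vapply(traces, function(t) t$mode, 0)
  a <- abs(slopes)
  best <- max(a)
  hits <- which(a >= best * (1 - tie_tol))
  list(mode = modes[hits[1]], tie = length(hits) > 1,
       slopes = setNames(slopes, modes))
}
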