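default_pipeline_schema <- function() list(
  population = list(n_samples = NULL, mode_variances = NULL,
                    residual_variance_total = NULL, noise_sd_surface = NULL,
                    pose_jitter = list(max_rotation_deg = NULL,
                                       max_translation = NULL),
                    fidelity = NULL),
  segmentation = list(bone_threshold = NULL, smoothing_sigma = NULL,
                      target_length = NULL),
  phantom = list(enabled = NULL, cortex_thickness = NULL, spacing = NULL),
  correspondence = list(n_points = NULL, tol = NULL, max_outer = NULL,
                        reference_index = NULL, use_template_init = NULL),
  model = list(n_modes_report = NULL, sd_range = NULL,
               variance_threshold = NULL),
  template = list(point_count = NULL, length = NULL, flare_ratio = NULL),
  seed = NULL)

check_keys <- function(given, schema, path = "") {
  if (!is.list(given)) return(invisible())
  bad <- setdiff(names(given), names(schema))
  if (length(bad))
    stop(sprintf("pipeline_config: unknown key%s %s%s",
                 if (length(bad) > 1) "s" else "",
                 path, paste(bad, collapse = ", ")))
  for (nm in names(given))
    if (is.list(schema[[nm]]))
      check_keys(given[[nm]], schema[[nm]], paste0(path, nm, "$"))
  invisible()
}

#' Pipeline configuration
#'
#' Nested, validated configuration for the full modeling pipeline. Unknown
#' keys are rejected before any stage runs. A single global seed fans out
#' deterministically to every stage.
#'
#' @param population overrides for \code{\link{population_config}}.
#' @param segmentation overrides for \code{\link{segmentation_config}}.
#' @param phantom list(enabled, cortex_thickness, spacing): rasterize each
#'   mesh sample into a CT-like phantom and run segmentation + smoothing
#'   (default enabled for mesh fidelity).
#' @param correspondence list(n_points, tol, max_outer, reference_index,
#'   use_template_init).
#' @param model list(n_modes_report, sd_range, variance_threshold).
#' @param template overrides for \code{\link{canal_template}}.
#' @param seed global integer seed.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(population = list(), segmentation = list(),
                            phantom = list(), correspondence = list(),
                            model = list(), template = list(), seed = 1L) {
  given <- list(population = population, segmentation = segmentation,
                phantom = phantom, correspondence = correspondence,
                model = model, template = template, seed = seed)
  check_keys(given, default_pipeline_schema())
  merge1 <- function(defaults, over) {
    for (nm in names(over)) defaults[[nm]] <- over[[nm]]
    defaults
  }
  cfg <- list(
    population = merge1(list(n_samples = 64L,
                             mode_variances = 1000 * c(3.8e5, 1.9e5, 1.5e5,
                                                       8.9e4, 6.1e4) / 3.8e5,
                             residual_variance_total = 1000 * 1.66e5 / 3.8e5,
                             noise_sd_surface = 0.3,
                             pose_jitter = list(max_rotation_deg = 10,
                                                max_translation = 5),
                             fidelity = "vector"), population),
    segmentation = merge1(list(bone_threshold = c(230, 3020),
                               smoothing_sigma = 1.5, target_length = 150),
                          segmentation),
    phantom = merge1(list(enabled = TRUE, cortex_thickness = 3, spacing = 1),
                     phantom),
    correspondence = merge1(list(n_points = 1002L, tol = 0.1, max_outer = 5L,
                                 reference_index = 1L,
                                 use_template_init = TRUE), correspondence),
    model = merge1(list(n_modes_report = 5L, sd_range = 3,
                        variance_threshold = 0.8), model),
    template = merge1(list(point_count = 1002L, length = 150,
                           flare_ratio = 2.5), template),
    seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

pipeline_population_config <- function(cfg) {
  p <- cfg$population
  population_config(n_samples = p$n_samples, mode_variances = p$mode_variances,
                    residual_variance_total = p$residual_variance_total,
                    noise_sd_surface = p$noise_sd_surface,
                    pose_jitter = p$pose_jitter, fidelity = p$fidelity,
                    seed = cfg$seed)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Generate a synthetic population on disk
#'
#' Writes one directory per case (mesh as PLY plus landmarks CSV for mesh
#' fidelity, wide shape CSV for vector fidelity; optional MetaImage
#' phantom), the ground-truth mode coefficients, and a manifest with the
#' seed, the config hash and per-file MD5 checksums, so a regenerated
#' population is checkably identical.
#'
#' @param config a \code{pipeline_config}.
#' @param out_dir output directory.
#' @return Path of the manifest JSON, invisibly.
#' @export
run_generate <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0)
    stop("run_generate: output directory is not writable")
  tpl <- canal_template(point_count = config$template$point_count,
                        length = config$template$length,
                        flare_ratio = config$template$flare_ratio)
  basis <- canal_mode_basis(tpl)
  samples <- sample_population(tpl, basis, pipeline_population_config(config))
  files <- character(0)
  for (i in seq_along(samples)) {
    cd <- file.path(out_dir, sprintf("case_%03d", i))
    dir.create(cd, showWarnings = FALSE)
    s <- samples[[i]]
    utils::write.csv(data.frame(mode = basis$labels,
                                coefficient = s$true_coefficients),
                     file.path(cd, "coefficients.csv"), row.names = FALSE)
    files <- c(files, file.path(cd, "coefficients.csv"))
    if (!is.null(s$mesh)) {
      write_ply(s$mesh, file.path(cd, "mesh.ply"))
      write_landmarks_csv(s$landmarks, file.path(cd, "landmarks.csv"))
      files <- c(files, file.path(cd, "mesh.ply"), file.path(cd, "landmarks.csv"))
      if (isTRUE(config$phantom$enabled)) {
        ph <- make_ct_phantom(s, cortex_thickness = config$phantom$cortex_thickness,
                              spacing = config$phantom$spacing)
        write_mhd(ph, file.path(cd, "phantom.mhd"))
        files <- c(files, file.path(cd, "phantom.mhd"),
                   file.path(cd, "phantom.raw"))
      }
    } else {
      df <- as.data.frame(t(flatten_shape(s$shape)))
      names(df) <- paste0(c("x", "y", "z"), rep(seq_len(nrow(s$shape)) - 1L,
                                                each = 3))
      utils::write.csv(df, file.path(cd, "shape.csv"), row.names = FALSE)
      files <- c(files, file.path(cd, "shape.csv"))
    }
  }
  manifest <- list(seed = config$seed, config_hash = config_hash(config),
                   n_cases = length(samples),
                   fidelity = config$population$fidelity,
                   checksums = as.list(tools::md5sum(files)))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Persist / load a shape model (JSON container)
#' @param model a \code{shape_model}.
#' @param path JSON path.
#' @param metadata optional named list stored alongside (seed, config hash).
#' @export
write_shape_model <- function(model, path, metadata = list()) {
  stopifnot(inherits(model, "shape_model"))
  obj <- list(mean = model$mean, modes = model$modes,
              eigenvalues = model$eigenvalues, n_samples = model$n_samples,
              n_points = model$n_points, metadata = metadata)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_shape_model
#' @return \code{read_shape_model}: the \code{shape_model} with a
#'   \code{metadata} element.
#' @export
read_shape_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$mean) || is.null(obj$eigenvalues))
    stop("read_shape_model: corrupt or incomplete model container")
  modes <- obj$modes
  if (is.null(dim(modes))) modes <- matrix(modes, ncol = 1)
  structure(list(mean = as.numeric(obj$mean), modes = modes,
                 eigenvalues = as.numeric(obj$eigenvalues),
                 n_samples = obj$n_samples, n_points = obj$n_points,
                 zero_variance = length(obj$eigenvalues) == 0,
                 metadata = obj$metadata),
            class = "shape_model")
}

#' Run the full modeling pipeline
#'
#' Executes the workflow end to end — generation (or user-supplied cases),
#' optional phantom rasterization + segmentation + smoothing + validation,
#' anatomical-frame alignment, cropping to the standard length (cases with
#' insufficient extent are excluded, as in the study design), iterative
#' mean-shape correspondence, and PCA — and writes the model container,
#' scree CSV, smoothing-validation CSV, volume-trace CSV, perturbation
#' meshes and a run log.
#'
#' @param config a \code{pipeline_config}.
#' @param out_dir output directory for reports (NULL = nothing written).
#' @param input_dir optional population directory from
#'   \code{\link{run_generate}}; default generates in memory.
#' @return list with \code{model}, \code{report} (variance_report),
#'   \code{traces}, \code{size_mode}, \code{validation} (data.frame or
#'   NULL), \code{corresponded}, \code{mean}, \code{excluded} (case ids),
#'   \code{log}, invisibly.
#' @export
run_build_model <- function(config, out_dir = NULL, input_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  logln <- local({
    lines <- character(0)
    function(fmt = NULL, ...) {
      if (is.null(fmt)) return(lines)
      lines <<- c(lines, sprintf(fmt, ...))
      invisible()
    }
  })
  logln("seed: %d  config: %s", config$seed, config_hash(config))

  tpl <- canal_template(point_count = config$template$point_count,
                        length = config$template$length,
                        flare_ratio = config$template$flare_ratio)
  if (is.null(input_dir)) {
    basis <- canal_mode_basis(tpl)
    samples <- sample_population(tpl, basis, pipeline_population_config(config))
    logln("generate: %d cases, fidelity %s", length(samples),
          config$population$fidelity)
  } else {
    cases <- list.dirs(input_dir, recursive = FALSE)
    cases <- cases[grepl("case_", basename(cases))]
    samples <- lapply(cases, function(cd) {
      if (file.exists(file.path(cd, "mesh.ply")))
        list(mesh = read_ply(file.path(cd, "mesh.ply")),
             landmarks = read_landmarks_csv(file.path(cd, "landmarks.csv")))
      else {
        row <- as.numeric(utils::read.csv(file.path(cd, "shape.csv"))[1, ])
        list(shape = unflatten_shape(row))
      }
    })
    logln("load: %d cases from %s", length(samples), input_dir)
  }

  validation <- NULL
  if (!is.null(samples[[1]]$shape)) {
    shapes <- lapply(samples, `[[`, "shape")
    ms <- compute_mean_shape(shapes)
    logln("correspondence: vector fidelity, index-wise mean")
  } else {
    seg_cfg <- segmentation_config(bone_threshold = config$segmentation$bone_threshold,
                                   smoothing_sigma = config$segmentation$smoothing_sigma,
                                   target_length = config$segmentation$target_length)
    meshes <- vector("list", length(samples))
    vrows <- list()
    for (i in seq_along(samples)) {
      mesh_i <- samples[[i]]$mesh
      if (isTRUE(config$phantom$enabled)) {
        ph <- make_ct_phantom(samples[[i]],
                              cortex_thickness = config$phantom$cortex_thickness,
                              spacing = config$phantom$spacing)
        seg <- segment_canal(ph, seg_cfg)
        if (is.null(seg$mesh))
          stop(sprintf("run_build_model: segmentation produced no canal for case %d", i))
        sm <- gaussian_smooth_mask(seg$mask, seg_cfg$smoothing_sigma)
        val <- validate_smoothing(seg$mesh, sm$mesh)
        vrows[[i]] <- data.frame(case = i, rmse = val$report$rmse,
                                 iou = val$report$iou, pass = val$pass)
        mesh_i <- sm$mesh
      }
      meshes[[i]] <- mesh_i
    }
    if (length(vrows)) validation <- do.call(rbind, vrows)
    if (isTRUE(config$phantom$enabled))
      logln("segmentation+smoothing: %d/%d cases pass fidelity thresholds",
            sum(validation$pass), nrow(validation))

    frames <- lapply(samples, function(s) anatomical_frame(s$landmarks))
    aligned <- align_population(meshes, frames)
    logln("alignment: %d cases in canonical frame", length(aligned))

    cropped <- list()
    excluded <- integer(0)
    for (i in seq_along(aligned)) {
      cropped_i <- tryCatch(
        crop_to_length(aligned[[i]],
                       target_length = config$segmentation$target_length),
        error = function(e) NULL)
      if (is.null(cropped_i)) excluded <- c(excluded, i)
      else cropped[[length(cropped) + 1L]] <- cropped_i
    }
    if (length(excluded))
      logln("crop: excluded %d case(s) shorter than %g mm: %s",
            length(excluded), config$segmentation$target_length,
            paste(excluded, collapse = ","))
    if (length(cropped) < 2)
      stop("run_build_model: fewer than two cases survive cropping")

    init <- if (isTRUE(config$correspondence$use_template_init))
      tpl$points else NULL
    ms <- compute_mean_shape(cropped,
                             reference_index = config$correspondence$reference_index,
                             max_outer = config$correspondence$max_outer,
                             tol = config$correspondence$tol,
                             init_points = init,
                             n_points = config$correspondence$n_points)
    logln("mean shape: %d rounds, final displacement %.4f mm (converged: %s)",
          length(ms$mean$history), utils::tail(ms$mean$history, 1),
          ms$mean$converged)
  }

  model <- fit_pca(ms$shapes)
  rep <- variance_report(model, config$model$variance_threshold)
  n_rep <- min(config$model$n_modes_report, ncol(model$modes))
  traces <- lapply(seq_len(n_rep), function(k)
    mode_volume_trace(model, tpl$faces, k))
  size <- identify_size_mode(traces)
  logln("pca: %d modes retained; %d modes reach %.0f%% cumulative; size mode: %d",
        ncol(model$modes), rep$k_threshold, 100 * rep$threshold, size$mode)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_shape_model(model, file.path(out_dir, "model.json"),
                      metadata = list(seed = config$seed,
                                      config_hash = config_hash(config)))
    utils::write.csv(rep$scree, file.path(out_dir, "scree.csv"),
                     row.names = FALSE)
    tr_df <- do.call(rbind, lapply(traces, function(t)
      data.frame(mode = t$mode, weight = t$weights, volume = t$volumes,
                 slope = t$slope)))
    utils::write.csv(tr_df, file.path(out_dir, "volume_traces.csv"),
                     row.names = FALSE)
    if (!is.null(validation))
      utils::write.csv(validation, file.path(out_dir, "validation.csv"),
                       row.names = FALSE)
    export_perturbations(model, tpl$faces, file.path(out_dir, "perturbations"),
                         sd_range = config$model$sd_range, n_modes = n_rep)
    writeLines(logln(), file.path(out_dir, "run_log.txt"))
  }
  invisible(list(model = model, report = rep, traces = traces,
                 size_mode = size, validation = validation,
                 corresponded = ms$shapes, mean = ms$mean,
                 excluded = if (exists("excluded")) excluded else integer(0),
                 log = logln()))
}

#' Print a human-readable model summary
#'
#' Per-mode eigenvalue, explained-variance fraction and cumulative
#' fraction, the identified size mode and the volume-trace slopes, plus
#' provenance (seed and config hash) from the model container.
#'
#' @param model_dir directory written by \code{\link{run_build_model}} (or
#'   a path to \code{model.json}).
#' @param n_modes modes to print (default 5).
#' @return The scree data.frame, invisibly.
#' @export
run_report <- function(model_dir, n_modes = 5L) {
  mp <- if (dir.exists(model_dir)) file.path(model_dir, "model.json") else model_dir
  if (!file.exists(mp)) stop("run_report: model container not found: ", mp)
  model <- read_shape_model(mp)
  rep <- variance_report(model)
  k <- min(n_modes, nrow(rep$scree))
  cat("Shape model summary\n")
  if (!is.null(model$metadata$seed))
    cat(sprintf("  seed: %s  config: %s\n", model$metadata$seed,
                model$metadata$config_hash))
  cat(sprintf("  samples: %d  points: %d  modes: %d\n", model$n_samples,
              model$n_points, length(model$eigenvalues)))
  for (i in seq_len(k))
    cat(sprintf("  mode %d: eigenvalue %.4g mm^2, %5.1f%% (cumulative %5.1f%%)\n",
                i, rep$scree$eigenvalue[i], 100 * rep$scree$fraction[i],
                100 * rep$scree$cumulative[i]))
  td <- file.path(dirname(mp), "volume_traces.csv")
  if (file.exists(td)) {
    tr <- utils::read.csv(td)
    sl <- unique(tr[, c("mode", "slope")])
    best <- sl$mode[which.max(abs(sl$slope))]
    cat(sprintf("  size mode (steepest volume trace): mode %d\n", best))
    for (i in seq_len(nrow(sl)))
      cat(sprintf("    mode %d volume slope: %.4g mm^3/SD\n",
                  sl$mode[i], sl$slope[i]))
  }
  invisible(rep$scree)
}
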