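test_that("fit_pca matches a brute-force covariance eigendecomposition on toy data", {
  set.seed(2)
  # 4 samples x 2 points (6 coordinates)
  x <- matrix(rnorm(24, sd = 3), 4, 6)
  model <- fit_pca(x)
  orc <- oracle_pca(x)
  m <- length(model$eigenvalues)
  expect_lt(max(abs(model$eigenvalues - orc$eigenvalues[seq_len(m)])), 1e-9)
  for (k in seq_len(m)) {
    align <- abs(sum(model$modes[, k] * orc$vectors[, k]))
    expect_equal(align, 1, tolerance = 1e-9)
  }

  # larger random instances with 3N <= 30
  for (rep in 1:3) {
    y <- matrix(rnorm(8 * 30), 8, 30)
    my <- fit_pca(y)
    oy <- oracle_pca(y)
    expect_lt(max(abs(my$eigenvalues -
                      oy$eigenvalues[seq_along(my$eigenvalues)])), 1e-9)
  }
})

test_that("identical shapes give a zero-variance model and mismatched lengths error", {
  tpl <- canal_template()
  model <- fit_pca(list(tpl$points, tpl$points, tpl$points))
  expect_true(model$zero_variance)
  expect_equal(ncol(model$modes), 0L)
  expect_error(variance_report(model), "zero")

  expect_error(fit_pca(list(tpl$points, tpl$points[1:10, ])), "mismatch")
})

test_that("the planted five-mode spectrum is recovered from n = 64 vector populations", {
  planted <- c(3.8e5, 1.9e5, 1.5e5, 8.9e4, 6.1e4)
  ev <- matrix(0, 3, 5)
  for (s in 1:3) {
    pop <- make_vector_population(n = 64, seed = s, variances = planted,
                                  residual = 1.66e5)
    model <- fit_pca(lapply(pop$samples, `[[`, "shape"))
    ev[s, ] <- model$eigenvalues[1:5]
  }
  expect_true(all(abs(colMeans(ev) - planted) / planted < 0.25))
  expect_true(all(diff(colMeans(ev)) < 0))
})

test_that("variance fractions, cumulative sums and the threshold count are exact arithmetic", {
  mk_model <- function(ev) structure(
    list(mean = numeric(6), modes = diag(6)[, seq_along(ev), drop = FALSE],
         eigenvalues = ev, n_samples = 10, n_points = 2,
         zero_variance = FALSE), class = "shape_model")

  r <- variance_report(mk_model(c(2, 1, 1)))
  expect_equal(r$fractions, c(0.5, 0.25, 0.25))
  expect_equal(r$cumulative, c(0.5, 0.75, 1))
  expect_equal(sum(r$fractions), 1, tolerance = 1e-9)

  r1 <- variance_report(mk_model(5))
  expect_equal(r1$fractions, 1)

  # the planted spectrum with its isotropic residual needs exactly 5 modes
  # to clear the 80% threshold
  ev <- c(3.8e5, 1.9e5, 1.5e5, 8.9e4, 6.1e4, rep(1.66e5 / 58, 58))
  r5 <- variance_report(structure(
    list(mean = numeric(200), modes = matrix(0, 200, 63), eigenvalues = ev,
         n_samples = 64, n_points = 200, zero_variance = FALSE),
    class = "shape_model"))
  expect_equal(r5$k_threshold, 5L)
})

test_that("reconstruction and projection are exact inverses with whitened training weights", {
  pop <- make_vector_population(n = 32, seed = 6)
  shapes <- lapply(pop$samples, `[[`, "shape")
  model <- fit_pca(shapes)

  expect_equal(flat(reconstruct_shape(model, numeric(0))), model$mean)

  w <- c(1.3, -0.4, 2.2, 0, -3)
  plus <- flat(reconstruct_shape(model, w))
  minus <- flat(reconstruct_shape(model, -w))
  expect_lt(max(abs(plus + minus - 2 * model$mean)), 1e-9)

  expect_equal(project_shape(model, reconstruct_shape(model, w),
                             n_modes = 5)[1:5], w, tolerance = 1e-9)
  expect_lt(max(abs(project_shape(model, unflattened <- reconstruct_shape(
    model, numeric(0))))), 1e-9)

  # full-rank round trip on a training shape
  w_full <- project_shape(model, shapes[[3]])
  rec <- reconstruct_shape(model, w_full)
  expect_lt(sqrt(mean((flat(rec) - flat(shapes[[3]]))^2)), 1e-6)

  # whitening: per-mode training weight variance is exactly 1
  ws <- t(vapply(shapes, function(s) project_shape(model, s),
                 numeric(ncol(model$modes))))
  expect_equal(unname(apply(ws[, 1:5], 2, var)), rep(1, 5),
               tolerance = 1e-9)

  expect_error(project_shape(model, shapes[[1]],
                             n_modes = ncol(model$modes) + 1), "zero")
})

test_that("perturbation export writes 5 x 7 systematically named meshes, weight 0 being the mean", {
  pop <- make_vector_population(n = 20, seed = 12)
  model <- fit_pca(lapply(pop$samples, `[[`, "shape"))
  d <- withr::local_tempdir()
  paths <- export_perturbations(model, pop$template$faces, d)
  expect_length(paths, 35)
  expect_true(all(file.exists(paths)))
  expect_true("mode3_w-3.ply" %in% basename(paths))

  zero <- read_ply(file.path(d, "mode1_w+0.ply"))
  expect_equal(flat(zero$vertices), model$mean, tolerance = 1e-8)
})

test_that("volume traces attribute size to the steepest slope with a closed-form fit", {
  tpl <- canal_template()
  basis <- canal_mode_basis(tpl)
  # model with a planted size mode and a planted pure-rotation mode
  model <- structure(
    list(mean = flat(tpl$points),
         modes = basis$fields[, c(1, 3)],
         eigenvalues = c(900, 900), n_samples = 10,
         n_points = nrow(tpl$points), zero_variance = FALSE),
    class = "shape_model")

  tr_size <- mode_volume_trace(model, tpl$faces, 1)
  tr_rot <- mode_volume_trace(model, tpl$faces, 2)
  expect_length(tr_size$volumes, 7)

  # slope equals the independent least-squares fit
  fit <- stats::lm(tr_size$volumes ~ tr_size$weights)
  expect_equal(tr_size$slope, unname(stats::coef(fit)[2]), tolerance = 1e-9)

  # rotation-like mode changes volume at least 100x less steeply
  expect_gt(tr_size$slope, 0)
  expect_lt(abs(tr_rot$slope), 0.01 * abs(tr_size$slope))

  sm <- identify_size_mode(list(tr_size, tr_rot))
  expect_equal(sm$mode, 1)
  expect_false(sm$tie)

  expect_equal(identify_size_mode(list(tr_rot))$mode, 2)
  t_a <- structure(list(mode = 1, weights = -3:3, volumes = rep(0, 7),
                        slope = 10), class = "mode_feature_trace")
  t_b <- structure(list(mode = 2, weights = -3:3, volumes = rep(0, 7),
                        slope = -10), class = "mode_feature_trace")
  tie <- identify_size_mode(list(t_a, t_b))
  expect_equal(tie$mode, 1)
  expect_true(tie$tie)
  expect_error(identify_size_mode(list()), "no traces")
})

test_that("planted-spectrum populations put the size mode first", {
  pop <- make_vector_population(n = 64, seed = 3)
  model <- fit_pca(lapply(pop$samples, `[[`, "shape"))
  traces <- lapply(1:5, function(k)
    mode_volume_trace(model, pop$template$faces, k))
  expect_equal(identify_size_mode(traces)$mode, 1)
})

test_that("eigenvalue sums and rigid equivariance hold for the fitted model", {
  pop <- make_vector_population(n = 24, seed = 14)
  shapes <- lapply(pop$samples, `[[`, "shape")
  model <- fit_pca(shapes)

  x <- do.call(rbind, lapply(shapes, flat))
  total_var <- sum(sweep(x, 2, colMeans(x))^2) / (nrow(x) - 1)
  expect_equal(sum(model$eigenvalues), total_var, tolerance = 1e-6)

  tr <- rigid_transform(rotation_about(c(1, -1, 2), 28), c(30, -12, 4))
  moved <- lapply(shapes, apply_rigid, tr = tr)
  model2 <- fit_pca(moved)
  expect_equal(model2$eigenvalues, model$eigenvalues, tolerance = 1e-6)
  expect_equal(matrix(model2$mean, ncol = 3, byrow = TRUE),
               unclass(apply_rigid(matrix(model$mean, ncol = 3, byrow = TRUE),
                                   tr)),
               tolerance = 1e-6, ignore_attr = TRUE)
})
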