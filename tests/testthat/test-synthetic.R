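test_that("the canal template is deterministic, 150 mm long, closed and proximally flared", {
  t1 <- canal_template()
  t2 <- canal_template()
  expect_identical(t1, t2)

  z <- t1$points[, 3]
  expect_equal(max(z) - min(z), 150, tolerance = 1e-6)

  tm <- template_mesh(t1)
  expect_true(is_closed_mesh(tm))
  expect_gt(mesh_volume(tm), 0)

  # flare: proximal radii >= distal radii
  expect_true(all(t1$radii[nrow(t1$radii), ] >= t1$radii[1, ]))
  expect_error(canal_template(flare_ratio = 0.8), "flare")
})

test_that("the planted mode basis is orthonormal with the documented geometric structure", {
  tpl <- canal_template()
  basis <- canal_mode_basis(tpl)
  gram <- crossprod(basis$fields)
  expect_lt(max(abs(gram - diag(5))), 1e-9)

  # raw size field inflates the volume monotonically
  tm <- template_mesh(tpl)
  vols <- vapply(c(0, 4, 8), function(w) {
    m <- tm
    m$vertices <- m$vertices + w * matrix(basis$raw[, "size"], ncol = 3,
                                          byrow = TRUE)
    mesh_volume(m)
  }, 0)
  expect_true(all(diff(vols) > 0))

  # proximal torsion vanishes distal to the calcar level
  z_calcar <- tpl$landmarks$calcar_point[3]
  distal <- tpl$points[, 3] <= z_calcar
  tor <- matrix(basis$raw[, "proximal_torsion"], ncol = 3, byrow = TRUE)
  expect_true(all(tor[distal, ] == 0))
})

test_that("population sampling is reproducible and degenerates to the template", {
  tpl <- canal_template()
  basis <- canal_mode_basis(tpl)
  cfg <- population_config(n_samples = 5, fidelity = "mesh", seed = 42)
  expect_identical(sample_population(tpl, basis, cfg),
                   sample_population(tpl, basis, cfg))

  cfg0 <- population_config(n_samples = 3, mode_variances = rep(0, 5),
                            residual_variance_total = 0,
                            noise_sd_surface = 0,
                            pose_jitter = list(max_rotation_deg = 0,
                                               max_translation = 0),
                            fidelity = "vector", seed = 9)
  pop0 <- sample_population(tpl, basis, cfg0)
  for (s in pop0)
    expect_equal(unclass(s$shape), unclass(tpl$points), ignore_attr = TRUE)

  expect_error(population_config(n_samples = 1), "n_samples")
})

test_that("planted coefficient variances are realized (law of large numbers)", {
  tpl <- canal_template()
  basis <- canal_mode_basis(tpl)
  cfg <- population_config(n_samples = 10000, residual_variance_total = 0,
                           fidelity = "vector", seed = 5)
  pop <- sample_population(tpl, basis, cfg)
  co <- t(vapply(pop, `[[`, numeric(5), "true_coefficients"))
  v <- apply(co, 2, var)
  expect_true(all(abs(v - cfg$mode_variances) / cfg$mode_variances < 0.05))
})

test_that("the generated covariance spectrum has the planted top-five eigenvalues", {
  tpl <- canal_template()
  basis <- canal_mode_basis(tpl)
  planted <- population_config()$mode_variances
  ev <- matrix(0, 3, 5)
  for (s in 1:3) {
    cfg <- population_config(n_samples = 5000, fidelity = "vector", seed = s)
    pop <- sample_population(tpl, basis, cfg)
    x <- do.call(rbind, lapply(pop, function(p) flat(p$shape)))
    xc <- sweep(x, 2, colMeans(x))
    d <- svd(xc, nu = 0, nv = 0)$d
    ev[s, ] <- d[1:5]^2 / (nrow(x) - 1)
  }
  expect_true(all(abs(colMeans(ev) - planted) / planted < 0.03))
})

test_that("clean mesh samples run through point mapping recover planted coefficients", {
  # zero pose jitter, zero noise: the rigid-like tilt mode must come back
  # within 5% of its SD; the size mode tracks truth near-perfectly up to
  # the documented normal-projection attenuation of nearest-point mapping.
  tpl <- canal_template()
  basis <- canal_mode_basis(tpl)
  cfg <- population_config(n_samples = 16, fidelity = "mesh",
                           noise_sd_surface = 0,
                           pose_jitter = list(max_rotation_deg = 0,
                                              max_translation = 0),
                           seed = 11)
  pop <- sample_population(tpl, basis, cfg)
  rec <- t(vapply(pop, function(s) {
    mp <- map_points(tpl$points, s$mesh)
    as.numeric(crossprod(basis$fields, flat(mp) - flat(tpl$points)))
  }, numeric(5)))
  tru <- t(vapply(pop, `[[`, numeric(5), "true_coefficients"))
  expect_lt(sd(rec[, 4] - tru[, 4]), 0.05 * sqrt(cfg$mode_variances[4]))
  expect_gt(cor(rec[, 1], tru[, 1]), 0.99)
})

test_that("CT phantoms carry a consistent three-label partition", {
  tpl <- canal_template()
  basis <- canal_mode_basis(tpl)
  cfg <- population_config(n_samples = 2, fidelity = "mesh", seed = 8)
  s <- sample_population(tpl, basis, cfg)[[1]]
  ph <- make_ct_phantom(s, cortex_thickness = 3, spacing = 1)

  canal_count <- sum(ph$values == 80)
  expect_lt(abs(canal_count * 1 - mesh_volume(s$mesh)) / mesh_volume(s$mesh),
            0.05)

  # default intensities: exactly one label (the cortex) falls inside the
  # default bone segmentation window; the canal label sits outside it
  w <- segmentation_config()$bone_threshold
  labs <- sort(unique(as.vector(ph$values)))
  expect_equal(labs, c(-1000, 80, 1200))
  expect_equal(sum(labs >= w[1] & labs <= w[2]), 1L)
  expect_false(80 >= w[1] && 80 <= w[2])

  expect_error(make_ct_phantom(s, cortex_thickness = 0), "cortex_thickness")
  vec <- sample_population(tpl, basis,
                           population_config(n_samples = 2, seed = 1))[[1]]
  expect_error(make_ct_phantom(vec), "mesh")
})
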