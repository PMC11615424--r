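test_that("the anatomical frame is the identity at canonical landmarks and inverts planted poses", {
  tpl <- canal_template()
  fr <- anatomical_frame(tpl$landmarks)
  expect_lt(max(abs(fr$transform$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(fr$transform$translation)), 1e-12)

  set.seed(13)
  for (rep in 1:3) {
    tr <- rigid_transform(rotation_about(rnorm(3), runif(1, -170, 170)),
                          rnorm(3, sd = 30))
    fr2 <- anatomical_frame(apply_rigid(tpl$landmarks, tr))
    back <- compose_rigid(fr2$transform, tr)
    expect_lt(max(abs(back$rotation - diag(3))), 1e-9)
    expect_lt(max(abs(back$translation)), 1e-9)
    r <- fr2$transform$rotation
    expect_lt(max(abs(crossprod(r) - diag(3))), 1e-9)
    expect_equal(det(r), 1, tolerance = 1e-9)
  }

  # crest collinear with the condylar line: degenerate
  bad <- landmark_set(c(-40, 0, 0), c(40, 0, 0), c(10, 0, 0),
                      c(-8, -4, -30), c(0, 10, 5), c(0, 0, -12))
  expect_error(anatomical_frame(bad), "degenerate")
})

test_that("population alignment is a no-op at identity and equivariant under common rigid motion", {
  tpl <- canal_template()
  tm <- template_mesh(tpl)
  fr0 <- anatomical_frame(tpl$landmarks)
  out <- align_population(list(tm), list(fr0))
  expect_equal(out[[1]]$vertices, tm$vertices, tolerance = 1e-12)

  tr <- rigid_transform(rotation_about(c(0.5, 1, -2), 35), c(7, -9, 2))
  fr1 <- anatomical_frame(apply_rigid(tpl$landmarks, tr))
  out1 <- align_population(list(apply_rigid(tm, tr)), list(fr1))
  expect_equal(out1[[1]]$vertices, tm$vertices, tolerance = 1e-6)

  expect_error(align_population(list(tm, tm), list(fr0)), "one frame")
})

test_that("alignment shrinks the pose spread of a jittered population", {
  tpl <- canal_template()
  basis <- canal_mode_basis(tpl)
  cfg <- population_config(n_samples = 4, fidelity = "mesh",
                           noise_sd_surface = 0.1, seed = 31)
  pop <- sample_population(tpl, basis, cfg)
  meshes <- lapply(pop, `[[`, "mesh")
  frames <- lapply(pop, function(s) anatomical_frame(s$landmarks))
  aligned <- align_population(meshes, frames)
  prs <- function(ms) {
    d <- 0
    n <- 0
    for (i in 1:3) for (j in (i + 1):4) {
      d <- d + surface_rmse(ms[[i]], ms[[j]], samples = 400)
      n <- n + 1
    }
    d / n
  }
  expect_lt(prs(aligned), prs(meshes))
})

test_that("point mapping preserves node count, fixes the identity and follows the target pose", {
  tpl <- canal_template()
  tm <- template_mesh(tpl)

  mp0 <- map_points(tpl$points, tm)
  expect_equal(nrow(mp0), nrow(tpl$points))
  expect_lt(max(abs(unclass(mp0) - unclass(tpl$points))), 1e-6)

  # small planted rigid offset: output equals the registered template
  tr <- rigid_transform(rotation_about(c(0, 0.3, 1), 4), c(1, -0.5, 0.8))
  mp1 <- map_points(tpl$points, apply_rigid(tm, tr), max_iter = 200,
                    tol = 1e-8)
  expect_lt(sqrt(mean(rowSums((unclass(mp1) -
                               apply_rigid(tpl$points, tr))^2))), 0.1)

  # exact equivariance with the target pose inside the convergence basin
  tr2 <- rigid_transform(rotation_about(c(1, 0, 0.2), -3), c(-0.7, 0.4, 1.1))
  mp2 <- map_points(tpl$points, apply_rigid(tm, tr2), max_iter = 200,
                    tol = 1e-8)
  back <- apply_rigid(mp2, invert_rigid(tr2))
  expect_lt(sqrt(mean(rowSums((unclass(back) - unclass(mp0))^2))), 0.05)

  # divergence cap flags cases that fail to register within budget
  flipped <- apply_rigid(tm, rigid_transform(axis_rotation("x", 90),
                                             c(40, 40, 0)))
  expect_error(map_points(tpl$points, flipped, max_iter = 2,
                          max_mean_distance = 1),
               "diverged")
})

test_that("the iterative mean shape converges to planted ground truth", {
  tpl <- canal_template()
  tm <- template_mesh(tpl)

  # population of one: the mean is that shape's mapped points
  one <- compute_mean_shape(list(tm), init_points = tpl$points)
  expect_lt(sqrt(mean(rowSums((unclass(one$mean$points) -
                               unclass(tpl$points))^2))), 1e-6)

  # symmetric vector pair at +c and -c averages to the template
  basis <- canal_mode_basis(tpl)
  c_vec <- c(30, 20, -15, 10, 5)
  d <- as.numeric(basis$fields %*% c_vec)
  plus <- tpl$points + matrix(d, ncol = 3, byrow = TRUE)
  minus <- tpl$points - matrix(d, ncol = 3, byrow = TRUE)
  sym <- compute_mean_shape(list(plus, minus))
  expect_lt(max(abs(unclass(sym$mean$points) - unclass(tpl$points))), 1e-9)

  # rigidly scrambled copies of one shape, re-aligned, average to that shape
  set.seed(17)
  copies <- list()
  frames <- list()
  for (i in 1:4) {
    tr <- rigid_transform(rotation_about(rnorm(3), runif(1, -20, 20)),
                          runif(3, -10, 10))
    copies[[i]] <- apply_rigid(tm, tr)
    frames[[i]] <- anatomical_frame(apply_rigid(tpl$landmarks, tr))
  }
  aligned <- align_population(copies, frames)
  ms <- compute_mean_shape(aligned, init_points = tpl$points, max_outer = 3)
  d_mean <- closest_points(unclass(ms$mean$points), tm)$distance
  expect_lt(sqrt(mean(d_mean^2)), 0.2)
  expect_true(all(diff(ms$mean$history) <= 1e-9) ||
                length(ms$mean$history) == 1)
})

test_that("the index-wise vector mean concentrates around the template as n grows", {
  tpl <- canal_template()
  basis <- canal_mode_basis(tpl)
  resid <- 400
  cfg <- population_config(n_samples = 48, mode_variances = rep(0, 5),
                           residual_variance_total = resid,
                           fidelity = "vector", seed = 19)
  pop <- sample_population(tpl, basis, cfg)
  ms <- compute_mean_shape(lapply(pop, `[[`, "shape"))
  dev <- flat(ms$mean$points) - flat(tpl$points)
  sd_dir <- sqrt(resid / (length(flat(tpl$points)) - 5))
  expect_lt(max(abs(dev)), 5 * sd_dir / sqrt(48))
  expect_lt(sqrt(mean(dev^2)), 1.5 * sd_dir / sqrt(48))
})

test_that("version measurement follows the anteversion-positive convention and is rigid-invariant", {
  mk <- function(version_deg) {
    a <- version_deg * pi / 180
    landmark_set(c(-40, 0, -380), c(40, 0, -380), c(0, 0, 0),
                 c(-8, -4, -30),
                 c(0, 0, -12) + 45 * c(-cos(a) * cos(0.7), sin(a) * cos(0.7),
                                       sin(0.7)),
                 c(0, 0, -12))
  }
  expect_equal(measure_version(mk(0)), 0, tolerance = 1e-9)
  expect_equal(measure_version(mk(20)), 20, tolerance = 1e-9)
  expect_equal(measure_version(mk(-10)), -10, tolerance = 1e-9)

  set.seed(29)
  lm <- mk(16.3)
  for (rep in 1:3) {
    tr <- rigid_transform(rotation_about(rnorm(3), runif(1, -150, 150)),
                          rnorm(3, sd = 50))
    expect_equal(measure_version(apply_rigid(lm, tr)), 16.3,
                 tolerance = 1e-9)
  }

  vertical <- landmark_set(c(-40, 0, -380), c(40, 0, -380), c(0, 0, 0),
                           c(-8, -4, -30), c(0, 0, 30), c(0, 0, -12))
  expect_error(measure_version(vertical), "axial")
})
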