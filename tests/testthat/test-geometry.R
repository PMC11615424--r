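test_that("rigid transforms validate and act as a group", {
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl), "determinant")

  cube <- make_box()
  expect_equal(apply_rigid(cube, identity_transform()), cube)

  a <- rigid_transform(rotation_about(c(1, 1, 0), 40), c(1, -2, 3))
  b <- rigid_transform(rotation_about(c(0, 2, 1), -25), c(-4, 0.5, 2))
  p <- matrix(rnorm(60), 20, 3)
  expect_equal(apply_rigid(apply_rigid(p, b), a),
               apply_rigid(p, compose_rigid(a, b)), tolerance = 1e-12)

  # planted 30 degree rotation preserves all cube edge lengths
  tr <- rigid_transform(rotation_about(c(0.3, -1, 2), 30), c(5, 6, -7))
  v <- apply_rigid(cube, tr)$vertices
  d0 <- as.matrix(dist(cube$vertices))
  d1 <- as.matrix(dist(v))
  expect_lt(max(abs(d0 - d1)), 1e-9)
})

test_that("mesh volume matches analytic values and scales as s^3", {
  cube <- make_box()
  expect_equal(mesh_volume(cube), 1)

  ico <- make_icosphere(10, 4)
  expect_lt(abs(mesh_volume(ico) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000),
            0.01)

  tpl <- template_mesh(canal_template())
  s <- 1.7
  scaled <- triangle_mesh(tpl$vertices * s, tpl$faces)
  expect_equal(mesh_volume(scaled), mesh_volume(tpl) * s^3,
               tolerance = 1e-9)

  # rigid invariance
  tr <- rigid_transform(rotation_about(c(1, 2, 3), 33), c(10, -4, 2))
  expect_equal(mesh_volume(apply_rigid(tpl, tr)), mesh_volume(tpl),
               tolerance = 1e-9)
})

test_that("open meshes are rejected with boundary info and cap_mesh closes them", {
  cube <- make_box()
  open_mesh <- triangle_mesh(cube$vertices, cube$faces[-(1:2), ])
  expect_false(is_closed_mesh(open_mesh))
  expect_error(mesh_volume(open_mesh), "boundary edges")
  capped <- cap_mesh(open_mesh)
  expect_true(is_closed_mesh(capped))
  expect_equal(mesh_volume(capped), 1, tolerance = 1e-12)
})

test_that("surface RMSE is zero on identity, exact on offset planes, and matches the exhaustive oracle", {
  cube <- make_box()
  expect_equal(surface_rmse(cube, cube, samples = 200), 0)

  patch <- function(z) triangle_mesh(
    rbind(c(0, 0, z), c(1, 0, z), c(1, 1, z), c(0, 1, z)),
    rbind(c(1, 2, 3), c(1, 3, 4)))
  expect_equal(surface_rmse(patch(0), patch(0.37), samples = 150), 0.37,
               tolerance = 1e-6)

  # ~100-vertex pair, vertex sampling vs exhaustive per-vertex search
  a <- make_icosphere(5, 1)
  b <- make_icosphere(5.6, 1, center = c(0.4, -0.2, 0.3))
  expect_equal(surface_rmse(a, b, samples = NULL, k_candidates = 0),
               oracle_surface_rmse(a, b), tolerance = 1e-6)
})

test_that("voxelization counts interior voxels correctly and converges to the mesh volume", {
  big <- make_box(c(0, 0, 0), c(10, 10, 10))
  vox <- voxelize(big, 1)
  expect_lt(abs(sum(vox$values) - 1000) / 1000, 0.05)

  ico <- make_icosphere(8, 3)
  vol <- mesh_volume(ico)
  errs <- vapply(c(2, 1, 0.5), function(s) {
    v <- voxelize(ico, s)
    abs(sum(v$values) * s^3 - vol) / vol
  }, 0)
  expect_true(all(diff(errs) < 0))  # error shrinks as spacing halves

  # open mesh and empty-interior degenerate input are rejected
  open_mesh <- triangle_mesh(big$vertices, big$faces[-1, ])
  expect_error(voxelize(open_mesh, 1), "closed")
  tiny <- make_icosphere(0.05, 1)  # no voxel center inside at 1 mm
  expect_error(voxelize(tiny, 1), "degenerate|inside")
})

test_that("IoU is 1 on identity, 1/3 on half-overlapping cubes, symmetric, 0 on disjoint", {
  a <- make_box(c(0, 0, 0), c(10, 10, 10))
  expect_equal(mesh_iou(a, a, 1), 1)

  b <- make_box(c(5, 0, 0), c(15, 10, 10))
  expect_equal(mesh_iou(a, b, 1), 1 / 3, tolerance = 0.02)

  set.seed(4)
  c1 <- make_icosphere(6, 2, center = c(2, 1, 0))
  c2 <- make_icosphere(5, 2, center = c(5, 0, 1))
  expect_equal(mesh_iou(c1, c2, 1), mesh_iou(c2, c1, 1))

  far <- make_box(c(100, 100, 100), c(110, 110, 110))
  expect_identical(mesh_iou(a, far, 1), 0)
})

test_that("Kabsch equals Horn's closed-form fit on small point sets", {
  set.seed(7)
  for (rep in 1:5) {
    p <- matrix(rnorm(30), 10, 3)
    tr <- rigid_transform(rotation_about(rnorm(3), runif(1, -60, 60)),
                          rnorm(3))
    q <- apply_rigid(p, tr) + matrix(rnorm(30, sd = 0.01), 10, 3)
    fit <- kabsch_fit(p, q)
    orc <- oracle_rigid_fit(p, q)
    expect_lt(max(abs(fit$rotation - orc$rotation)), 1e-9)
    expect_lt(max(abs(fit$translation - orc$translation)), 1e-9)
  }
})

test_that("ICP recovers planted rigid transforms and decreases mean distance monotonically", {
  tm <- template_mesh(canal_template())
  src <- sample_mesh_points(tm, 400)

  # fixed point: source already on target
  reg0 <- icp_rigid(src, tm, max_iter = 10, tol = 1e-6)
  expect_lt(rotation_angle_deg(reg0$transform$rotation, diag(3)), 1e-3)
  expect_lt(sqrt(sum(reg0$transform$translation^2)), 1e-2)

  set.seed(21)
  for (rep in 1:3) {
    planted <- rigid_transform(rotation_about(rnorm(3), runif(1, -15, 15)),
                               runif(3, -5, 5))
    target <- apply_rigid(tm, planted)
    reg <- icp_rigid(src, target, max_iter = 80, tol = 1e-7)
    expect_lt(rotation_angle_deg(reg$transform$rotation, planted$rotation), 0.5)
    expect_lt(sqrt(sum((reg$transform$translation - planted$translation)^2)),
              0.1)
    expect_true(all(diff(reg$history) <= 1e-9))
  }

  expect_error(icp_rigid(matrix(c(0, 0, 0, 1, 1, 1, 2, 2, 2), 3, 3,
                                byrow = TRUE), tm),
               "degenerate")
})

test_that("surface metrics are invariant under a common rigid transform", {
  tpl <- canal_template()
  tm <- template_mesh(tpl)
  noisy <- tm
  set.seed(3)
  noisy$vertices <- noisy$vertices + matrix(rnorm(length(noisy$vertices),
                                                  sd = 0.2), ncol = 3)
  tr <- rigid_transform(rotation_about(c(2, -1, 1), 47), c(12, 3, -8))
  r0 <- surface_rmse(tm, noisy, samples = NULL)
  r1 <- surface_rmse(apply_rigid(tm, tr), apply_rigid(noisy, tr),
                     samples = NULL)
  expect_equal(r1, r0, tolerance = 1e-6)

  i0 <- mesh_iou(tm, noisy, 1)
  i1 <- mesh_iou(apply_rigid(tm, tr), apply_rigid(noisy, tr), 1)
  expect_lt(abs(i1 - i0), 0.02)  # voxel-level tolerance
})
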