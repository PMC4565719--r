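# Geometry kernel: mass properties, sphere fitting, proximity queries,
# transforms.

test_that("divergence-theorem mass properties are exact on closed forms", {
  cube <- box_mesh(center = c(0.5, 0.5, 0.5), dims = c(1, 1, 1))
  mp <- mass_properties(cube, density = 1000)
  expect_equal(mp$volume, 1)
  expect_equal(mp$mass, 0.001)
  expect_equal(mp$com, c(0.5, 0.5, 0.5))

  # sphere volume converges to 4/3 pi r^3 with subdivision
  errs <- vapply(c(16, 32, 64), function(n) {
    mp <- mass_properties(sphere_mesh(10, n_theta = n, n_phi = 2 * n))
    abs(mp$volume - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000)
  }, numeric(1))
  expect_lt(errs[3], 0.002)
  expect_true(all(diff(errs) < 0))
  mp <- mass_properties(sphere_mesh(10, n_theta = 64, n_phi = 128))
  expect_equal(mp$com, c(0, 0, 0), tolerance = 1e-10)
})

test_that("mass properties refuse open meshes and report open edge count", {
  cube <- box_mesh()
  open_cube <- tri_mesh(cube$vertices, cube$faces[-1, ])
  expect_false(is_watertight(open_cube))
  expect_error(mass_properties(open_cube), "3 open edge")
})

test_that("mesh volume agrees with an independent voxel/volume oracle", {
  blob <- blob_mesh(7)
  expect_true(is_watertight(blob))
  vol <- mass_properties(blob)$volume
  obj <- file.path(tempdir(), "blob-oracle.obj")
  write_mesh(blob, obj)
  out <- system2("python", c("-c", shQuote(sprintf(
    "import trimesh; m = trimesh.load('%s'); print(m.volume)", obj
  ))), stdout = TRUE, stderr = FALSE)
  oracle <- as.numeric(out[length(out)])
  expect_false(is.na(oracle))
  expect_equal(vol, oracle, tolerance = 1e-6)
})

test_that("volume is additive and CoM composes mass-weighted over disjoint parts", {
  a <- box_mesh(center = c(0, 0, 0), dims = c(2, 1, 1))
  b <- box_mesh(center = c(5, 1, 0), dims = c(1, 3, 2))
  mpa <- mass_properties(a)
  mpb <- mass_properties(b)
  both <- mass_properties(merge_meshes(a, b))
  expect_equal(both$volume, mpa$volume + mpb$volume)
  expect_equal(
    both$com,
    (mpa$mass * mpa$com + mpb$mass * mpb$com) / (mpa$mass + mpb$mass),
    tolerance = 1e-12
  )

  # the same composition property on seeded random blob pairs
  for (seed in 1:4) {
    set.seed(seed)
    b1 <- blob_mesh(seed)
    shift <- stats::runif(3, 4, 8)
    b2 <- apply_transform(blob_mesh(seed + 100), affine_transform(diag(3), shift))
    m1 <- mass_properties(b1)
    m2 <- mass_properties(b2)
    mc <- mass_properties(merge_meshes(b1, b2))
    expect_equal(mc$volume, m1$volume + m2$volume, tolerance = 1e-9)
    expect_equal(mc$com, (m1$mass * m1$com + m2$mass * m2$com) / (m1$mass + m2$mass),
      tolerance = 1e-9)
  }
})

test_that("mass properties are translation-equivariant and rotation-invariant in volume", {
  blob <- blob_mesh(3)
  mp <- mass_properties(blob)
  shifted <- apply_transform(blob, affine_transform(diag(3), c(3, -2, 7)))
  mps <- mass_properties(shifted)
  expect_equal(mps$volume, mp$volume, tolerance = 1e-12)
  expect_equal(mps$com, mp$com + c(3, -2, 7), tolerance = 1e-10)
  rot <- rotation_about(c(1, 2, 3), 37)
  mpr <- mass_properties(apply_transform(blob, rot))
  expect_equal(mpr$volume, mp$volume, tolerance = 1e-10)
})

test_that("sphere fit recovers exact spheres from full and partial coverage", {
  full <- noisy_sphere_points(100, c(1, 2, 3), 5, sigma = 0, seed = 2)
  fit <- fit_sphere(full)
  expect_equal(fit$center, c(1, 2, 3), tolerance = 1e-9)
  expect_equal(fit$radius, 5, tolerance = 1e-9)

  patch <- noisy_sphere_points(60, c(-2, 0.5, 4), 3, sigma = 0, seed = 3, cap_deg = 60)
  fitp <- fit_sphere(patch)
  expect_equal(fitp$center, c(-2, 0.5, 4), tolerance = 1e-9)
  expect_equal(fitp$radius, 3, tolerance = 1e-9)
})

test_that("sphere fit on noisy points matches a grid-search oracle", {
  n <- 200
  sigma <- 0.05
  pts <- noisy_sphere_points(n, c(1, -1, 2), 5, sigma = sigma, seed = 11)
  fit <- fit_sphere(pts)
  oracle <- r_grid_sphere(pts, colMeans(pts), half_width = 2)
  # both land within a sigma/sqrt(n)-scaled ball of the truth and of each other
  bound <- 6 * sigma / sqrt(n)
  expect_lt(sqrt(sum((fit$center - c(1, -1, 2))^2)), bound)
  expect_lt(sqrt(sum((fit$center - oracle$center)^2)), bound)
  expect_lt(fit$rms, oracle$rms * 1.05)
})

test_that("sphere fit rejects degenerate input", {
  flat <- cbind(stats::runif(20), stats::runif(20), 0)
  expect_error(fit_sphere(flat), "degenerate|coplanar")
  expect_error(fit_sphere(matrix(1, 3, 3)), "at least 4")
})

test_that("min_distance matches closed forms and the brute-force oracle", {
  a <- box_mesh(center = c(0, 0, 0), dims = c(1, 1, 1))
  b <- box_mesh(center = c(1.5, 0, 0), dims = c(1, 1, 1))
  expect_equal(min_distance(a, b), 0.5, tolerance = 1e-12)
  expect_equal(min_distance(a, a), 0)

  m1 <- blob_mesh(21, coarse = TRUE)
  m2 <- apply_transform(blob_mesh(22, coarse = TRUE),
    affine_transform(diag(3), c(3.5, 0.5, -0.5)))
  d <- min_distance(m1, m2)
  expect_equal(min_distance(m2, m1), d, tolerance = 1e-12)
  expect_equal(d, r_mesh_min_dist(m1, m2), tolerance = 1e-4)
})

test_that("distance is zero exactly when meshes intersect", {
  a <- box_mesh(center = c(0, 0, 0), dims = c(1, 1, 1))
  overlapping <- box_mesh(center = c(0.5, 0, 0), dims = c(1, 1, 1))
  expect_true(intersects(a, overlapping))
  expect_equal(min_distance(a, overlapping), 0)
  separated <- box_mesh(center = c(2, 0, 0), dims = c(1, 1, 1))
  expect_false(intersects(a, separated))
  expect_gt(min_distance(a, separated), 0)
  # containment counts as collision even though the surfaces never touch
  big <- sphere_mesh(3)
  expect_true(intersects(a, big))
  expect_true(intersects(big, a))
  expect_gt(min_distance(a, big), 0)
  expect_true(contains_mesh(big, a))
  expect_false(contains_mesh(a, big))
})

test_that("transforms preserve orientation semantics", {
  blob <- blob_mesh(5)
  mp <- mass_properties(blob)
  expect_equal(
    mass_properties(apply_transform(blob, affine_transform(diag(3))))$volume,
    mp$volume
  )
  scaled <- apply_transform(blob, affine_transform(2 * diag(3)))
  expect_equal(mass_properties(scaled)$volume, 8 * mp$volume, tolerance = 1e-10)
  mirrored <- apply_transform(blob, affine_transform(diag(c(-1, 1, 1))))
  mpm <- mass_properties(mirrored)  # would error if orientation flipped
  expect_equal(mpm$volume, mp$volume, tolerance = 1e-10)
  expect_error(affine_transform(matrix(0, 3, 3)), "singular")
  tr <- affine_transform(matrix(c(1, 0, 0, 1, 1, 0, 0, 0, 1), 3), c(1, 2, 3))
  inv <- invert_transform(tr)
  round_trip <- compose_transforms(inv, tr)
  expect_equal(round_trip$linear, diag(3), tolerance = 1e-12)
  expect_equal(round_trip$translation, c(0, 0, 0), tolerance = 1e-12)
})
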