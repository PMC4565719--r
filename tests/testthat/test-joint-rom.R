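# Collision-based joint mobility: ACS construction, joint-space offsets,
# single-axis collision sweeps and the mobility table.

test_that("build_acs fits the joint centre and orthonormalises the hints", {
  fx <- make_socket_joint()
  # exact spherical head: take a cap of head vertices as the joint surface
  head_pts <- fx$bone$vertices[seq_len(200), ]
  head_pts <- head_pts[abs(rowSums(head_pts^2) - 1) < 1e-9, ]
  acs <- build_acs(head_pts, long_axis = c(1, 0, 0), up = c(0, 1, 0),
    cranial = c(0, 0, 1))
  expect_equal(acs$origin, c(0, 0, 0), tolerance = 1e-9)

  hints <- joint_acs(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  expect_equal(hints$x, c(0, 1, 0))
  expect_equal(hints$y, c(0, 0, 1))
  expect_equal(hints$z, c(1, 0, 0))

  skew <- joint_acs(c(0, 0, 0), c(1, 0, 0), c(0.3, 1, 0), c(0.1, 0.2, 1))
  # Gram-Schmidt with x first: x exact, y = normalised residual of the hint
  expect_equal(skew$x, c(1, 0, 0))
  expect_equal(skew$y, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(skew$z, c(0, 0, 1), tolerance = 1e-12)
  M <- cbind(skew$x, skew$y, skew$z)
  expect_equal(crossprod(M), diag(3), tolerance = 1e-12)
  expect_equal(det(M), 1, tolerance = 1e-12)
  expect_error(joint_acs(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, -1)),
    "left-handed")
})

test_that("joint space translates the bone and its rotation centre outward", {
  fx <- make_socket_joint()
  p0 <- apply_joint_space(fx$bone, fx$acs, fx$socket_center, 0)
  expect_equal(p0$bone$vertices, fx$bone$vertices)
  expect_equal(p0$acs$origin, fx$acs$origin)

  p1 <- apply_joint_space(fx$bone, fx$acs, fx$socket_center, 1)
  expect_equal(p1$bone$vertices - fx$bone$vertices,
    matrix(rep(c(0.1, 0, 0), each = nrow(fx$bone$vertices)), ncol = 3),
    tolerance = 1e-12)
  expect_equal(p1$acs$origin, c(0.1, 0, 0))

  # pushing out of a convex cup never decreases clearance
  d0 <- min_distance(fx$girdle, p0$bone)
  d1 <- min_distance(fx$girdle, p1$bone)
  expect_gte(d1, d0)
  expect_error(apply_joint_space(fx$bone, fx$acs, fx$acs$origin, 1), "coincide")
})

test_that("an unconstrained bone sweeps to the cap and a colliding pose returns zero", {
  fx <- make_socket_joint()
  empty_girdle <- box_mesh(center = c(50, 50, 50), dims = c(1, 1, 1))
  cfg <- sweep_config(increment = 5, limit_lar = 360, limit_other = 180)
  expect_equal(
    as.numeric(sweep_to_collision(empty_girdle, fx$bone, fx$acs, "z", 1, cfg)), 180)
  expect_equal(
    as.numeric(sweep_to_collision(empty_girdle, fx$bone, fx$acs, "x", 1, cfg)), 360)

  # bone starting in collision: flagged zero
  sunk <- apply_transform(fx$bone, affine_transform(diag(3), c(-0.2, 0, 0)))
  res <- sweep_to_collision(fx$girdle, sunk, fx$acs, "z", 1, cfg)
  expect_equal(as.numeric(res), 0)
  expect_true(attr(res, "ref_collision"))
})

test_that("sweep agrees with closed-form rim contact and a 10x finer sweep", {
  fx <- make_socket_joint()
  inc <- 0.5
  cfg <- sweep_config(increment = inc, joint_spaces = c(0, 1.5))
  fine <- sweep_config(increment = inc / 10)
  for (s in c(0, 1.5)) {
    placed <- apply_joint_space(fx$bone, fx$acs, fx$socket_center, s)
    predicted <- predicted_contact_angle(fx, s)
    for (d in list(c("z", 1), c("z", -1), c("y", 1))) {
      coarse <- as.numeric(sweep_to_collision(
        fx$girdle, placed$bone, placed$acs, d[1], as.numeric(d[2]), cfg))
      exact <- as.numeric(sweep_to_collision(
        fx$girdle, placed$bone, placed$acs, d[1], as.numeric(d[2]), fine))
      expect_lte(abs(coarse - exact), inc)
      expect_lte(abs(coarse - predicted), inc)
    }
  }
})

test_that("LAR limits are symmetric for a laterally symmetric crest and lip", {
  fx <- make_socket_joint(lip = TRUE)
  # dorsal crest on the shaft makes LAR finite; fixture symmetric in y.
  # sized so its corners clear the lip at the reference pose but sweep into
  # it under rotation about the long axis
  crest <- box_mesh(center = c(0.55, 0, 0.55), dims = c(1.0, 0.9, 1.0))
  bone <- merge_meshes(fx$bone, crest)
  cfg <- sweep_config(increment = 0.5, joint_spaces = 0)
  cw <- as.numeric(sweep_to_collision(fx$girdle, bone, fx$acs, "x", -1, cfg))
  ccw <- as.numeric(sweep_to_collision(fx$girdle, bone, fx$acs, "x", +1, cfg))
  expect_lt(cw, 360)
  expect_equal(cw, ccw)
})

test_that("the mobility table is monotone in joint space and shaped like the study table", {
  fx <- make_socket_joint(lip = TRUE)
  cfg <- sweep_config(increment = 1, joint_spaces = seq(0, 2.5, by = 0.5))
  tbl <- rom_table(fx$girdle, fx$bone, fx$acs, fx$socket_center, cfg)
  expect_equal(nrow(tbl), 6)
  expect_named(tbl, c("joint_space_mm", "adduction", "abduction", "protraction",
    "retraction", "lar_cw", "lar_ccw", "ref_collision"))
  for (col in c("adduction", "abduction", "protraction", "retraction",
    "lar_cw", "lar_ccw")) {
    expect_true(all(diff(tbl[[col]]) >= 0))
  }
  # asymmetric dorsal lip: protraction blocked well before retraction
  expect_true(all(tbl$protraction < tbl$retraction))
  expect_false(any(tbl$ref_collision))

  # single-entry joint-space list gives a single row
  one <- rom_table(fx$girdle, fx$bone, fx$acs, fx$socket_center,
    sweep_config(increment = 2, joint_spaces = 1.5))
  expect_equal(nrow(one), 1)

  # determinism: identical inputs give identical tables
  tbl2 <- rom_table(fx$girdle, fx$bone, fx$acs, fx$socket_center, cfg)
  expect_identical(tbl, tbl2)
})
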