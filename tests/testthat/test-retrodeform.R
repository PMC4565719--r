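# Rule-based retrodeformation: orthogonality restoration (rule 1),
# round-section decompression (rule 2), and the reciprocal cross-check.

test_that("rule 1 is the identity on an already-orthonormal triad", {
  sk <- make_skull()
  r <- restore_orthogonality(sk, axis_triad())
  expect_equal(r$transform$linear, diag(3), tolerance = 1e-12)
  expect_equal(r$transform$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(r$mesh$vertices, sk$vertices, tolerance = 1e-12)
})

test_that("rule 1 inverts a known shear and restores bilateral symmetry", {
  sk <- make_skull()
  for (seed in c(1, 7, 31)) {
    S <- random_shear(seed)
    d <- distort(sk, S)  # shear only, no compaction
    sheared_triad <- axis_triad(
      c(0, 0, 0),
      as.numeric(S$linear %*% c(1, 0, 0)),
      as.numeric(S$linear %*% c(0, 1, 0)),
      as.numeric(S$linear %*% c(0, 0, 1))
    )
    r <- restore_orthogonality(d$mesh, sheared_triad)
    expect_equal(r$transform$linear, solve(S$linear), tolerance = 1e-9)
    rms <- sqrt(mean((r$mesh$vertices - sk$vertices)^2))
    expect_lt(rms, 1e-9)
    # triad orthonormal after correction
    M <- r$transform$linear %*% sheared_triad$M
    expect_equal(crossprod(M), diag(3), tolerance = 1e-9)
    # sagittal symmetry restored: reflected vertex cloud matches the original
    refl <- r$mesh$vertices %*% diag(c(1, -1, 1))
    d2 <- apply(refl, 1, function(p) {
      min(colSums((t(r$mesh$vertices) - p)^2))
    })
    expect_lt(sqrt(max(d2)), 1e-9)
  }
})

test_that("rule 1 inverts a pure rotation and preserves volume", {
  sk <- make_skull()
  R <- rotation_about(c(0.3, 1, 0.2), 25)
  d <- apply_transform(sk, R)
  tri <- axis_triad(c(0, 0, 0),
    as.numeric(R$linear %*% c(1, 0, 0)),
    as.numeric(R$linear %*% c(0, 1, 0)),
    as.numeric(R$linear %*% c(0, 0, 1)))
  r <- restore_orthogonality(d, tri)
  expect_equal(r$transform$linear, t(R$linear), tolerance = 1e-9)
  expect_equal(mass_properties(r$mesh)$volume, mass_properties(sk)$volume,
    tolerance = 1e-10)
})

test_that("restore_orthogonality rejects degenerate triads", {
  expect_error(axis_triad(e_rc = c(1, 0, 0), e_ll = c(2, 0, 0)), "linearly dependent")
  sk <- make_skull()
  skew <- axis_triad(e_rc = c(1, 0.1, 0), e_ll = c(0, 1, 0))
  expect_error(restore_orthogonality(sk, axis_triad(), target = skew), "orthonormal")
})

test_that("roundness measurement matches closed forms and a brute-force extent oracle", {
  vert <- make_vertebra(radius = 1.2, length = 2.5)
  sr <- measure_roundness(vert, c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(sr$ratio, 1, tolerance = 1e-9)
  expect_equal(sr$lateral_diameter, 2.4, tolerance = 1e-3)

  flat <- distort(vert, dv_compression = 0.6)$mesh
  sr_f <- measure_roundness(flat, c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(sr_f$ratio, 0.6, tolerance = 1e-9)

  # arbitrary convex section: extents equal the brute-force vertex-pair oracle
  blob <- blob_mesh(13)
  pts <- section_points(blob, c(0, 0, 0.1), c(0.2, 0.1, 1))
  n <- c(0.2, 0.1, 1); n <- n / sqrt(sum(n^2))
  lat <- c(1, 0, 0) - sum(c(1, 0, 0) * n) * n; lat <- lat / sqrt(sum(lat^2))
  sr_b <- measure_roundness(blob, c(0, 0, 0.1), c(0.2, 0.1, 1), c(1, 0, 0))
  oracle_ext <- max(outer(as.numeric(pts %*% lat), as.numeric(pts %*% lat), "-"))
  expect_equal(sr_b$lateral_diameter, oracle_ext, tolerance = 1e-12)

  expect_error(measure_roundness(vert, c(100, 0, 0), c(1, 0, 0), c(0, 1, 0)),
    "does not intersect")
})

test_that("rule 2 recovers a known dorso-ventral compression exactly", {
  vert <- make_vertebra()
  d <- distort(vert, dv_compression = 0.6)
  sr <- measure_roundness(d$mesh, c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  r2 <- decompress_round(d$mesh, sr)
  expect_equal(r2$scale, 1 / 0.6, tolerance = 1e-9)
  expect_equal(r2$roundness$ratio, 1, tolerance = 1e-6)
  expect_lt(sqrt(mean((r2$mesh$vertices - vert$vertices)^2)), 1e-9)
  # extents perpendicular to the stretch axis are untouched
  expect_equal(mesh_extents(r2$mesh)[1:2], mesh_extents(d$mesh)[1:2],
    tolerance = 1e-12)

  # already-round section: identity
  sr0 <- measure_roundness(vert, c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  r0 <- decompress_round(vert, sr0)
  expect_equal(r0$scale, 1, tolerance = 1e-9)
})

test_that("seeded distortion round trips recover fixtures below 1e-9 RMS", {
  for (seed in c(2, 12, 77)) {
    vert <- make_vertebra(radius = 1 + seed / 100, length = 2 + seed / 50)
    set.seed(seed)
    comp <- stats::runif(1, 0.5, 0.9)
    d <- distort(vert, random_shear(seed + 1, 0.2), dv_compression = comp)
    undone <- apply_transform(d$mesh, d$inverse)
    expect_lt(sqrt(mean((undone$vertices - vert$vertices)^2)), 1e-9)
    # rule-based recovery: rule 1 with the distorted triad undoes shear,
    # then rule 2 undoes the compaction
    tri <- axis_triad(c(0, 0, 0),
      as.numeric(d$transform$linear %*% c(1, 0, 0)) / 1,
      as.numeric(d$transform$linear %*% c(0, 1, 0)),
      as.numeric(d$transform$linear %*% c(0, 0, 1)))
    # normalise: rule 1 maps the (sheared, compressed) axes to orthonormal,
    # which also undoes the compression scale embedded in the triad
    r1 <- restore_orthogonality(d$mesh, tri)
    expect_lt(sqrt(mean((r1$mesh$vertices - vert$vertices)^2)), 1e-9)
  }
})

test_that("the reciprocal cross-check passes at the true rate and fails off by 20%", {
  vert <- make_vertebra()
  true_ext <- mesh_extents(vert)
  # upright specimen flattened dorso-ventrally; isolated one cranio-caudally
  comp <- 0.6
  upright <- distort(vert, dv_compression = comp)$mesh
  isolated <- distort(vert, dv_compression = comp, dv_dir = c(1, 0, 0))$mesh
  sr <- measure_roundness(upright, c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  scale <- decompress_round(upright, sr)$scale
  chk <- cross_check_reciprocal(isolated, c(1, 0, 0), scale, true_ext)
  expect_true(chk$pass)
  expect_equal(max(chk$rel_diff), 0, tolerance = 1e-9)
  expect_false(cross_check_reciprocal(isolated, c(1, 0, 0), scale * 1.2, true_ext)$pass)
  expect_false(cross_check_reciprocal(isolated, c(1, 0, 0), scale * 0.8, true_ext)$pass)
  # trivial self-check at scale 1
  chk1 <- cross_check_reciprocal(vert, c(1, 0, 0), 1, true_ext)
  expect_true(chk1$pass)
  # mismatched fixtures report hand-computable discrepancies
  wrong <- cross_check_reciprocal(isolated, c(1, 0, 0), scale * 1.2, true_ext)
  expect_equal(wrong$extents[1], true_ext[1] * 1.2, tolerance = 1e-9)
})
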