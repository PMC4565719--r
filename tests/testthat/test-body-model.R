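# Octagonal hoops, lofting, outline variants, cavity subtraction, and the
# whole-body combination rules.

test_that("octagon vertices realise the named profiles", {
  h <- hoop_profile(c(0, 0, 0), axis = c(1, 0, 0), up = c(0, 0, 1), a = 1, b = 1, k = 1)
  oct <- make_octagon(h)
  expect_equal(dim(oct), c(8, 3))
  expect_equal(oct[, 1], rep(0, 8))             # lies in the hoop plane
  r <- sqrt(rowSums(oct^2))
  expect_equal(r, rep(1, 8), tolerance = 1e-12)  # k = 1: inscribed in unit circle
  expect_equal(shoelace_area(oct[, 2:3]), 2 * sqrt(2), tolerance = 1e-12)

  hsq <- hoop_profile(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1), 1, 1, sqrt(2))
  expect_equal(shoelace_area(make_octagon(hsq)[, 2:3]), 4, tolerance = 1e-12)

  # intermediate profile sits strictly between ellipse-octagon and rectangle
  hmid <- hoop_profile(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1), 2, 1, 1.207)
  a_mid <- shoelace_area(make_octagon(hmid)[, 2:3])
  a_ell <- shoelace_area(octagon_2d(2, 1, 1))
  expect_gt(a_mid, a_ell)
  expect_lt(a_mid, 4 * 2 * 1)
  expect_equal(a_mid, octagon_area(2, 1, 1.207), tolerance = 1e-12)
})

test_that("octagon winding is counter-clockwise viewed along the hoop axis", {
  h <- hoop_profile(c(0, 0, 0), axis = c(0, 1, 0), up = c(1, 0, 0), a = 2, b = 1)
  oct <- make_octagon(h)
  # signed area in the (lat, up) frame must be positive
  lat <- c(0, 0, 1)  # up x axis = (1,0,0) x (0,1,0) for this hoop
  p2 <- cbind(oct %*% lat, oct %*% c(1, 0, 0))
  n <- nrow(p2)
  j <- c(2:n, 1)
  signed <- sum(p2[, 1] * p2[j, 2] - p2[j, 1] * p2[, 2]) / 2
  expect_gt(signed, 0)
})

test_that("lofted prisms and tapers reproduce closed-form volumes", {
  r <- 1.5
  L <- 10
  prism <- segment_spec("p", "trunk", toy_hoops_test(0, L, r, r, r, r, 2, k = sqrt(2)))
  expect_true(is_watertight(loft(prism)))
  expect_equal(mass_properties(loft(prism))$volume, 4 * r^2 * L, tolerance = 1e-12)

  octo <- segment_spec("o", "trunk", toy_hoops_test(0, L, r, r, r, r, 12, k = 1))
  expect_equal(mass_properties(loft(octo))$volume, 2 * sqrt(2) * r^2 * L,
    tolerance = 1e-12)

  cone <- segment_spec("c", "trunk", toy_hoops_test(0, L, r, r * 1e-3, r, r * 1e-3, 16))
  vol <- mass_properties(loft(cone))$volume
  expect_equal(vol, r_slice_volume(r, r * 1e-3, r, r * 1e-3, 1, L), tolerance = 1e-4)
})

test_that("loft volume converges to the smooth-taper limit as hoops increase", {
  # curved (quadratic) radius profile: linear interpolation between hoops
  # under-resolves it, and the error must shrink at order >= 1 in spacing
  prof <- function(t) 1 + 0.8 * t * (1 - t) * 4
  target <- integrate(function(t) 2 * sqrt(2) * prof(t)^2 * 10, 0, 1)$value
  errs <- vapply(c(4, 8, 16, 32), function(n) {
    t <- seq(0, 1, length.out = n)
    hoops <- lapply(t, function(ti) {
      hoop_profile(c(10 * ti, 0, 0), c(1, 0, 0), c(0, 0, 1), prof(ti), prof(ti))
    })
    seg <- segment_spec("s", "trunk", hoops)
    abs(mass_properties(loft(seg))$volume - target)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(orders >= 1))
})

test_that("outline variants scale radii and diagonal factors as specified", {
  h <- hoop_profile(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1), 1, 1)
  seg <- segment_spec("s", "trunk", list(
    h, hoop_profile(c(5, 0, 0), c(1, 0, 0), c(0, 0, 1), 1, 1)
  ))
  mn <- apply_variant(seg, "min")
  mx <- apply_variant(seg, "max")
  expect_equal(mn$hoops[[1]]$a, 1)
  expect_equal(mn$hoops[[1]]$k, 0.8535534, tolerance = 1e-7)
  expect_equal(mx$hoops[[1]]$a, 1.2)
  expect_equal(mx$hoops[[1]]$b, 1.2)
  expect_equal(mx$hoops[[1]]$k, 1.2071068, tolerance = 1e-7)
  expect_equal(mx$hoops[[1]]$center, h$center)

  # volume ratio for a prism = radial^2 times the octagon area ratio
  vr <- mass_properties(loft(mx))$volume / mass_properties(loft(mn))$volume
  a_ratio <- shoelace_area(octagon_2d(1, 1, octagon_k("ellipse-square"))) /
    shoelace_area(octagon_2d(1, 1, octagon_k("ellipse-diamond")))
  expect_equal(vr, 1.2^2 * a_ratio, tolerance = 1e-10)
})

test_that("cavity subtraction matches explicit hollowed meshes", {
  outer <- box_mesh(center = c(0, 0, 0), dims = c(10, 10, 10))
  centred <- box_mesh(center = c(0, 0, 0), dims = c(2, 2, 2))
  mp <- subtract_cavities(mass_properties(outer), list(mass_properties(centred)))
  expect_equal(mp$volume, 992)
  expect_equal(mp$com, c(0, 0, 0), tolerance = 1e-12)

  off <- box_mesh(center = c(3, 1, -2), dims = c(2, 2, 2))
  mp_off <- subtract_cavities(mass_properties(outer), list(mass_properties(off)))
  # oracle: hollowed mesh = outer shell + inward-facing cavity surface
  inward <- off
  inward$faces <- inward$faces[, c(1, 3, 2)]
  hollow <- merge_meshes(outer, inward)
  mp_hollow <- mass_properties(hollow)
  expect_equal(mp_off$volume, mp_hollow$volume, tolerance = 1e-12)
  expect_equal(mp_off$com, mp_hollow$com, tolerance = 1e-12)
  expect_true(all(sign(mp_off$com) == -sign(c(3, 1, -2))))  # CoM moves away

  expect_equal(subtract_cavities(mass_properties(outer), list()),
    mass_properties(outer))
})

test_that("segment mass properties reject escaping cavities", {
  seg <- segment_spec("s", "trunk",
    toy_hoops_test(0, 10, 2, 2, 2, 2, 4),
    cavities = list(box_mesh(center = c(9.5, 0, 0), dims = c(3, 1, 1))))
  expect_error(segment_mass_properties(seg), "not fully contained")
})

test_that("total mass and whole-body CoM follow the summation rules", {
  expect_equal(total_mass(c(1, 2), c(2, 1)), 4)
  expect_equal(total_mass(numeric(0), integer(0)), 0)
  expect_equal(
    whole_body_com(c(1, 1), rbind(c(1, 0, 0), c(-1, 0, 0))),
    c(0, 0, 0)
  )
  # single segment degenerates to its own CoM
  expect_equal(whole_body_com(2, rbind(c(3, -1, 2))), c(3, -1, 2))
  expect_error(whole_body_com(0, rbind(c(0, 0, 0))), "positive")
  # mirrored pair: y cancels exactly, x/z double-weighted
  com <- whole_body_com(1, rbind(c(2, 5, 1)), counts = 2L, mirrored = TRUE)
  expect_identical(com[2], 0)
  expect_equal(com, c(2, 0, 1))
})

test_that("sensitivity report obeys the envelope ordering and symmetry", {
  body <- make_toy_body(hoops_per_segment = 5)
  rep <- sensitivity_report(body$segments)
  seg <- rep$segments
  for (s in unique(seg$segment[seg$variant != "single"])) {
    mx <- seg$mass_kg[seg$segment == s & seg$variant == "max"]
    mn <- seg$mass_kg[seg$segment == s & seg$variant == "min"]
    expect_gt(mx, mn)
  }
  wb <- rep$whole_body
  g <- function(m, col) wb[[col]][wb$model == m]
  expect_gte(g("max_overall", "mass_kg"), g("max_cranial", "mass_kg"))
  expect_gte(g("max_cranial", "mass_kg"), g("min_overall", "mass_kg"))
  expect_gte(g("max_overall", "mass_kg"), g("max_caudal", "mass_kg"))
  expect_gte(g("max_caudal", "mass_kg"), g("min_overall", "mass_kg"))
  expect_gte(g("max_cranial", "x_cm"), g("mean", "x_cm"))
  expect_gte(g("mean", "x_cm"), g("max_caudal", "x_cm"))
  expect_equal(wb$y_cm, rep(0, 5), tolerance = 1e-12)
})

test_that("a two-segment synthetic body matches a hand-computed combination", {
  # prism 1: 2sqrt(2)*1*1*10 cm^3 at x = 5; prism 2: 2sqrt(2)*2*1*4 at x = 12
  s1 <- segment_spec("s1", "trunk", toy_hoops_test(0, 10, 1, 1, 1, 1, 3))
  s2 <- segment_spec("s2", "tail", toy_hoops_test(10, 14, 2, 2, 1, 1, 3))
  m1 <- segment_mass_properties(s1)
  m2 <- segment_mass_properties(s2)
  v1 <- 2 * sqrt(2) * 10
  v2 <- 2 * sqrt(2) * 2 * 4
  expect_equal(m1$volume, v1, tolerance = 1e-12)
  expect_equal(m2$volume, v2, tolerance = 1e-12)
  m_tot <- total_mass(c(m1$mass, m2$mass))
  com <- whole_body_com(c(m1$mass, m2$mass), rbind(m1$com, m2$com))
  expect_equal(m_tot, (v1 + v2) * 1e-3, tolerance = 1e-12)
  expect_equal(com[1], (v1 * 5 + v2 * 12) / (v1 + v2), tolerance = 1e-10)
})
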