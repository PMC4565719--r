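# Procedural synthetic specimens with closed-form ground truth. These stand in
# for fossil material that is not machine-readably deposited: a segmented toy
# body with analytic volumes and centres of mass, parametric ball-and-socket
# joints whose first-contact angles have closed forms, symmetric vertebra and
# skull stand-ins, and known-distortion generators for retrodeformation
# round trips. Fixtures are generated at run time, never stored; identical
# parameters (and seed, where noise is involved) give identical output.

#' Analytic mass properties of a hoop segment
#'
#' Closed-form volume and centre of mass of a lofted hoop segment, assuming
#' hoop centres lie on a straight line and semi-axes/diagonal factor vary
#' linearly between consecutive hoops. The octagon cross-section area is
#' `2*sqrt(2)*k*a*b`, a polynomial in the interpolation parameter, so each
#' hoop-to-hoop piece integrates exactly. For prisms and uniformly scaled
#' tapers the lofted mesh encloses exactly this volume, independent of hoop
#' count.
#'
#' @param segment a [segment_spec()].
#' @return `mass_properties` (per single copy, cavities ignored).
#' @export
analytic_hoop_mass_properties <- function(segment) {
  stopifnot(inherits(segment, "segment_spec"))
  hoops <- segment$hoops
  vol <- 0
  mom <- c(0, 0, 0)
  for (i in seq_len(length(hoops) - 1L)) {
    h0 <- hoops[[i]]; h1 <- hoops[[i + 1L]]
    L <- sqrt(sum((h1$center - h0$center)^2))
    # p(t) = k(t) a(t) b(t), cubic in t on [0, 1]
    dk <- h1$k - h0$k; da <- h1$a - h0$a; db <- h1$b - h0$b
    c0 <- h0$k * h0$a * h0$b
    c1 <- dk * h0$a * h0$b + h0$k * da * h0$b + h0$k * h0$a * db
    c2 <- dk * da * h0$b + dk * h0$a * db + h0$k * da * db
    c3 <- dk * da * db
    int_p <- c0 + c1 / 2 + c2 / 3 + c3 / 4
    int_tp <- c0 / 2 + c1 / 3 + c2 / 4 + c3 / 5
    v_i <- 2 * sqrt(2) * L * int_p
    mom <- mom + 2 * sqrt(2) * L * (h0$center * int_p + (h1$center - h0$center) * int_tp)
    vol <- vol + v_i
  }
  mass_properties_record(volume = vol, density = segment$density, com = mom / vol)
}

toy_hoops <- function(x0, x1, a0, a1, b0, b1, n, axis = c(1, 0, 0), up = c(0, 0, 1),
                      origin = c(0, 0, 0)) {
  t <- seq(0, 1, length.out = n)
  lapply(t, function(ti) {
    hoop_profile(
      center = origin + axis * (x0 + ti * (x1 - x0)),
      axis = axis, up = up,
      a = a0 + ti * (a1 - a0), b = b0 + ti * (b1 - b0)
    )
  })
}

#' Six-region toy body with analytic ground truth
#'
#' A segmented quadruped body at roughly the scale of the study animal
#' (~4 kg, ~85 cm nose to tail tip): prismatic trunk and neck, uniformly
#' tapered head and tail along the cranio-caudal x axis, and paired
#' cylindrical limb segments hanging ventrally, mirrored about the sagittal
#' plane. Every segment carries closed-form expected mass properties from
#' [analytic_hoop_mass_properties()].
#'
#' @param hoops_per_segment hoop count per segment (default 9).
#' @param trunk_scale multiplier on the trunk semi-axes (scaling law checks).
#' @return List with `segments` (list of [segment_spec()]) and `analytic`
#'   (data.frame of expected volume/mass/CoM per single copy).
#' @export
make_toy_body <- function(hoops_per_segment = 9, trunk_scale = 1) {
  n <- hoops_per_segment
  down <- c(0, 0, -1)
  segs <- list(
    segment_spec("head", "head",
      toy_hoops(38, 47, 3 * 0.999, 3 * 0.333, 2.4 * 0.999, 2.4 * 0.333, n,
        up = c(0, 0, 1))),
    segment_spec("neck", "neck", toy_hoops(30, 38, 2.4, 2.4, 2.2, 2.2, n)),
    segment_spec("trunk", "trunk",
      toy_hoops(0, 30, 5.2 * trunk_scale, 5.2 * trunk_scale,
        4.3 * trunk_scale, 4.3 * trunk_scale, n)),
    segment_spec("pectoral limb", "pectoral",
      lapply(seq(0, 1, length.out = n), function(t) {
        hoop_profile(c(27, 8.8, -2) + down * (12 * t), axis = down, up = c(1, 0, 0),
          a = 1.25, b = 1.25)
      }), count = 2L),
    segment_spec("pelvic limb", "pelvic",
      lapply(seq(0, 1, length.out = n), function(t) {
        hoop_profile(c(0, 10.5, -0.5) + down * (14 * t), axis = down, up = c(1, 0, 0),
          a = 1.55, b = 1.55)
      }), count = 2L),
    # tail runs caudally, so its loft axis is -x with distances 0..38
    segment_spec("tail", "tail",
      toy_hoops(0, 38, 3 * 0.999, 3 * 0.12, 3 * 0.999, 3 * 0.12, n,
        axis = c(-1, 0, 0), up = c(0, 0, 1)))
  )
  analytic <- do.call(rbind, lapply(segs, function(s) {
    mp <- analytic_hoop_mass_properties(s)
    data.frame(
      segment = s$name, region = s$region, count = s$count,
      volume_cm3 = mp$volume, mass_kg = mp$mass,
      x_cm = mp$com[1], y_cm = mp$com[2], z_cm = mp$com[3]
    )
  }))
  list(segments = segs, analytic = analytic)
}

cup_mesh <- function(cup_radius, thickness, rim_half_angle_deg, center = c(0, 0, 0),
                     n_alpha = 20, n_phi = 64) {
  # spherical-shell cup, axis along x, deep pole at -x, opening towards +x;
  # rim_half_angle measured from the deep pole (90 = hemisphere)
  stopifnot(rim_half_angle_deg > 0, rim_half_angle_deg < 180)
  psi <- pi - rim_half_angle_deg * pi / 180  # polar angle of the rim from +x
  alpha <- seq(psi, pi, length.out = n_alpha + 1)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  dirs <- function(al) cbind(cos(al), sin(al) * cos(phi), sin(al) * sin(phi))
  rings_in <- lapply(alpha[-length(alpha)], function(al) dirs(al) * cup_radius)
  rings_out <- lapply(alpha[-length(alpha)], function(al) dirs(al) * (cup_radius + thickness))
  nr <- length(rings_in)
  v <- do.call(rbind, c(rings_in, rings_out))
  v <- rbind(v, c(-cup_radius, 0, 0), c(-(cup_radius + thickness), 0, 0))
  pole_in <- nrow(v) - 1L
  pole_out <- nrow(v)
  idx <- function(block, i, j) {
    (if (block == 0L) 0L else nr * n_phi) + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  }
  faces <- list()
  band <- function(i, inner) {
    # quad band between ring i and ring i+1 (or pole fan at the last ring)
    for (j in seq_len(n_phi)) {
      a <- idx(if (inner) 0L else 1L, i, j)
      b <- idx(if (inner) 0L else 1L, i, j + 1)
      if (i < nr) {
        c_ <- idx(if (inner) 0L else 1L, i + 1, j)
        d <- idx(if (inner) 0L else 1L, i + 1, j + 1)
        if (inner) {
          faces[[length(faces) + 1L]] <<- c(a, c_, b)
          faces[[length(faces) + 1L]] <<- c(b, c_, d)
        } else {
          faces[[length(faces) + 1L]] <<- c(a, b, c_)
          faces[[length(faces) + 1L]] <<- c(b, d, c_)
        }
      } else {
        p <- if (inner) pole_in else pole_out
        if (inner) {
          faces[[length(faces) + 1L]] <<- c(a, p, b)
        } else {
          faces[[length(faces) + 1L]] <<- c(a, b, p)
        }
      }
    }
  }
  for (i in seq_len(nr)) {
    band(i, inner = TRUE)
    band(i, inner = FALSE)
  }
  for (j in seq_len(n_phi)) {  # rim annulus at alpha = psi
    a <- idx(0L, 1, j); b <- idx(0L, 1, j + 1)
    c_ <- idx(1L, 1, j); d <- idx(1L, 1, j + 1)
    faces[[length(faces) + 1L]] <- c(a, b, c_)
    faces[[length(faces) + 1L]] <- c(b, d, c_)
  }
  m <- tri_mesh(sweep(v, 2, -center), do.call(rbind, faces))
  if (signed_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Parametric ball-and-socket joint fixture
#'
#' A spherical humeral/femoral head with a cylindrical shaft along +x, seated
#' concentrically in a spherical-shell cup (glenoid/acetabulum stand-in)
#' opening towards +x, optionally with a protruding bony lip over the cranial
#' (+z) rim sector. In the reference pose the shaft (long axis, ACS x) points
#' laterally out of the cup, ACS y is up and ACS z cranial.
#'
#' For the no-lip cup the first bone-bone contact during any single-axis
#' rotation away from the reference pose is the shaft cylinder meeting the
#' inner rim circle, which has the closed form implemented in
#' [predicted_contact_angle()].
#'
#' @param head_radius head sphere radius (cm).
#' @param neck_radius shaft cylinder radius (cm); must be < `head_radius`.
#' @param cup_radius inner cup radius (cm); > `head_radius` so the reference
#'   pose is collision-free.
#' @param cup_thickness shell thickness (cm).
#' @param rim_half_angle_deg angular extent of the cup from its deep pole
#'   (90 = hemisphere), in (0, 180).
#' @param shaft_length shaft length from the head centre (cm).
#' @param lip add a bony lip over the cranial rim sector?
#' @param lip_height lip protrusion height above the rim plane (cm).
#' @param lip_width lip width along y (cm).
#' @param resolution angular resolution multiplier (1 = default meshing).
#' @return List with `girdle`, `bone` ([tri_mesh()]), `acs` ([joint_acs()]
#'   at the head centre), `socket_center` (push-out direction anchor),
#'   `params`.
#' @export
make_socket_joint <- function(head_radius = 1, neck_radius = 0.35, cup_radius = 1.05,
                              cup_thickness = 0.25, rim_half_angle_deg = 90,
                              shaft_length = 5, lip = FALSE, lip_height = 0.8,
                              lip_width = 1.0, resolution = 1) {
  if (neck_radius >= head_radius) stop("neck radius must be smaller than head radius")
  if (cup_radius <= head_radius) stop("cup radius must exceed head radius")
  if (rim_half_angle_deg <= 0 || rim_half_angle_deg >= 180) {
    stop("rim half-angle must lie in (0, 180) degrees")
  }
  n_phi <- max(16L, as.integer(round(64 * resolution / 4)) * 4L)
  n_alpha <- max(6L, as.integer(round(20 * resolution)))
  girdle <- cup_mesh(cup_radius, cup_thickness, rim_half_angle_deg,
    n_alpha = n_alpha, n_phi = n_phi)
  if (lip) {
    psi <- pi - rim_half_angle_deg * pi / 180
    rim_x <- cup_radius * cos(psi)
    rim_r <- cup_radius * sin(psi)
    # protrudes laterally past the rim plane, rooted in the cup shell, and
    # clears the head sphere so the reference pose stays collision-free
    z0 <- max(rim_r, head_radius) + 0.05
    lip_box <- box_mesh(
      center = c(rim_x - 0.1 + (lip_height + 0.1) / 2, 0, z0 + 0.25),
      dims = c(lip_height + 0.1, lip_width, 0.5)
    )
    girdle <- merge_meshes(girdle, lip_box)
  }
  head <- sphere_mesh(head_radius, c(0, 0, 0),
    n_theta = max(8L, as.integer(24 * resolution)),
    n_phi = max(16L, as.integer(round(48 * resolution / 4)) * 4L))
  shaft <- cylinder_mesh(neck_radius, shaft_length, base = c(0, 0, 0), axis = c(1, 0, 0),
    n = max(16L, as.integer(round(48 * resolution / 4)) * 4L))
  bone <- merge_meshes(head, shaft)
  acs <- joint_acs(c(0, 0, 0), x_axis = c(1, 0, 0), y_axis = c(0, 1, 0),
    z_axis = c(0, 0, 1))
  list(
    girdle = girdle, bone = bone, acs = acs,
    socket_center = c(-cup_radius / 2, 0, 0),
    params = list(
      head_radius = head_radius, neck_radius = neck_radius, cup_radius = cup_radius,
      cup_thickness = cup_thickness, rim_half_angle_deg = rim_half_angle_deg,
      shaft_length = shaft_length, lip = lip
    )
  )
}

#' Closed-form first-contact angle for the no-lip socket fixture
#'
#' Rotating the shaft about any axis perpendicular to it through the (joint
#' space offset) head centre, the first contact is the shaft cylinder
#' touching the inner rim circle of the cup. With the head centre pushed out
#' by `s` mm along +x, the in-plane rim point sits at angle
#' `atan2(R sin(psi), R cos(psi) - d)` from the shaft axis (`psi` the rim
#' polar angle from +x, `R` the cup radius, `d = s/10` cm) and contact occurs
#' one cylinder half-width earlier: `theta* = alpha0 - asin(r_neck / |rim -
#' centre|)`.
#'
#' @param joint a [make_socket_joint()] result (no lip).
#' @param s joint space in mm.
#' @return First-contact angle in degrees.
#' @export
predicted_contact_angle <- function(joint, s = 0) {
  p <- joint$params
  psi <- pi - p$rim_half_angle_deg * pi / 180
  d <- s / 10
  R <- p$cup_radius
  v <- c(R * cos(psi) - d, R * sin(psi))
  alpha0 <- atan2(v[2], v[1])
  (alpha0 - asin(p$neck_radius / sqrt(sum(v^2)))) * 180 / pi
}

#' Cylindrical vertebra stand-in
#'
#' A circular-section cylinder along the cranio-caudal (x) axis: a reference
#' element whose centrum cross-section is exactly round, for rule-2
#' retrodeformation fixtures.
#'
#' @param radius centrum radius (cm).
#' @param length centrum length (cm).
#' @param n circumferential resolution.
#' @return Watertight [tri_mesh()].
#' @export
make_vertebra <- function(radius = 1.2, length = 2.5, n = 64) {
  cylinder_mesh(radius, length, base = c(-length / 2, 0, 0), axis = c(1, 0, 0), n = n)
}

#' Bilaterally symmetric skull stand-in
#'
#' A braincase ellipsoid with a tapering snout, exactly symmetric about the
#' sagittal plane (y = 0): the fixture for shear-correction (rule 1) and
#' symmetry-restoration tests.
#'
#' @param length skull length (cm).
#' @param width skull width (cm).
#' @param height skull height (cm).
#' @return Watertight [tri_mesh()] (two closed components).
#' @export
make_skull <- function(length = 8, width = 5, height = 3.5) {
  braincase <- apply_transform(
    sphere_mesh(1, c(0, 0, 0), n_theta = 16, n_phi = 32),
    affine_transform(diag(c(length * 0.3, width / 2, height / 2)))
  )
  snout <- segment_spec("snout", "head", toy_hoops(
    length * 0.2, length * 0.75,
    width * 0.35 * 0.999, width * 0.35 * 0.25,
    height * 0.35 * 0.999, height * 0.35 * 0.25, 6
  ))
  merge_meshes(braincase, loft(snout))
}

#' Apply a known diagenetic distortion
#'
#' Composes a uniaxial compaction (scale `dv_compression` along `dv_dir`)
#' followed by a shear, and records the exact inverse so round trips can be
#' verified.
#'
#' @param mesh a [tri_mesh()].
#' @param shear an [affine_transform()] (identity by default).
#' @param dv_compression compaction factor in (0, 1].
#' @param dv_dir compaction direction (default dorso-ventral z).
#' @return List with `mesh` (distorted), `transform`, `inverse`.
#' @export
distort <- function(mesh, shear = affine_transform(), dv_compression = 1,
                    dv_dir = c(0, 0, 1)) {
  stopifnot(inherits(mesh, "tri_mesh"), dv_compression > 0, dv_compression <= 1)
  u <- dv_dir / sqrt(sum(dv_dir^2))
  comp <- affine_transform(diag(3) + (dv_compression - 1) * tcrossprod(u))
  tr <- compose_transforms(shear, comp)
  list(mesh = apply_transform(mesh, tr), transform = tr, inverse = invert_transform(tr))
}

#' Random shear transform (seeded)
#'
#' Small random off-diagonal shear for round-trip tests.
#'
#' @param seed RNG seed.
#' @param magnitude maximal off-diagonal entry (default 0.3).
#' @return An [affine_transform()].
#' @export
random_shear <- function(seed, magnitude = 0.3) {
  set.seed(seed)
  S <- diag(3)
  S[upper.tri(S)] <- stats::runif(3, -magnitude, magnitude)
  affine_transform(S)
}

#' Points on a sphere with seeded Gaussian surface noise
#'
#' @param n number of points.
#' @param center sphere centre (cm).
#' @param radius sphere radius (cm).
#' @param sigma radial Gaussian noise sd (cm).
#' @param seed RNG seed.
#' @param cap_deg restrict to a spherical cap of this half-angle about +z
#'   (180 = full sphere).
#' @return n x 3 matrix.
#' @export
noisy_sphere_points <- function(n, center = c(0, 0, 0), radius = 1, sigma = 0,
                                seed = 1, cap_deg = 180) {
  set.seed(seed)
  cosmin <- cos(cap_deg * pi / 180)
  z <- stats::runif(n, cosmin, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  u <- cbind(s * cos(phi), s * sin(phi), z)
  r <- radius + if (sigma > 0) stats::rnorm(n, 0, sigma) else 0
  sweep(u * r, 2, -center)
}
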