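# Octagonal-hoop body outline modelling: lofted segments, outline variants,
# cavity subtraction, and the whole-body mass / centre-of-mass combinatorics.
#
# Coordinate convention (system frame): x cranio-caudal (cranial positive),
# y medio-lateral, z dorso-ventral; origin midway between the hips in the
# reference pose. The sagittal plane is y = 0.

#' Octagonal hoop profile
#'
#' One planar cross-section of a body segment: an octagon with four cardinal
#' vertices at the lateral (`a`) and dorso-ventral (`b`) semi-axes and four
#' diagonal vertices at `k * (a, b) / sqrt(2)`. `k = 1` is the elliptical
#' profile (diagonal vertices on the ellipse); `k = sqrt(2)` degenerates to
#' the bounding rectangle, `k = 1/sqrt(2)` to the diamond.
#'
#' @param center hoop centre on the skeletal axis (cm).
#' @param axis loft direction (unit vector; hoop lies in the plane
#'   perpendicular to it).
#' @param up dorso-ventral direction within the hoop plane; components along
#'   `axis` are removed.
#' @param a lateral semi-axis (cm).
#' @param b dorso-ventral semi-axis (cm).
#' @param k diagonal scale factor, in `[1/sqrt(2), sqrt(2)]`.
#' @return A `hoop_profile` object.
#' @export
hoop_profile <- function(center, axis, up, a, b, k = 1) {
  stopifnot(length(center) == 3L, length(axis) == 3L, length(up) == 3L)
  if (a <= 0 || b <= 0) stop("semi-axes must be positive")
  if (k < 1 / sqrt(2) - 1e-9 || k > sqrt(2) + 1e-9) {
    stop("k must lie between 1/sqrt(2) (diamond) and sqrt(2) (square)")
  }
  ax <- axis / sqrt(sum(axis^2))
  u <- up - sum(up * ax) * ax
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12) stop("up direction is parallel to the hoop axis")
  structure(
    list(center = as.numeric(center), axis = ax, up = u / nu, a = a, b = b, k = k),
    class = "hoop_profile"
  )
}

#' Octagon vertices of a hoop
#'
#' @param h a [hoop_profile()].
#' @return 8 x 3 matrix of vertices, ordered counter-clockwise viewed along
#'   the hoop axis, starting at the +lateral cardinal vertex.
#' @export
make_octagon <- function(h) {
  stopifnot(inherits(h, "hoop_profile"))
  lat <- c(
    h$up[2] * h$axis[3] - h$up[3] * h$axis[2],
    h$up[3] * h$axis[1] - h$up[1] * h$axis[3],
    h$up[1] * h$axis[2] - h$up[2] * h$axis[1]
  )  # up x axis, so (lat, up, axis) is right-handed
  s <- 1 / sqrt(2)
  local2 <- rbind(
    c(h$a, 0),
    h$k * c(h$a * s, h$b * s),
    c(0, h$b),
    h$k * c(-h$a * s, h$b * s),
    c(-h$a, 0),
    h$k * c(-h$a * s, -h$b * s),
    c(0, -h$b),
    h$k * c(h$a * s, -h$b * s)
  )
  sweep(local2[, 1, drop = FALSE] %*% rbind(lat) +
    local2[, 2, drop = FALSE] %*% rbind(h$up), 2, -h$center)
}

#' Area of the octagonal profile
#'
#' Closed form `2 * sqrt(2) * k * a * b`, the shoelace area of the
#' eight-vertex profile.
#'
#' @param a,b semi-axes (cm).
#' @param k diagonal scale factor.
#' @return Area in cm^2.
#' @export
octagon_area <- function(a, b, k = 1) 2 * sqrt(2) * k * a * b

#' Diagonal scale factors for octagon profile calibration
#'
#' Derives the diagonal scale factor of the named profile geometrically.
#' With unit semi-axes the diagonal vertex of the elliptical profile sits at
#' radius 1 along the 45-degree diagonal (`k = 1`); the corner of the
#' circumscribing rectangle at `sqrt(2)`; the edge midpoint of the inscribed
#' diamond at `1/sqrt(2)`. The intermediate profiles are the arithmetic means:
#' `(1 + sqrt(2)) / 2 = 1.2071` for the profile halfway between ellipse and
#' square, and `(1 + 1/sqrt(2)) / 2 = 0.8536` for the profile halfway between
#' ellipse and diamond — the 120.7% and 85.3% diagonal scalings used by the
#' outline sensitivity analysis.
#'
#' @param profile one of `"ellipse"`, `"square"`, `"diamond"`,
#'   `"ellipse-square"`, `"ellipse-diamond"`.
#' @return The diagonal scale factor k (dimensionless).
#' @export
octagon_k <- function(profile = c("ellipse-square", "ellipse-diamond", "ellipse",
                                  "square", "diamond")) {
  profile <- match.arg(profile)
  k_ellipse <- 1
  k_square <- sqrt(2)
  k_diamond <- 1 / sqrt(2)
  switch(profile,
    "ellipse" = k_ellipse,
    "square" = k_square,
    "diamond" = k_diamond,
    "ellipse-square" = (k_ellipse + k_square) / 2,
    "ellipse-diamond" = (k_ellipse + k_diamond) / 2
  )
}

#' Body segment specification
#'
#' A body segment described as ordered octagonal hoops lofted along a skeletal
#' axis, with optional cavity meshes to subtract and a multiplicity for paired
#' (bilaterally mirrored) segments.
#'
#' @param name segment label.
#' @param region body region tag: one of `"head"`, `"neck"`, `"trunk"`,
#'   `"pectoral"`, `"pelvic"`, `"tail"`.
#' @param hoops list of [hoop_profile()] (>= 2), centres strictly ordered
#'   along the segment axis.
#' @param cavities list of watertight `tri_mesh` cavities contained in the
#'   segment (air spaces excluded from the mass).
#' @param density density in kg m^-3 (default 1000).
#' @param count multiplicity: 2 for paired limbs, else 1.
#' @param mirrored should paired copies be mirrored about the sagittal plane
#'   (y = 0)? Defaults to `count == 2`.
#' @return A `segment_spec` object.
#' @export
segment_spec <- function(name, region, hoops, cavities = list(), density = 1000,
                         count = 1L, mirrored = count == 2L) {
  region <- match.arg(region, c("head", "neck", "trunk", "pectoral", "pelvic", "tail"))
  if (length(hoops) < 2L) stop("a segment needs at least 2 hoops")
  if (!all(vapply(hoops, inherits, logical(1), "hoop_profile"))) {
    stop("hoops must be hoop_profile objects")
  }
  ax <- hoops[[1]]$axis
  t_along <- vapply(hoops, function(h) sum(h$center * ax), numeric(1))
  if (any(diff(t_along) <= 0)) stop("hoop centers must be strictly ordered along the axis")
  if (count < 1L) stop("count must be >= 1")
  structure(
    list(
      name = name, region = region, hoops = hoops, cavities = cavities,
      density = density, count = as.integer(count), mirrored = isTRUE(mirrored)
    ),
    class = "segment_spec"
  )
}

#' Loft a segment's hoops into a watertight mesh
#'
#' Corresponding vertices of consecutive octagons are joined by quad strips
#' (split into triangles); the first and last hoops are closed with triangle
#' fans around their centres.
#'
#' @param segment a [segment_spec()].
#' @return Watertight [tri_mesh()] of the segment outline (single copy, no
#'   mirroring, cavities not subtracted).
#' @export
loft <- function(segment) {
  stopifnot(inherits(segment, "segment_spec"))
  octs <- lapply(segment$hoops, make_octagon)
  nh <- length(octs)
  v <- do.call(rbind, octs)
  v <- rbind(v, segment$hoops[[1]]$center, segment$hoops[[nh]]$center)
  c_first <- 8L * nh + 1L
  c_last <- 8L * nh + 2L
  faces <- vector("list", (nh - 1L) * 16L + 16L)
  fi <- 0L
  for (i in seq_len(nh - 1L)) {
    o0 <- 8L * (i - 1L)
    o1 <- 8L * i
    for (j in seq_len(8L)) {
      jn <- if (j == 8L) 1L else j + 1L
      a <- o0 + j; b <- o0 + jn; c_ <- o1 + j; d <- o1 + jn
      faces[[fi + 1L]] <- c(a, b, c_)
      faces[[fi + 2L]] <- c(b, d, c_)
      fi <- fi + 2L
    }
  }
  for (j in seq_len(8L)) {
    jn <- if (j == 8L) 1L else j + 1L
    faces[[fi + 1L]] <- c(c_first, jn, j)                       # cap faces -axis
    faces[[fi + 2L]] <- c(c_last, 8L * (nh - 1L) + j, 8L * (nh - 1L) + jn)
    fi <- fi + 2L
  }
  mesh <- tri_mesh(v, do.call(rbind, faces[seq_len(fi)]))
  # self-intersection diagnostic: radius change between hoops exceeding spacing
  ax <- segment$hoops[[1]]$axis
  t_along <- vapply(segment$hoops, function(h) sum(h$center * ax), numeric(1))
  rmax <- vapply(segment$hoops, function(h) max(h$a, h$b), numeric(1))
  if (any(abs(diff(rmax)) > diff(t_along) * 25)) {
    warning("hoop radii change much faster than hoop spacing; loft may self-intersect")
  }
  mesh
}

#' Outline sensitivity variant parameters
#'
#' The body outline sensitivity envelope: the maximal outline scales each
#' hoop's radial semi-axes to `radial_scale` (default 120%) of the
#' skeleton-hugging values and sets the diagonal factor to the
#' ellipse-square intermediate (120.7%); the minimal outline keeps the
#' initial radii and sets the diagonal factor to the ellipse-diamond
#' intermediate (85.3%).
#'
#' @param radial_scale radial inflation of the maximal outline (default 1.2).
#' @param k_max diagonal factor of the maximal outline
#'   (default [octagon_k]`("ellipse-square")`).
#' @param k_min diagonal factor of the minimal outline
#'   (default [octagon_k]`("ellipse-diamond")`).
#' @return An `outline_variant` object.
#' @export
outline_variant <- function(radial_scale = 1.2,
                            k_max = octagon_k("ellipse-square"),
                            k_min = octagon_k("ellipse-diamond")) {
  if (radial_scale < 1 || radial_scale > 1.2 + 1e-9) {
    stop("radial_scale must lie in [1, 1.2]")
  }
  structure(
    list(radial_scale = radial_scale, k_max = k_max, k_min = k_min),
    class = "outline_variant"
  )
}

#' Apply the minimal or maximal outline variant to a segment
#'
#' Scaling is radial about each hoop's own centre: hoop centres and axes are
#' untouched, only the semi-axes and diagonal factor change.
#'
#' @param segment a [segment_spec()].
#' @param which `"min"` or `"max"`.
#' @param variant an [outline_variant()].
#' @return The modified `segment_spec`.
#' @export
apply_variant <- function(segment, which = c("max", "min"), variant = outline_variant()) {
  stopifnot(inherits(segment, "segment_spec"), inherits(variant, "outline_variant"))
  which <- match.arg(which)
  scale <- if (which == "max") variant$radial_scale else 1
  k_new <- if (which == "max") variant$k_max else variant$k_min
  segment$hoops <- lapply(segment$hoops, function(h) {
    hoop_profile(h$center, h$axis, h$up, h$a * scale, h$b * scale, k_new)
  })
  segment
}

#' Subtract cavity volumes from segment mass properties
#'
#' Mass-property subtraction — exactly equivalent to a boolean difference for
#' cavities fully contained in the segment, with none of the numerical
#' fragility of mesh booleans: `V <- V - Vc`, `CoM <- (V r - Vc rc) / (V - Vc)`.
#'
#' @param mp `mass_properties` of the full segment.
#' @param cavities list of `mass_properties` of the cavities (computed at the
#'   same density).
#' @return Adjusted `mass_properties`.
#' @export
subtract_cavities <- function(mp, cavities = list()) {
  stopifnot(inherits(mp, "mass_properties"))
  if (length(cavities) == 0L) return(mp)
  vol <- mp$volume
  mom <- mp$com * mp$volume
  for (cav in cavities) {
    stopifnot(inherits(cav, "mass_properties"))
    if (cav$volume >= vol) stop("cavity volume exceeds remaining segment volume")
    vol <- vol - cav$volume
    mom <- mom - cav$com * cav$volume
  }
  mass_properties_record(volume = vol, density = mp$density, com = mom / vol)
}

#' Mass properties of one lofted segment (single copy)
#'
#' Lofts the hoops, computes divergence-theorem mass properties, verifies that
#' each cavity is contained in the segment outline, and subtracts cavity
#' volumes.
#'
#' @param segment a [segment_spec()].
#' @return `mass_properties` of a single copy of the segment.
#' @export
segment_mass_properties <- function(segment) {
  stopifnot(inherits(segment, "segment_spec"))
  mesh <- loft(segment)
  mp <- mass_properties(mesh, density = segment$density)
  if (length(segment$cavities) > 0L) {
    cav_mp <- lapply(segment$cavities, function(cav) {
      stopifnot(inherits(cav, "tri_mesh"))
      if (!contains_mesh(mesh, cav)) {
        stop(sprintf("cavity is not fully contained in segment '%s'", segment$name))
      }
      mass_properties(cav, density = segment$density)
    })
    mp <- subtract_cavities(mp, cav_mp)
  }
  mp
}

#' Total body mass
#'
#' Sum of segment masses, paired segments counted by their multiplicity.
#'
#' @param masses numeric vector of per-copy segment masses (kg).
#' @param counts integer multiplicities (default all 1).
#' @return Total mass in kg.
#' @export
total_mass <- function(masses, counts = rep(1L, length(masses))) {
  stopifnot(length(masses) == length(counts), all(masses >= 0), all(counts >= 1))
  sum(masses * counts)
}

#' Whole-body centre of mass
#'
#' Mass-weighted mean of segment centres of mass in the system frame. A
#' mirrored paired segment with per-copy CoM `(x, y, z)` contributes both
#' `(x, y, z)` and `(x, -y, z)`, so its net y-moment is exactly zero.
#'
#' @param masses per-copy segment masses (kg).
#' @param coms n x 3 matrix of per-copy segment CoMs (cm).
#' @param counts multiplicities (default 1).
#' @param mirrored logical: is the segment a bilaterally mirrored pair?
#'   (only meaningful with `counts == 2`).
#' @return Length-3 CoM (cm).
#' @export
whole_body_com <- function(masses, coms, counts = rep(1L, length(masses)),
                           mirrored = rep(FALSE, length(masses))) {
  coms <- matrix(as.numeric(coms), ncol = 3)
  m_tot <- total_mass(masses, counts)
  if (m_tot <= 0) stop("total mass must be positive")
  mom <- c(0, 0, 0)
  for (i in seq_along(masses)) {
    if (mirrored[i] && counts[i] == 2L) {
      mom <- mom + masses[i] * c(2 * coms[i, 1], 0, 2 * coms[i, 3])
    } else {
      mom <- mom + masses[i] * counts[i] * coms[i, ]
    }
  }
  mom / m_tot
}

#' Published-style segment table of a small quadruped
#'
#' Reads the packaged per-segment mass/CoM estimates (minimal and maximal
#' outline variants) for the study specimen, a ~4 kg early tetrapod. Columns:
#' `segment`, `region`, `variant` (min/max/single), `mass_kg`, `x_cm`, `y_cm`,
#' `z_cm`, `count`. Paired limbs are listed once with `count = 2` and
#' mirrored about the sagittal plane when combined.
#'
#' @return A data.frame of per-segment estimates.
#' @export
example_segment_table <- function() {
  path <- system.file("extdata", "specimen_segments.csv", package = "osteomech")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# combine selected rows of a segment table into (mass, com)
combine_rows <- function(tbl) {
  m <- total_mass(tbl$mass_kg, tbl$count)
  com <- whole_body_com(
    tbl$mass_kg, cbind(tbl$x_cm, tbl$y_cm, tbl$z_cm),
    tbl$count, tbl$count == 2L
  )
  list(mass = m, com = com)
}

#' Whole-body mass envelope from a per-segment estimate table
#'
#' Combines minimal/maximal segment estimates into the canonical whole-body
#' models: `max_overall` (all maximal), `min_overall` (all minimal),
#' `max_cranial` (maximal neck, trunk and pectoral limbs with minimal pelvic
#' limbs and tail — the most cranial plausible mass distribution),
#' `max_caudal` (the converse), and `mean` (arithmetic mean of the
#' min/max-overall models' mass and CoM). Segments tagged `variant =
#' "single"` (the head) enter every model unchanged.
#'
#' @param tbl a segment table shaped like [example_segment_table()].
#' @return A data.frame with one row per whole-body model: `model`,
#'   `mass_kg`, `x_cm`, `y_cm`, `z_cm`.
#' @export
body_mass_envelope <- function(tbl) {
  needed <- c("segment", "region", "variant", "mass_kg", "x_cm", "y_cm", "z_cm", "count")
  if (!all(needed %in% names(tbl))) {
    stop("segment table must have columns: ", paste(needed, collapse = ", "))
  }
  regions <- unique(tbl$region)
  pick <- function(choice) {
    # choice: named character vector region -> "min"/"max"; "single" rows always in
    rows <- lapply(regions, function(r) {
      sub <- tbl[tbl$region == r, , drop = FALSE]
      if (any(sub$variant == "single")) {
        sub[sub$variant == "single", , drop = FALSE]
      } else {
        want <- choice[[r]]
        out <- sub[sub$variant == want, , drop = FALSE]
        if (nrow(out) == 0L) stop(sprintf("region '%s' has no '%s' variant row", r, want))
        out
      }
    })
    do.call(rbind, rows)
  }
  varied <- setdiff(regions, tbl$region[tbl$variant == "single"])
  all_of <- function(w) stats::setNames(rep(w, length(varied)), varied)
  cranial_regions <- intersect(c("neck", "trunk", "pectoral"), varied)
  caudal_regions <- intersect(c("pelvic", "tail"), varied)
  cranial_choice <- all_of("min")
  cranial_choice[cranial_regions] <- "max"
  caudal_choice <- all_of("max")
  caudal_choice[cranial_regions] <- "min"
  caudal_choice[caudal_regions] <- "max"
  models <- list(
    max_cranial = combine_rows(pick(cranial_choice)),
    max_caudal = combine_rows(pick(caudal_choice)),
    max_overall = combine_rows(pick(all_of("max"))),
    min_overall = combine_rows(pick(all_of("min")))
  )
  mean_model <- list(
    mass = (models$max_overall$mass + models$min_overall$mass) / 2,
    com = (models$max_overall$com + models$min_overall$com) / 2
  )
  models$mean <- mean_model
  data.frame(
    model = names(models),
    mass_kg = vapply(models, `[[`, numeric(1), "mass"),
    x_cm = vapply(models, function(m) m$com[1], numeric(1)),
    y_cm = vapply(models, function(m) m$com[2], numeric(1)),
    z_cm = vapply(models, function(m) m$com[3], numeric(1)),
    row.names = NULL
  )
}

#' Outline sensitivity report for a hoop-modelled body
#'
#' Computes minimal- and maximal-outline mass properties for every segment
#' (the head is held at its single, unmodified estimate), then the whole-body
#' envelope models via [body_mass_envelope()].
#'
#' @param segments list of [segment_spec()] covering the six body regions.
#' @param variant an [outline_variant()].
#' @return A list of class `body_mass_report` with elements `segments` (per
#'   segment/variant data.frame) and `whole_body` (envelope data.frame).
#' @export
sensitivity_report <- function(segments, variant = outline_variant()) {
  stopifnot(all(vapply(segments, inherits, logical(1), "segment_spec")))
  regions <- vapply(segments, `[[`, character(1), "region")
  if (anyNA(match(regions, c("head", "neck", "trunk", "pectoral", "pelvic", "tail")))) {
    stop("every segment needs a valid body-region tag")
  }
  rows <- list()
  for (seg in segments) {
    if (seg$region == "head") {
      mp <- segment_mass_properties(seg)
      rows[[length(rows) + 1L]] <- data.frame(
        segment = seg$name, region = seg$region, variant = "single",
        mass_kg = mp$mass, x_cm = mp$com[1], y_cm = mp$com[2], z_cm = mp$com[3],
        count = seg$count
      )
    } else {
      for (w in c("max", "min")) {
        mp <- segment_mass_properties(apply_variant(seg, w, variant))
        rows[[length(rows) + 1L]] <- data.frame(
          segment = seg$name, region = seg$region, variant = w,
          mass_kg = mp$mass, x_cm = mp$com[1], y_cm = mp$com[2], z_cm = mp$com[3],
          count = seg$count
        )
      }
    }
  }
  seg_tbl <- do.call(rbind, rows)
  structure(
    list(segments = seg_tbl, whole_body = body_mass_envelope(seg_tbl)),
    class = "body_mass_report"
  )
}

#' @export
print.body_mass_report <- function(x, ...) {
  cat("Per-segment estimates:\n")
  print(x$segments, digits = 4)
  cat("\nWhole-body models:\n")
  print(x$whole_body, digits = 4)
  invisible(x)
}
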