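# Osteological joint mobility: rotate the stylopodium about an anatomical
# joint coordinate system (ACS) anchored at a sphere-fitted joint centre
# until bone-bone collision with the girdle, swept over assumed joint spaces.
#
# ACS semantics (right-handed): x = stylopodium long axis (rotations are
# long-axis rotation, LAR); y = up (pro-/retraction); z = cranial
# (ab-/adduction). All angles are reported relative to the reference pose:
# a sprawling posture with the long axis perpendicular to the sagittal plane
# and the epicondylar axis horizontal.

#' Anatomical joint coordinate system
#'
#' @param origin rotation centre (cm), typically a fitted sphere centre.
#' @param x_axis stylopodium long axis (LAR axis).
#' @param y_axis up direction (pro-/retraction axis).
#' @param z_axis cranial direction (ab-/adduction axis).
#' @return A `joint_acs` with an exactly right-handed orthonormal triad.
#' @export
joint_acs <- function(origin, x_axis, y_axis, z_axis) {
  x <- x_axis / sqrt(sum(x_axis^2))
  y <- y_axis - sum(y_axis * x) * x
  ny <- sqrt(sum(y^2))
  if (ny < 1e-12) stop("y axis parallel to x axis")
  y <- y / ny
  z <- c(x[2] * y[3] - x[3] * y[2], x[3] * y[1] - x[1] * y[3], x[1] * y[2] - x[2] * y[1])
  if (sum(z * z_axis) < 0) {
    stop("axis hints are left-handed: flip one of the directions")
  }
  structure(
    list(origin = as.numeric(origin), x = x, y = y, z = z),
    class = "joint_acs"
  )
}

#' @export
print.joint_acs <- function(x, ...) {
  cat(sprintf(
    "<joint_acs at (%.3f, %.3f, %.3f) cm>\n  x (long axis): %s\n  y (up):        %s\n  z (cranial):   %s\n",
    x$origin[1], x$origin[2], x$origin[3],
    paste(round(x$x, 4), collapse = " "),
    paste(round(x$y, 4), collapse = " "),
    paste(round(x$z, 4), collapse = " ")
  ))
  invisible(x)
}

#' Build an ACS from a proximal joint-surface vertex selection
#'
#' The rotation centre is the centre of a least-squares sphere fitted into
#' the selected proximal joint-surface points of the mobile bone. The axes
#' are the Gram-Schmidt orthonormalisation of the anatomical direction hints,
#' x (long axis) first, so x is exactly along `long_axis`.
#'
#' @param mobile_surface_points n x 3 matrix: vertices on the mobile bone's
#'   proximal articular surface (user-selected; the articular surface is an
#'   anatomical judgement, not inferred here).
#' @param long_axis,up,cranial anatomical direction hints.
#' @return A [joint_acs()].
#' @export
build_acs <- function(mobile_surface_points, long_axis, up, cranial) {
  fit <- fit_sphere(mobile_surface_points)
  joint_acs(fit$center, long_axis, up, cranial)
}

#' Offset the mobile bone by an assumed joint space
#'
#' The joint space (a proxy for lost articular cartilage) is realised by
#' translating the mobile bone along the line from the socket centre through
#' the fitted head centre, pushing it out of the socket; the rotation centre
#' moves with the bone. Mobility therefore grows with joint space, since the
#' bony stops engage later.
#'
#' @param bone mobile bone [tri_mesh()] in the reference pose.
#' @param acs the bone's [joint_acs()] (origin = fitted head centre).
#' @param socket_center centre of the socket (glenoid/acetabulum) sphere (cm).
#' @param s joint space in mm (>= 0).
#' @return List with translated `bone` and `acs`.
#' @export
apply_joint_space <- function(bone, acs, socket_center, s) {
  stopifnot(inherits(bone, "tri_mesh"), inherits(acs, "joint_acs"), s >= 0)
  dir <- acs$origin - as.numeric(socket_center)
  nd <- sqrt(sum(dir^2))
  if (nd < 1e-12) stop("socket centre coincides with the head centre")
  shift <- dir / nd * (s / 10)  # mm -> cm
  tr <- affine_transform(diag(3), shift)
  acs2 <- acs
  acs2$origin <- acs$origin + shift
  list(bone = apply_transform(bone, tr), acs = acs2)
}

#' Sweep configuration for collision-based mobility
#'
#' @param increment angular step in degrees (default 0.1).
#' @param limit_lar sweep cap for long-axis rotation (default 360).
#' @param limit_other sweep cap for the other axes (default 180).
#' @param joint_spaces joint-space offsets in mm (default 0 to 2.5 by 0.5).
#' @return A `sweep_config` object.
#' @export
sweep_config <- function(increment = 0.1, limit_lar = 360, limit_other = 180,
                         joint_spaces = seq(0, 2.5, by = 0.5)) {
  stopifnot(increment > 0, all(joint_spaces >= 0))
  structure(
    list(
      increment = increment, limit_lar = limit_lar, limit_other = limit_other,
      joint_spaces = joint_spaces
    ),
    class = "sweep_config"
  )
}

#' Maximum collision-free rotation about one ACS axis
#'
#' Rotates the mobile bone about the given ACS axis through the ACS origin in
#' steps of the configured increment and returns the largest angle theta such
#' that no pose in [0, theta] collides with the girdle (collision = surface
#' intersection or full containment). The result is a multiple of the
#' increment, conservative by at most one increment, and capped at the sweep
#' limit. If the bone already collides in the reference pose the sweep
#' returns 0 with attribute `ref_collision = TRUE`.
#'
#' @param girdle fixed girdle [tri_mesh()].
#' @param bone mobile bone [tri_mesh()] at the reference pose (already offset
#'   by the joint space).
#' @param acs the bone's [joint_acs()].
#' @param axis `"x"`, `"y"` or `"z"` (LAR, pro-/retraction, ab-/adduction).
#' @param direction +1 or -1: sense of rotation about the axis (right-hand
#'   rule).
#' @param cfg a [sweep_config()].
#' @return Angle in degrees (>= 0).
#' @export
sweep_to_collision <- function(girdle, bone, acs, axis = c("x", "y", "z"),
                               direction = 1, cfg = sweep_config()) {
  stopifnot(
    inherits(girdle, "tri_mesh"), inherits(bone, "tri_mesh"),
    inherits(acs, "joint_acs"), direction %in% c(-1, 1)
  )
  axis <- match.arg(axis)
  if (intersects(girdle, bone)) {
    return(structure(0, ref_collision = TRUE))
  }
  limit <- if (axis == "x") cfg$limit_lar else cfg$limit_other
  nsteps <- floor(limit / cfg$increment + 1e-9)
  ax <- acs[[axis]] * direction
  k <- cpp_first_collision(
    girdle$vertices, girdle$faces - 1L, bone$vertices, bone$faces - 1L,
    acs$origin, ax, cfg$increment * pi / 180, as.integer(nsteps)
  )
  if (k == 0L) limit else (k - 1L) * cfg$increment
}

#' Table of maximal mobility over joint spaces
#'
#' For each joint space, six independent single-axis sweeps from the reference
#' pose: adduction and abduction (about -z and +z), protraction and
#' retraction (about +y and -y), and clockwise / counter-clockwise LAR
#' (about -x and +x; the clockwise sense is that of the right-side bone seen
#' in right lateral view, cranial to the right).
#'
#' @param girdle fixed girdle [tri_mesh()].
#' @param bone mobile bone [tri_mesh()] in the reference pose at zero joint
#'   space.
#' @param acs the bone's [joint_acs()].
#' @param socket_center socket sphere centre (cm) used to direct the
#'   joint-space offset.
#' @param cfg a [sweep_config()].
#' @return A `rom_result` data.frame: one row per joint space with columns
#'   `joint_space_mm`, `adduction`, `abduction`, `protraction`, `retraction`,
#'   `lar_cw`, `lar_ccw` (degrees), plus `ref_collision`.
#' @export
rom_table <- function(girdle, bone, acs, socket_center, cfg = sweep_config()) {
  dirs <- list(
    adduction = list(axis = "z", dir = -1),
    abduction = list(axis = "z", dir = +1),
    protraction = list(axis = "y", dir = -1),  # -y swings the long axis cranially
    retraction = list(axis = "y", dir = +1),
    lar_cw = list(axis = "x", dir = -1),
    lar_ccw = list(axis = "x", dir = +1)
  )
  rows <- lapply(cfg$joint_spaces, function(s) {
    placed <- apply_joint_space(bone, acs, socket_center, s)
    flag <- intersects(girdle, placed$bone)
    vals <- vapply(dirs, function(d) {
      as.numeric(sweep_to_collision(girdle, placed$bone, placed$acs, d$axis, d$dir, cfg))
    }, numeric(1))
    data.frame(
      joint_space_mm = s, t(vals), ref_collision = flag
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rom_result", "data.frame")
  out
}
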