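#' @useDynLib osteomech, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct a triangle mesh
#'
#' A `tri_mesh` is the universal geometric currency of the package: a triangle
#' surface with vertices in centimetres and outward-oriented faces. Most
#' downstream operations (mass properties, collision sweeps, retrodeformation)
#' act on `tri_mesh` objects.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in cm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices
#'   ordered counter-clockwise when viewed from outside.
#' @return An object of class `tri_mesh` with elements `vertices` and `faces`.
#' @examples
#' cube <- box_mesh(center = c(0, 0, 0), dims = c(1, 1, 1))
#' mass_properties(cube)
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) > 0L && (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf(
    "<tri_mesh: %d vertices, %d faces, %s>\n",
    nrow(x$vertices), nrow(x$faces),
    if (is_watertight(x)) "watertight" else sprintf("%d open edges", n_open_edges(x))
  ))
  invisible(x)
}

# directed edge table; watertight iff every undirected edge appears exactly
# twice, once in each direction
edge_key <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  list(
    directed = paste(e[, 1], e[, 2]),
    undirected = paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  )
}

#' Count boundary (open) edges of a mesh
#'
#' @param mesh a [tri_mesh()].
#' @return Number of undirected edges not shared by exactly two faces.
#' @export
n_open_edges <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(0L)
  tab <- table(edge_key(mesh)$undirected)
  sum(tab != 2L)
}

#' Test whether a mesh is watertight and consistently oriented
#'
#' Watertight means every undirected edge is shared by exactly two faces;
#' consistent orientation additionally requires the two incident faces to
#' traverse the edge in opposite directions.
#'
#' @param mesh a [tri_mesh()].
#' @return Logical scalar.
#' @export
is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(FALSE)
  ek <- edge_key(mesh)
  all(table(ek$undirected) == 2L) && !anyDuplicated(ek$directed)
}

#' Signed volume of a mesh
#'
#' Divergence-theorem signed volume; positive for a watertight,
#' outward-oriented mesh.
#'
#' @param mesh a [tri_mesh()].
#' @return Signed volume in cm^3.
#' @export
signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(det6) / 6
}

#' Mass properties of a watertight mesh
#'
#' Volume and volume centroid are computed exactly by the divergence theorem
#' (signed tetrahedra spanned by each face and the origin); mass is volume
#' times density with the cm^3 to m^3 conversion applied internally.
#'
#' @param mesh a watertight, outward-oriented [tri_mesh()] in cm.
#' @param density material density in kg m^-3 (default 1000, the standard
#'   whole-body density used for volumetric reconstructions).
#' @return A `mass_properties` list: `volume` (cm^3), `mass` (kg), `com`
#'   (cm, length-3).
#' @examples
#' mass_properties(box_mesh(c(0.5, 0.5, 0.5), c(1, 1, 1)))
#' @export
mass_properties <- function(mesh, density = 1000) {
  stopifnot(inherits(mesh, "tri_mesh"))
  open <- n_open_edges(mesh)
  if (open > 0L) {
    stop(sprintf("mesh is not watertight: %d open edge(s)", open))
  }
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  # signed volume of tetra (0, a, b, c) = det[a b c]/6
  det6 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  vol <- sum(det6) / 6
  if (vol <= 0) stop("signed volume is non-positive; check face orientation")
  centroid <- colSums((a + b + c_) / 4 * det6) / 6 / vol
  mass_properties_record(volume = vol, density = density, com = centroid)
}

mass_properties_record <- function(volume, density, com) {
  structure(
    list(
      volume = volume,
      mass = volume * 1e-6 * density,  # cm^3 -> m^3
      com = as.numeric(com),
      density = density
    ),
    class = "mass_properties"
  )
}

#' @export
print.mass_properties <- function(x, ...) {
  cat(sprintf(
    "<mass_properties: V = %.4g cm^3, m = %.4g kg, CoM = (%.3f, %.3f, %.3f) cm>\n",
    x$volume, x$mass, x$com[1], x$com[2], x$com[3]
  ))
  invisible(x)
}

#' Least-squares sphere fit
#'
#' Fits a sphere to 3D points by the linear algebraic least-squares
#' formulation: minimising the algebraic residual
#' \eqn{\|p\|^2 - 2 c \cdot p - (r^2 - \|c\|^2)} over centre c and radius r.
#' Exact on noise-free spherical data for any patch of at least four
#' non-coplanar points (full coverage is not required), deterministic, and
#' initialisation-free — the properties needed when the centre defines a joint
#' centre of rotation.
#'
#' @param points numeric matrix (n x 3), n >= 4, not coplanar.
#' @return A `sphere` list: `center` (cm), `radius` (cm), `rms` geometric
#'   residual (cm).
#' @examples
#' u <- matrix(rnorm(300), ncol = 3)
#' pts <- 5 * u / sqrt(rowSums(u^2)) + rep(c(1, 2, 3), each = 100)
#' fit_sphere(pts)
#' @export
fit_sphere <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be n x 3")
  if (nrow(points) < 4L) stop("sphere fit needs at least 4 points")
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  qr_A <- qr(A)
  if (qr_A$rank < 4L) stop("degenerate (coplanar or coincident) points: cannot fit a sphere")
  sol <- qr.coef(qr_A, b)
  center <- sol[1:3]
  r2 <- sol[4] + sum(center^2)
  if (r2 <= 0) stop("degenerate sphere fit (non-positive squared radius)")
  radius <- as.numeric(sqrt(r2))
  resid <- sqrt(rowSums(sweep(points, 2, center)^2)) - radius
  structure(
    list(center = as.numeric(center), radius = radius, rms = sqrt(mean(resid^2))),
    class = "sphere"
  )
}

#' @export
print.sphere <- function(x, ...) {
  cat(sprintf(
    "<sphere: c = (%.4f, %.4f, %.4f) cm, r = %.4f cm, rms = %.2g cm>\n",
    x$center[1], x$center[2], x$center[3], x$radius, x$rms
  ))
  invisible(x)
}

#' Affine transform (3x3 linear part plus translation)
#'
#' @param linear invertible 3x3 matrix.
#' @param translation length-3 numeric (cm), default zero.
#' @return An `affine_transform` object.
#' @export
affine_transform <- function(linear = diag(3), translation = c(0, 0, 0)) {
  linear <- as.matrix(linear)
  stopifnot(all(dim(linear) == c(3L, 3L)), length(translation) == 3L)
  if (abs(det(linear)) < 1e-12) stop("singular linear part: transform not invertible")
  structure(
    list(linear = linear, translation = as.numeric(translation)),
    class = "affine_transform"
  )
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\nlinear:\n")
  print(round(x$linear, 6))
  cat("translation:", round(x$translation, 6), "\n")
  invisible(x)
}

#' Compose two affine transforms
#'
#' `compose_transforms(t2, t1)` is the map applying `t1` first, then `t2`.
#'
#' @param t2,t1 `affine_transform` objects.
#' @return Their composition as an `affine_transform`.
#' @export
compose_transforms <- function(t2, t1) {
  affine_transform(
    linear = t2$linear %*% t1$linear,
    translation = as.numeric(t2$linear %*% t1$translation) + t2$translation
  )
}

#' Invert an affine transform
#'
#' @param t an `affine_transform`.
#' @return The inverse transform.
#' @export
invert_transform <- function(t) {
  inv <- solve(t$linear)
  affine_transform(linear = inv, translation = as.numeric(-inv %*% t$translation))
}

#' Apply an affine transform to a mesh
#'
#' Vertices are mapped through the transform. If the linear part has negative
#' determinant (a reflection) the face winding is flipped so the mesh stays
#' outward-oriented and its signed volume positive.
#'
#' @param mesh a [tri_mesh()].
#' @param t an [affine_transform()].
#' @return The transformed `tri_mesh`.
#' @export
apply_transform <- function(mesh, t) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(t, "affine_transform"))
  v <- mesh$vertices %*% t(t$linear)
  v <- sweep(v, 2, -t$translation)
  f <- mesh$faces
  if (det(t$linear) < 0) f <- f[, c(1, 3, 2), drop = FALSE]
  tri_mesh(v, f)
}

#' Apply a transform to a point set
#'
#' @param points n x 3 matrix or length-3 vector.
#' @param t an [affine_transform()].
#' @return Transformed points, same shape.
#' @export
transform_points <- function(points, t) {
  one <- is.null(dim(points))
  p <- if (one) matrix(points, 1) else as.matrix(points)
  out <- sweep(p %*% t(t$linear), 2, -t$translation)
  if (one) as.numeric(out) else out
}

#' Minimum distance between two meshes
#'
#' Exact minimum triangle-to-triangle distance, accelerated by an AABB tree;
#' zero if and only if the surfaces touch or intersect.
#'
#' @param a,b [tri_mesh()] objects.
#' @return Non-negative distance in cm.
#' @export
min_distance <- function(a, b) {
  stopifnot(inherits(a, "tri_mesh"), inherits(b, "tri_mesh"))
  cpp_min_distance(a$vertices, a$faces - 1L, b$vertices, b$faces - 1L)
}

#' Do two meshes collide?
#'
#' True if any triangle pair intersects, or if one closed mesh is entirely
#' contained in the other (a bone fully inside another bone is certainly a
#' collision, even without surface contact).
#'
#' @param a,b [tri_mesh()] objects.
#' @return Logical scalar.
#' @export
intersects <- function(a, b) {
  stopifnot(inherits(a, "tri_mesh"), inherits(b, "tri_mesh"))
  if (nrow(a$faces) == 0L || nrow(b$faces) == 0L) return(FALSE)
  if (cpp_surface_intersects(a$vertices, a$faces - 1L, b$vertices, b$faces - 1L)) {
    return(TRUE)
  }
  cpp_point_in_mesh(b$vertices, b$faces - 1L, a$vertices[1, ]) ||
    cpp_point_in_mesh(a$vertices, a$faces - 1L, b$vertices[1, ])
}

#' Is one closed mesh fully contained in another?
#'
#' @param outer,inner [tri_mesh()] objects; `outer` must be closed.
#' @return TRUE if every part of `inner` lies inside `outer` with no surface
#'   contact.
#' @export
contains_mesh <- function(outer, inner) {
  stopifnot(inherits(outer, "tri_mesh"), inherits(inner, "tri_mesh"))
  if (cpp_surface_intersects(
    outer$vertices, outer$faces - 1L,
    inner$vertices, inner$faces - 1L
  )) {
    return(FALSE)
  }
  cpp_point_in_mesh(outer$vertices, outer$faces - 1L, inner$vertices[1, ])
}

#' Merge meshes into a single (possibly multi-component) mesh
#'
#' @param ... `tri_mesh` objects.
#' @return One `tri_mesh` holding all components.
#' @export
merge_meshes <- function(...) {
  meshes <- list(...)
  if (length(meshes) == 1L && is.list(meshes[[1]]) && !inherits(meshes[[1]], "tri_mesh")) {
    meshes <- meshes[[1]]
  }
  v <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  off <- cumsum(c(0L, vapply(meshes, function(m) nrow(m$vertices), integer(1))))
  f <- do.call(rbind, Map(function(m, o) m$faces + o, meshes, off[-length(off)]))
  tri_mesh(v, f)
}
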