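# Watertight primitive meshes used by fixtures, cavities and joint models.

#' Axis-aligned box mesh
#'
#' @param center box centre (cm).
#' @param dims edge lengths (cm).
#' @return Watertight [tri_mesh()] (12 triangles).
#' @export
box_mesh <- function(center = c(0, 0, 0), dims = c(1, 1, 1)) {
  h <- dims / 2
  s <- expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  v <- sweep(as.matrix(s) * rep(h, each = 8), 2, -center)
  # vertex order from expand.grid: index = 1 + (x>0) + 2*(y>0) + 4*(z>0)
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4), # z-
    c(5, 6, 7), c(6, 8, 7), # z+
    c(1, 2, 5), c(2, 6, 5), # y-
    c(3, 7, 4), c(4, 7, 8), # y+
    c(1, 5, 3), c(3, 5, 7), # x-
    c(2, 4, 6), c(4, 8, 6)  # x+
  )
  tri_mesh(v, f)
}

#' Latitude-longitude sphere mesh
#'
#' @param radius sphere radius (cm).
#' @param center centre (cm).
#' @param n_theta number of latitude bands (>= 3).
#' @param n_phi number of longitude segments (>= 3).
#' @return Watertight [tri_mesh()].
#' @export
sphere_mesh <- function(radius = 1, center = c(0, 0, 0), n_theta = 24, n_phi = 48) {
  stopifnot(radius > 0, n_theta >= 3, n_phi >= 3)
  theta <- seq(0, pi, length.out = n_theta + 1)[-c(1, n_theta + 1)]
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  grid <- expand.grid(phi = phi, theta = theta)
  ring <- cbind(
    sin(grid$theta) * cos(grid$phi),
    sin(grid$theta) * sin(grid$phi),
    cos(grid$theta)
  )
  v <- rbind(c(0, 0, 1), ring, c(0, 0, -1)) * radius
  v <- sweep(v, 2, -center)
  idx <- function(i, j) 1L + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L  # ring i, seg j
  faces <- list()
  for (j in seq_len(n_phi)) {
    faces[[length(faces) + 1L]] <- c(1L, idx(1, j), idx(1, j + 1))
  }
  nr <- n_theta - 1L
  for (i in seq_len(nr - 1L)) {
    for (j in seq_len(n_phi)) {
      a <- idx(i, j); b <- idx(i, j + 1); c_ <- idx(i + 1, j); d <- idx(i + 1, j + 1)
      faces[[length(faces) + 1L]] <- c(a, c_, b)
      faces[[length(faces) + 1L]] <- c(b, c_, d)
    }
  }
  south <- nrow(v)
  for (j in seq_len(n_phi)) {
    faces[[length(faces) + 1L]] <- c(south, idx(nr, j + 1), idx(nr, j))
  }
  tri_mesh(v, do.call(rbind, faces))
}

#' Closed cylinder mesh
#'
#' Axis along `axis` through `base`; end caps are triangle fans.
#'
#' @param radius cylinder radius (cm).
#' @param length cylinder length (cm).
#' @param base centre of the starting cap (cm).
#' @param axis direction of the cylinder axis (normalised internally).
#' @param n number of circumferential segments.
#' @return Watertight [tri_mesh()].
#' @export
cylinder_mesh <- function(radius = 1, length = 1, base = c(0, 0, 0),
                          axis = c(0, 0, 1), n = 48) {
  stopifnot(radius > 0, length > 0, n >= 3)
  ax <- axis / sqrt(sum(axis^2))
  u <- orthonormal_basis(ax)
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  circ <- outer(cos(phi), u$e1) + outer(sin(phi), u$e2)
  ring0 <- sweep(circ * radius, 2, -base)
  ring1 <- sweep(ring0, 2, -ax * length)
  c0 <- base
  c1 <- base + ax * length
  v <- rbind(ring0, ring1, c0, c1)
  i0 <- seq_len(n)
  i1 <- n + i0
  nxt <- c(i0[-1], i0[1])
  faces <- list()
  for (j in seq_len(n)) {
    a <- i0[j]; b <- nxt[j]; c_ <- i1[j]; d <- n + nxt[j]
    faces[[length(faces) + 1L]] <- c(a, b, c_)
    faces[[length(faces) + 1L]] <- c(b, d, c_)
    faces[[length(faces) + 1L]] <- c(2L * n + 1L, b, a)          # base cap (outward -ax)
    faces[[length(faces) + 1L]] <- c(2L * n + 2L, c_, d)         # far cap (outward +ax)
  }
  tri_mesh(v, do.call(rbind, faces))
}

#' Two unit vectors completing `axis` to a right-handed orthonormal basis
#'
#' @param axis direction vector (normalised internally).
#' @return List with `e1`, `e2` such that `(e1, e2, axis)` is right-handed.
#' @export
orthonormal_basis <- function(axis) {
  ax <- axis / sqrt(sum(axis^2))
  helper <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- helper - sum(helper * ax) * ax
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    ax[2] * e1[3] - ax[3] * e1[2],
    ax[3] * e1[1] - ax[1] * e1[3],
    ax[1] * e1[2] - ax[2] * e1[1]
  )
  list(e1 = e1, e2 = e2)
}

#' Rotation about an arbitrary axis as an affine transform
#'
#' @param axis rotation axis (normalised internally).
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @param origin point the axis passes through (default global origin).
#' @return An [affine_transform()].
#' @export
rotation_about <- function(axis, angle_deg, origin = c(0, 0, 0)) {
  ax <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  affine_transform(R, as.numeric(origin - R %*% origin))
}
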