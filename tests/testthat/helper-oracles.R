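# Independent oracles, implemented in plain R with no calls into the
# package's geometry kernel.

# shoelace area of a 2D polygon (n x 2 matrix, ordered)
shoelace_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

# closest distance from point p to triangle (a, b, c), by dense barycentric
# refinement around the best candidate (robust, derivative-free)
r_point_tri_dist <- function(p, a, b, c) {
  f <- function(u, v) {
    q <- (1 - u - v) * a + u * b + v * c
    sqrt(sum((p - q)^2))
  }
  best <- Inf
  bu <- bv <- 0
  step <- 0.5
  grid <- expand.grid(u = seq(0, 1, 0.1), v = seq(0, 1, 0.1))
  grid <- grid[grid$u + grid$v <= 1, ]
  for (i in seq_len(nrow(grid))) {
    d <- f(grid$u[i], grid$v[i])
    if (d < best) {
      best <- d; bu <- grid$u[i]; bv <- grid$v[i]
    }
  }
  for (iter in 1:40) {
    for (du in c(-step, 0, step)) {
      for (dv in c(-step, 0, step)) {
        u <- min(max(bu + du, 0), 1)
        v <- min(max(bv + dv, 0), 1 - u)
        d <- f(u, v)
        if (d < best) {
          best <- d; bu <- u; bv <- v
        }
      }
    }
    step <- step * 0.6
  }
  best
}

# min distance between segments p1-q1 and p2-q2 by dense parameter search
r_seg_seg_dist <- function(p1, q1, p2, q2) {
  f <- function(s, t) {
    sqrt(sum(((1 - s) * p1 + s * q1 - (1 - t) * p2 - t * q2)^2))
  }
  best <- Inf
  bs <- bt <- 0
  for (s in seq(0, 1, 0.05)) {
    for (t in seq(0, 1, 0.05)) {
      d <- f(s, t)
      if (d < best) {
        best <- d; bs <- s; bt <- t
      }
    }
  }
  step <- 0.05
  for (iter in 1:40) {
    for (ds in c(-step, 0, step)) {
      for (dt in c(-step, 0, step)) {
        s <- min(max(bs + ds, 0), 1)
        t <- min(max(bt + dt, 0), 1)
        d <- f(s, t)
        if (d < best) {
          best <- d; bs <- s; bt <- t
        }
      }
    }
    step <- step * 0.6
  }
  best
}

# brute-force distance between two triangle meshes: min over all triangle
# pairs of (all vertex-triangle and edge-edge distances)
r_mesh_min_dist <- function(ma, mb) {
  best <- Inf
  for (i in seq_len(nrow(ma$faces))) {
    ta <- lapply(1:3, function(k) ma$vertices[ma$faces[i, k], ])
    for (j in seq_len(nrow(mb$faces))) {
      tb <- lapply(1:3, function(k) mb$vertices[mb$faces[j, k], ])
      for (k in 1:3) {
        best <- min(best, r_point_tri_dist(ta[[k]], tb[[1]], tb[[2]], tb[[3]]))
        best <- min(best, r_point_tri_dist(tb[[k]], ta[[1]], ta[[2]], ta[[3]]))
      }
      for (k in 1:3) {
        kn <- if (k == 3) 1 else k + 1
        for (l in 1:3) {
          ln <- if (l == 3) 1 else l + 1
          best <- min(best, r_seg_seg_dist(ta[[k]], ta[[kn]], tb[[l]], tb[[ln]]))
        }
      }
    }
  }
  best
}

# grid-search sphere fit: coarse-to-fine search over centres, radius = mean
# distance to the candidate centre
r_grid_sphere <- function(points, center0, half_width) {
  obj <- function(c0) {
    d <- sqrt(rowSums(sweep(points, 2, c0)^2))
    r <- mean(d)
    sqrt(mean((d - r)^2))
  }
  best <- Inf
  bc <- center0
  w <- half_width
  for (level in 1:6) {
    g <- as.matrix(expand.grid(
      x = bc[1] + seq(-w, w, length.out = 7),
      y = bc[2] + seq(-w, w, length.out = 7),
      z = bc[3] + seq(-w, w, length.out = 7)
    ))
    vals <- apply(g, 1, obj)
    i <- which.min(vals)
    if (vals[i] < best) {
      best <- vals[i]
      bc <- g[i, ]
    }
    w <- w / 3
  }
  d <- sqrt(rowSums(sweep(points, 2, bc)^2))
  list(center = as.numeric(bc), radius = mean(d), rms = best)
}

# numeric fine-slice volume of a lofted octagon segment with linearly
# interpolated semi-axes (midpoint rule)
r_slice_volume <- function(a0, a1, b0, b1, k, L, n = 20000) {
  t <- (seq_len(n) - 0.5) / n
  a <- a0 + t * (a1 - a0)
  b <- b0 + t * (b1 - b0)
  sum(2 * sqrt(2) * k * a * b) * L / n
}

# octagon vertices in 2D for a profile (a, b, k) - mirrors the geometric
# definition, used to feed the shoelace oracle
octagon_2d <- function(a, b, k) {
  s <- 1 / sqrt(2)
  rbind(
    c(a, 0), k * c(a * s, b * s), c(0, b), k * c(-a * s, b * s),
    c(-a, 0), k * c(-a * s, -b * s), c(0, -b), k * c(a * s, -b * s)
  )
}

# hoops along +x with linearly interpolated semi-axes
toy_hoops_test <- function(x0, x1, a0, a1, b0, b1, n, k = 1) {
  t <- seq(0, 1, length.out = n)
  lapply(t, function(ti) {
    hoop_profile(
      center = c(x0 + ti * (x1 - x0), 0, 0), axis = c(1, 0, 0), up = c(0, 0, 1),
      a = a0 + ti * (a1 - a0), b = b0 + ti * (b1 - b0), k = k
    )
  })
}

# small deterministic "blob": unit sphere mesh pushed through a fixed affine
# map (kept convex so containment semantics stay simple); `coarse` gives a
# tiny mesh sized for the brute-force distance oracle
blob_mesh <- function(seed = 1, coarse = FALSE) {
  set.seed(seed)
  A <- diag(3) + matrix(stats::runif(9, -0.25, 0.25), 3, 3)
  if (det(A) < 0) A[, 1] <- -A[, 1]
  base <- if (coarse) {
    sphere_mesh(1, n_theta = 3, n_phi = 5)
  } else {
    sphere_mesh(1, n_theta = 10, n_phi = 16)
  }
  apply_transform(base, affine_transform(A))
}
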