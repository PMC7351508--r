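# Fixture builders and independent oracles used across the test files.
# Everything here is deliberately naive (loops, quadrature, exhaustive
# search) and independent of the package's computational paths.

# --- fixtures -------------------------------------------------------------

unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # 12 triangles, outward orientation
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),       # z = 0
    c(5, 6, 7), c(6, 8, 7),       # z = 1
    c(1, 2, 5), c(2, 6, 5),       # y = 0
    c(3, 7, 4), c(4, 7, 8),       # y = 1
    c(1, 5, 3), c(3, 5, 7),       # x = 0
    c(2, 4, 6), c(4, 8, 6))       # x = 1
  trimesh(v, f, name = "unit_cube")
}

# an irregular (chiral) tetrahedron
chiral_tetrahedron <- function() {
  v <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 2, 0), c(0.7, 0.4, 1.5))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  trimesh(v, f, name = "tetra")
}

small_bone_cloud <- function(n = 300, seed = 1) {
  m <- make_base_shape(resolution = 3L)
  set.seed(seed)
  center_align(point_cloud(m$vertices[sample(nrow(m$vertices), n), ]))
}

# --- oracles --------------------------------------------------------------

# trapezoid-grid quadrature of f over a 3D box; Gaussian-tail spacing
quad3d <- function(f, lower, upper, h = 0.6) {
  gx <- seq(lower[1], upper[1], by = h)
  gy <- seq(lower[2], upper[2], by = h)
  gz <- seq(lower[3], upper[3], by = h)
  g <- as.matrix(expand.grid(gx, gy, gz))
  sum(f(g)) * h^3
}

# brute-force grid-average downsample
oracle_grid_average <- function(p, cell) {
  lo <- apply(p, 2, min)
  ix <- floor(sweep(p, 2, lo) / cell)
  key <- paste(ix[, 1], ix[, 2], ix[, 3])
  out <- NULL
  for (k in unique(key)) {
    out <- rbind(out, colMeans(p[key == k, , drop = FALSE]))
  }
  out
}

# exhaustive point-to-triangle distance (barycentric clamp, plain R)
oracle_point_triangle <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum((p - a)^2)))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum((p - b)^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    t <- d1 / (d1 - d3)
    return(sqrt(sum((p - (a + t * ab))^2)))
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum((p - c)^2)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    t <- d2 / (d2 - d6)
    return(sqrt(sum((p - (a + t * ac))^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    t <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((p - (b + t * (c - b)))^2)))
  }
  den <- va + vb + vc
  v <- vb / den; w <- vc / den
  sqrt(sum((p - (a + v * ab + w * ac))^2))
}

oracle_point_mesh <- function(points, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  apply(points, 1, function(p)
    min(vapply(seq_len(nrow(f)), function(i)
      oracle_point_triangle(p, v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ]),
      numeric(1))))
}

# finite-difference gradient of a scalar function of a matrix argument
fd_gradient <- function(fun, theta, h = 1e-6) {
  g <- theta * 0
  for (i in seq_len(nrow(theta))) for (k in seq_len(ncol(theta))) {
    tp <- theta; tp[i, k] <- tp[i, k] + h
    tm <- theta; tm[i, k] <- tm[i, k] - h
    g[i, k] <- (fun(tp) - fun(tm)) / (2 * h)
  }
  g
}

# exhaustive search over rotations (axis-angle grid) for the best
# superposition of two point sets; used to certify chirality
best_rotation_rmsd <- function(a, b, n_axis = 26, n_angle = 24) {
  axes <- unique(rbind(diag(3), -diag(3),
                       as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))))
  axes <- axes / sqrt(rowSums(axes^2))
  angles <- seq(0, 2 * pi, length.out = n_angle + 1)[-1]
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  best <- Inf
  for (i in seq_len(nrow(axes))) for (th in angles) {
    k <- axes[i, ]
    K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    rmsd <- sqrt(mean(rowSums((ac %*% t(R) - bc)^2)))
    best <- min(best, rmsd)
  }
  # refine with Kabsch on best correspondence-free guess is not needed:
  # the tetrahedra tested have labelled vertices, so identity pairing is
  # the candidate correspondence.
  best
}
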