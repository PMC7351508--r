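#' Subdivided icosahedral sphere mesh
#'
#' Starts from a regular icosahedron, subdivides each triangle into four
#' (new vertices cached per edge so the mesh stays closed), and projects
#' every vertex onto the unit sphere.  Vertex count is `10 * 4^level + 2`.
#'
#' @param level subdivision level (0 = icosahedron).
#' @param radius sphere radius (mm).
#' @return a closed, outward-oriented [trimesh()].
#' @export
icosphere <- function(level = 3L, radius = 1) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(level)) {
    nv <- nrow(v)
    edge_key <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
    mids <- new.env(hash = TRUE)
    vlist <- list(v)
    next_id <- nv
    midpoint <- function(a, b) {
      key <- as.character(edge_key(a, b))
      id <- mids[[key]]
      if (!is.null(id)) return(id)
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      next_id <<- next_id + 1L
      vlist[[length(vlist) + 1L]] <<- matrix(m, 1)
      mids[[key]] <- next_id
      next_id
    }
    nf <- matrix(0L, 4 * nrow(f), 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[4 * i - 3, ] <- c(a, ab, ca)
      nf[4 * i - 2, ] <- c(b, bc, ab)
      nf[4 * i - 1, ] <- c(cc, ca, bc)
      nf[4 * i, ]     <- c(ab, bc, ca)
    }
    v <- do.call(rbind, vlist)
    f <- nf
  }
  trimesh(v * radius, f, name = sprintf("icosphere_l%d", level))
}

#' Synthetic bone-like base shape
#'
#' A stylized talus: an ellipsoid body with one smooth protrusion
#' (emulating the talar head/neck) raised along the local outward
#' direction by a Gaussian bump in angular distance from a chosen
#' direction.  Deterministic; the mesh is closed and genus 0 by
#' construction.
#'
#' @param axes ellipsoid semi-axes (mm); the default c(25, 18, 14) plus
#'   the head protrusion gives an adult-talus-sized body (~50 x 40 x 30
#'   mm overall, volume ~36,000 mm^3).
#' @param protrusion_amplitude bump height (mm); 0 gives a pure ellipsoid.
#' @param protrusion_direction unit-ish direction of the bump centre.
#' @param protrusion_radius angular bump radius (radians).
#' @param resolution icosphere subdivision level.
#' @return a closed [trimesh()], centred near the origin.
#' @export
make_base_shape <- function(axes = c(25, 18, 14), protrusion_amplitude = 8,
                            protrusion_direction = c(1, 0, 0),
                            protrusion_radius = 0.8, resolution = 4L) {
  if (any(axes <= 0)) stop("axes must be positive")
  ico <- icosphere(resolution)
  u <- ico$vertices                       # unit directions
  e <- sweep(u, 2, axes, `*`)             # ellipsoid
  d <- protrusion_direction / sqrt(sum(protrusion_direction^2))
  ang <- acos(pmin(1, pmax(-1, u %*% d)))
  bump <- protrusion_amplitude * exp(-ang^2 / (2 * protrusion_radius^2))
  out_dir <- e / sqrt(rowSums(e^2))
  trimesh(e + as.vector(bump) * out_dir, ico$faces, name = "base_shape")
}

#' Specification of a synthetic shape population
#'
#' Defines the generative model for a seeded population of bone-like
#' surfaces: a shared base shape, a dominant multiplicative size mode,
#' one or more planted smooth local-displacement modes (Gaussian bumps
#' along vertex normals, mutually orthogonalized as 3n-vectors), small
#' iid residual vertex noise, random rigid perturbations, and optional
#' mirroring of a fraction of subjects (emulating left-side bones).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param base named list passed to [make_base_shape()].
#' @param scale_sd SD of the global scale factor (dimensionless).
#' @param mode_amplitudes per-planted-mode score SD (mm of peak vertex
#'   displacement); the vector length sets the number of planted modes.
#' @param noise_sd residual per-coordinate vertex noise SD (mm).
#' @param rot_sd_deg rigid jitter: rotation angle SD (degrees).
#' @param trans_sd_mm rigid jitter: translation SD per axis (mm).
#' @param mirror_fraction expected fraction of mirrored (left-side)
#'   subjects.
#' @param seed RNG seed; the whole population is a deterministic function
#'   of the spec.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n_subjects = 30L,
                            base = list(),
                            scale_sd = 0.05,
                            mode_amplitudes = c(1.0),
                            noise_sd = 0.05,
                            rot_sd_deg = 5,
                            trans_sd_mm = 2,
                            mirror_fraction = 0.5,
                            seed = 1L) {
  stopifnot(n_subjects >= 2, scale_sd >= 0, all(mode_amplitudes >= 0),
            noise_sd >= 0, rot_sd_deg >= 0, trans_sd_mm >= 0,
            mirror_fraction >= 0, mirror_fraction <= 1)
  structure(list(n_subjects = as.integer(n_subjects), base = base,
                 scale_sd = scale_sd, mode_amplitudes = mode_amplitudes,
                 noise_sd = noise_sd, rot_sd_deg = rot_sd_deg,
                 trans_sd_mm = trans_sd_mm,
                 mirror_fraction = mirror_fraction, seed = as.integer(seed)),
            class = "population_spec")
}

# Outward vertex normals (area-weighted average of incident face normals).
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  fn <- cross3(v[f[, 2], ] - v[f[, 1], ], v[f[, 3], ] - v[f[, 1], ])
  n <- matrix(0, nrow(v), 3)
  for (c in 1:3) {
    n <- n + accum_rows(nrow(v), f[, c], fn)
  }
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

# Planted displacement fields: Gaussian bumps along vertex normals at
# fixed centre directions, orthogonalized (Gram-Schmidt) against the
# scale-mode direction and each other, then rescaled so the peak vertex
# displacement is 1 mm (scores are in mm of peak displacement).
planted_mode_fields <- function(base_mesh, n_modes, bump_radius = 0.7) {
  v <- base_mesh$vertices
  ctr <- colMeans(v)
  vc <- sweep(v, 2, ctr)
  nrm <- vertex_normals(base_mesh)
  u <- vc / sqrt(rowSums(vc^2))
  centres <- rbind(c(0, 0, 1), c(0, 1, 0), c(0, 0, -1), c(0, -1, 0),
                   c(-1, 0, 0))
  if (n_modes > nrow(centres)) stop("at most ", nrow(centres), " planted modes")
  scale_dir <- as.vector(vc)
  scale_dir <- scale_dir / sqrt(sum(scale_dir^2))
  fields <- matrix(0, 3 * nrow(v), n_modes)
  for (k in seq_len(n_modes)) {
    ang <- acos(pmin(1, pmax(-1, u %*% centres[k, ])))
    w <- exp(-ang^2 / (2 * bump_radius^2))
    fk <- as.vector(as.vector(w) * nrm)
    fk <- fk - sum(fk * scale_dir) * scale_dir
    if (k > 1) for (j in seq_len(k - 1))
      fk <- fk - sum(fk * fields[, j]) * fields[, j]
    fields[, k] <- fk / sqrt(sum(fk^2))
  }
  # rescale each (now orthonormal) field so peak displacement is 1 mm
  for (k in seq_len(n_modes)) {
    disp <- matrix(fields[, k], ncol = 3)
    fields[, k] <- fields[, k] / max(sqrt(rowSums(disp^2)))
  }
  fields
}

# Rotation matrix from an axis-angle vector.
rotation_from_axis_angle <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Generate a seeded synthetic shape population
#'
#' Subject i is the base mesh scaled by `1 + scale_i` about its centroid,
#' displaced along each planted mode field by `score_ik`, perturbed by iid
#' vertex noise, rigidly jittered, and mirrored with probability
#' `mirror_fraction`.  Everything drawn is recorded in the ground truth,
#' and the output is a deterministic function of the spec (seed included).
#'
#' @param spec a [population_spec()].
#' @return list with elements `meshes` (list of [trimesh()]),
#'   `base_mesh`, and `truth` — a list holding per-subject `scale`,
#'   `scores` (n x K, mm), `mirrored`, `rotations`, `translations`,
#'   `mode_fields` (3n x K), and the identity vertex `correspondence`.
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  base_mesh <- do.call(make_base_shape, spec$base)
  v0 <- base_mesh$vertices
  ctr <- colMeans(v0)
  K <- length(spec$mode_amplitudes)
  has_modes <- K > 0 && any(spec$mode_amplitudes > 0)
  fields <- if (K > 0) planted_mode_fields(base_mesh, K) else
    matrix(0, 3 * nrow(v0), 0)

  set.seed(spec$seed)
  n <- spec$n_subjects
  scales <- rnorm(n, 0, spec$scale_sd)
  # fix the empirical spread of the size factors at the nominal value
  # (part of the orthogonal design below: the planted spectrum should be
  # a property of the spec, not of the luck of the draw)
  if (spec$scale_sd > 0 && sd(scales) > 0)
    scales <- mean(scales) + (scales - mean(scales)) *
      spec$scale_sd / sd(scales)
  scores <- if (K > 0)
    sapply(seq_len(K), function(k) rnorm(n, 0, spec$mode_amplitudes[k]))
  else matrix(0, n, 0)
  scores <- matrix(scores, n, K)
  # orthogonal design: decorrelate each planted score column from the
  # scale draws and from earlier modes, then restore its nominal spread,
  # so the planted factors are identifiable rather than confounded by
  # finite-sample correlation between random draws
  if (K > 0 && spec$scale_sd > 0) {
    basis_cols <- cbind(scales - mean(scales))
    for (k in seq_len(K)) {
      v <- scores[, k] - mean(scores[, k])
      for (j in seq_len(ncol(basis_cols))) {
        b <- basis_cols[, j]
        v <- v - sum(v * b) / sum(b * b) * b
      }
      if (sd(v) > 0 && spec$mode_amplitudes[k] > 0)
        v <- v * spec$mode_amplitudes[k] / sd(v)
      scores[, k] <- v
      basis_cols <- cbind(basis_cols, v)
    }
  }
  mirrored <- runif(n) < spec$mirror_fraction
  rots <- vector("list", n)
  trans <- vector("list", n)
  meshes <- vector("list", n)

  for (i in seq_len(n)) {
    v <- sweep(sweep(v0, 2, ctr), 2, rep(1 + scales[i], 3), `*`)
    v <- sweep(v, 2, ctr, `+`)
    if (K > 0)
      v <- v + matrix(fields %*% scores[i, ], ncol = 3)
    if (spec$noise_sd > 0)
      v <- v + matrix(rnorm(length(v), 0, spec$noise_sd), ncol = 3)
    w <- rnorm(3) ; w <- w / max(sqrt(sum(w^2)), 1e-12)
    ang <- rnorm(1, 0, spec$rot_sd_deg * pi / 180)
    R <- rotation_from_axis_angle(w * ang)
    tr <- rnorm(3, 0, spec$trans_sd_mm)
    rots[[i]] <- R
    trans[[i]] <- tr
    v <- v %*% t(R) + matrix(tr, nrow(v), 3, byrow = TRUE)
    m <- trimesh(v, base_mesh$faces, name = sprintf("subject_%02d", i))
    if (mirrored[i]) m <- mirror_mesh(m, "x")
    meshes[[i]] <- m
  }
  list(meshes = meshes, base_mesh = base_mesh,
       truth = list(scale = scales, scores = scores, mirrored = mirrored,
                    rotations = rots, translations = trans,
                    mode_fields = fields,
                    correspondence = seq_len(nrow(v0))))
}

#' Recovery metrics of a shape model against planted ground truth
#'
#' Compares the model's per-subject mode scores with the planted
#' generative parameters: absolute correlations between each leading PC
#' score vector and each planted score vector (global scale first, then
#' the planted local modes), and the principal angles between the leading
#' recovered score subspace and the planted score subspace.
#'
#' @param model a [shape_model()] built from the population (subjects in
#'   generation order).
#' @param truth the `truth` element of [generate_population()].
#' @param n_modes how many leading modes to compare; defaults to the
#'   number of planted parameters (scale + local modes).
#' @return list: `correlations` (n_modes x n_planted, |r|),
#'   `principal_angles_deg` (length n_modes, ascending).
#' @export
evaluate_recovery <- function(model, truth, n_modes = NULL) {
  planted <- cbind(scale = truth$scale, truth$scores)
  if (nrow(planted) != model$n_subjects)
    stop("model has ", model$n_subjects, " subjects but truth has ",
         nrow(planted))
  if (is.null(n_modes)) n_modes <- ncol(planted)
  n_modes <- min(n_modes, ncol(model$scores), ncol(planted))
  S <- model$scores[, seq_len(n_modes), drop = FALSE]
  P <- planted[, seq_len(n_modes), drop = FALSE]
  correlations <- abs(stats::cor(S, P))
  Qs <- qr.Q(qr(scale(S, scale = FALSE)))
  Qp <- qr.Q(qr(scale(P, scale = FALSE)))
  sv <- svd(crossprod(Qs, Qp))$d
  angles <- acos(pmin(1, pmax(-1, sv))) * 180 / pi
  list(correlations = correlations,
       principal_angles_deg = sort(angles))
}
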