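# helper: population of clouds in exact correspondence (no registration),
# built from the generator's ground-truth vertex correspondence
truth_clouds <- function(pop) {
  lapply(pop$meshes, function(m) point_cloud(m$vertices))
}

# a small aligned population: no mirroring, no rigid jitter, so the raw
# vertices are already corresponded and comparable
aligned_spec <- function(...) {
  population_spec(base = list(resolution = 2L), rot_sd_deg = 0,
                  trans_sd_mm = 0, mirror_fraction = 0, ...)
}

test_that("two subjects give one non-zero eigenvalue and the midpoint mean", {
  set.seed(1)
  a <- matrix(rnorm(30), ncol = 3)
  b <- a + matrix(rnorm(30, sd = 0.5), ncol = 3)
  m <- build_shape_model(list(point_cloud(a), point_cloud(b)))
  expect_identical(length(m$eigenvalues), 1L)
  expect_gt(m$eigenvalues[1], 0)
  expect_equal(m$mean_shape, (a + b) / 2)
  expect_equal(variance_explained(m, 1), 1)
})

test_that("a population of identical shapes has zero variance and that shape as mean", {
  a <- matrix(rnorm(30), ncol = 3)
  m <- build_shape_model(replicate(4, point_cloud(a), simplify = FALSE))
  expect_equal(max(m$eigenvalues), 0, tolerance = 1e-18)
  expect_equal(m$mean_shape, a)
})

test_that("PC1 recovers a planted pure scale mode", {
  spec <- aligned_spec(n_subjects = 20, scale_sd = 0.05,
                       mode_amplitudes = numeric(0), noise_sd = 0.01,
                       seed = 31)
  pop <- generate_population(spec)
  m <- build_shape_model(truth_clouds(pop))
  expect_gt(abs(cor(m$scores[, 1], pop$truth$scale)), 0.99)
  expect_gt(variance_explained(m, 1), 0.95)
})

test_that("synthesis at score 0 is the mean and reconstruction is exact", {
  spec <- aligned_spec(n_subjects = 8, seed = 32)
  pop <- generate_population(spec)
  clouds <- truth_clouds(pop)
  m <- build_shape_model(clouds)
  expect_equal(synthesize_shape(m)$points, m$mean_shape)
  # full-score synthesis reproduces every training shape
  for (i in seq_along(clouds)) {
    sc <- m$scores[i, ] / sqrt(pmax(m$eigenvalues, 1e-300))
    rec <- synthesize_shape(m, sc)
    expect_equal(rec$points, clouds[[i]]$points, tolerance = 1e-6)
  }
  expect_error(synthesize_shape(m, rep(0, 50)), "modes")
})

test_that("+3 sigma on a scale mode scales volume cubically", {
  spec <- aligned_spec(n_subjects = 24, scale_sd = 0.04,
                       mode_amplitudes = numeric(0), noise_sd = 0,
                       seed = 33)
  pop <- generate_population(spec)
  m <- build_shape_model(truth_clouds(pop))
  sigma_scale <- sd(pop$truth$scale)
  mean_mesh <- triangulate_correspondence(point_cloud(m$mean_shape),
                                          pop$base_mesh)
  plus3 <- triangulate_correspondence(synthesize_shape(m, 3),
                                      pop$base_mesh)
  ratio <- mesh_volume(plus3) / mesh_volume(mean_mesh)
  # sign of the mode is arbitrary; compare against whichever direction
  expected <- (1 + 3 * sigma_scale)^3
  expected_neg <- (1 - 3 * sigma_scale)^3
  expect_true(abs(ratio - expected) / expected < 0.02 ||
              abs(ratio - expected_neg) / expected_neg < 0.02)
})

test_that("variance fractions sum to one, are sorted, and validate k", {
  spec <- aligned_spec(n_subjects = 10, seed = 34)
  pop <- generate_population(spec)
  m <- build_shape_model(truth_clouds(pop))
  expect_equal(sum(m$variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(m$variance_fraction) <= 1e-12))
  expect_equal(variance_explained(m, length(m$eigenvalues)), 1,
               tolerance = 1e-9)
  expect_error(variance_explained(m, 0), "range")
  expect_error(variance_explained(m, 99), "range")
})

test_that("eigenvalue sum equals the total coordinate variance (trace)", {
  spec <- aligned_spec(n_subjects = 9, seed = 35)
  pop <- generate_population(spec)
  clouds <- truth_clouds(pop)
  m <- build_shape_model(clouds)
  X <- t(sapply(clouds, function(cl) as.vector(cl$points)))
  total <- sum(apply(X, 2, stats::var))
  expect_equal(sum(m$eigenvalues), total, tolerance = 1e-9 * total)
})

test_that("eigenvectors are orthonormal with deterministic signs", {
  spec <- aligned_spec(n_subjects = 7, seed = 36)
  pop <- generate_population(spec)
  m <- build_shape_model(truth_clouds(pop))
  V <- m$eigenvectors
  expect_equal(crossprod(V), diag(ncol(V)), tolerance = 1e-9)
  for (k in seq_len(ncol(V)))
    expect_gt(V[which.max(abs(V[, k])), k], 0)
  m2 <- build_shape_model(truth_clouds(pop))
  expect_identical(m$eigenvectors, m2$eigenvectors)
})

test_that("mismatched point counts are a correspondence error", {
  a <- point_cloud(matrix(rnorm(30), ncol = 3))
  b <- point_cloud(matrix(rnorm(33), ncol = 3))
  expect_error(build_shape_model(list(a, b)), "mismatch")
  expect_error(build_shape_model(list(a)), "2 subjects")
})

test_that("triangulate_correspondence transfers reference connectivity", {
  m <- make_base_shape(resolution = 2L)
  same <- triangulate_correspondence(mesh_to_cloud(m), m)
  expect_identical(same$faces, m$faces)
  expect_equal(same$vertices, m$vertices)
  scaled <- triangulate_correspondence(point_cloud(2 * m$vertices), m)
  expect_equal(mesh_volume(scaled), 8 * mesh_volume(m), tolerance = 1e-9)
  expect_true(isTRUE(is_closed_mesh(scaled)))
  expect_error(
    triangulate_correspondence(point_cloud(m$vertices[-1, ]), m),
    "mismatch")
})

test_that("warp_mesh lifts a sparse correspondence to the full mesh", {
  m <- make_base_shape(resolution = 3L)
  cl <- center_align(ssmreg:::downsample_to_count(mesh_to_cloud(m), 200L))
  # a pure translation of the cloud should translate the mesh
  moved <- point_cloud(cl$points + matrix(c(1, 2, 3), nrow(cl$points), 3,
                                          byrow = TRUE))
  wm <- warp_mesh(m, cl, moved)
  expect_equal(colMeans(wm$vertices) - colMeans(m$vertices), c(1, 2, 3),
               tolerance = 0.05)
  expect_identical(wm$faces, m$faces)
})

test_that("cohort labels never mix subjects between models", {
  spec <- aligned_spec(n_subjects = 10, seed = 37)
  pop <- generate_population(spec)
  clouds <- truth_clouds(pop)
  males <- clouds[1:5]; females <- clouds[6:10]
  mm <- build_shape_model(males, "male")
  mf <- build_shape_model(females, "female")
  expect_identical(mm$n_subjects, 5L)
  expect_identical(mf$cohort_label, "female")
  Xm <- t(sapply(males, function(cl) as.vector(cl$points)))
  expect_equal(as.vector(mm$mean_shape), colMeans(Xm))
})
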