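test_that("signed distances have hand-checkable values on the unit cube", {
  cube <- unit_cube_mesh()
  d <- signed_distances(rbind(c(0.5, 0.5, 1.5), c(0.5, 0.5, 0.5),
                              c(0.5, 0.5, 0.25)), cube)
  expect_equal(d, c(0.5, -0.5, -0.25), tolerance = 1e-12)
  # points sampled on the surface itself are at distance ~0
  on_surf <- rbind(c(0.3, 0.7, 0), c(1, 0.2, 0.8), c(0.5, 1, 0.5))
  expect_equal(abs(signed_distances(on_surf, cube)), rep(0, 3),
               tolerance = 1e-9)
})

test_that("point-to-mesh distance matches the exhaustive triangle oracle", {
  set.seed(1)
  sph <- icosphere(2)
  pts <- matrix(rnorm(3 * 60, sd = 1.2), ncol = 3)
  fast <- abs(signed_distances(pts, sph))
  slow <- oracle_point_mesh(pts, sph)
  expect_equal(fast, slow, tolerance = 1e-9)
})

test_that("signed distance requires a closed mesh unless unsigned is requested", {
  cube <- unit_cube_mesh()
  open_mesh <- trimesh(cube$vertices, cube$faces[-1, ])
  p <- matrix(c(0.5, 0.5, 2), 1)
  expect_error(signed_distances(p, open_mesh), "closed")
  expect_equal(signed_distances(p, open_mesh, signed = FALSE), 1,
               tolerance = 1e-12)
})

test_that("deviation reports equal brute-force statistics", {
  set.seed(2)
  sph <- icosphere(2)
  pts <- matrix(rnorm(150, sd = 1.3), ncol = 3)
  rep_ <- deviation_report(point_cloud(pts), sph, threshold = 0.25)
  d <- rep_$distances
  expect_equal(rep_$mean_signed, mean(d))
  expect_equal(rep_$mean_abs, mean(abs(d)))
  expect_equal(rep_$max_positive, max(c(d[d > 0], 0)))
  expect_equal(rep_$max_negative, min(c(d[d < 0], 0)))
  expect_equal(rep_$fraction_over, mean(abs(d) > 0.25))
  expect_lte(rep_$max_negative, 0)
  expect_gte(rep_$max_positive, 0)
  expect_lte(abs(rep_$mean_signed), rep_$mean_abs)
})

test_that("identical shapes give an all-zero report", {
  sph <- icosphere(2)
  rep_ <- deviation_report(mesh_to_cloud(sph), sph)
  expect_equal(rep_$mean_abs, 0, tolerance = 1e-9)
  expect_equal(rep_$fraction_over, 0)
})

test_that("a uniformly inflated cube deviates by exactly the offset", {
  cube <- unit_cube_mesh()
  big <- cube
  big$vertices <- sweep(sweep(big$vertices, 2, 0.5), 2, rep(5, 3), `*`)
  big$vertices <- sweep(big$vertices, 2, 0.5, `+`)  # 5x cube, same centre
  # vertices of the big cube are corners: distance to unit cube = corner gap
  d <- signed_distances(big$vertices, cube)
  expect_true(all(d > 0))
  expect_equal(min(d), sqrt(3 * 2^2), tolerance = 1e-9)
  rep_ <- deviation_report(mesh_to_cloud(big), cube, threshold = 1)
  expect_equal(rep_$fraction_over, 1)
})

test_that("a half-on-surface, half-offset cloud gives fraction_over one half", {
  sph <- icosphere(3)
  v <- sph$vertices
  test <- rbind(v[1:100, ], 1.5 * v[101:200, ])   # 0.5 outside radially
  rep_ <- deviation_report(point_cloud(test), sph, threshold = 0.25)
  expect_equal(rep_$fraction_over, 0.5, tolerance = 0.01)
})

test_that("fraction_over is monotone non-increasing in the threshold", {
  set.seed(3)
  sph <- icosphere(2)
  pts <- matrix(rnorm(120, sd = 1.4), ncol = 3)
  fr <- vapply(c(0.05, 0.1, 0.3, 0.6, 1), function(th)
    deviation_report(point_cloud(pts), sph, threshold = th)$fraction_over,
    numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("distances are invariant under a common rigid motion", {
  set.seed(4)
  sph <- icosphere(2)
  pts <- matrix(rnorm(90, sd = 1.2), ncol = 3)
  d0 <- signed_distances(pts, sph)
  ang <- 0.6
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  tf <- rigid_transform(R, c(2, -3, 1))
  d1 <- signed_distances(apply_rigid(tf, point_cloud(pts))$points,
                         apply_rigid(tf, sph))
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("volume matching removes pure scale differences", {
  sph <- icosphere(3)
  big <- sph; big$vertices <- big$vertices * 2
  rep_ <- compare_volume_matched(sph, big, 10)
  expect_lt(rep_$mean_abs, 1e-6)
  expect_equal(rep_$fraction_over, 0)
  # mesh against itself at any target volume
  rep2 <- compare_volume_matched(sph, sph, 33540)
  expect_lt(rep2$mean_abs, 1e-6)
})

test_that("a planted bump survives volume matching at its height", {
  base <- make_base_shape(resolution = 3L, protrusion_amplitude = 0)
  bumped <- make_base_shape(resolution = 3L, protrusion_amplitude = 1.5,
                            protrusion_radius = 0.35)
  rep_ <- compare_volume_matched(base, bumped, mesh_volume(base),
                                 threshold = 1)
  expect_gt(rep_$max_positive, 0.9)
  expect_lt(rep_$max_positive, 2.1)
})

test_that("plane sections recover closed-form circumferences", {
  cube <- unit_cube_mesh()
  s <- plane_sections(cube, "z", 0.5)
  expect_identical(length(s$polylines), 1L)
  expect_equal(s$circumference, 4, tolerance = 1e-9)
  loop <- s$polylines[[1]]
  expect_equal(loop[1, ], loop[nrow(loop), ])
  sph <- plane_sections(icosphere(4), "x", 0)
  expect_equal(sph$circumference, 2 * pi, tolerance = 0.01 * 2 * pi)
  empty <- plane_sections(cube, "z", 10)
  expect_identical(length(empty$polylines), 0L)
  expect_equal(empty$circumference, 0)
})

test_that("section circumference is stable under mesh refinement", {
  c3 <- plane_sections(icosphere(3), "z", 0.2)$circumference
  c4 <- plane_sections(icosphere(4), "z", 0.2)$circumference
  expect_equal(c3, c4, tolerance = 0.01 * c4)
})

test_that("section differences scale with the mesh and vanish on identity", {
  cube <- unit_cube_mesh()
  for (ax in c("x", "y", "z"))
    expect_equal(section_difference(cube, cube, ax)$difference, 0)
  big <- cube
  big$vertices <- sweep(sweep(big$vertices, 2, 0.5), 2, rep(1.1, 3), `*`)
  big$vertices <- sweep(big$vertices, 2, 0.5, `+`)
  sd_ <- section_difference(cube, big, "z")
  expect_equal(sd_$difference, 0.4, tolerance = 1e-9)
  # independent oracle: total polyline length difference
  ca <- plane_sections(cube, "z", 0.5)$circumference
  cb <- plane_sections(big, "z", 0.5)$circumference
  expect_equal(sd_$difference, abs(ca - cb), tolerance = 1e-9)
})
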