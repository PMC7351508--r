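test_that("STL round trips preserve topology and coordinates", {
  cube <- unit_cube_mesh()
  for (mode in c("binary", "ascii")) {
    f <- withr::local_tempfile(fileext = ".stl")
    write_stl(cube, f, mode = mode)
    back <- read_stl(f)
    expect_equal(nrow(back$vertices), 8L)
    expect_equal(nrow(back$faces), 12L)
    # same vertex set (order may differ)
    key <- function(v) sort(apply(v, 1, paste, collapse = "|"))
    expect_identical(key(back$vertices), key(cube$vertices))
    expect_equal(mesh_volume(back), 1.0, tolerance = 1e-9)
  }
})

test_that("binary STL obeys the 84 + 50 * nfac byte layout", {
  f <- withr::local_tempfile(fileext = ".stl")
  write_stl(unit_cube_mesh(), f, mode = "binary")
  expect_equal(file.info(f)$size, 84 + 12 * 50)
})

test_that("ASCII STL of a single triangle parses to 3 vertices, 1 face", {
  f <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid tri", " facet normal 0 0 1", "  outer loop",
               "   vertex 0 0 0", "   vertex 1 0 0", "   vertex 0 1 0",
               "  endloop", " endfacet", "endsolid tri"), f)
  m <- read_stl(f)
  expect_equal(nrow(m$vertices), 3L)
  expect_equal(nrow(m$faces), 1L)
})

test_that("corrupt and empty STL inputs are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".stl")
  con <- file(f, "wb")               # header claims facets beyond EOF
  writeBin(as.raw(rep(0, 80)), con)
  writeBin(1000L, con, size = 4, endian = "little")
  close(con)
  expect_error(read_stl(f), "byte")
  expect_error(write_stl(trimesh(matrix(0, 1, 3), matrix(integer(0), 0, 3)),
                         f), "empty")
  expect_error(read_stl(file.path(tempdir(), "nope.stl")), "no such file")
})

test_that("mirroring is an involution that preserves volume and flips chirality", {
  tet <- chiral_tetrahedron()
  mir <- mirror_mesh(tet, "x")
  expect_equal(mirror_mesh(mir, "x"), tet)
  expect_equal(mesh_volume(mir), mesh_volume(tet), tolerance = 1e-12)
  expect_equal(mesh_volume(mirror_mesh(unit_cube_mesh(), "y")), 1.0)
  # no rotation superimposes a chiral shape on its mirror image
  expect_gt(best_rotation_rmsd(tet$vertices, mir$vertices), 0.05)
  # sanity: the same search DOES superimpose the shape on a rotated copy
  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  expect_lt(best_rotation_rmsd(tet$vertices, tet$vertices %*% t(R)), 1e-6)
})

test_that("grid-average downsampling equals the brute-force per-cell centroid", {
  expect_equal(
    grid_average_downsample(point_cloud(rbind(c(0, 0, 0), c(0.1, 0, 0))), 1)$points,
    matrix(c(0.05, 0, 0), 1))
  p2 <- rbind(c(0, 0, 0), c(5, 0, 0))
  expect_equal(grid_average_downsample(point_cloud(p2), 1)$points, p2)
  set.seed(3)
  p <- matrix(runif(3 * 2000, 0, 10), ncol = 3)
  ds <- grid_average_downsample(point_cloud(p), 1)$points
  expect_lte(nrow(ds), 1000)
  orc <- oracle_grid_average(p, 1)
  key <- function(v) sort(apply(round(v, 9), 1, paste, collapse = "|"))
  expect_identical(key(ds), key(orc))
  # every output point lies within its cell bounds
  lo <- apply(p, 2, min)
  ix <- floor(sweep(ds, 2, lo) / 1)
  expect_true(all(ds >= sweep(ix, 2, lo, function(a, b) a + b) - 1e-9))
  expect_error(grid_average_downsample(point_cloud(p), 0), "positive")
})

test_that("center_align puts the centroid at the origin", {
  p <- matrix(rnorm(30, 5), ncol = 3)
  out <- center_align(point_cloud(p))
  expect_equal(colMeans(out$points), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(center_align(out), out)
  expect_equal(center_align(point_cloud(matrix(1, 1, 3)))$points,
               matrix(0, 1, 3))
})

test_that("best-fit rigid ICP recovers a known rotation + translation", {
  set.seed(5)
  src <- small_bone_cloud(400)
  ang <- 10 * pi / 180
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  tr <- c(1, 2, 3)
  tgt <- point_cloud(src$points %*% t(R) +
                     matrix(tr, nrow(src$points), 3, byrow = TRUE))
  fit <- best_fit_rigid(src, tgt)
  expect_equal(fit$rotation, R, tolerance = 1e-6)
  expect_equal(fit$translation, tr, tolerance = 1e-6)
  # identity when target equals source
  id <- best_fit_rigid(src, src)
  expect_equal(id$rotation, diag(3), tolerance = 1e-9)
  # alignment never increases the mean closest-point error
  before <- mean(ssmreg:::cpp_knn(src$points, tgt$points, 1L)$dist[, 1])
  after <- mean(ssmreg:::cpp_knn(apply_rigid(fit, src)$points,
                                 tgt$points, 1L)$dist[, 1])
  expect_lte(after, before)
  # degenerate clouds are rejected
  line <- point_cloud(cbind(1:10, 0, 0))
  expect_error(best_fit_rigid(line, line), "rank|collinear")
})

test_that("rigid transforms invert to identity", {
  ang <- 0.7
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  tf <- rigid_transform(R, c(4, -1, 2))
  p <- point_cloud(matrix(rnorm(30), ncol = 3))
  back <- apply_rigid(invert_rigid(tf), apply_rigid(tf, p))
  expect_equal(back$points, p$points, tolerance = 1e-9)
})

test_that("mesh volume matches closed forms and scales cubically", {
  cube <- unit_cube_mesh()
  expect_equal(mesh_volume(cube), 1.0)
  big <- cube; big$vertices <- big$vertices * 2
  expect_equal(mesh_volume(big), 8.0)
  expect_equal(mesh_volume(icosphere(4)), 4 * pi / 3, tolerance = 0.01)
  for (s in c(0.5, 2, 3)) {
    sc <- cube; sc$vertices <- sc$vertices * s
    expect_equal(mesh_volume(sc), s^3, tolerance = 1e-12)
  }
  open_mesh <- trimesh(cube$vertices, cube$faces[-1, ])
  expect_error(mesh_volume(open_mesh), "boundary")
})

test_that("scale_to_volume hits the target volume and preserves the centroid", {
  cube <- unit_cube_mesh()
  s8 <- scale_to_volume(cube, 8)
  expect_equal(mesh_volume(s8), 8, tolerance = 1e-6)
  expect_equal(diff(range(s8$vertices[, 1])), 2, tolerance = 1e-9)
  expect_equal(colMeans(s8$vertices), colMeans(cube$vertices),
               tolerance = 1e-9)
  expect_equal(scale_to_volume(cube, mesh_volume(cube)), cube,
               tolerance = 1e-12)
  expect_error(scale_to_volume(cube, -1), "positive")
})
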