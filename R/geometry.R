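#' Mirror a mesh across a coordinate plane
#'
#' Negates the chosen coordinate and flips the face winding so outward
#' normals are preserved.  Used to map left-side bones onto the right-side
#' convention before pooling a cohort.  Enclosed volume is unchanged and
#' mirroring twice restores the original mesh.
#'
#' @param mesh a [trimesh()].
#' @param axis which coordinate to negate: "x" (default, sagittal), "y", "z".
#' @return the mirrored `trimesh`.
#' @export
mirror_mesh <- function(mesh, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  k <- match(axis, c("x", "y", "z"))
  v <- mesh$vertices
  v[, k] <- -v[, k]
  trimesh(v, mesh$faces[, c(1L, 3L, 2L), drop = FALSE], name = mesh$name)
}

#' Grid-average downsampling of a point cloud
#'
#' Partitions space into axis-aligned cubic cells of edge `cell_size`
#' anchored at the cloud's minimum corner and replaces the points of each
#' non-empty cell by their centroid.
#'
#' @param cloud a [point_cloud()].
#' @param cell_size cell edge length in mm; must be positive.
#' @return a downsampled `point_cloud` (at most as many points as the input).
#' @export
grid_average_downsample <- function(cloud, cell_size) {
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  p <- coords(cloud)
  lo <- apply(p, 2, min)
  ix <- floor(sweep(p, 2, lo) / cell_size)
  key <- ix[, 1] + 1e6 * ix[, 2] + 1e12 * ix[, 3]
  g <- match(key, unique(key))
  out <- rowsum(p, g) / tabulate(g)
  dimnames(out) <- NULL
  point_cloud(out, source_id = if (inherits(cloud, "point_cloud"))
    cloud$source_id else "")
}

#' Translate a point cloud so its centroid is at the origin
#'
#' @param cloud a [point_cloud()] (or coordinate matrix).
#' @return the centered `point_cloud`.
#' @export
center_align <- function(cloud) {
  p <- coords(cloud)
  if (nrow(p) == 0L) stop("empty cloud")
  replace_coords(cloud, sweep(p, 2, colMeans(p)))
}

#' Rigid alignment of two point clouds by iterative closest point
#'
#' Alternates nearest-neighbour correspondence with the least-squares
#' rigid (Kabsch) update until the mean closest-point distance stops
#' improving.  No scaling is applied: size differences are part of the
#' shape variation the downstream model must see.
#'
#' @param source,target [point_cloud()]s with at least 4 points each.
#' @param max_iter maximum ICP iterations.
#' @param tol relative improvement in mean closest-point distance below
#'   which iteration stops.
#' @return a [rigid_transform()] mapping `source` toward `target`.
#' @export
best_fit_rigid <- function(source, target, max_iter = 50L, tol = 1e-8) {
  src <- coords(source)
  tgt <- coords(target)
  if (nrow(src) < 4L || nrow(tgt) < 4L) stop("need at least 4 points per cloud")
  R <- diag(3)
  tr <- c(0, 0, 0)
  cur <- src
  last_err <- Inf
  for (it in seq_len(max_iter)) {
    nn <- cpp_knn(cur, tgt, 1L)
    err <- mean(nn$dist[, 1])
    if (is.finite(last_err) && (last_err - err) <= tol * max(last_err, 1e-12))
      break
    last_err <- err
    matched <- tgt[nn$index[, 1], , drop = FALSE]
    upd <- kabsch(cur, matched)
    R <- upd$rotation %*% R
    tr <- as.numeric(upd$rotation %*% tr) + upd$translation
    cur <- cur %*% t(upd$rotation) +
      matrix(upd$translation, nrow(cur), 3, byrow = TRUE)
  }
  rigid_transform(R, tr)
}

# Least-squares rigid transform mapping x onto y (rows paired).
kabsch <- function(x, y) {
  cx <- colMeans(x)
  cy <- colMeans(y)
  H <- crossprod(sweep(x, 2, cx), sweep(y, 2, cy))
  s <- svd(H)
  if (min(s$d) < 1e-12 * max(s$d, 1e-300))
    stop("rank-deficient (collinear) point configuration in rigid fit")
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  list(rotation = R, translation = as.numeric(cy - R %*% cx))
}

# Directed edges of every face, as a 2-column matrix.
mesh_edges <- function(mesh) {
  f <- mesh$faces
  rbind(f[, 1:2, drop = FALSE], f[, 2:3, drop = FALSE],
        cbind(f[, 3], f[, 1]))
}

#' Check that a mesh is closed (watertight)
#'
#' A closed, consistently oriented triangle mesh has every undirected edge
#' shared by exactly two faces, once in each direction.
#'
#' @param mesh a [trimesh()].
#' @return TRUE if closed; otherwise FALSE with attribute
#'   `boundary_edges` listing offending undirected edges.
#' @export
is_closed_mesh <- function(mesh) {
  e <- mesh_edges(mesh)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  bad <- names(cnt)[cnt != 2]
  if (length(bad) == 0) return(TRUE)
  structure(FALSE, boundary_edges = bad)
}

#' Enclosed volume of a closed mesh
#'
#' Signed sum of tetrahedra spanned by each face and the origin
#' (divergence theorem), returned as a positive magnitude.
#'
#' @param mesh a closed, consistently oriented [trimesh()].
#' @return volume in cubic millimetres.
#' @export
mesh_volume <- function(mesh) {
  closed <- is_closed_mesh(mesh)
  if (!isTRUE(closed)) {
    be <- attr(closed, "boundary_edges")
    stop("mesh is not closed; ", length(be), " boundary edge(s), e.g. ",
         paste(head(be, 5), collapse = "; "))
  }
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  vol <- sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
             a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
             a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
  abs(vol)
}

#' Uniformly scale a mesh to a target enclosed volume
#'
#' Scales about the vertex centroid by `(target_volume / volume)^(1/3)`,
#' so position is preserved and only size changes.
#'
#' @param mesh a closed [trimesh()].
#' @param target_volume desired volume in cubic mm; must be positive.
#' @return the rescaled `trimesh`.
#' @export
scale_to_volume <- function(mesh, target_volume) {
  if (!is.numeric(target_volume) || target_volume <= 0)
    stop("target_volume must be positive")
  vol <- mesh_volume(mesh)
  if (vol <= 0) stop("mesh has zero volume")
  s <- (target_volume / vol)^(1 / 3)
  ctr <- colMeans(mesh$vertices)
  v <- sweep(sweep(mesh$vertices, 2, ctr), 2, rep(s, 3), `*`)
  trimesh(sweep(v, 2, ctr, `+`), mesh$faces, name = mesh$name)
}

#' Vertices of a mesh as a point cloud
#' @param mesh a [trimesh()].
#' @return a [point_cloud()] of the mesh vertices.
#' @export
mesh_to_cloud <- function(mesh) point_cloud(mesh$vertices, source_id = mesh$name)
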