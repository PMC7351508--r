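#' Thin-plate-spline radial basis matrix
#'
#' Entry (m, n) is the Euclidean distance between point m and control
#' point n.  The kernel U(r) = r is the fundamental solution of the
#' biharmonic equation in 3D, so no r^2 log r term (the 2D kernel) and no
#' polynomial block appear.
#'
#' @param points evaluation points ([point_cloud()] or n x 3 matrix).
#' @param control_points control points ([point_cloud()] or n_phi x 3 matrix).
#' @return an `n x n_phi` matrix of distances.
#' @export
tps_basis <- function(points, control_points) {
  p <- coords(points)
  q <- coords(control_points)
  # |p - q|^2 = |p|^2 + |q|^2 - 2 p.q, clipped at 0 against roundoff
  d2 <- outer(rowSums(p^2), rowSums(q^2), `+`) - 2 * tcrossprod(p, q)
  sqrt(pmax(d2, 0))
}

#' Thin-plate-spline transform
#'
#' A non-rigid deformation `T(x) = x + phi(x) theta` where `phi(x)` holds
#' the radial basis values of `x` against the control points.  No affine
#' block is included by default: gross pose is handled by rigid
#' pre-alignment, and a global affine component would let the optimizer
#' remove size variation that the shape model must retain.
#'
#' @param control_points n_phi x 3 matrix (or [point_cloud()]) of control
#'   points; at least 4, mutually distinct.
#' @param theta n_phi x 3 coefficient matrix; defaults to zeros (identity
#'   transform).
#' @return an object of class `tps_transform`.
#' @export
tps_transform <- function(control_points, theta = NULL) {
  cp <- coords(control_points)
  if (nrow(cp) < 4L) stop("need at least 4 control points")
  if (anyDuplicated(paste(cp[, 1], cp[, 2], cp[, 3])))
    stop("control points must be distinct")
  if (is.null(theta)) theta <- matrix(0, nrow(cp), 3)
  theta <- as.matrix(theta)
  if (!all(dim(theta) == c(nrow(cp), 3L)))
    stop("theta must be ", nrow(cp), " x 3")
  if (any(!is.finite(theta))) stop("non-finite theta")
  structure(list(control_points = cp, theta = theta), class = "tps_transform")
}

#' @export
print.tps_transform <- function(x, ...) {
  cat(sprintf("tps_transform: %d control points, |theta| = %.4g\n",
              nrow(x$control_points), sqrt(sum(x$theta^2))))
  invisible(x)
}

#' Apply a TPS transform to points
#'
#' @param transform a [tps_transform()].
#' @param points [point_cloud()] or n x 3 matrix.
#' @param basis optional precomputed `tps_basis(points, control_points)`;
#'   pass it when applying the same transform repeatedly.
#' @return the deformed points, same class as the input.
#' @export
tps_apply <- function(transform, points, basis = NULL) {
  p <- coords(points)
  if (is.null(basis)) basis <- tps_basis(p, transform$control_points)
  if (ncol(basis) != nrow(transform$theta))
    stop("basis has ", ncol(basis), " columns but theta has ",
         nrow(transform$theta), " rows")
  replace_coords(points, p + basis %*% transform$theta)
}

#' TPS bending (stress) energy
#'
#' The quadratic roughness penalty `tr(theta' phi' phi theta)`, i.e. the
#' squared Frobenius norm of the displacement field `phi theta` sampled at
#' the points that generated `basis`.
#'
#' @param transform a [tps_transform()].
#' @param basis basis matrix `phi` (rows = evaluation points).
#' @return a non-negative scalar.
#' @export
tps_stress <- function(transform, basis) {
  d <- basis %*% transform$theta
  sum(d * d)
}

#' Gradient of the TPS stress energy with respect to theta
#'
#' Analytic form `2 phi' phi theta`.
#'
#' @inheritParams tps_stress
#' @return an `n_phi x 3` matrix.
#' @export
tps_stress_gradient <- function(transform, basis) {
  2 * crossprod(basis, basis %*% transform$theta)
}

#' Write a TPS transform to a plain-text file
#'
#' Stores the control-point block and the coefficient block in a simple
#' whitespace-delimited format for reproducibility.
#'
#' @param transform a [tps_transform()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_tps <- function(transform, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(transform$control_points)
  writeLines(sprintf("tps %d", n), con)
  writeLines("control_points", con)
  utils::write.table(format(transform$control_points, digits = 17),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines("theta", con)
  utils::write.table(format(transform$theta, digits = 17),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a TPS transform written by [write_tps()]
#' @param path path to the file.
#' @return a [tps_transform()].
#' @export
read_tps <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\\s+")[[1]]
  if (hdr[1] != "tps") stop("not a tps transform file: ", path)
  n <- as.integer(hdr[2])
  stopifnot(lines[2] == "control_points", lines[3 + n] == "theta")
  parse_block <- function(block) {
    vals <- lapply(strsplit(trimws(block), "\\s+"), as.numeric)
    do.call(rbind, vals)
  }
  cp <- parse_block(lines[3:(2 + n)])
  th <- parse_block(lines[(4 + n):(3 + 2 * n)])
  tps_transform(cp, th)
}

#' Pick control points by coarse grid-average downsampling
#'
#' Chooses approximately `n_target` control points by bisecting the
#' grid-average cell size on the reference cloud.
#'
#' @param cloud the reference [point_cloud()].
#' @param n_target desired number of control points; `NA` returns the
#'   cloud itself (every point a control point).
#' @return a [point_cloud()] of control points.
#' @export
select_control_points <- function(cloud, n_target = NA_integer_) {
  p <- coords(cloud)
  if (is.na(n_target) || nrow(p) <= n_target) return(point_cloud(p))
  downsample_to_count(point_cloud(p), n_target)
}

# Bisection on grid cell size to approximate a target point count.
downsample_to_count <- function(cloud, n_target, max_iter = 40L) {
  p <- coords(cloud)
  if (nrow(p) <= n_target) return(point_cloud(p, source_id =
    if (inherits(cloud, "point_cloud")) cloud$source_id else ""))
  ext <- max(apply(p, 2, function(z) diff(range(z))))
  lo <- ext / (2 * n_target)   # tiny cells: many points
  hi <- ext                    # one giant cell: few points
  best <- NULL
  best_gap <- Inf
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    ds <- grid_average_downsample(cloud, mid)
    cnt <- nrow(ds$points)
    gap <- abs(cnt - n_target)
    if (gap < best_gap) { best <- ds; best_gap <- gap }
    if (cnt == n_target) break
    if (cnt > n_target) lo <- mid else hi <- mid
  }
  best
}
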