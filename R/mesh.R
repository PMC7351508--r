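#' Triangulated surface mesh
#'
#' Constructs a `trimesh` object: vertex coordinates in millimetres and
#' triangle connectivity (1-based vertex indices).
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates (mm).
#' @param faces integer matrix, m x 3, vertex indices per triangle.
#' @param name optional label carried through I/O and reports.
#' @return an object of class `trimesh` with elements `vertices`, `faces`,
#'   `name`.
#' @export
trimesh <- function(vertices, faces, name = "") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) > 0L) {
    if (max(faces) > nrow(vertices) || min(faces) < 1L)
      stop("face index out of range: vertex count is ", nrow(vertices))
    degen <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
      faces[, 2] == faces[, 3]
    if (any(degen))
      stop("degenerate faces (repeated vertex index): ",
           paste(which(degen)[seq_len(min(5, sum(degen)))], collapse = ", "))
  }
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates")
  structure(list(vertices = vertices, faces = faces, name = as.character(name)),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh '%s': %d vertices, %d faces\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Unordered 3D point cloud
#'
#' @param points numeric matrix, n x 3, coordinates in mm.
#' @param source_id subject label.
#' @return object of class `point_cloud` with elements `points`, `source_id`.
#' @export
point_cloud <- function(points, source_id = "") {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix")
  if (any(!is.finite(points))) stop("non-finite point coordinates")
  structure(list(points = points, source_id = as.character(source_id)),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud '%s': %d points\n", x$source_id, nrow(x$points)))
  invisible(x)
}

# Coerce mesh/cloud/matrix to a coordinate matrix.
coords <- function(x) {
  if (inherits(x, "trimesh")) return(x$vertices)
  if (inherits(x, "point_cloud")) return(x$points)
  as.matrix(x)
}

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector (mm).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3 x 3")
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation determinant must be +1 (no reflection)")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' Maps each row x to `rotation %*% x + translation`.
#'
#' @param transform a [rigid_transform()].
#' @param x point matrix, `point_cloud` or `trimesh`.
#' @return object of the same class as `x` with transformed coordinates.
#' @export
apply_rigid <- function(transform, x) {
  p <- coords(x)
  out <- p %*% t(transform$rotation) +
    matrix(transform$translation, nrow(p), 3, byrow = TRUE)
  replace_coords(x, out)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return the inverse `rigid_transform`.
#' @export
invert_rigid <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

replace_coords <- function(x, p) {
  if (inherits(x, "trimesh")) {
    x$vertices <- p
    x
  } else if (inherits(x, "point_cloud")) {
    x$points <- p
    x
  } else p
}
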