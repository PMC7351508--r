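#' Build a PCA statistical shape model from registered correspondences
#'
#' Each subject's registered cloud (same point count and ordering as the
#' reference — the dense correspondence) is flattened to a 3n-vector; the
#' mean shape is the coordinate-wise average and the eigenmodes come from
#' the sample covariance (divisor N - 1), computed through the singular
#' value decomposition of the centred data so only min(N, 3n) modes are
#' formed.  PCA runs on raw millimetre coordinates — no size
#' normalization — so the first mode is free to capture overall scale, as
#' it does in bone populations.
#'
#' Each eigenvector's sign is fixed so that its largest-magnitude
#' component is positive, making model builds reproducible.
#'
#' @param registered a `registered_set` from [groupwise_register()], or a
#'   list of [point_cloud()]s in correspondence.
#' @param cohort_label label stored with the model (e.g. "male", "female").
#' @return an object of class `shape_model`: `mean_shape` (n x 3),
#'   `eigenvectors` (3n x k, orthonormal columns), `eigenvalues`
#'   (variances, mm^2, descending), `variance_fraction`, `scores`
#'   (N x k, training-shape scores), `n_subjects`, `cohort_label`.
#' @export
build_shape_model <- function(registered, cohort_label = "") {
  clouds <- if (inherits(registered, "registered_set")) registered$registered
            else registered
  if (length(clouds) < 2L) stop("need at least 2 subjects")
  mats <- lapply(clouds, coords)
  n <- nrow(mats[[1]])
  if (any(vapply(mats, nrow, integer(1)) != n))
    stop("subjects have mismatched point counts; correspondence is broken")
  X <- t(vapply(mats, as.vector, numeric(3 * n)))  # N x 3n
  N <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = N, nv = min(N, ncol(Xc)))
  eigenvalues <- sv$d^2 / (N - 1)
  keep <- seq_len(min(N - 1, length(eigenvalues)))
  eigenvalues <- eigenvalues[keep]
  V <- sv$v[, keep, drop = FALSE]
  # deterministic sign: largest-magnitude component positive
  for (k in seq_len(ncol(V))) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  scores <- Xc %*% V
  total <- sum(eigenvalues)
  structure(list(
    mean_shape = matrix(mu, n, 3),
    eigenvectors = V,
    eigenvalues = eigenvalues,
    variance_fraction = if (total > 0) eigenvalues / total
                        else rep(0, length(eigenvalues)),
    scores = scores,
    n_subjects = N,
    cohort_label = as.character(cohort_label)),
    class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("shape_model '%s': %d subjects, %d points, %d modes\n",
              x$cohort_label, x$n_subjects, nrow(x$mean_shape),
              length(x$eigenvalues)))
  vf <- round(100 * x$variance_fraction[seq_len(min(5, length(x$eigenvalues)))], 1)
  cat("  variance explained (%):", paste(vf, collapse = ", "), "\n")
  invisible(x)
}

#' Synthesize a shape from the model
#'
#' Returns `mean + sum_k scores_k * sqrt(lambda_k) * v_k`, i.e. scores are
#' in units of per-mode standard deviations: `synthesize_shape(model,
#' c(3))` is the "+3 sigma" first-mode shape.
#'
#' @param model a [shape_model()].
#' @param scores numeric vector of per-mode coefficients (sigma units);
#'   shorter than the mode count is fine, longer is an error.
#' @return a [point_cloud()] with the model's point count.
#' @export
synthesize_shape <- function(model, scores = numeric(0)) {
  k <- length(scores)
  if (k > length(model$eigenvalues))
    stop("scores for ", k, " modes requested but model has ",
         length(model$eigenvalues))
  x <- as.vector(model$mean_shape)
  if (k > 0) {
    amp <- scores * sqrt(model$eigenvalues[seq_len(k)])
    x <- x + as.vector(model$eigenvectors[, seq_len(k), drop = FALSE] %*% amp)
  }
  point_cloud(matrix(x, ncol = 3),
              source_id = sprintf("%s_synth", model$cohort_label))
}

#' Cumulative variance explained by the first k modes
#'
#' @param model a [shape_model()].
#' @param k number of leading modes (1 <= k <= mode count).
#' @return fraction in [0, 1].
#' @export
variance_explained <- function(model, k) {
  if (k < 1 || k > length(model$eigenvalues)) stop("k out of range")
  sum(model$variance_fraction[seq_len(k)])
}

#' Transfer reference connectivity to a corresponded point cloud
#'
#' Because every registered cloud (and everything synthesized from the
#' model) shares the reference's point ordering, the reference mesh's
#' triangles can be reused directly: point i of the cloud replaces
#' reference point i.  Requires the reference cloud to be the reference
#' mesh's vertex set.
#'
#' @param cloud a [point_cloud()] in correspondence with `reference_cloud`.
#' @param reference_mesh the [trimesh()] supplying connectivity.
#' @param reference_cloud the reference [point_cloud()]; must match the
#'   mesh's vertex count (defaults to the mesh vertices).
#' @return a [trimesh()] over the cloud's points.
#' @export
triangulate_correspondence <- function(cloud, reference_mesh,
                                       reference_cloud = NULL) {
  p <- coords(cloud)
  if (is.null(reference_cloud)) reference_cloud <- mesh_to_cloud(reference_mesh)
  q <- coords(reference_cloud)
  if (nrow(p) != nrow(q))
    stop("correspondence count mismatch: cloud has ", nrow(p),
         " points, reference cloud has ", nrow(q))
  if (nrow(q) != nrow(reference_mesh$vertices))
    stop("correspondence count mismatch: reference cloud has ", nrow(q),
         " points but the mesh has ", nrow(reference_mesh$vertices),
         " vertices")
  trimesh(p, reference_mesh$faces, name = "corresponded")
}

#' Warp a full-resolution mesh through a sparse correspondence
#'
#' Fits an interpolating TPS-style map from `reference_cloud` to `cloud`
#' (least-squares in the shared radial basis, with a small ridge for
#' conditioning) and applies it to the mesh vertices.  Used to visualize
#' mean shapes and eigenmode shapes at full mesh resolution when the
#' registration cloud is a subsample of the reference mesh.
#'
#' @param reference_mesh the full-resolution reference [trimesh()].
#' @param reference_cloud the subsampled reference [point_cloud()].
#' @param cloud the deformed positions corresponding to `reference_cloud`.
#' @param ridge ridge factor stabilizing the basis solve.
#' @return the warped [trimesh()].
#' @export
warp_mesh <- function(reference_mesh, reference_cloud, cloud, ridge = 1e-8) {
  q <- coords(reference_cloud)
  p <- coords(cloud)
  if (nrow(p) != nrow(q)) stop("correspondence count mismatch")
  phi <- tps_basis(q, q)
  disp <- p - q
  A <- crossprod(phi) + ridge * mean(diag(crossprod(phi))) * diag(nrow(q))
  theta <- solve(A, crossprod(phi, disp))
  v <- reference_mesh$vertices + tps_basis(reference_mesh$vertices, q) %*% theta
  trimesh(v, reference_mesh$faces, name = reference_mesh$name)
}
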