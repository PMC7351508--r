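#' Signed point-to-surface distances
#'
#' For each test point: the unsigned distance to the nearest point on the
#' reference surface (exact point-to-triangle, not vertex-only), signed
#' positive outside the closed reference mesh and negative inside.  The
#' inside test uses the generalized winding number, which is robust for
#' closed oriented meshes.
#'
#' @param test a [point_cloud()] (or n x 3 matrix).
#' @param reference_mesh a closed, consistently oriented [trimesh()].
#' @param signed if FALSE, skip the inside test and return unsigned
#'   distances (allowed for open meshes).
#' @return numeric vector of distances in mm, one per test point.
#' @export
signed_distances <- function(test, reference_mesh, signed = TRUE) {
  p <- coords(test)
  if (nrow(p) == 0L) stop("empty test cloud")
  if (signed && !isTRUE(is_closed_mesh(reference_mesh)))
    stop("reference mesh is not closed; sign is undefined ",
         "(use signed = FALSE for unsigned distances)")
  d <- cpp_point_mesh_distance(p, reference_mesh$vertices,
                               reference_mesh$faces)
  if (!signed) return(d)
  w <- cpp_winding_number(p, reference_mesh$vertices, reference_mesh$faces)
  ifelse(w > 0.5, -d, d)
}

#' Deviation report between a test cloud and a reference surface
#'
#' Summary statistics over the signed per-point distances, including the
#' fraction of points whose absolute deviation strictly exceeds the
#' threshold (default 1 mm, the conventional clinical-relevance cutoff
#' for talar geometry).
#'
#' @param test a [point_cloud()].
#' @param reference_mesh a closed [trimesh()].
#' @param threshold deviation threshold in mm.
#' @return an object of class `deviation_report`: `distances`,
#'   `mean_signed`, `mean_abs`, `max_positive`, `max_negative`,
#'   `fraction_over`, `threshold`.
#' @export
deviation_report <- function(test, reference_mesh, threshold = 1.0) {
  d <- signed_distances(test, reference_mesh)
  structure(list(
    distances = d,
    mean_signed = mean(d),
    mean_abs = mean(abs(d)),
    max_positive = max(c(d[d > 0], 0)),
    max_negative = min(c(d[d < 0], 0)),
    fraction_over = mean(abs(d) > threshold),
    threshold = threshold),
    class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf(
    paste0("deviation_report (%d points): mean signed %.4f mm, mean |d| ",
           "%.4f mm,\n  max +%.4f / %.4f mm, %.1f%% of points beyond %g mm\n"),
    length(x$distances), x$mean_signed, x$mean_abs, x$max_positive,
    x$max_negative, 100 * x$fraction_over, x$threshold))
  invisible(x)
}

#' Volume-matched shape comparison
#'
#' Scales both meshes to a common enclosed volume (removing size so the
#' residual is pure shape), rigidly aligns B onto A by ICP, and reports
#' the deviation of B's vertices against A's surface.
#'
#' @param meshA the reference [trimesh()] (closed).
#' @param meshB the test [trimesh()] (closed).
#' @param target_volume common volume in cubic mm.
#' @param threshold deviation threshold in mm.
#' @return a `deviation_report` (see [deviation_report()]).
#' @export
compare_volume_matched <- function(meshA, meshB, target_volume,
                                   threshold = 1.0) {
  A <- scale_to_volume(meshA, target_volume)
  B <- scale_to_volume(meshB, target_volume)
  ca <- center_align(mesh_to_cloud(A))
  A$vertices <- ca$points
  cb <- center_align(mesh_to_cloud(B))
  B$vertices <- cb$points
  rig <- best_fit_rigid(mesh_to_cloud(B), mesh_to_cloud(A))
  B <- apply_rigid(rig, B)
  deviation_report(mesh_to_cloud(B), A, threshold = threshold)
}

#' Cross-section of a mesh by an axis-aligned plane
#'
#' Intersects every triangle with the plane `coordinate[axis] = offset`,
#' chains the resulting segments into closed loops, and sums their
#' lengths.
#'
#' @param mesh a [trimesh()].
#' @param axis "x", "y" or "z": the plane normal direction.
#' @param offset plane position along that axis (mm).
#' @return an object of class `plane_section`: `axis`, `offset`,
#'   `polylines` (list of closed loops, each a k x 3 matrix whose first
#'   and last rows coincide), `circumference` (total loop length, mm).
#'   A plane that misses the mesh gives zero loops and circumference 0.
#' @export
plane_sections <- function(mesh, axis = c("x", "y", "z"), offset = 0) {
  axis <- match.arg(axis)
  k <- match(axis, c("x", "y", "z"))
  v <- mesh$vertices
  f <- mesh$faces
  s <- v[, k] - offset

  segs <- list()
  for (i in seq_len(nrow(f))) {
    id <- f[i, ]
    si <- s[id]
    pos <- si > 0
    if (all(pos) || all(!pos)) next
    # the two edges crossing the plane
    pts <- matrix(NA_real_, 0, 3)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- si[e[1]]; b <- si[e[2]]
      if ((a > 0) != (b > 0)) {
        t <- a / (a - b)
        pts <- rbind(pts, v[id[e[1]], ] + t * (v[id[e[2]], ] - v[id[e[1]], ]))
      } else if (a == 0 && b == 0) {
        pts <- rbind(pts, v[id[e[1]], ], v[id[e[2]], ])
      }
    }
    if (nrow(pts) >= 2) segs[[length(segs) + 1L]] <- pts[1:2, , drop = FALSE]
  }
  if (length(segs) == 0L)
    return(structure(list(axis = axis, offset = offset, polylines = list(),
                          circumference = 0), class = "plane_section"))

  loops <- chain_segments(segs)
  circ <- sum(vapply(loops, function(L) {
    sum(sqrt(rowSums((L[-1, , drop = FALSE] -
                      L[-nrow(L), , drop = FALSE])^2)))
  }, numeric(1)))
  structure(list(axis = axis, offset = offset, polylines = loops,
                 circumference = circ), class = "plane_section")
}

# Chain unordered segments into closed polylines by matching endpoints
# within a tolerance scaled to segment length.
chain_segments <- function(segs) {
  ends <- do.call(rbind, lapply(segs, function(s) rbind(s[1, ], s[2, ])))
  lens <- vapply(segs, function(s) sqrt(sum((s[2, ] - s[1, ])^2)), numeric(1))
  tol <- max(1e-9, 1e-7 * stats::median(lens[lens > 0]))
  used <- rep(FALSE, length(segs))
  loops <- list()
  for (start in seq_along(segs)) {
    if (used[start]) next
    used[start] <- TRUE
    loop <- segs[[start]]
    repeat {
      tip <- loop[nrow(loop), ]
      found <- FALSE
      for (j in seq_along(segs)) {
        if (used[j]) next
        s <- segs[[j]]
        if (sum((s[1, ] - tip)^2) < tol^2) {
          loop <- rbind(loop, s[2, ]); used[j] <- TRUE; found <- TRUE; break
        }
        if (sum((s[2, ] - tip)^2) < tol^2) {
          loop <- rbind(loop, s[1, ]); used[j] <- TRUE; found <- TRUE; break
        }
      }
      if (!found) break
      if (sum((loop[nrow(loop), ] - loop[1, ])^2) < tol^2) break
    }
    # close the loop exactly
    loop[nrow(loop), ] <- if (sum((loop[nrow(loop), ] - loop[1, ])^2) < tol^2)
      loop[1, ] else loop[nrow(loop), ]
    if (!all(loop[nrow(loop), ] == loop[1, ])) loop <- rbind(loop, loop[1, ])
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' @export
print.plane_section <- function(x, ...) {
  cat(sprintf("plane_section %s = %g: %d loop(s), circumference %.4f mm\n",
              x$axis, x$offset, length(x$polylines), x$circumference))
  invisible(x)
}

#' Plane-section circumference difference between two meshes
#'
#' Sections both meshes with the axis plane through their common (mean of
#' the two) centroid and returns the absolute circumference difference —
#' the registration-accuracy check used on matched shape pairs.
#'
#' @param meshA,meshB closed [trimesh()]es, already aligned.
#' @param axis "x", "y" or "z".
#' @return list: `difference` (|cA - cB|, mm), `circumference_a`,
#'   `circumference_b`, `offset`, `empty` (TRUE if either section missed
#'   its mesh).
#' @export
section_difference <- function(meshA, meshB, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  k <- match(axis, c("x", "y", "z"))
  ctr <- (colMeans(meshA$vertices) + colMeans(meshB$vertices)) / 2
  sa <- plane_sections(meshA, axis, ctr[k])
  sb <- plane_sections(meshB, axis, ctr[k])
  empty <- length(sa$polylines) == 0L || length(sb$polylines) == 0L
  list(difference = abs(sa$circumference - sb$circumference),
       circumference_a = sa$circumference,
       circumference_b = sb$circumference,
       offset = ctr[k], empty = empty)
}
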