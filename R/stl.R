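#' Read a triangulated mesh from an STL file
#'
#' Handles both binary STL (80-byte header, uint32 facet count, 50-byte
#' little-endian facet records) and the ASCII dialect.  Vertices repeated
#' across facets are deduplicated by exact coordinate match; no tolerance
#' welding is applied, so the topology of a well-formed file is recovered
#' deterministically.
#'
#' @param path path to an STL file.
#' @param name optional mesh label; defaults to the file's base name.
#' @return a [trimesh()].
#' @export
read_stl <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(name)) name <- sub("\\.[sS][tT][lL]$", "", basename(path))
  size <- file.info(path)$size
  if (size < 15) stop("corrupt STL '", path, "': only ", size, " bytes")

  con <- file(path, "rb")
  on.exit(close(con))
  head80 <- readBin(con, "raw", n = min(80, size))
  is_ascii <- identical(head80[1:5], charToRaw("solid"))
  if (is_ascii) {
    # Binary files may also begin with "solid"; confirm the ASCII dialect by
    # looking for the 'facet' keyword in the first kilobyte.
    seek(con, 0)
    probe <- readBin(con, "raw", n = min(1024, size))
    txt <- rawToChar(probe[probe != as.raw(0)])
    if (!grepl("facet", txt) && size >= 84) is_ascii <- FALSE
  }

  if (is_ascii) {
    tri <- parse_stl_ascii(path)
  } else {
    if (size < 84)
      stop("corrupt STL '", path, "': binary header truncated at byte ", size)
    seek(con, 80)
    nfac <- readBin(con, "integer", size = 4, endian = "little")
    expected <- 84 + 50 * as.numeric(nfac)
    if (nfac < 0 || expected > size)
      stop("corrupt STL '", path, "': facet count ", nfac,
           " implies ", expected, " bytes but file has ", size,
           " (truncated at byte ", size, ")")
    if (nfac == 0L) stop("empty solid in '", path, "'")
    rec <- readBin(con, "raw", n = 50 * nfac)
    m <- matrix(rec, nrow = 50)
    coordbytes <- m[13:48, , drop = FALSE]  # drop normal (1:12) and attr (49:50)
    vals <- readBin(as.raw(coordbytes), "double", size = 4,
                    n = 9 * nfac, endian = "little")
    tri <- matrix(vals, ncol = 3, byrow = TRUE)  # 3*nfac rows of xyz
  }
  if (nrow(tri) == 0) stop("empty solid in '", path, "'")

  key <- paste(tri[, 1], tri[, 2], tri[, 3], sep = "|")
  uk <- !duplicated(key)
  verts <- tri[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  trimesh(verts, faces, name = name)
}

parse_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0) stop("empty solid in '", path, "'")
  if (length(vl) %% 3 != 0)
    stop("corrupt ASCII STL '", path, "': vertex count ", length(vl),
         " not a multiple of 3")
  toks <- strsplit(trimws(vl), "\\s+")
  vals <- vapply(toks, function(t) as.numeric(t[2:4]), numeric(3))
  tri <- t(vals)
  if (any(!is.finite(tri))) stop("corrupt ASCII STL '", path, "': bad numeral")
  tri
}

#' Write a mesh to an STL file
#'
#' @param mesh a [trimesh()].
#' @param path output path.
#' @param mode "binary" (default) or "ascii".
#' @return invisibly, the path.
#' @export
write_stl <- function(mesh, path, mode = c("binary", "ascii")) {
  mode <- match.arg(mode)
  if (!inherits(mesh, "trimesh")) stop("mesh must be a trimesh")
  if (nrow(mesh$faces) == 0L) stop("refusing to write an empty mesh")
  v <- mesh$vertices
  f <- mesh$faces
  # facet normals from winding (right-hand rule)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  n <- cross3(b - a, cc - a)
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len

  if (mode == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", paste0("ssmreg ", mesh$name)))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    # interleave: normal, v1, v2, v3 per facet as float32 + uint16 attr
    rec <- cbind(n, a, b, cc)           # nf x 12
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(rec[i, ]), con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", mesh$name), con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("  facet normal %.9e %.9e %.9e", n[i, 1], n[i, 2], n[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9e %.9e %.9e", a[i, 1], a[i, 2], a[i, 3]),
        sprintf("      vertex %.9e %.9e %.9e", b[i, 1], b[i, 2], b[i, 3]),
        sprintf("      vertex %.9e %.9e %.9e", cc[i, 1], cc[i, 2], cc[i, 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines(sprintf("endsolid %s", mesh$name), con)
  }
  invisible(path)
}

# row-wise cross product of n x 3 matrices
cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}
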