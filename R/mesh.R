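#' Triangle mesh constructor
#'
#' @param vertices Numeric n x 3 matrix (mm).
#' @param faces Integer k x 3 matrix of 1-based vertex indices.
#' @return An object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3,
            min(faces) >= 1, max(faces) <= nrow(vertices))
  structure(list(vertices = vertices, faces = faces), class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat("Triangle mesh:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "faces\n")
  invisible(x)
}

#' Closest points on a mesh surface
#'
#' For each query point, the exact nearest point on the triangle mesh
#' (point-to-triangle, not point-to-vertex).
#'
#' @param query Numeric n x 3 matrix (or a single 3-vector) of query points.
#' @param mesh A [trimesh()].
#' @return List with `points` (n x 3), `distance` (n), `triangle` (n,
#'   1-based index of the supporting triangle).
#' @export
mesh_closest_points <- function(query, mesh) {
  stopifnot(inherits(mesh, "trimesh"))
  if (is.null(dim(query))) query <- matrix(query, ncol = 3)
  mesh_closest_points_cpp(as.matrix(query), mesh$vertices, mesh$faces)
}

#' Check that a mesh is closed and manifold
#'
#' Every undirected edge must be shared by exactly two faces.
#'
#' @param mesh A [trimesh()].
#' @return Logical scalar.
#' @export
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Write a triangle mesh to STL
#'
#' @param mesh A [trimesh()].
#' @param path Output path.
#' @param binary Write binary STL (default) or ASCII.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  stopifnot(inherits(mesh, "trimesh"))
  V <- mesh$vertices
  F <- mesh$faces
  n <- nrow(F)
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  cc <- V[F[, 3], , drop = FALSE]
  u <- b - a; w <- cc - a
  nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(n), con, size = 4, endian = "little")
    # interleave: normal, v1, v2, v3 (floats), attribute count (uint16)
    tri <- t(cbind(nrm, a, b, cc)) # 12 x n
    for (i in seq_len(n)) {
      writeBin(as.numeric(tri[, i]), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(n)) {
      writeLines(sprintf("facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2],
                         nrm[i, 3]), con)
      writeLines("  outer loop", con)
      writeLines(sprintf("    vertex %.9g %.9g %.9g",
                         c(a[i, 1], b[i, 1], cc[i, 1]),
                         c(a[i, 2], b[i, 2], cc[i, 2]),
                         c(a[i, 3], b[i, 3], cc[i, 3])), con)
      writeLines("  endloop", con)
      writeLines("endfacet", con)
    }
    writeLines("endsolid mesh", con)
  }
  invisible(path)
}

#' Read a triangle mesh from STL (binary or ASCII)
#'
#' Duplicate vertices are merged exactly so connectivity-based checks
#' ([mesh_is_closed()]) work on round-tripped meshes.
#'
#' @param path Path to an STL file.
#' @return A [trimesh()].
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80)
  close(con)
  is_ascii <- identical(rawToChar(head[1:5]), "solid") &&
    !is_binary_stl(path)
  if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
}

is_binary_stl <- function(path) {
  sz <- file.info(path)$size
  if (sz < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  sz == 84 + 50 * n
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  tri <- matrix(NA_real_, 12, n)
  for (i in seq_len(n)) {
    tri[, i] <- readBin(con, "numeric", 12, size = 4, endian = "little")
    invisible(readBin(con, "raw", 2))
  }
  verts <- matrix(as.vector(tri[4:12, ]), ncol = 3, byrow = TRUE)
  build_indexed_mesh(verts)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path)
  vlines <- grep("^\\s*vertex", lines, value = TRUE)
  verts <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                                 function(x) as.numeric(x[2:4])))
  build_indexed_mesh(verts)
}

build_indexed_mesh <- function(verts) {
  key <- apply(verts, 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  idx <- match(key, key[uniq])
  trimesh(verts[uniq, , drop = FALSE], matrix(idx, ncol = 3, byrow = TRUE))
}
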