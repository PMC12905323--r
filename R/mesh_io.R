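# STL / PLY surface-mesh readers. STL stores a triangle soup; vertices are
# merged by exact coordinate match (after rounding to 1e-6 mm) so that
# edge-manifold checks are meaningful.

.merge_soup <- function(tri, name) {
  # tri: (3m) x 3 matrix, consecutive triples are triangles
  key <- apply(round(tri, 6), 1L, paste, collapse = ",")
  uid <- match(key, unique(key))
  verts <- tri[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3L, byrow = TRUE)
  mesh_shape(verts, faces, name = name)
}

#' Read an STL surface mesh (ASCII or binary)
#'
#' @param path Path to the .stl file.
#' @param name Label stored on the mesh; defaults to the file name.
#' @return A `mesh_shape` in the file's native units (assumed mm).
#' @export
read_stl <- function(path, name = basename(path)) {
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", 80L)
  close(con)
  txt_head <- rawToChar(head80[head80 != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", txt_head) &&
    any(grepl("facet", readLines(path, n = 20L, warn = FALSE)))
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    nums <- t(vapply(strsplit(trimws(vl), "\\s+"), function(x)
      as.numeric(x[2:4]), numeric(3)))
    if (nrow(nums) %% 3L != 0L)
      stop("malformed ASCII STL: vertex count not a multiple of 3 in ", path)
    .merge_soup(nums, name)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80L)
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    tri <- matrix(NA_real_, 3L * n, 3L)
    for (i in seq_len(n)) {
      vals <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
      readBin(con, "raw", 2L)
      tri[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3L, 3L, byrow = TRUE)
    }
    .merge_soup(tri, name)
  }
}

#' Write a mesh as ASCII STL
#'
#' @param mesh A `mesh_shape`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", mesh$name), con)
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1L], ]; b <- v[f[i, 2L], ]; cc <- v[f[i, 3L], ]
    e1 <- b - a; e2 <- cc - a
    n <- c(e1[2] * e2[3] - e1[3] * e2[2],
           e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g", a[1], a[2], a[3]),
                 sprintf("      vertex %.9g %.9g %.9g", b[1], b[2], b[3]),
                 sprintf("      vertex %.9g %.9g %.9g", cc[1], cc[2], cc[3]),
                 "    endloop",
                 "  endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", mesh$name), con)
  invisible(path)
}

#' Read an ASCII PLY surface mesh
#'
#' Supports the vertex (x, y, z) and face (vertex index list) elements of
#' the ASCII 1.0 format; faces must be triangles.
#'
#' @param path Path to the .ply file.
#' @param name Label stored on the mesh; defaults to the file name.
#' @return A `mesh_shape`.
#' @export
read_ply <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  if (trimws(lines[1L]) != "ply") stop("not a PLY file: ", path)
  endh <- which(trimws(lines) == "end_header")[1L]
  if (is.na(endh)) stop("PLY header not terminated in ", path)
  header <- lines[seq_len(endh)]
  if (any(grepl("format\\s+binary", header)))
    stop("binary PLY not supported: ", path)
  el <- grep("^element", trimws(header), value = TRUE)
  counts <- setNames(
    as.integer(sub("^element\\s+\\S+\\s+(\\d+).*$", "\\1", el)),
    sub("^element\\s+(\\S+).*$", "\\1", el))
  nv <- counts[["vertex"]]; nf <- counts[["face"]]
  body <- lines[(endh + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  vtx <- t(vapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"), function(x)
    as.numeric(x[1:3]), numeric(3)))
  fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- t(vapply(fl, function(x) {
    k <- as.integer(x[1L])
    if (k != 3L) stop("non-triangular face in ", path)
    as.integer(x[2:4]) + 1L
  }, integer(3)))
  mesh_shape(vtx, faces, name = name)
}

# Regular closed cylinder triangulation (used by phantom export and tests).
cylinder_mesh <- function(cx, cy, radius, z_range, n_seg = 48L,
                          name = "cylinder") {
  th <- seq(0, 2 * pi, length.out = n_seg + 1L)[-(n_seg + 1L)]
  ring <- cbind(cx + radius * cos(th), cy + radius * sin(th))
  v <- rbind(cbind(ring, z_range[1L]), cbind(ring, z_range[2L]),
             c(cx, cy, z_range[1L]), c(cx, cy, z_range[2L]))
  n <- n_seg
  bot <- seq_len(n); top <- n + seq_len(n)
  cb <- 2L * n + 1L; ct <- 2L * n + 2L
  faces <- NULL
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    faces <- rbind(faces,
                   c(bot[i], bot[j], top[i]),  # side quad, outward
                   c(bot[j], top[j], top[i]),
                   c(bot[j], bot[i], cb),      # bottom cap, normal -z
                   c(top[i], top[j], ct))      # top cap, normal +z
  }
  mesh_shape(v, faces, name = name)
}
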