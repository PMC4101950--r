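# STL and PLY readers/writers. STL files carry no units; this package treats
# all coordinates as millimetres, the convention of the surgical-planning
# formats it consumes (a `units` argument documents and enforces this).

weld_vertices <- function(verts, faces) {
  key <- paste(verts[, 1], verts[, 2], verts[, 3], sep = "|")
  first <- !duplicated(key)
  remap <- match(key, key[first])   # position in the unique-vertex list
  tri_mesh(verts[first, , drop = FALSE],
           matrix(remap[faces], ncol = 3))
}

#' Read a surface mesh from STL or PLY
#'
#' Binary and ASCII STL and ASCII PLY are supported. STL triangle soup is
#' welded back into indexed form by exact coordinate match. Coordinates are
#' interpreted as millimetres.
#'
#' @param path file path; format chosen by extension (`.stl`, `.ply`).
#' @param units unit the file is assumed to be in; only `"mm"` is supported
#'   (STL itself is unitless, so this makes the assumption explicit).
#' @return A [tri_mesh()].
#' @export
read_mesh <- function(path, units = "mm") {
  if (!identical(units, "mm"))
    stop("only millimetre meshes are supported (units = 'mm')", call. = FALSE)
  if (!file.exists(path)) stop("mesh file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    stl = read_stl(path),
    ply = read_ply(path),
    stop("unsupported mesh format '", ext, "' for ", path, call. = FALSE))
  if (nrow(mesh$vertices) == 0L)
    stop("mesh file contains no geometry: ", path, call. = FALSE)
  mesh
}

#' Write a surface mesh to STL or PLY
#'
#' @param mesh a [tri_mesh()].
#' @param path output path; format chosen by extension (`.stl`, `.ply`).
#' @param ascii for STL, write the ASCII dialect instead of binary.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, ascii = FALSE) {
  check_mesh(mesh)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    stl = if (ascii) write_stl_ascii(mesh, path) else write_stl_binary(mesh, path),
    ply = write_ply(mesh, path),
    stop("unsupported mesh format '", ext, "' for ", path, call. = FALSE))
  invisible(path)
}

face_normals <- function(mesh) {
  V <- mesh$vertices
  a <- V[mesh$faces[, 1], , drop = FALSE]
  b <- V[mesh$faces[, 2], , drop = FALSE]
  cc <- V[mesh$faces[, 3], , drop = FALSE]
  n <- cross3_rows(b - a, cc - a)
  len <- sqrt(rowSums(n * n))
  len[len < 1e-30] <- 1
  n / len
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(mesh$faces)), con, size = 4, endian = "little")
  nrm <- face_normals(mesh)
  V <- mesh$vertices
  for (i in seq_len(nrow(mesh$faces))) {
    tri <- rbind(nrm[i, ], V[mesh$faces[i, ], ])
    writeBin(as.numeric(t(tri)), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
}

write_stl_ascii <- function(mesh, path) {
  nrm <- face_normals(mesh)
  V <- mesh$vertices
  out <- vector("list", nrow(mesh$faces))
  for (i in seq_len(nrow(mesh$faces))) {
    tri <- V[mesh$faces[i, ], , drop = FALSE]
    out[[i]] <- c(
      sprintf("  facet normal %.9e %.9e %.9e", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
      "    outer loop",
      sprintf("      vertex %.9e %.9e %.9e", tri[, 1], tri[, 2], tri[, 3]),
      "    endloop",
      "  endfacet")
  }
  writeLines(c("solid mesh", unlist(out), "endsolid mesh"), path)
}

read_stl <- function(path) {
  size <- file.info(path)$size
  if (is.na(size) || size < 15) stop("unreadable STL file: ", path, call. = FALSE)
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = min(size, 512))
  close(con)
  is_binary <- FALSE
  if (size >= 84) {
    ntri <- readBin(head[81:84], "integer", size = 4, endian = "little")
    if (!is.na(ntri) && ntri >= 0 && size == 84 + 50 * as.numeric(ntri))
      is_binary <- TRUE
  }
  if (!is_binary) {
    txt <- rawToChar(head[head != as.raw(0)])
    if (!grepl("solid", txt, ignore.case = TRUE))
      stop("not a recognizable STL file: ", path, call. = FALSE)
    return(read_stl_ascii(path))
  }
  read_stl_binary(path)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  ntri <- readBin(con, "integer", size = 4, endian = "little")
  if (ntri == 0L) stop("STL file contains no facets: ", path, call. = FALSE)
  verts <- matrix(0, 3 * ntri, 3)
  for (i in seq_len(ntri)) {
    vals <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    readBin(con, "integer", n = 1, size = 2, endian = "little")
    verts[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
  }
  faces <- matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE)
  weld_vertices(verts, faces)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vlines) || length(vlines) %% 3 != 0)
    stop("malformed ASCII STL (vertex count not a multiple of 3): ", path,
         call. = FALSE)
  nums <- lapply(strsplit(trimws(vlines), "\\s+"), function(f)
    as.numeric(f[2:4]))
  verts <- do.call(rbind, nums)
  if (anyNA(verts)) stop("malformed ASCII STL coordinates: ", path, call. = FALSE)
  faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  weld_vertices(verts, faces)
}

write_ply <- function(mesh, path) {
  V <- mesh$vertices
  F <- mesh$faces
  header <- c("ply", "format ascii 1.0",
              sprintf("element vertex %d", nrow(V)),
              "property double x", "property double y", "property double z",
              sprintf("element face %d", nrow(F)),
              "property list uchar int vertex_indices",
              "end_header")
  vtx <- sprintf("%.12g %.12g %.12g", V[, 1], V[, 2], V[, 3])
  fc <- sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L)
  writeLines(c(header, vtx, fc), path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path, call. = FALSE)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("malformed PLY header: ", path, call. = FALSE)
  head <- trimws(lines[seq_len(endh)])
  if (!any(grepl("^format ascii", head)))
    stop("only ASCII PLY is supported: ", path, call. = FALSE)
  nv <- as.integer(sub("^element vertex ", "", grep("^element vertex ", head, value = TRUE)[1]))
  nf <- as.integer(sub("^element face ", "", grep("^element face ", head, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("malformed PLY header: ", path, call. = FALSE)
  body <- lines[(endh + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) stop("truncated PLY body: ", path, call. = FALSE)
  vparts <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- do.call(rbind, lapply(vparts, function(f) as.numeric(f[1:3])))
  fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- do.call(rbind, lapply(fparts, function(f) {
    k <- as.integer(f[1])
    if (k != 3L) stop("only triangle faces are supported in PLY: ", path,
                      call. = FALSE)
    as.integer(f[2:4]) + 1L
  }))
  if (anyNA(verts) || anyNA(faces))
    stop("malformed PLY body: ", path, call. = FALSE)
  tri_mesh(verts, faces)
}
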