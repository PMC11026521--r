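# STL (ASCII + binary) and PLY (ASCII) surface I/O.
# Coordinates are always millimetres, right-handed.

#' Read a triangulated surface from STL or PLY
#'
#' Binary and ASCII STL dialects are both accepted; PLY support covers the
#' ASCII dialect with `float`/`double` vertex properties and triangular
#' faces. STL files carry no shared-vertex topology, so exactly coincident
#' vertices are merged on read.
#'
#' @param path file path.
#' @param format `"stl"`, `"ply"`, or `"auto"` (from the file extension).
#' @return An `aaa_surface`.
#' @export
read_surface <- function(path, format = c("auto", "stl", "ply")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_aaa("aaa_io_error", "file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, stl = "stl", ply = "ply",
                     stop_aaa("aaa_format_error", "cannot infer format from extension '%s'", ext))
  }
  if (format == "stl") .read_stl(path) else .read_ply(path)
}

#' Write a triangulated surface to STL or PLY
#'
#' ASCII STL is written with 10 significant digits so that a write/read
#' round trip preserves geometry well within 1e-6 mm at anatomical scales.
#' Binary STL stores 32-bit floats (the format's fixed precision).
#'
#' @param surface an `aaa_surface`.
#' @param path output file path.
#' @param format `"stl"`, `"ply"`, or `"auto"` (from the extension).
#' @param binary write binary STL instead of ASCII (STL only).
#' @export
write_surface <- function(surface, path, format = c("auto", "stl", "ply"), binary = FALSE) {
  format <- match.arg(format)
  .validate_surface(surface)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, stl = "stl", ply = "ply",
                     stop_aaa("aaa_format_error", "cannot infer format from extension '%s'", ext))
  }
  ok <- tryCatch({
    if (format == "stl") {
      if (binary) .write_stl_binary(surface, path) else .write_stl_ascii(surface, path)
    } else {
      .write_ply(surface, path)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    if (inherits(ok, "aaa_error")) stop(ok)
    stop_aaa("aaa_io_error", "cannot write %s: %s", path, conditionMessage(ok))
  }
  invisible(path)
}

# --- STL ---------------------------------------------------------------------

.read_stl <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz == 0) stop_aaa("aaa_format_error", "empty or unreadable STL file: %s", path)
  con <- file(path, "rb"); on.exit(close(con))
  head <- readBin(con, "raw", n = min(84, sz))
  is_binary <- FALSE
  if (sz >= 84) {
    ntri <- readBin(head[81:84], "integer", 1, size = 4)
    if (!is.na(ntri) && ntri > 0 && sz == 84 + 50 * as.double(ntri)) is_binary <- TRUE
  }
  if (!is_binary && !grepl("^\\s*solid", rawToChar(head[1:min(40, length(head))]))) {
    stop_aaa("aaa_format_error", "not an STL file: %s", path)
  }
  tri <- if (is_binary) .read_stl_binary_tris(con, sz) else .read_stl_ascii_tris(path)
  if (is.null(tri) || nrow(tri) == 0) stop_aaa("aaa_format_error", "STL file has zero facets: %s", path)
  .soup_to_surface(tri)
}

.read_stl_binary_tris <- function(con, sz) {
  seek(con, 80)
  n <- readBin(con, "integer", 1, size = 4)
  r <- readBin(con, "raw", 50 * n)
  if (length(r) < 50 * n) stop_aaa("aaa_format_error", "truncated binary STL")
  idx <- as.vector(outer(1:48, (0:(n - 1)) * 50L, "+"))
  vals <- readBin(r[idx], "numeric", n * 12L, size = 4)
  m <- matrix(vals, nrow = 12)          # per facet: normal(3), v1, v2, v3
  t(m[4:12, , drop = FALSE])            # n x 9: the three vertices
}

.read_stl_ascii_tris <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) return(NULL)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(tok) as.numeric(tok[2:4]))
  V <- do.call(rbind, nums)
  if (any(!is.finite(V)) || nrow(V) %% 3 != 0) {
    stop_aaa("aaa_format_error", "malformed ASCII STL: %s", path)
  }
  matrix(t(V), ncol = 9, byrow = TRUE)
}

# triangle soup (n x 9) -> surface with exactly-coincident vertices merged
.soup_to_surface <- function(tri) {
  V <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE], tri[, 7:9, drop = FALSE])
  n <- nrow(tri)
  ord <- as.vector(t(matrix(seq_len(3 * n), ncol = 3)))  # interleave back to per-face order
  V <- V[ord, , drop = FALSE]
  key <- paste(sprintf("%.17g", V[, 1]), sprintf("%.17g", V[, 2]), sprintf("%.17g", V[, 3]))
  uid <- match(key, unique(key))
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  verts <- V[!duplicated(key), , drop = FALSE]
  triangle_surface(verts, faces)
}

.write_stl_ascii <- function(surface, path) {
  V <- surface$vertices; F <- surface$faces
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  nx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  ny <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  nz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  nn <- pmax(sqrt(nx^2 + ny^2 + nz^2), 1e-30)
  fmt <- function(x) sprintf("%.10g", x)
  body <- sprintf(
    "facet normal %s %s %s\nouter loop\nvertex %s %s %s\nvertex %s %s %s\nvertex %s %s %s\nendloop\nendfacet",
    fmt(nx / nn), fmt(ny / nn), fmt(nz / nn),
    fmt(V[F[, 1], 1]), fmt(V[F[, 1], 2]), fmt(V[F[, 1], 3]),
    fmt(V[F[, 2], 1]), fmt(V[F[, 2], 2]), fmt(V[F[, 2], 3]),
    fmt(V[F[, 3], 1]), fmt(V[F[, 3], 2]), fmt(V[F[, 3], 3]))
  writeLines(c("solid aaamorph", body, "endsolid aaamorph"), path)
}

.write_stl_binary <- function(surface, path) {
  V <- surface$vertices; F <- surface$faces
  con <- file(path, "wb"); on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "aaamorph binary STL"))[1:80]
  writeBin(hdr, con)
  writeBin(as.integer(nrow(F)), con, size = 4)
  attr_bytes <- as.raw(c(0, 0))
  for (i in seq_len(nrow(F))) {
    p1 <- V[F[i, 1], ]; p2 <- V[F[i, 2], ]; p3 <- V[F[i, 3], ]
    nrm <- .cross3(p2 - p1, p3 - p1)
    nn <- .vnorm(nrm); if (nn > 1e-30) nrm <- nrm / nn
    writeBin(c(nrm, p1, p2, p3), con, size = 4)
    writeBin(attr_bytes, con)
  }
}

# --- PLY (ASCII) -------------------------------------------------------------

.read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^ply\\s*$", lines[1])) {
    stop_aaa("aaa_format_error", "not a PLY file: %s", path)
  }
  end <- match(TRUE, grepl("^end_header", lines))
  if (is.na(end)) stop_aaa("aaa_format_error", "PLY header not terminated: %s", path)
  header <- lines[seq_len(end)]
  if (!any(grepl("^format ascii", header))) {
    stop_aaa("aaa_format_error", "only ASCII PLY is supported: %s", path)
  }
  nv <- as.integer(sub("^element vertex\\s+", "", grep("^element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "", grep("^element face", header, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf) || nf == 0) stop_aaa("aaa_format_error", "PLY without faces: %s", path)
  body <- lines[(end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) stop_aaa("aaa_format_error", "truncated PLY body: %s", path)
  vt <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  V <- do.call(rbind, lapply(vt, function(tok) as.numeric(tok[1:3])))
  ft <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  Fm <- do.call(rbind, lapply(ft, function(tok) {
    k <- as.integer(tok[1])
    if (is.na(k) || k != 3L) stop_aaa("aaa_format_error", "non-triangular PLY face")
    as.integer(tok[2:4]) + 1L
  }))
  triangle_surface(V, Fm)
}

.write_ply <- function(surface, path) {
  V <- surface$vertices; F <- surface$faces
  header <- c("ply", "format ascii 1.0", "comment aaamorph surface (units mm)",
              sprintf("element vertex %d", nrow(V)),
              "property double x", "property double y", "property double z",
              sprintf("element face %d", nrow(F)),
              "property list uchar int vertex_indices", "end_header")
  vl <- sprintf("%.10g %.10g %.10g", V[, 1], V[, 2], V[, 3])
  fl <- sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L)
  writeLines(c(header, vl, fl), path)
}
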