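# Geometric kernel: triangle surfaces, oriented planes, plane-mesh sectioning,
# contour chaining, contour chord measurement, and half-space mesh clipping.
# All coordinates are world millimetres, right-handed.

#' Triangulated surface model
#'
#' Constructs a triangulated 3D surface (for example an aortic lumen plus
#' thrombus exported from segmentation). Vertices are world coordinates in
#' millimetres; faces index vertices (1-based). Open meshes are permitted:
#' watertightness is neither required nor enforced.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of vertex indices, 1-based.
#' @return An object of class `aaa_surface` with elements `vertices`,
#'   `faces`, and `units` (always `"mm"`).
#' @examples
#' s <- cube_surface(10)
#' nrow(s$faces)
#' @export
triangle_surface <- function(vertices, faces) {
  vertices <- .as_point_matrix(vertices, "vertices")
  if (is.data.frame(faces)) faces <- as.matrix(faces)
  if (!is.matrix(faces) || ncol(faces) != 3) {
    stop_aaa("aaa_precondition_error", "faces must be an m x 3 index matrix")
  }
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  s <- structure(list(vertices = vertices, faces = faces, units = "mm"),
                 class = "aaa_surface")
  .validate_surface(s)
  s
}

.validate_surface <- function(s) {
  v <- s$vertices; f <- s$faces
  if (nrow(v) < 4L || nrow(f) < 4L) {
    stop_aaa("aaa_precondition_error",
             "surface needs at least 4 vertices and 4 faces (got %d, %d)",
             nrow(v), nrow(f))
  }
  if (any(!is.finite(v))) stop_aaa("aaa_precondition_error", "non-finite vertex coordinates")
  if (any(is.na(f)) || any(f < 1L) || any(f > nrow(v))) {
    stop_aaa("aaa_precondition_error", "face index out of range")
  }
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3])) {
    stop_aaa("aaa_precondition_error", "degenerate face with repeated vertex index")
  }
  invisible(s)
}

#' @export
print.aaa_surface <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("<aaa_surface> %d vertices, %d faces (mm)\n",
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bbox x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Oriented section plane
#'
#' A plane given by a point and a normal, used both as cutting plane for
#' cross-sections and to separate the iliac arteries from the aortic trunk.
#' The normal is normalized to unit length on construction.
#'
#' @param origin 3-vector, a point on the plane (mm).
#' @param normal 3-vector, plane normal (normalized internally).
#' @return Object of class `aaa_plane` with unit `normal` and `origin`.
#' @export
section_plane <- function(origin, normal) {
  origin <- as.double(origin); normal <- as.double(normal)
  if (length(origin) != 3L || length(normal) != 3L || any(!is.finite(c(origin, normal)))) {
    stop_aaa("aaa_precondition_error", "plane needs finite 3-vector origin and normal")
  }
  structure(list(origin = origin, normal = .unitize(normal, "plane normal")),
            class = "aaa_plane")
}

#' Planar contour from a plane-mesh intersection
#'
#' An ordered loop (or open chain) of 3D points lying on a section plane.
#' Closed contours do not repeat the first point at the end; closure is
#' implicit.
#'
#' @param points n x 3 matrix of ordered points (mm), n >= 2.
#' @param closed logical; whether the chain closes on itself.
#' @param plane the `aaa_plane` the contour lies on.
#' @param tol_plane tolerance (mm) for the on-plane check.
#' @return Object of class `aaa_contour`.
#' @export
planar_contour <- function(points, closed, plane, tol_plane = 1e-6) {
  points <- .as_point_matrix(points)
  if (nrow(points) < 2L) stop_aaa("aaa_precondition_error", "contour needs >= 2 points")
  if (!inherits(plane, "aaa_plane")) stop_aaa("aaa_precondition_error", "plane must be an aaa_plane")
  off <- abs(as.vector(points %*% plane$normal) - sum(plane$origin * plane$normal))
  if (max(off) > tol_plane) {
    stop_aaa("aaa_precondition_error",
             "contour point off plane by %.3g mm (tol %.3g)", max(off), tol_plane)
  }
  structure(list(points = points, closed = isTRUE(closed), plane = plane),
            class = "aaa_contour")
}

#' Intersect a surface with a plane
#'
#' Every triangle crossing the plane contributes one straight segment, with
#' endpoints interpolated along the crossing edges at the signed-distance zero
#' crossing. Segments sharing endpoints (within `tol_chain`) are chained into
#' ordered contours; chains whose free ends meet are marked closed. Vertices
#' lying exactly on the plane (|signed distance| <= 1e-9 mm) are treated as on
#' the positive side, which avoids duplicated segments along shared edges.
#'
#' @param surface an `aaa_surface`.
#' @param plane an `aaa_plane`.
#' @param tol_chain endpoint matching tolerance in mm.
#' @return List of `aaa_contour` (possibly empty when no triangle crosses).
#' @examples
#' s <- cube_surface(10)
#' cs <- plane_section(s, section_plane(c(0, 0, 0), c(0, 0, 1)))
#' contour_length(cs[[1]])  # 40 mm square cross-section
#' @export
plane_section <- function(surface, plane, tol_chain = 1e-6) {
  .validate_surface(surface)
  if (!inherits(plane, "aaa_plane")) stop_aaa("aaa_precondition_error", "plane must be an aaa_plane")
  segs <- .section_segments(surface, plane)
  if (is.null(segs)) return(list())
  chains <- .chain_segments(segs$a, segs$b, tol_chain)
  lapply(chains, function(ch) {
    planar_contour(ch$points, ch$closed, plane, tol_plane = 1e-6 + 1e-9 * max(abs(ch$points)))
  })
}

# Raw per-triangle crossing segments: list(a = m x 3, b = m x 3) or NULL.
.section_segments <- function(surface, plane) {
  V <- surface$vertices; F <- surface$faces
  n <- plane$normal
  d <- as.vector(V %*% n) - sum(plane$origin * n)
  pos <- d >= -1e-9  # on-plane vertices count as positive
  s1 <- pos[F[, 1]]; s2 <- pos[F[, 2]]; s3 <- pos[F[, 3]]
  cnt <- s1 + s2 + s3
  ci <- which(cnt == 1L | cnt == 2L)
  if (!length(ci)) return(NULL)

  edge_point <- function(a, b) {
    # canonical ordering so both triangles sharing an edge compute identical points
    sw <- a > b
    lo <- ifelse(sw, b, a); hi <- ifelse(sw, a, b)
    t <- d[lo] / (d[lo] - d[hi])
    V[lo, , drop = FALSE] + t * (V[hi, , drop = FALSE] - V[lo, , drop = FALSE])
  }

  f1 <- F[ci, 1]; f2 <- F[ci, 2]; f3 <- F[ci, 3]
  cr12 <- pos[f1] != pos[f2]
  cr23 <- pos[f2] != pos[f3]
  cr31 <- pos[f3] != pos[f1]
  P12 <- edge_point(f1, f2); P23 <- edge_point(f2, f3); P31 <- edge_point(f3, f1)

  m <- length(ci)
  A <- matrix(NA_real_, m, 3); B <- A
  sel1 <- cr12
  A[sel1, ] <- P12[sel1, , drop = FALSE]
  A[!sel1, ] <- P23[!sel1, , drop = FALSE]
  sel2 <- cr31
  B[sel2, ] <- P31[sel2, , drop = FALSE]
  B[!sel2, ] <- P23[!sel2, , drop = FALSE]

  len2 <- rowSums((A - B)^2)
  keep <- len2 > 1e-24
  if (!any(keep)) return(NULL)
  list(a = A[keep, , drop = FALSE], b = B[keep, , drop = FALSE])
}

# Greedy chaining of segments into ordered open/closed polylines.
.chain_segments <- function(A, B, tol) {
  m <- nrow(A)
  used <- rep(FALSE, m)
  tol2 <- tol * tol
  nearest_free <- function(p) {
    cand <- which(!used)
    if (!length(cand)) return(NULL)
    da <- (A[cand, 1] - p[1])^2 + (A[cand, 2] - p[2])^2 + (A[cand, 3] - p[3])^2
    db <- (B[cand, 1] - p[1])^2 + (B[cand, 2] - p[2])^2 + (B[cand, 3] - p[3])^2
    ia <- which.min(da); ib <- which.min(db)
    if (da[ia] <= db[ib]) {
      if (da[ia] <= tol2) return(list(i = cand[ia], from_a = TRUE))
    } else {
      if (db[ib] <= tol2) return(list(i = cand[ib], from_a = FALSE))
    }
    NULL
  }
  out <- list()
  for (s in seq_len(m)) {
    if (used[s]) next
    used[s] <- TRUE
    pts <- rbind(A[s, ], B[s, ])
    repeat {  # extend tail
      hit <- nearest_free(pts[nrow(pts), ])
      if (is.null(hit)) break
      used[hit$i] <- TRUE
      pts <- rbind(pts, if (hit$from_a) B[hit$i, ] else A[hit$i, ])
    }
    repeat {  # extend head
      hit <- nearest_free(pts[1, ])
      if (is.null(hit)) break
      used[hit$i] <- TRUE
      pts <- rbind(if (hit$from_a) B[hit$i, ] else A[hit$i, ], pts)
    }
    closed <- FALSE
    if (nrow(pts) >= 4L &&
        sum((pts[1, ] - pts[nrow(pts), ])^2) <= tol2) {
      pts <- pts[-nrow(pts), , drop = FALSE]
      closed <- TRUE
    }
    out[[length(out) + 1L]] <- list(points = pts, closed = closed)
  }
  out
}

#' Contour length (perimeter for closed contours)
#'
#' Sum of consecutive segment lengths, plus the closing segment for closed
#' contours. This is the key on which the longest contour is selected.
#'
#' @param contour an `aaa_contour`.
#' @return Length in mm.
#' @export
contour_length <- function(contour) {
  if (!inherits(contour, "aaa_contour")) stop_aaa("aaa_precondition_error", "not an aaa_contour")
  p <- contour$points
  L <- sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
  if (contour$closed) L <- L + sqrt(sum((p[1, ] - p[nrow(p), ])^2))
  L
}

#' Select the longest contour
#'
#' Among the contours produced by one plane section, the longest one is the
#' vessel cross-section of interest. Ties break to the lowest index so the
#' choice is deterministic.
#'
#' @param contours non-empty list of `aaa_contour`.
#' @return The contour maximizing [contour_length()].
#' @export
longest_contour <- function(contours) {
  if (!is.list(contours) || length(contours) == 0L) {
    stop_aaa("aaa_no_contour_error", "no contours to select from")
  }
  lens <- vapply(contours, contour_length, numeric(1))
  contours[[which.max(lens)]]
}

#' Maximum contour diameter (max chord)
#'
#' The maximum Euclidean distance over all point pairs of the contour,
#' computed by exhaustive pairwise distances. Points are coplanar, so the 3D
#' chord equals the in-plane chord.
#'
#' @param contour an `aaa_contour` (or n x 3 point matrix) with >= 2 points.
#' @return Diameter in mm.
#' @export
max_contour_diameter <- function(contour) {
  p <- if (inherits(contour, "aaa_contour")) contour$points else .as_point_matrix(contour)
  if (nrow(p) < 2L) stop_aaa("aaa_precondition_error", "need >= 2 points for a chord")
  max(stats::dist(p))
}

#' Cut a surface with a plane, keeping one side
#'
#' Returns the sub-mesh on the requested side of the plane (signed distance
#' > 0 for `"positive"`). Triangles crossing the plane are clipped at the
#' plane; the cut boundary is left open (no capping). Used to separate an
#' iliac artery from the aortic trunk before measuring it.
#'
#' @param surface an `aaa_surface`.
#' @param plane an `aaa_plane`.
#' @param keep `"positive"` or `"negative"` half-space.
#' @return A clipped `aaa_surface`.
#' @export
cut_surface_by_plane <- function(surface, plane, keep = c("positive", "negative")) {
  keep <- match.arg(keep)
  .validate_surface(surface)
  V <- surface$vertices; F <- surface$faces
  n <- plane$normal
  d <- as.vector(V %*% n) - sum(plane$origin * n)
  eff_pos <- d >= -1e-9
  kv <- if (keep == "positive") eff_pos else !eff_pos

  k1 <- kv[F[, 1]]; k2 <- kv[F[, 2]]; k3 <- kv[F[, 3]]
  cnt <- k1 + k2 + k3
  keep_whole <- which(cnt == 3L)
  mixed <- which(cnt == 1L | cnt == 2L)

  new_v <- list(); new_f <- list()
  nv <- nrow(V)
  add_pt <- function(p) {
    new_v[[length(new_v) + 1L]] <<- p
    nv <<- nv + 1L
    nv
  }
  edge_point <- function(a, b) {
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    t <- d[a] / (d[a] - d[b])
    V[a, ] + t * (V[b, ] - V[a, ])
  }
  for (fi in mixed) {
    tri <- F[fi, ]
    kk <- kv[tri]
    # rotate so the pattern starts at a canonical vertex, preserving winding
    if (sum(kk) == 1L) {
      r <- which(kk)  # kept vertex first
      ord <- ((r - 1L + 0:2) %% 3L) + 1L
      a <- tri[ord[1]]; b <- tri[ord[2]]; c <- tri[ord[3]]
      pab <- edge_point(a, b); pca <- edge_point(c, a)
      i1 <- add_pt(pab); i2 <- add_pt(pca)
      new_f[[length(new_f) + 1L]] <- c(a, i1, i2)
    } else {
      r <- which(!kk)  # dropped vertex first
      ord <- ((r - 1L + 0:2) %% 3L) + 1L
      dv <- tri[ord[1]]; a <- tri[ord[2]]; b <- tri[ord[3]]
      pda <- edge_point(dv, a); pbd <- edge_point(b, dv)
      i1 <- add_pt(pda); i2 <- add_pt(pbd)
      new_f[[length(new_f) + 1L]] <- c(i1, a, b)
      new_f[[length(new_f) + 1L]] <- c(i1, b, i2)
    }
  }

  faces <- rbind(F[keep_whole, , drop = FALSE],
                 if (length(new_f)) do.call(rbind, new_f))
  if (is.null(faces) || nrow(faces) == 0L) {
    stop_aaa("aaa_empty_result_error", "no geometry on the %s side of the plane", keep)
  }
  verts <- rbind(V, if (length(new_v)) do.call(rbind, new_v))
  # drop unreferenced vertices
  idx <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(verts)); remap[idx] <- seq_along(idx)
  faces <- matrix(remap[faces], ncol = 3)
  verts <- verts[idx, , drop = FALSE]
  if (nrow(verts) < 4L || nrow(faces) < 4L) {
    stop_aaa("aaa_empty_result_error", "cut leaves a degenerate sliver (%d faces)", nrow(faces))
  }
  triangle_surface(verts, faces)
}

#' Total surface area of a triangulated mesh
#'
#' @param surface an `aaa_surface`.
#' @return Area in mm^2.
#' @export
surface_area <- function(surface) {
  .validate_surface(surface)
  V <- surface$vertices; F <- surface$faces
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sum(sqrt(cx^2 + cy^2 + cz^2))
}

#' Axis-aligned cube mesh (test and demonstration geometry)
#'
#' @param side edge length in mm; the cube is centred at `center`.
#' @param center 3-vector centre (mm).
#' @return An `aaa_surface` with 8 vertices and 12 faces.
#' @export
cube_surface <- function(side = 10, center = c(0, 0, 0)) {
  h <- side / 2
  v <- as.matrix(expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h)))
  v <- sweep(v, 2, center, "+")
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = -h
    c(5, 6, 8), c(5, 8, 7),   # z = +h
    c(1, 2, 6), c(1, 6, 5),   # y = -h
    c(3, 7, 8), c(3, 8, 4),   # y = +h
    c(1, 5, 7), c(1, 7, 3),   # x = -h
    c(2, 4, 8), c(2, 8, 6)    # x = +h
  )
  triangle_surface(v, f)
}
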