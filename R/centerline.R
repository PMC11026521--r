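# Vessel centerline polylines, resampling, station frames, arc/chord lengths,
# and the JSON interchange format carrying the four named centerlines plus the
# two iliac start planes.

#' Vessel centerline polyline
#'
#' An ordered 3D polyline in millimetres. Four named instances drive the
#' measurement pipeline: the aortic neck, the aneurysm, and the right and
#' left common iliac arteries.
#'
#' @param points n x 3 matrix of ordered points (mm), n >= 2; consecutive
#'   duplicates (closer than 1e-9 mm) are rejected.
#' @param name free label, conventionally one of `"neck"`, `"aneurysm"`,
#'   `"right_iliac"`, `"left_iliac"`.
#' @return Object of class `aaa_centerline`.
#' @export
centerline <- function(points, name = "centerline") {
  points <- .as_point_matrix(points)
  if (nrow(points) < 2L) {
    stop_aaa("aaa_validation_error", "centerline '%s' needs >= 2 points", name)
  }
  step <- sqrt(rowSums((points[-1, , drop = FALSE] - points[-nrow(points), , drop = FALSE])^2))
  if (any(step < 1e-9)) {
    stop_aaa("aaa_validation_error",
             "centerline '%s' has consecutive points closer than 1e-9 mm", name)
  }
  structure(list(points = points, name = as.character(name)[1]),
            class = "aaa_centerline")
}

#' @export
print.aaa_centerline <- function(x, ...) {
  cat(sprintf("<aaa_centerline> '%s': %d points, arc %.2f mm, chord %.2f mm\n",
              x$name, nrow(x$points), arc_length(x), chord_length(x)))
  invisible(x)
}

#' Measurement station: point plus local direction
#'
#' A point on a centerline together with the unit direction to its
#' consecutive point; each station defines a cross-sectional cutting plane.
#'
#' @param point 3-vector (mm).
#' @param direction 3-vector; normalized internally.
#' @return Object of class `aaa_station`.
#' @export
station <- function(point, direction) {
  structure(list(point = as.double(point), direction = .unitize(as.double(direction), "station direction")),
            class = "aaa_station")
}

#' Bundle of the four named centerlines and the iliac start planes
#'
#' The five manually prepared inputs of the automated measurement, minus the
#' surface model itself: neck, aneurysm, right and left iliac centerlines,
#' and the two planes that separate the iliac arteries from the trunk. Plane
#' normals point toward the iliac territory they isolate.
#'
#' @param neck,aneurysm,right_iliac,left_iliac `aaa_centerline` objects.
#' @param right_plane,left_plane `aaa_plane` objects.
#' @return Object of class `aaa_centerline_set`.
#' @export
centerline_set <- function(neck, aneurysm, right_iliac, left_iliac,
                           right_plane, left_plane) {
  for (cl in list(neck, aneurysm, right_iliac, left_iliac)) {
    if (!inherits(cl, "aaa_centerline")) {
      stop_aaa("aaa_validation_error", "all four centerlines must be aaa_centerline objects")
    }
  }
  if (!inherits(right_plane, "aaa_plane") || !inherits(left_plane, "aaa_plane")) {
    stop_aaa("aaa_validation_error", "both iliac planes must be aaa_plane objects")
  }
  structure(list(neck = neck, aneurysm = aneurysm,
                 right_iliac = right_iliac, left_iliac = left_iliac,
                 right_plane = right_plane, left_plane = left_plane),
            class = "aaa_centerline_set")
}

#' Read a centerline set from JSON
#'
#' Expected schema:
#' \preformatted{
#' {"units": "mm",
#'  "centerlines": {"neck": [[x,y,z], ...], "aneurysm": [...],
#'                  "right_iliac": [...], "left_iliac": [...]},
#'  "planes": {"right_iliac": {"origin": [x,y,z], "normal": [x,y,z]},
#'             "left_iliac":  {...}}}
#' }
#' Normals need not be unit length in the file; they are normalized on load.
#' Units must be declared `"mm"`.
#'
#' @param path JSON file path.
#' @return An `aaa_centerline_set`.
#' @export
read_centerlines <- function(path) {
  if (!file.exists(path)) stop_aaa("aaa_io_error", "file not found: %s", path)
  j <- tryCatch(jsonlite::fromJSON(path, simplifyMatrix = TRUE),
                error = function(e) stop_aaa("aaa_schema_error", "cannot parse JSON: %s", conditionMessage(e)))
  units <- j$units
  if (is.null(units)) stop_aaa("aaa_schema_error", "missing 'units' key in %s", path)
  if (!identical(as.character(units), "mm")) {
    stop_aaa("aaa_validation_error", "units must be 'mm', got '%s'", as.character(units))
  }
  need <- c("neck", "aneurysm", "right_iliac", "left_iliac")
  cls <- j$centerlines
  if (is.null(cls)) stop_aaa("aaa_schema_error", "missing 'centerlines' key")
  miss <- setdiff(need, names(cls))
  if (length(miss)) stop_aaa("aaa_schema_error", "missing centerline(s): %s", paste(miss, collapse = ", "))
  mk <- function(nm) {
    p <- cls[[nm]]
    if (is.null(dim(p))) stop_aaa("aaa_validation_error", "centerline '%s' is not a point list", nm)
    centerline(p, nm)
  }
  planes <- j$planes
  if (is.null(planes) || is.null(planes$right_iliac) || is.null(planes$left_iliac)) {
    stop_aaa("aaa_schema_error", "missing 'planes' (right_iliac / left_iliac)")
  }
  mkp <- function(pl) {
    if (is.null(pl$origin) || is.null(pl$normal)) stop_aaa("aaa_schema_error", "plane needs origin and normal")
    section_plane(pl$origin, pl$normal)
  }
  cs <- centerline_set(mk("neck"), mk("aneurysm"), mk("right_iliac"), mk("left_iliac"),
                       mkp(planes$right_iliac), mkp(planes$left_iliac))
  attr(cs, "source") <- path
  cs
}

#' Write a centerline set to JSON
#'
#' Inverse of [read_centerlines()]; used by the phantom generator.
#'
#' @param cset an `aaa_centerline_set`.
#' @param path output JSON path.
#' @export
write_centerlines <- function(cset, path) {
  j <- list(
    units = "mm",
    centerlines = list(
      neck = cset$neck$points,
      aneurysm = cset$aneurysm$points,
      right_iliac = cset$right_iliac$points,
      left_iliac = cset$left_iliac$points
    ),
    planes = list(
      right_iliac = list(origin = cset$right_plane$origin, normal = cset$right_plane$normal),
      left_iliac = list(origin = cset$left_plane$origin, normal = cset$left_plane$normal)
    )
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.cumulative_arc <- function(p) {
  c(0, cumsum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))))
}

#' Resample a centerline at a fixed arc-length step
#'
#' Points are placed at arc-length multiples of `step` from the start, with
#' the original endpoint appended so the extremities are preserved exactly.
#'
#' @param c an `aaa_centerline`.
#' @param step arc-length spacing in mm (> 0).
#' @return A resampled `aaa_centerline`.
#' @export
resample_centerline <- function(c, step) {
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) || step <= 0) {
    stop_aaa("aaa_precondition_error", "step must be a positive length (mm)")
  }
  p <- c$points
  cum <- .cumulative_arc(p)
  L <- cum[length(cum)]
  s <- seq(0, L, by = step)
  if (L - s[length(s)] > 1e-9) s <- c(s, L)
  # piecewise-linear interpolation along the polyline
  seg <- pmin(pmax(findInterval(s, cum, rightmost.closed = TRUE), 1L), nrow(p) - 1L)
  t <- (s - cum[seg]) / pmax(cum[seg + 1L] - cum[seg], 1e-300)
  q <- p[seg, , drop = FALSE] + t * (p[seg + 1L, , drop = FALSE] - p[seg, , drop = FALSE])
  q[1, ] <- p[1, ]; q[nrow(q), ] <- p[nrow(p), ]
  # guard against a final point essentially coincident with the previous one
  if (nrow(q) > 2L && sqrt(sum((q[nrow(q), ] - q[nrow(q) - 1L, ])^2)) < 1e-9) {
    q <- q[-(nrow(q) - 1L), , drop = FALSE]
  }
  centerline(q, c$name)
}

#' Station frames along a centerline
#'
#' One station per point; the direction at point i is the unit vector toward
#' point i+1 (forward difference), and the last point reuses its
#' predecessor's direction.
#'
#' @param c an `aaa_centerline`.
#' @return List of `aaa_station`.
#' @export
station_frames <- function(c) {
  p <- c$points
  n <- nrow(p)
  dirs <- p[-1, , drop = FALSE] - p[-n, , drop = FALSE]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  dirs <- rbind(dirs, dirs[n - 1L, ])
  lapply(seq_len(n), function(i) station(p[i, ], dirs[i, ]))
}

#' Station at half the total arc length
#'
#' The centerline is resampled at `step`, and the resampled point closest to
#' half the total arc length becomes the mid station; its direction points to
#' the consecutive resampled point. This is the single plane from which the
#' aortic neck diameter is measured.
#'
#' @param c an `aaa_centerline`.
#' @param step resampling step in mm.
#' @return An `aaa_station`.
#' @export
midpoint_station <- function(c, step = 1.0) {
  r <- resample_centerline(c, step)
  p <- r$points
  cum <- .cumulative_arc(p)
  L <- cum[length(cum)]
  i <- which.min(abs(cum - L / 2))
  dir <- if (i < nrow(p)) p[i + 1L, ] - p[i, ] else p[i, ] - p[i - 1L, ]
  station(p[i, ], dir)
}

#' Arc length of a centerline
#'
#' Sum of consecutive segment lengths (the "curve length" of tortuosity).
#'
#' @param c an `aaa_centerline`.
#' @return Length in mm.
#' @export
arc_length <- function(c) {
  p <- c$points
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Chord (straight) length of a centerline
#'
#' Euclidean distance between the first and last points (the "line length"
#' of tortuosity).
#'
#' @param c an `aaa_centerline`.
#' @return Length in mm.
#' @export
chord_length <- function(c) {
  p <- c$points
  sqrt(sum((p[nrow(p), ] - p[1, ])^2))
}
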