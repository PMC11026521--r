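# The seven-landmark automated measurement pipeline: cross-sectional
# diameters along centerline stations, neck length, iliac tortuosity, and
# neck angulation, plus the whole-case driver and report serialization.

#' Measurement configuration
#'
#' @param resample_step station spacing along centerlines, mm. 1.0 mm is
#'   sub-voxel relative to typical CT slice thickness (2.5-5.0 mm).
#' @param tol_chord minimum chord length (mm) below which a centerline is
#'   considered degenerate for tortuosity/angulation.
#' @param output_format `"json"` or `"csv"` for report files.
#' @param log_level one of `"quiet"`, `"info"`.
#' @return A list of class `aaa_measure_config`.
#' @export
measure_config <- function(resample_step = 1.0, tol_chord = 1e-6,
                           output_format = c("json", "csv"),
                           log_level = c("quiet", "info")) {
  if (!is.numeric(resample_step) || resample_step <= 0) {
    stop_aaa("aaa_precondition_error", "resample_step must be > 0")
  }
  structure(list(resample_step = resample_step, tol_chord = tol_chord,
                 output_format = match.arg(output_format),
                 log_level = match.arg(log_level)),
            class = "aaa_measure_config")
}

.diameter_result <- function(diameter, station, perimeter) {
  structure(list(diameter = diameter, station = station,
                 contour_perimeter = perimeter),
            class = "aaa_diameter_result")
}

.measure_station <- function(surface, st) {
  # section at one station; NULL when the plane misses the mesh.
  # Cutting planes are unbounded, so a section can pick up geometry far from
  # the vessel the station belongs to; contours whose nearest point is
  # farther from the station than their own length cannot enclose it and are
  # discarded as unrelated.
  pl <- section_plane(st$point, st$direction)
  cs <- plane_section(surface, pl)
  if (!length(cs)) return(NULL)
  near <- Filter(function(ct) {
    mind <- sqrt(min(rowSums((ct$points - rep(st$point, each = nrow(ct$points)))^2)))
    mind <= contour_length(ct)
  }, cs)
  if (!length(near)) return(NULL)
  best <- longest_contour(near)
  list(diameter = max_contour_diameter(best),
       perimeter = contour_length(best),
       station = st)
}

#' Maximum cross-sectional diameter along a centerline
#'
#' The core sectioning loop: stations are generated along the resampled
#' centerline, each station's plane (origin = station point, normal =
#' forward-difference direction) is intersected with the surface, the longest
#' contour of each section is selected, and its maximum chord measured. The
#' station with the largest chord wins. Stations whose section is empty are
#' skipped.
#'
#' @param surface an `aaa_surface`.
#' @param c an `aaa_centerline` traversing the surface.
#' @param step station spacing in mm.
#' @return An `aaa_diameter_result`: `diameter` (mm), `station` (plane
#'   location of the maximum), `contour_perimeter` (mm).
#' @export
max_diameter_along_centerline <- function(surface, c, step = 1.0) {
  stations <- station_frames(resample_centerline(c, step))
  best <- NULL
  for (st in stations) {
    m <- .measure_station(surface, st)
    if (is.null(m)) next
    if (is.null(best) || m$diameter > best$diameter) best <- m
  }
  if (is.null(best)) {
    stop_aaa("aaa_measurement_failure",
             "centerline '%s' does not traverse the mesh (all sections empty)", c$name)
  }
  .diameter_result(best$diameter, best$station, best$perimeter)
}

#' Aortic neck diameter
#'
#' Measured from a single plane at the station halfway (by arc length) along
#' the neck centerline, i.e. midway between the lowest renal artery and the
#' aneurysm start: the longest contour of that section is taken and its
#' maximum chord reported.
#'
#' @param surface an `aaa_surface`.
#' @param neck the neck `aaa_centerline`.
#' @param step resampling step (mm) used to locate the midpoint.
#' @return An `aaa_diameter_result`.
#' @export
neck_diameter <- function(surface, neck, step = 1.0) {
  st <- midpoint_station(neck, step)
  m <- .measure_station(surface, st)
  if (is.null(m)) {
    stop_aaa("aaa_measurement_failure", "empty section at the neck midpoint")
  }
  .diameter_result(m$diameter, m$station, m$perimeter)
}

#' Aneurysm maximum diameter
#'
#' The maximum cross-sectional diameter over the aneurysm region, obtained by
#' running the sectioning loop along the aneurysm centerline.
#'
#' @inheritParams neck_diameter
#' @param aneurysm the aneurysm `aaa_centerline`.
#' @return An `aaa_diameter_result`.
#' @export
aneurysm_diameter <- function(surface, aneurysm, step = 1.0) {
  max_diameter_along_centerline(surface, aneurysm, step)
}

#' Iliac artery maximum diameter
#'
#' The model is first cut at the iliac start plane (keeping the positive
#' half-space, into which the stored normal points), isolating the iliac
#' territory from the aortic trunk; the sectioning loop then runs along the
#' iliac centerline on the cut sub-mesh. Stations proximal to the plane fall
#' in empty space and are skipped.
#'
#' @param surface an `aaa_surface` of the whole model.
#' @param start_plane the iliac start plane, normal toward the iliac side.
#' @param iliac the iliac `aaa_centerline`.
#' @param step station spacing in mm.
#' @return An `aaa_diameter_result`.
#' @export
iliac_diameter <- function(surface, start_plane, iliac, step = 1.0) {
  part <- cut_surface_by_plane(surface, start_plane, "positive")
  max_diameter_along_centerline(part, iliac, step)
}

#' Aortic neck length
#'
#' Arc length of the neck centerline, i.e. the along-vessel distance between
#' the lowest renal artery and the start of the aneurysm. For a straight neck
#' this equals the straight-line distance.
#'
#' @param neck the neck `aaa_centerline`.
#' @return Length in mm.
#' @export
neck_length <- function(neck) {
  arc_length(neck)
}

#' Common iliac artery tortuosity
#'
#' Ratio of the centerline arc length to the straight start-to-end distance.
#' A straight vessel has ratio 1; the ratio can never drop below 1 (triangle
#' inequality).
#'
#' @param iliac the iliac `aaa_centerline`.
#' @param tol_chord minimum admissible chord length (mm).
#' @return Object of class `aaa_tortuosity_result` with `curve_length`,
#'   `line_length`, `ratio`.
#' @export
iliac_tortuosity <- function(iliac, tol_chord = 1e-6) {
  line <- chord_length(iliac)
  if (line <= tol_chord) {
    stop_aaa("aaa_degenerate_centerline",
             "centerline '%s' is (near-)closed: chord %.3g mm", iliac$name, line)
  }
  curve <- arc_length(iliac)
  structure(list(curve_length = curve, line_length = line, ratio = curve / line),
            class = "aaa_tortuosity_result")
}

#' Aortic neck angulation
#'
#' Angle in degrees between the start-to-end chord of the neck centerline and
#' the start-to-end chord of the aneurysm centerline, in [0, 180].
#'
#' @param neck,aneurysm `aaa_centerline` objects.
#' @param tol_chord minimum admissible chord length (mm).
#' @return Angle in degrees.
#' @export
neck_angulation <- function(neck, aneurysm, tol_chord = 1e-6) {
  v1 <- neck$points[nrow(neck$points), ] - neck$points[1, ]
  v2 <- aneurysm$points[nrow(aneurysm$points), ] - aneurysm$points[1, ]
  if (.vnorm(v1) <= tol_chord || .vnorm(v2) <= tol_chord) {
    stop_aaa("aaa_degenerate_centerline", "degenerate chord for angulation")
  }
  ct <- sum(v1 * v2) / (.vnorm(v1) * .vnorm(v2))
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Measure all seven landmarks of an AAA model
#'
#' Runs the full automated measurement over a surface plus the four named
#' centerlines and two iliac start planes: neck diameter, aneurysm maximum
#' diameter, right and left iliac diameters, neck length, right and left
#' iliac tortuosity, and neck angulation. A failure of one landmark is
#' recorded as an explicit per-landmark error entry; the remaining landmarks
#' are still measured.
#'
#' @param surface an `aaa_surface`.
#' @param inputs an `aaa_centerline_set`.
#' @param config an [measure_config()] list.
#' @return Object of class `aaa_report` with elements `values` (the seven
#'   landmarks), `stations` (plane locations of the diameter maxima),
#'   `errors` (named per-landmark messages), and `provenance`.
#' @examples
#' ph <- make_fusiform_phantom(phantom_spec())
#' rep <- measure_all(ph$surface, ph$centerlines)
#' rep$values$aneurysm_diameter_mm
#' @export
measure_all <- function(surface, inputs, config = measure_config()) {
  if (!inherits(surface, "aaa_surface")) stop_aaa("aaa_input_error", "surface must be an aaa_surface")
  if (!inherits(inputs, "aaa_centerline_set")) stop_aaa("aaa_input_error", "inputs must be an aaa_centerline_set")
  step <- config$resample_step
  values <- list(); stations <- list(); errors <- list()

  grab <- function(key, expr, station_key = NULL) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[key]] <<- conditionMessage(res)
      return(invisible(NULL))
    }
    if (inherits(res, "aaa_diameter_result")) {
      values[[key]] <<- res$diameter
      if (!is.null(station_key)) {
        stations[[station_key]] <<- list(point = res$station$point,
                                         direction = res$station$direction,
                                         contour_perimeter_mm = res$contour_perimeter)
      }
    } else if (inherits(res, "aaa_tortuosity_result")) {
      values[[key]] <<- list(curve_mm = res$curve_length,
                             line_mm = res$line_length,
                             ratio = res$ratio)
    } else {
      values[[key]] <<- res
    }
    invisible(NULL)
  }

  grab("neck_diameter_mm", neck_diameter(surface, inputs$neck, step), "neck")
  grab("aneurysm_diameter_mm", aneurysm_diameter(surface, inputs$aneurysm, step), "aneurysm")
  grab("right_iliac_diameter_mm",
       iliac_diameter(surface, inputs$right_plane, inputs$right_iliac, step), "right_iliac")
  grab("left_iliac_diameter_mm",
       iliac_diameter(surface, inputs$left_plane, inputs$left_iliac, step), "left_iliac")
  grab("neck_length_mm", neck_length(inputs$neck))
  grab("right_tortuosity", iliac_tortuosity(inputs$right_iliac, config$tol_chord))
  grab("left_tortuosity", iliac_tortuosity(inputs$left_iliac, config$tol_chord))
  grab("neck_angulation_deg", neck_angulation(inputs$neck, inputs$aneurysm, config$tol_chord))

  structure(list(
    values = values,
    stations = stations,
    errors = errors,
    provenance = list(
      surface = attr(surface, "source") %||% "<in-memory>",
      centerlines = attr(inputs, "source") %||% "<in-memory>",
      resample_step_mm = step,
      package = sprintf("aaamorph %s", as.character(utils::packageVersion("aaamorph")))
    )
  ), class = "aaa_report")
}

#' @export
print.aaa_report <- function(x, ...) {
  cat("<aaa_report> seven-landmark AAA measurement\n")
  fmt1 <- function(k, v, unit) if (!is.null(v)) cat(sprintf("  %-26s %8.3f %s\n", k, v, unit))
  fmt1("neck diameter", x$values$neck_diameter_mm, "mm")
  fmt1("aneurysm diameter", x$values$aneurysm_diameter_mm, "mm")
  fmt1("right iliac diameter", x$values$right_iliac_diameter_mm, "mm")
  fmt1("left iliac diameter", x$values$left_iliac_diameter_mm, "mm")
  fmt1("neck length", x$values$neck_length_mm, "mm")
  if (!is.null(x$values$right_tortuosity)) {
    fmt1("right tortuosity ratio", x$values$right_tortuosity$ratio, "")
  }
  if (!is.null(x$values$left_tortuosity)) {
    fmt1("left tortuosity ratio", x$values$left_tortuosity$ratio, "")
  }
  fmt1("neck angulation", x$values$neck_angulation_deg, "deg")
  if (length(x$errors)) {
    cat("  errors:\n")
    for (k in names(x$errors)) cat(sprintf("    %s: %s\n", k, x$errors[[k]]))
  }
  invisible(x)
}

# Canonical JSON: sorted keys, numbers rounded to 6 decimals, so re-runs on
# identical inputs are byte-identical and diffable.
.canonicalize <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && any(nzchar(nm))) x <- x[order(nm)]
    lapply(x, .canonicalize)
  } else if (is.numeric(x)) {
    round(x, 6)
  } else x
}

#' Serialize a landmark report to canonical JSON
#'
#' Keys are sorted and floats fixed to 6 decimals so that repeated runs on
#' the same inputs produce byte-identical files.
#'
#' @param report an `aaa_report`.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_to_json <- function(report, path = NULL) {
  j <- jsonlite::toJSON(.canonicalize(unclass(report)), auto_unbox = TRUE,
                        digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(j))
  writeLines(as.character(j), path)
  invisible(as.character(j))
}

#' Flatten a landmark report to a one-row data frame
#'
#' A flat CSV-ready row per case, for cohort tables.
#'
#' @param report an `aaa_report`.
#' @param case case identifier placed in the first column.
#' @return A one-row `data.frame`.
#' @export
report_to_csv_row <- function(report, case = "case") {
  v <- report$values
  num <- function(x) if (is.null(x)) NA_real_ else x
  data.frame(
    case = case,
    neck_diameter_mm = num(v$neck_diameter_mm),
    aneurysm_diameter_mm = num(v$aneurysm_diameter_mm),
    right_iliac_diameter_mm = num(v$right_iliac_diameter_mm),
    left_iliac_diameter_mm = num(v$left_iliac_diameter_mm),
    neck_length_mm = num(v$neck_length_mm),
    right_tortuosity_curve_mm = num(v$right_tortuosity$curve_mm),
    right_tortuosity_line_mm = num(v$right_tortuosity$line_mm),
    right_tortuosity_ratio = num(v$right_tortuosity$ratio),
    left_tortuosity_curve_mm = num(v$left_tortuosity$curve_mm),
    left_tortuosity_line_mm = num(v$left_tortuosity$line_mm),
    left_tortuosity_ratio = num(v$left_tortuosity$ratio),
    neck_angulation_deg = num(v$neck_angulation_deg),
    n_errors = length(report$errors),
    stringsAsFactors = FALSE
  )
}
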