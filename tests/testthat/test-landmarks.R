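# The seven-landmark measurement operations and the whole-case driver.

test_that("maximum diameter along a straight tube recovers the true diameter", {
  tube <- straight_tube(radius = 10, len = 50, segments = 72)
  res <- max_diameter_along_centerline(tube$surface, tube$centerline, step = 1)
  expect_equal(res$diameter, 20, tolerance = 0.005)
  expect_gte(res$contour_perimeter, res$diameter)
})

test_that("the bulge apex is found at the right station on a fusiform tube", {
  len <- 80; apex_z <- 40
  cl <- centerline(cbind(0, 0, seq(0, len, by = 1)), "a")
  prof <- function(s) 10 + 15 * sin(pi * s / len)^2  # peak radius 25 at s = 40
  surf <- make_tube_surface(cl, prof, 72)
  res <- max_diameter_along_centerline(surf, cl, step = 1)
  expect_equal(res$diameter, 50, tolerance = 0.01 * 50)
  expect_lt(abs(res$station$point[3] - apex_z), 1)
})

test_that("a centerline far outside the mesh is a measurement failure", {
  tube <- straight_tube(radius = 10, len = 50, segments = 48)
  off <- centerline(cbind(100, 100, seq(0, 50, by = 5)), "off")
  expect_error(max_diameter_along_centerline(tube$surface, off, 1),
               class = "aaa_measurement_failure")
  expect_error(neck_diameter(tube$surface, off), class = "aaa_measurement_failure")
})

test_that("neck diameter is taken at the arc-length midpoint of the neck", {
  tube <- straight_tube(radius = 12, len = 40, segments = 72)
  expect_equal(neck_diameter(tube$surface, tube$centerline)$diameter, 24,
               tolerance = 0.005 * 24)
  # linear taper 10 -> 14: radius at the arc midpoint is 12
  cl <- centerline(cbind(0, 0, seq(0, 40, by = 1)), "taper")
  cone <- make_tube_surface(cl, function(s) 10 + 4 * s / 40, 72)
  expect_equal(neck_diameter(cone, cl)$diameter, 24, tolerance = 0.01 * 24)
})

test_that("iliac diameter is measured on the plane-separated branch", {
  ph <- make_fusiform_phantom(phantom_spec())
  cs <- ph$centerlines
  r <- iliac_diameter(ph$surface, cs$right_plane, cs$right_iliac)
  l <- iliac_diameter(ph$surface, cs$left_plane, cs$left_iliac)
  expect_equal(r$diameter, ph$ledger$right_iliac_diameter_mm, tolerance = 0.01 * 18)
  expect_equal(l$diameter, ph$ledger$left_iliac_diameter_mm, tolerance = 0.01 * 16)
  # plane beyond the whole branch leaves nothing to measure
  far <- section_plane(c(0, 0, 1000), c(0, 0, 1))
  expect_error(iliac_diameter(ph$surface, far, cs$right_iliac),
               class = "aaa_empty_result_error")
})

test_that("a focal bulge on an iliac branch sets its maximum diameter", {
  cl <- centerline(cbind(0, 0, seq(0, 60, by = 1)), "l")
  prof <- function(s) 8 + 3 * exp(-((s - 30) / 6)^2)  # radius 11 at the bulge
  surf <- make_tube_surface(cl, prof, 72)
  res <- max_diameter_along_centerline(surf, cl, 1)
  expect_equal(res$diameter, 22, tolerance = 0.01 * 22)
  expect_lt(abs(res$station$point[3] - 30), 1)
})

test_that("neck length is the centerline arc length", {
  straight <- centerline(cbind(0, 0, seq(0, 33, by = 1)), "neck")
  expect_equal(neck_length(straight), 33, tolerance = 1e-12)
  arc <- quarter_circle_centerline(40, 2000, "neck")
  expect_equal(neck_length(arc), 40 * pi / 2, tolerance = 1e-3 * 62.8)
  expect_identical(neck_length(centerline(rbind(c(0, 0, 0), c(0, 0, 1)), "n")), 1)
})

test_that("tortuosity matches the arc/chord closed form and rejects loops", {
  straight <- centerline(cbind(0, 0, 0:50), "i")
  ts <- iliac_tortuosity(straight)
  expect_identical(ts$ratio, 1)
  arc <- quarter_circle_centerline(60, 2000, "i")
  ta <- iliac_tortuosity(arc)
  expect_equal(ta$ratio, (pi / 2) / (2 * sin(pi / 4)), tolerance = 0.001)
  expect_equal(ta$ratio, ta$curve_length / ta$line_length, tolerance = 1e-12)
  loop <- centerline(rbind(c(0, 0, 0), c(5, 0, 0), c(5, 5, 0), c(0, 0, 1e-9)), "o")
  expect_error(iliac_tortuosity(loop), class = "aaa_degenerate_centerline")
})

test_that("tortuosity ratio is always >= 1 on random smooth centerlines", {
  set.seed(3)
  for (i in 1:30) {
    t <- seq(0, 1, length.out = 50)
    p <- cbind(10 * t + sin(3 * t) * runif(1, 0, 5),
               cos(2 * t) * runif(1, 0, 5),
               40 * t)
    r <- iliac_tortuosity(centerline(p, "r"))
    expect_gte(r$ratio, 1 - 1e-12)
  }
})

test_that("neck angulation is the angle between endpoint chords", {
  up <- centerline(cbind(0, 0, 0:10), "neck")
  up2 <- centerline(cbind(0, 0, 10:20), "an")
  expect_equal(neck_angulation(up, up2), 0, tolerance = 1e-9)
  th <- 30 * pi / 180
  tilted <- centerline(rbind(c(0, 0, 0), c(0, 10 * sin(th), -10 * cos(th))), "an")
  down <- centerline(rbind(c(0, 0, 0), c(0, 0, -10)), "neck")
  expect_equal(neck_angulation(down, tilted), 30, tolerance = 1e-6)
  perp <- centerline(rbind(c(0, 0, 0), c(0, 7, 0)), "an")
  expect_equal(neck_angulation(down, perp), 90, tolerance = 1e-9)
  point <- centerline(rbind(c(0, 0, 0), c(1e-8, 0, 0)), "bad")
  expect_error(neck_angulation(point, up2), class = "aaa_degenerate_centerline")
})

test_that("measure_all recovers the phantom ledger within tolerances", {
  ph <- make_fusiform_phantom(phantom_spec())
  rep <- measure_all(ph$surface, ph$centerlines)
  v <- rep$values; g <- ph$ledger
  expect_length(rep$errors, 0L)
  expect_equal(v$neck_diameter_mm, g$neck_diameter_mm, tolerance = 0.01)
  expect_equal(v$aneurysm_diameter_mm, g$aneurysm_diameter_mm, tolerance = 0.01)
  expect_equal(v$right_iliac_diameter_mm, g$right_iliac_diameter_mm, tolerance = 0.01)
  expect_equal(v$left_iliac_diameter_mm, g$left_iliac_diameter_mm, tolerance = 0.01)
  expect_equal(v$neck_length_mm, g$neck_length_mm, tolerance = 0.005)
  expect_lt(abs(v$right_tortuosity$ratio - g$right_tortuosity$ratio), 0.002)
  expect_lt(abs(v$left_tortuosity$ratio - g$left_tortuosity$ratio), 0.002)
  expect_lt(abs(v$neck_angulation_deg - g$neck_angulation_deg), 0.5)
})

test_that("sampling density can only sharpen the aneurysm diameter estimate", {
  ph <- make_fusiform_phantom(phantom_spec(circumferential_segments = 48))
  d5 <- aneurysm_diameter(ph$surface, ph$centerlines$aneurysm, step = 5)$diameter
  d1 <- aneurysm_diameter(ph$surface, ph$centerlines$aneurysm, step = 1)$diameter
  expect_gte(d1, d5 - 0.5)
})

test_that("one failed landmark is reported without aborting the others", {
  ph <- make_fusiform_phantom(phantom_spec())
  cs <- ph$centerlines
  broken <- centerline_set(cs$neck, cs$aneurysm, cs$right_iliac, cs$left_iliac,
                           section_plane(c(0, 0, 1000), c(0, 0, 1)),  # misplaced
                           cs$left_plane)
  rep <- measure_all(ph$surface, broken)
  expect_named(rep$errors, "right_iliac_diameter_mm")
  expect_null(rep$values$right_iliac_diameter_mm)
  expect_length(rep$values, 7L)  # the other seven entries survive
  row <- report_to_csv_row(rep)
  expect_true(is.na(row$right_iliac_diameter_mm))
  expect_identical(row$n_errors, 1L)
})

test_that("reports serialize to canonical JSON with sorted keys", {
  ph <- make_fusiform_phantom(phantom_spec(circumferential_segments = 24, axial_step = 3))
  rep <- measure_all(ph$surface, ph$centerlines)
  j1 <- report_to_json(rep)
  j2 <- report_to_json(measure_all(ph$surface, ph$centerlines))
  expect_identical(j1, j2)
  parsed <- jsonlite::fromJSON(j1)
  expect_true(all(c("errors", "provenance", "stations", "values") %in% names(parsed)))
  expect_identical(names(parsed), sort(names(parsed)))
})
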