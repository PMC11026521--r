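# Parametric vascular phantoms with analytic ground truth: swept-tube
# meshes along centerlines, a fusiform AAA phantom (bent neck, cosine-bell
# aneurysm bulge, two iliac arc branches, iliac separation planes), and
# shifted-box label-volume fixtures for the segmentation metrics.

#' Phantom specification
#'
#' Parameters of the synthetic AAA model. Defaults are scaled to a typical
#' clinical cohort (neck diameter ~24 mm, aneurysm diameter ~55 mm, neck
#' length ~33 mm, iliac diameters 16-18 mm) so phantom measurements land in
#' a realistic range; ground truth is always the analytic ledger computed
#' from the spec, never a cohort table.
#'
#' @param neck_radius neck tube radius, mm.
#' @param neck_length neck centerline arc length, mm.
#' @param neck_bend_deg angle (degrees) between the neck chord and the
#'   aneurysm axis. The neck is a circular arc with total turning angle
#'   twice this value that joins the aneurysm axis tangentially, so the
#'   chord-to-axis angle (the angulation ground truth) equals this
#'   parameter exactly.
#' @param aneurysm_max_radius peak radius of the fusiform bulge, mm
#'   (>= `neck_radius`).
#' @param aneurysm_length aneurysm segment length, mm.
#' @param iliac_radii c(right, left) branch radii, mm.
#' @param iliac_arc_deg c(right, left) branch arc angles, degrees (0 =
#'   straight branch).
#' @param iliac_length branch centerline length, mm (fixed; the arc radius
#'   follows from the arc angle).
#' @param branch_tilt_deg initial tilt of each branch from the trunk axis
#'   (degrees). At 45 degrees each branch starts perpendicular to the other
#'   side's start-plane normal, which keeps the plane separation clean.
#' @param plane_margin arc-length position (mm) of the iliac start plane
#'   along each branch centerline.
#' @param circumferential_segments vertices per tube ring (>= 16).
#' @param axial_step ring spacing along centerlines, mm.
#' @param seed stored for provenance; the generator itself is deterministic.
#' @return A list of class `aaa_phantom_spec`.
#' @export
phantom_spec <- function(neck_radius = 12, neck_length = 33, neck_bend_deg = 30,
                         aneurysm_max_radius = 27.5, aneurysm_length = 90,
                         iliac_radii = c(9, 8), iliac_arc_deg = c(0, 90),
                         iliac_length = 70, branch_tilt_deg = 45,
                         plane_margin = 20,
                         circumferential_segments = 72, axial_step = 1.0,
                         seed = 1L) {
  sp <- list(neck_radius = neck_radius, neck_length = neck_length,
             neck_bend_deg = neck_bend_deg,
             aneurysm_max_radius = aneurysm_max_radius,
             aneurysm_length = aneurysm_length,
             iliac_radii = as.double(iliac_radii),
             iliac_arc_deg = as.double(iliac_arc_deg),
             iliac_length = iliac_length,
             branch_tilt_deg = branch_tilt_deg,
             plane_margin = plane_margin,
             circumferential_segments = as.integer(circumferential_segments),
             axial_step = axial_step, seed = as.integer(seed))
  .validate_phantom_spec(sp)
  structure(sp, class = "aaa_phantom_spec")
}

.validate_phantom_spec <- function(sp) {
  radii <- c(sp$neck_radius, sp$aneurysm_max_radius, sp$iliac_radii)
  if (any(!is.finite(radii)) || any(radii <= 0)) {
    stop_aaa("aaa_input_error", "all phantom radii must be positive")
  }
  if (sp$aneurysm_max_radius < sp$neck_radius) {
    stop_aaa("aaa_input_error", "aneurysm_max_radius must be >= neck_radius")
  }
  if (sp$circumferential_segments < 16L) {
    stop_aaa("aaa_input_error", "need >= 16 circumferential segments")
  }
  if (length(sp$iliac_radii) != 2L || length(sp$iliac_arc_deg) != 2L) {
    stop_aaa("aaa_input_error", "iliac_radii and iliac_arc_deg must have length 2 (right, left)")
  }
  if (any(sp$iliac_arc_deg < 0) || any(sp$iliac_arc_deg > 90)) {
    stop_aaa("aaa_input_error", "iliac arc angles must lie in [0, 90] degrees")
  }
  if (sp$neck_bend_deg < 0 || sp$neck_bend_deg > 45) {
    stop_aaa("aaa_input_error", "neck_bend_deg must lie in [0, 45] degrees")
  }
  if (sp$axial_step <= 0 || sp$neck_length <= 0 || sp$aneurysm_length <= 0 ||
      sp$iliac_length <= 0) {
    stop_aaa("aaa_input_error", "lengths and axial_step must be positive")
  }
  if (sp$plane_margin <= 0 || sp$plane_margin >= sp$iliac_length - 5) {
    stop_aaa("aaa_input_error", "plane_margin must lie well inside the iliac branch")
  }
  invisible(sp)
}

#' Swept-tube triangulation along a centerline
#'
#' Builds an open-ended tube by sweeping a ring of `segments` vertices along
#' the centerline. Ring orientation is parallel-transported from point to
#' point so the tube carries no twist, which keeps bent tubes free of
#' self-intersection.
#'
#' @param centerline an `aaa_centerline`; must be smooth (no consecutive
#'   tangent flip beyond 90 degrees).
#' @param radius_profile either a single positive number or a function of
#'   arc length (mm, from the start) returning the local radius in mm.
#' @param segments circumferential vertex count (>= 4).
#' @return An `aaa_surface`.
#' @export
make_tube_surface <- function(centerline, radius_profile, segments = 72L) {
  if (!inherits(centerline, "aaa_centerline")) {
    stop_aaa("aaa_precondition_error", "centerline must be an aaa_centerline")
  }
  segments <- as.integer(segments)
  if (is.na(segments) || segments < 4L) {
    stop_aaa("aaa_precondition_error", "need >= 4 circumferential segments")
  }
  p <- centerline$points
  n <- nrow(p)
  seg_t <- p[-1, , drop = FALSE] - p[-n, , drop = FALSE]
  seg_t <- seg_t / sqrt(rowSums(seg_t^2))
  if (n > 2L) {
    dots <- rowSums(seg_t[-1, , drop = FALSE] * seg_t[-(n - 1), , drop = FALSE])
    if (any(dots < 0)) {
      stop_aaa("aaa_geometry_error", "centerline tangent flips by more than 90 degrees")
    }
  }
  # per-point tangents: forward/backward at ends, angle-bisecting inside
  tang <- matrix(0, n, 3)
  tang[1, ] <- seg_t[1, ]
  tang[n, ] <- seg_t[n - 1, ]
  if (n > 2L) {
    mid <- seg_t[-1, , drop = FALSE] + seg_t[-(n - 1), , drop = FALSE]
    tang[2:(n - 1), ] <- mid / sqrt(rowSums(mid^2))
  }

  cum <- .cumulative_arc(p)
  radii <- if (is.function(radius_profile)) {
    vapply(cum, radius_profile, numeric(1))
  } else rep(as.double(radius_profile)[1], n)
  if (any(!is.finite(radii)) || any(radii <= 0)) {
    stop_aaa("aaa_precondition_error", "radius profile must be positive everywhere")
  }

  # parallel-transported frame
  t1 <- tang[1, ]
  ref <- diag(3)[, which.min(abs(t1))]
  e1 <- .unitize(ref - sum(ref * t1) * t1)
  E1 <- matrix(0, n, 3); E1[1, ] <- e1
  for (i in 2:n) {
    a <- tang[i - 1, ]; b <- tang[i, ]
    ax <- .cross3(a, b)
    s <- .vnorm(ax)
    if (s < 1e-12) {
      e1 <- E1[i - 1, ]
    } else {
      ax <- ax / s
      cth <- max(-1, min(1, sum(a * b)))
      th <- atan2(s, cth)
      v <- E1[i - 1, ]
      e1 <- v * cos(th) + .cross3(ax, v) * sin(th) + ax * sum(ax * v) * (1 - cos(th))
    }
    e1 <- .unitize(e1 - sum(e1 * tang[i, ]) * tang[i, ])  # re-orthogonalize
    E1[i, ] <- e1
  }

  phi <- 2 * pi * (seq_len(segments) - 1L) / segments
  verts <- matrix(0, n * segments, 3)
  for (i in seq_len(n)) {
    e2 <- .cross3(tang[i, ], E1[i, ])
    ring <- p[rep(i, segments), , drop = FALSE] +
      radii[i] * (outer(cos(phi), E1[i, ]) + outer(sin(phi), e2))
    verts[(i - 1L) * segments + seq_len(segments), ] <- ring
  }
  j1 <- seq_len(segments); j2 <- c(seq_len(segments)[-1], 1L)
  faces <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    a <- (i - 1L) * segments + j1
    b <- (i - 1L) * segments + j2
    cc <- i * segments + j2
    dd <- i * segments + j1
    faces[[i]] <- rbind(cbind(a, b, cc), cbind(a, cc, dd))
  }
  triangle_surface(verts, do.call(rbind, faces))
}

.merge_surfaces <- function(...) {
  parts <- list(...)
  off <- 0L
  V <- list(); F <- list()
  for (s in parts) {
    V[[length(V) + 1L]] <- s$vertices
    F[[length(F) + 1L]] <- s$faces + off
    off <- off + nrow(s$vertices)
  }
  triangle_surface(do.call(rbind, V), do.call(rbind, F))
}

# sample an arc-length parameter range as ~axial_step-spaced values
.arc_samples <- function(total, step) {
  k <- max(2L, as.integer(ceiling(total / step)) + 1L)
  seq(0, total, length.out = k)
}

#' Fusiform AAA phantom with analytic ground truth
#'
#' Builds the full synthetic model: a neck tube (optionally bent as a
#' circular arc joining the aneurysm axis tangentially), a fusiform bulge
#' with a cosine-bell radius profile peaking at `aneurysm_max_radius`, and
#' two iliac branch tubes following circular arcs. Emits the matching
#' centerline set (neck, aneurysm, right and left iliac) and the two iliac
#' start planes, normals pointing into the iliac territory, plus the ledger
#' of the seven landmark values implied analytically by the spec.
#'
#' @param spec an [phantom_spec()].
#' @return List with `surface` (`aaa_surface`), `centerlines`
#'   (`aaa_centerline_set`), and `ledger` (named list mirroring the
#'   measurement report).
#' @export
make_fusiform_phantom <- function(spec) {
  if (!inherits(spec, "aaa_phantom_spec")) spec <- do.call(phantom_spec, spec)
  .validate_phantom_spec(spec)
  h <- spec$axial_step
  r_n <- spec$neck_radius; L_n <- spec$neck_length
  beta <- spec$neck_bend_deg * pi / 180
  r_max <- spec$aneurysm_max_radius; L_a <- spec$aneurysm_length

  # neck centerline: ends at the origin with tangent +z (the aneurysm axis)
  if (beta < 1e-9) {
    s <- .arc_samples(L_n, h)
    neck_pts <- cbind(0, 0, s - L_n)
  } else {
    R_arc <- L_n / (2 * beta)
    chi <- seq(2 * beta, 0, length.out = max(2L, as.integer(ceiling(L_n / h)) + 1L))
    neck_pts <- cbind(R_arc * (1 - cos(chi)), 0, -R_arc * sin(chi))
  }
  neck_cl <- centerline(neck_pts, "neck")

  # aneurysm centerline: straight along +z
  sa <- .arc_samples(L_a, h)
  an_pts <- cbind(0, 0, sa)
  an_cl <- centerline(an_pts, "aneurysm")

  # one continuous trunk tube (C1 radius junction at the origin)
  trunk_pts <- rbind(neck_pts[-nrow(neck_pts), , drop = FALSE], an_pts)
  trunk_cl <- centerline(trunk_pts, "trunk")
  cum <- .cumulative_arc(trunk_pts)
  s_junction <- cum[nrow(neck_pts)]    # arc position of the neck/aneurysm joint
  s_total <- cum[length(cum)]
  bulge <- function(s) {
    if (s <= s_junction) return(r_n)
    tau <- (s - s_junction) / (s_total - s_junction)
    r_n + (r_max - r_n) * sin(pi * tau)^2
  }
  trunk <- make_tube_surface(trunk_cl, bulge, spec$circumferential_segments)

  # iliac branches: arcs in the xz-plane tilted outward from the trunk axis
  alpha <- spec$branch_tilt_deg * pi / 180
  A1 <- c(0, 0, L_a)
  branch <- function(side) {  # +1 right (+x), -1 left (-x)
    i <- if (side > 0) 1L else 2L
    r_i <- spec$iliac_radii[i]
    theta <- spec$iliac_arc_deg[i] * pi / 180
    L_i <- spec$iliac_length
    u <- .arc_samples(L_i, h)
    if (theta < 1e-6) {
      t0 <- c(side * sin(alpha), 0, cos(alpha))
      pts <- sweep(outer(u, t0), 2, A1, "+")
    } else {
      R <- L_i / theta
      psi <- alpha + u / R
      pts <- cbind(side * R * (cos(alpha) - cos(psi)), 0, R * (sin(psi) - sin(alpha)))
      pts <- sweep(pts, 2, A1, "+")
    }
    cl <- centerline(pts, if (side > 0) "right_iliac" else "left_iliac")
    tube <- make_tube_surface(cl, r_i, spec$circumferential_segments)
    # start plane at arc length plane_margin, normal along the initial tangent
    t0 <- .unitize(pts[2, ] - pts[1, ])
    m <- spec$plane_margin
    cum_b <- .cumulative_arc(pts)
    k <- findInterval(m, cum_b, rightmost.closed = TRUE)
    tt <- (m - cum_b[k]) / (cum_b[k + 1] - cum_b[k])
    porig <- pts[k, ] + tt * (pts[k + 1, ] - pts[k, ])
    list(cl = cl, tube = tube, plane = section_plane(porig, t0), theta = theta,
         r = r_i, L = L_i)
  }
  right <- branch(+1); left <- branch(-1)

  surface <- .merge_surfaces(trunk, right$tube, left$tube)

  # verify the separation convention: everything that is not the branch's own
  # tube must lie strictly on the negative side of its start plane
  check_sep <- function(br, own, others) {
    n <- br$plane$normal; o <- br$plane$origin
    for (s in others) {
      dmax <- max(as.vector(s$vertices %*% n) - sum(o * n))
      if (dmax > -0.5) {
        stop_aaa("aaa_geometry_error",
                 "iliac start plane fails to separate (margin %.2f mm)", -dmax)
      }
    }
  }
  check_sep(right, right$tube, list(trunk, left$tube))
  check_sep(left, left$tube, list(trunk, right$tube))

  cset <- centerline_set(neck_cl, an_cl, right$cl, left$cl, right$plane, left$plane)

  tort <- function(br) {
    if (br$theta < 1e-6) {
      list(curve_mm = br$L, line_mm = br$L, ratio = 1.0)
    } else {
      half <- br$theta / 2
      list(curve_mm = br$L, line_mm = br$L * sin(half) / half, ratio = half / sin(half))
    }
  }
  ledger <- list(
    neck_diameter_mm = 2 * r_n,
    aneurysm_diameter_mm = 2 * r_max,
    right_iliac_diameter_mm = 2 * right$r,
    left_iliac_diameter_mm = 2 * left$r,
    neck_length_mm = L_n,
    right_tortuosity = tort(right),
    left_tortuosity = tort(left),
    neck_angulation_deg = spec$neck_bend_deg
  )
  list(surface = surface, centerlines = cset, ledger = ledger, spec = spec)
}

#' Seeded random phantom specifications
#'
#' Draws `n` specs with anatomically plausible parameter ranges (neck radius
#' 10-14 mm, neck length 25-45 mm, neck bend 0-30 deg, aneurysm radius 20-30
#' mm and length 70-100 mm, iliac radii 6-9.5 mm, iliac arcs 0-90 deg) for
#' parameter-recovery testing. Coarser tessellation (64 segments, 1.5 mm
#' rings) keeps batch runs fast without visible loss of measurement accuracy.
#'
#' @param n number of specs.
#' @param seed RNG seed.
#' @return List of `aaa_phantom_spec`.
#' @export
random_phantom_specs <- function(n = 20L, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    phantom_spec(
      neck_radius = stats::runif(1, 10, 14),
      neck_length = stats::runif(1, 25, 45),
      neck_bend_deg = stats::runif(1, 0, 30),
      aneurysm_max_radius = stats::runif(1, 20, 30),
      aneurysm_length = stats::runif(1, 70, 100),
      iliac_radii = stats::runif(2, 6, 9.5),
      iliac_arc_deg = stats::runif(2, 0, 90),
      circumferential_segments = 64L,
      axial_step = 1.5,
      seed = seed + i
    )
  })
}

#' Shifted-box label-volume pair with exact expected metrics
#'
#' Two binary masks containing the same axis-aligned box, the second shifted
#' by an integer voxel offset. The expected Dice follows from the exact
#' overlap count; the expected HD95 is computed by an independent
#' brute-force all-pairs boundary oracle.
#'
#' @param shape voxel grid dimensions (3 integers).
#' @param box box extents in voxels (3 integers).
#' @param shift voxel offset of the second box (3 integers).
#' @param spacing voxel spacing in mm (3 values).
#' @return List with `a`, `b` (`aaa_label_volume`), `expected_dice`,
#'   `expected_hd95`.
#' @export
make_shifted_box_volumes <- function(shape, box, shift, spacing = c(1, 1, 1)) {
  shape <- as.integer(shape); box <- as.integer(box); shift <- as.integer(shift)
  if (length(shape) != 3L || length(box) != 3L || length(shift) != 3L) {
    stop_aaa("aaa_input_error", "shape, box, and shift must be integer triples")
  }
  if (any(box < 1L)) stop_aaa("aaa_input_error", "box extents must be >= 1 voxel")
  start <- pmax(1L, 1L - shift)
  if (any(start + box - 1L > shape) || any(start + shift < 1L) ||
      any(start + shift + box - 1L > shape)) {
    stop_aaa("aaa_input_error", "box and shifted box must fit inside the grid")
  }
  mk <- function(s0) {
    a <- array(0L, shape)
    a[s0[1]:(s0[1] + box[1] - 1L),
      s0[2]:(s0[2] + box[2] - 1L),
      s0[3]:(s0[3] + box[3] - 1L)] <- 1L
    label_volume(a, spacing = spacing)
  }
  va <- mk(start); vb <- mk(start + shift)
  overlap <- prod(pmax(box - abs(shift), 0L))
  expected_dice <- 2 * overlap / (2 * prod(box))
  expected_hd95 <- .hd95_bruteforce(va$voxels == 1L, vb$voxels == 1L, as.double(spacing))
  list(a = va, b = vb, expected_dice = expected_dice, expected_hd95 = expected_hd95)
}

# Independent all-pairs oracle for HD95 on small masks: explicit neighbor
# checks for the boundary, full distance matrix, type-7 percentile.
.hd95_bruteforce <- function(ma, mb, spacing) {
  bpts <- function(m) {
    idx <- which(m, arr.ind = TRUE)
    d <- dim(m)
    on_b <- logical(nrow(idx))
    for (r in seq_len(nrow(idx))) {
      v <- idx[r, ]
      for (ax in 1:3) for (dlt in c(-1L, 1L)) {
        w <- v; w[ax] <- w[ax] + dlt
        if (w[ax] < 1L || w[ax] > d[ax] || !m[w[1], w[2], w[3]]) { on_b[r] <- TRUE }
      }
    }
    sweep(idx[on_b, , drop = FALSE] - 1, 2, spacing, "*")
  }
  A <- bpts(ma); B <- bpts(mb)
  if (nrow(A) == 0L || nrow(B) == 0L) {
    stop_aaa("aaa_undefined_distance", "empty mask in brute-force HD95")
  }
  dmin_ab <- numeric(nrow(A)); dmin_ba <- rep(Inf, nrow(B))
  for (i in seq_len(nrow(A))) {
    dd <- sqrt(colSums((t(B) - A[i, ])^2))
    dmin_ab[i] <- min(dd)
    dmin_ba <- pmin(dmin_ba, dd)
  }
  max(stats::quantile(dmin_ab, 0.95, type = 7, names = FALSE),
      stats::quantile(dmin_ba, 0.95, type = 7, names = FALSE))
}
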