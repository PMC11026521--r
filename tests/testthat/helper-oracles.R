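# Independent oracles and fixture builders used across the suite. These
# deliberately avoid the package's own code paths: plain double loops and
# textbook formulas only.

# O(n^2) double-loop maximum chord
chord_oracle <- function(points) {
  n <- nrow(points)
  best <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((points[i, ] - points[j, ])^2))
      if (d > best) best <- d
    }
  }
  best
}

# all-pairs boundary HD95 oracle on small binary arrays (explicit loops)
hd95_oracle <- function(ma, mb, spacing = c(1, 1, 1)) {
  boundary <- function(m) {
    d <- dim(m)
    idx <- which(m, arr.ind = TRUE)
    keep <- logical(nrow(idx))
    for (r in seq_len(nrow(idx))) {
      v <- idx[r, ]
      for (ax in 1:3) {
        for (dl in c(-1L, 1L)) {
          w <- v; w[ax] <- w[ax] + dl
          if (w[ax] < 1 || w[ax] > d[ax] || !m[w[1], w[2], w[3]]) keep[r] <- TRUE
        }
      }
    }
    sweep(idx[keep, , drop = FALSE] - 1, 2, spacing, "*")
  }
  A <- boundary(ma); B <- boundary(mb)
  dmat <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      dmat[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2))
    }
  }
  dab <- apply(dmat, 1, min)
  dba <- apply(dmat, 2, min)
  max(quantile(dab, 0.95, type = 7, names = FALSE),
      quantile(dba, 0.95, type = 7, names = FALSE))
}

# exact (maximum) Hausdorff distance from the same boundary sets
hausdorff_max_oracle <- function(ma, mb, spacing = c(1, 1, 1)) {
  boundary <- function(m) {
    d <- dim(m)
    idx <- which(m, arr.ind = TRUE)
    keep <- logical(nrow(idx))
    for (r in seq_len(nrow(idx))) {
      v <- idx[r, ]
      for (ax in 1:3) {
        for (dl in c(-1L, 1L)) {
          w <- v; w[ax] <- w[ax] + dl
          if (w[ax] < 1 || w[ax] > d[ax] || !m[w[1], w[2], w[3]]) keep[r] <- TRUE
        }
      }
    }
    sweep(idx[keep, , drop = FALSE] - 1, 2, spacing, "*")
  }
  A <- boundary(ma); B <- boundary(mb)
  dmat <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      dmat[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2))
    }
  }
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

# ICC(2,1) via stats::aov mean squares (independent decomposition path)
icc_aov_oracle <- function(ratings) {
  n <- nrow(ratings); k <- ncol(ratings)
  df <- data.frame(
    y = as.vector(ratings),
    subject = factor(rep(seq_len(n), k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(aov(y ~ subject + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# random closed planar contour: noisy star polygon embedded in a random plane
random_planar_contour <- function(npts = 40) {
  axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  org <- rnorm(3, sd = 20)
  th <- sort(runif(npts, 0, 2 * pi))
  r <- runif(npts, 2, 15)
  pts <- t(vapply(seq_len(npts), function(i) {
    org + r[i] * (cos(th[i]) * e1 + sin(th[i]) * e2)
  }, numeric(3)))
  planar_contour(pts, closed = TRUE, plane = section_plane(org, axis),
                 tol_plane = 1e-6)
}

# rigid-motion helpers (rotation about a unit axis by angle, then shift)
rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

transform_points <- function(p, R, shift) {
  sweep(p %*% t(R), 2, shift, "+")
}

transform_surface <- function(s, R, shift) {
  triangle_surface(transform_points(s$vertices, R, shift), s$faces)
}

transform_centerline <- function(cl, R, shift) {
  centerline(transform_points(cl$points, R, shift), cl$name)
}

transform_cset <- function(cs, R, shift) {
  tp <- function(pl) section_plane(as.vector(R %*% pl$origin) + shift,
                                   as.vector(R %*% pl$normal))
  centerline_set(
    transform_centerline(cs$neck, R, shift),
    transform_centerline(cs$aneurysm, R, shift),
    transform_centerline(cs$right_iliac, R, shift),
    transform_centerline(cs$left_iliac, R, shift),
    tp(cs$right_plane), tp(cs$left_plane)
  )
}

scale_cset <- function(cs, s) {
  sc <- function(cl) centerline(cl$points * s, cl$name)
  sp <- function(pl) section_plane(pl$origin * s, pl$normal)
  centerline_set(sc(cs$neck), sc(cs$aneurysm), sc(cs$right_iliac),
                 sc(cs$left_iliac), sp(cs$right_plane), sp(cs$left_plane))
}

# quarter-circle centerline of radius R in the xz-plane, finely sampled
quarter_circle_centerline <- function(R = 60, npts = 1000, name = "arc") {
  th <- seq(0, pi / 2, length.out = npts)
  centerline(cbind(R * sin(th), 0, R * (1 - cos(th))), name)
}

# straight-tube fixture: axis +z from 0 to len
straight_tube <- function(radius = 10, len = 50, segments = 72, step = 1) {
  cl <- centerline(cbind(0, 0, seq(0, len, by = step)), "axis")
  list(surface = make_tube_surface(cl, radius, segments), centerline = cl)
}
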