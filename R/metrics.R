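# Evaluation statistics: Dice similarity coefficient and 95th-percentile
# Hausdorff distance on voxel label volumes, Bland-Altman limits of
# agreement, and the two-way random-effects absolute-agreement intraclass
# correlation ICC(2,1).

#' Integer label volume on a regular voxel grid
#'
#' @param voxels 3D integer array; 0 = background, positive integers are
#'   class labels (1..4 = aorta, thrombus, calcification, vessels by
#'   convention).
#' @param spacing voxel spacing, mm per axis (3-vector, all > 0).
#' @param origin world position of the first voxel (mm).
#' @return Object of class `aaa_label_volume`.
#' @export
label_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop_aaa("aaa_precondition_error", "voxels must be a 3D array")
  }
  if (any(!is.finite(voxels)) || any(voxels < 0) || any(voxels != round(voxels))) {
    stop_aaa("aaa_precondition_error", "labels must be non-negative integers")
  }
  spacing <- as.double(spacing); origin <- as.double(origin)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop_aaa("aaa_precondition_error", "spacing must be three positive lengths (mm)")
  }
  storage.mode(voxels) <- "integer"
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "aaa_label_volume")
}

#' Read a label volume from NIfTI
#'
#' Spacing and origin are taken from the image geometry (pixdim and the
#' xform translation).
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return An `aaa_label_volume`.
#' @export
read_label_volume <- function(path) {
  if (!file.exists(path)) stop_aaa("aaa_io_error", "file not found: %s", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop_aaa("aaa_format_error", "expected a 3D NIfTI volume")
  xf <- RNifti::xform(img)
  label_volume(round(arr), spacing = RNifti::pixdim(img)[1:3], origin = xf[1:3, 4])
}

#' Write a label volume to NIfTI
#'
#' @param vol an `aaa_label_volume`.
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_label_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

.check_same_grid <- function(a, b) {
  if (!inherits(a, "aaa_label_volume") || !inherits(b, "aaa_label_volume")) {
    stop_aaa("aaa_precondition_error", "both inputs must be aaa_label_volume")
  }
  if (!identical(dim(a$voxels), dim(b$voxels)) ||
      max(abs(a$spacing - b$spacing)) > 1e-9 ||
      max(abs(a$origin - b$origin)) > 1e-6) {
    stop_aaa("aaa_geometry_error", "label volumes are not on the same grid")
  }
}

#' Dice similarity coefficient for one label
#'
#' `2|A n B| / (|A| + |B|)` over voxels equal to `label`; 1 means perfect
#' overlap, 0 none. When the label is absent from both volumes the result is
#' 1.0 (total agreement on absence) with a warning; when absent from exactly
#' one, 0.0.
#'
#' @param a,b `aaa_label_volume` objects on the same grid.
#' @param label integer class label.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(a, b, label = 1L) {
  .check_same_grid(a, b)
  A <- a$voxels == label; B <- b$voxels == label
  na <- sum(A); nb <- sum(B)
  if (na == 0L && nb == 0L) {
    warning("label absent from both volumes; Dice defined as 1.0")
    return(1.0)
  }
  if (na == 0L || nb == 0L) return(0.0)
  2 * sum(A & B) / (na + nb)
}

# Boundary voxels of a binary mask: labeled voxels with at least one
# face-adjacent (6-connectivity) unlabeled neighbor; volume borders count as
# unlabeled outside.
.boundary_mask <- function(m) {
  d <- dim(m)
  all_nb <- array(TRUE, d)
  shift_and <- function(axis, by) {
    s <- array(FALSE, d)
    idx_src <- lapply(d, seq_len); idx_dst <- idx_src
    n <- d[axis]
    if (by > 0) { idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- 1:(n - 1) }
    else { idx_dst[[axis]] <- 1:(n - 1); idx_src[[axis]] <- 2:n }
    s <- do.call(`[<-`, c(list(s), idx_dst, list(do.call(`[`, c(list(m), idx_src)))))
    s
  }
  for (axis in 1:3) for (by in c(-1L, 1L)) {
    all_nb <- all_nb & shift_and(axis, by)
  }
  m & !all_nb
}

.boundary_points_mm <- function(vol, label) {
  m <- vol$voxels == label
  if (!any(m)) return(NULL)
  bm <- .boundary_mask(m)
  idx <- which(bm, arr.ind = TRUE)
  sweep(idx - 1, 2, vol$spacing, "*")
}

# Directed nearest-neighbour distances from each row of A to the set B,
# computed in blocks to bound memory.
.min_dists <- function(A, B, block = 2e6) {
  na <- nrow(A); nb <- nrow(B)
  rb <- rowSums(B^2)
  out <- numeric(na)
  chunk <- max(1L, floor(block / nb))
  i <- 1L
  while (i <= na) {
    j <- min(na, i + chunk - 1L)
    Ai <- A[i:j, , drop = FALSE]
    D2 <- matrix(rowSums(Ai^2), j - i + 1L, nb) +
      matrix(rb, j - i + 1L, nb, byrow = TRUE) - 2 * (Ai %*% t(B))
    k <- max.col(-D2, ties.method = "first")
    out[i:j] <- sqrt(pmax(D2[cbind(seq_len(j - i + 1L), k)], 0))
    i <- j + 1L
  }
  out
}

#' 95th-percentile Hausdorff distance for one label
#'
#' Boundary voxels (6-connectivity face adjacency) of each mask are mapped to
#' physical mm; each directed distance is the 95th percentile (linear
#' interpolation between order statistics) of nearest-boundary distances, and
#' the symmetric HD95 is the maximum of the two directions. Robust variant of
#' the maximum Hausdorff distance: the percentile discards outlier surface
#' distances.
#'
#' @param a,b `aaa_label_volume` objects on the same grid, both containing
#'   the label.
#' @param label integer class label.
#' @return Distance in mm.
#' @export
hd95 <- function(a, b, label = 1L) {
  .check_same_grid(a, b)
  Pa <- .boundary_points_mm(a, label)
  Pb <- .boundary_points_mm(b, label)
  if (is.null(Pa) || is.null(Pb)) {
    stop_aaa("aaa_undefined_distance", "label %d empty in at least one volume", label)
  }
  dab <- stats::quantile(.min_dists(Pa, Pb), 0.95, type = 7, names = FALSE)
  dba <- stats::quantile(.min_dists(Pb, Pa), 0.95, type = 7, names = FALSE)
  max(dab, dba)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = x - y`; bias is their mean, and the limits of agreement
#' are `bias +/- 1.96 * sd` (sample standard deviation, n-1 denominator).
#' With `remove_outliers = TRUE`, points whose difference falls outside the
#' initial limits are dropped once and the statistics recomputed; the initial
#' pass is retained in the `initial` element.
#'
#' @param x,y paired measurement vectors of equal length >= 2.
#' @param remove_outliers drop outliers outside the initial 95% limits once.
#' @return Object of class `aaa_agreement` with `bias`, `sd`, `loa_low`,
#'   `loa_high`, `n_used`, `outliers_removed`, and (when outliers were
#'   removed) `initial`.
#' @export
bland_altman <- function(x, y, remove_outliers = FALSE) {
  x <- as.double(x); y <- as.double(y)
  if (length(x) != length(y)) stop_aaa("aaa_input_error", "x and y must have equal length")
  if (length(x) < 2L) stop_aaa("aaa_input_error", "need at least 2 paired measurements")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_aaa("aaa_input_error", "non-finite measurements")
  pass <- function(d, removed) {
    b <- mean(d); s <- stats::sd(d)
    structure(list(bias = b, sd = s,
                   loa_low = b - 1.96 * s, loa_high = b + 1.96 * s,
                   n_used = length(d), outliers_removed = removed),
              class = "aaa_agreement")
  }
  d <- x - y
  first <- pass(d, 0L)
  if (!remove_outliers) return(first)
  keep <- d >= first$loa_low & d <= first$loa_high
  second <- pass(d[keep], sum(!keep))
  second$initial <- first
  second
}

#' @export
print.aaa_agreement <- function(x, ...) {
  cat(sprintf("<aaa_agreement> bias %.4g, sd %.4g, LoA [%.4g, %.4g], n = %d (%d outliers removed)\n",
              x$bias, x$sd, x$loa_low, x$loa_high, x$n_used, x$outliers_removed))
  invisible(x)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater intraclass
#' correlation from the two-way ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' where MSR, MSC, MSE are the subject, observer, and residual mean squares
#' of an n subjects x k observers table. The result is clamped to [-1, 1].
#' A table with zero total variance (all cells identical) is defined as 1.0
#' with a warning.
#'
#' @param ratings numeric matrix, n subjects (rows) x k observers (columns),
#'   no missing cells, n >= 2, k >= 2.
#' @return ICC(2,1) coefficient.
#' @export
icc <- function(ratings) {
  if (is.data.frame(ratings)) ratings <- as.matrix(ratings)
  if (!is.matrix(ratings) || !is.numeric(ratings)) {
    stop_aaa("aaa_input_error", "ratings must be a numeric matrix")
  }
  if (anyNA(ratings)) stop_aaa("aaa_input_error", "missing cells are not allowed")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) stop_aaa("aaa_input_error", "need >= 2 subjects and >= 2 observers")
  g <- mean(ratings)
  ss_total <- sum((ratings - g)^2)
  if (ss_total < 1e-24) {
    warning("zero total variance: all raters and subjects identical; ICC defined as 1.0")
    return(1.0)
  }
  rowm <- rowMeans(ratings); colm <- colMeans(ratings)
  msr <- k * sum((rowm - g)^2) / (n - 1)
  msc <- n * sum((colm - g)^2) / (k - 1)
  sse <- ss_total - k * sum((rowm - g)^2) - n * sum((colm - g)^2)
  mse <- max(sse, 0) / ((n - 1) * (k - 1))
  val <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  max(-1, min(1, val))
}

#' Pairwise observer Pearson correlations
#'
#' Pearson correlation of every observer-column pair, reported as a named
#' vector (`r_12`, `r_13`, ...). Complements [icc()] when per-pair agreement
#' is wanted.
#'
#' @param ratings numeric matrix, n subjects x k observers.
#' @return Named numeric vector of pairwise correlations.
#' @export
observer_correlations <- function(ratings) {
  if (is.data.frame(ratings)) ratings <- as.matrix(ratings)
  if (!is.matrix(ratings) || ncol(ratings) < 2L) {
    stop_aaa("aaa_input_error", "need a matrix with >= 2 observer columns")
  }
  k <- ncol(ratings)
  pairs <- utils::combn(k, 2)
  out <- apply(pairs, 2, function(p) stats::cor(ratings[, p[1]], ratings[, p[2]]))
  names(out) <- apply(pairs, 2, function(p) sprintf("r_%d%d", p[1], p[2]))
  out
}
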