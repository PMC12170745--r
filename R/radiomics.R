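#' Discretization settings for texture features
#'
#' Fixed-bin-count discretization over the ROI intensity range: `n_bins`
#' equal-width bins on `[min, max]`, top bin inclusive, so the ROI minimum
#' maps to level 1 and the maximum to level `n_bins`. A constant ROI maps
#' entirely to level 1.
#'
#' @param n_bins number of gray levels (>= 2).
#' @return a `discretization_spec` list.
#' @export
discretization_spec <- function(n_bins = 32L) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  structure(list(n_bins = n_bins), class = "discretization_spec")
}

#' Discretize ROI intensities to integer gray levels
#'
#' @param image numeric 3D array.
#' @param mask logical 3D array (ROI).
#' @param spec a [discretization_spec()].
#' @return integer 3D array: 0 outside the ROI, 1..n_bins inside.
#' @export
discretize <- function(image, mask, spec = discretization_spec()) {
  check_mask(mask)
  check_same_geometry(image, mask, "image/mask")
  if (!any(mask)) stop("empty mask: nothing to discretize", call. = FALSE)
  vals <- image[mask]
  lo <- min(vals); hi <- max(vals)
  lab <- integer(length(image))
  if (hi > lo) {
    g <- floor((vals - lo) / (hi - lo) * spec$n_bins) + 1L
    g[g > spec$n_bins] <- spec$n_bins  # top edge inclusive
    lab[which(mask)] <- as.integer(g)
  } else {
    lab[which(mask)] <- 1L
  }
  array(lab, dim(image))
}

glrlm_feature_names <- function() {
  c("sre", "lre", "gln", "glnn", "rln", "rlnn", "rp", "glv", "rlv", "re",
    "lglre", "hglre", "srlgle", "srhgle", "lrlgle", "lrhgle")
}

# 16 run-length features from one run-length matrix P (levels x lengths)
glrlm_from_matrix <- function(P, n_voxels) {
  Nr <- sum(P)
  if (Nr == 0) return(setNames(rep(NA_real_, 16L), glrlm_feature_names()))
  g <- seq_len(nrow(P))
  l <- seq_len(ncol(P))
  rg <- rowSums(P)   # runs per gray level
  rl <- colSums(P)   # runs per length
  p <- P / Nr
  mu_g <- sum(rg / Nr * g)
  mu_l <- sum(rl / Nr * l)
  pn0 <- p[p > 0]
  c(sre    = sum(rl / l^2) / Nr,
    lre    = sum(rl * l^2) / Nr,
    gln    = sum(rg^2) / Nr,
    glnn   = sum(rg^2) / Nr^2,
    rln    = sum(rl^2) / Nr,
    rlnn   = sum(rl^2) / Nr^2,
    rp     = Nr / n_voxels,
    glv    = sum(rg / Nr * (g - mu_g)^2),
    rlv    = sum(rl / Nr * (l - mu_l)^2),
    re     = -sum(pn0 * log2(pn0)),
    lglre  = sum(rg / g^2) / Nr,
    hglre  = sum(rg * g^2) / Nr,
    srlgle = sum(sweep(sweep(P, 1, g^2, `/`), 2, l^2, `/`)) / Nr,
    srhgle = sum(sweep(sweep(P, 1, g^2, `*`), 2, l^2, `/`)) / Nr,
    lrlgle = sum(sweep(sweep(P, 1, g^2, `/`), 2, l^2, `*`)) / Nr,
    lrhgle = sum(sweep(sweep(P, 1, g^2, `*`), 2, l^2, `*`)) / Nr)
}

#' Gray-level run-length (GLRLM) features
#'
#' Builds one run-length matrix for each of the 13 unique 3D directions
#' (maximal runs of equal discretized gray level, confined to the ROI: a gap
#' in the mask ends a run), computes the 16-feature run-length set per
#' direction, and reports the unweighted mean over directions.
#'
#' Features: short/long run emphasis (sre, lre), gray-level and run-length
#' non-uniformity and their normalized variants (gln, glnn, rln, rlnn), run
#' percentage (rp), gray-level and run-length variance (glv, rlv), run
#' entropy (re), and the four low/high gray-level x short/long run emphases
#' (lglre, hglre, srlgle, srhgle, lrlgle, lrhgle).
#'
#' @param labels integer 3D array from [discretize()] (0 outside ROI).
#' @param n_levels number of gray levels used at discretization.
#' @return named numeric vector of 16 direction-averaged features.
#' @export
glrlm_features <- function(labels, n_levels) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D integer array", call. = FALSE)
  n_voxels <- sum(labels > 0L)
  if (n_voxels == 0L) stop("empty ROI", call. = FALSE)
  mats <- cpp_glrlm(as.integer(labels), dim(labels), as.integer(n_levels))
  per_dir <- vapply(mats, glrlm_from_matrix, numeric(16L),
                    n_voxels = n_voxels)
  setNames(rowMeans(per_dir), glrlm_feature_names())
}

first_order_feature_names <- function() {
  c("mean", "median", "variance", "skewness", "kurtosis", "energy", "rms",
    "min", "max", "range", "iqr", "mad", "p10", "p90", "entropy",
    "uniformity")
}

#' First-order (intensity histogram) features
#'
#' Moments and order statistics of the raw ROI intensities, plus entropy
#' (bits) and uniformity computed on the fixed-bin-count discretized
#' histogram. Skewness and kurtosis use population moments
#' (`m3/m2^(3/2)`, `m4/m2^2`) and are reported as 0 for a constant ROI.
#'
#' @inheritParams discretize
#' @return named numeric vector of 16 features.
#' @export
first_order_features <- function(image, mask, spec = discretization_spec()) {
  check_mask(mask)
  check_same_geometry(image, mask, "image/mask")
  if (!any(mask)) stop("empty mask", call. = FALSE)
  x <- image[mask]
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  skew <- if (m2 > 0) mean((x - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - m)^4) / m2^2 else 0
  lab <- discretize(image, mask, spec)
  pr <- tabulate(lab[mask], nbins = spec$n_bins) / n
  pr0 <- pr[pr > 0]
  c(mean = m, median = median(x), variance = m2, skewness = skew,
    kurtosis = kurt, energy = sum(x^2), rms = sqrt(mean(x^2)),
    min = min(x), max = max(x), range = max(x) - min(x),
    iqr = unname(quantile(x, 0.75) - quantile(x, 0.25)),
    mad = mean(abs(x - m)),
    p10 = unname(quantile(x, 0.10)), p90 = unname(quantile(x, 0.90)),
    entropy = -sum(pr0 * log2(pr0)), uniformity = sum(pr0^2))
}

shape_feature_names <- function() {
  c("volume_ml", "surface_area_mm2", "sphericity", "max_diameter_3d",
    "max_diameter_axial", "max_diameter_coronal", "max_diameter_sagittal",
    "elongation", "flatness")
}

# rows of `idx` that are extreme (min or max) in column `val` within each
# group defined by the remaining key columns
line_extreme_rows <- function(idx, val, keys) {
  key <- do.call(paste, c(lapply(keys, function(k) idx[, k]), sep = "\r"))
  o <- order(key, idx[, val])
  k <- key[o]
  o[!duplicated(k) | !duplicated(k, fromLast = TRUE)]
}

# exact diameter candidate set: every convex-hull vertex is an extreme
# point of its grid line along each axis, so intersecting the three
# per-line extreme sets keeps all hull vertices (hence the exact maximum)
# while discarding the blob interior
diameter_candidates_3d <- function(idx) {
  r1 <- line_extreme_rows(idx, 1, c(2, 3))
  r2 <- line_extreme_rows(idx, 2, c(1, 3))
  r3 <- line_extreme_rows(idx, 3, c(1, 2))
  idx[intersect(intersect(r1, r2), r3), , drop = FALSE]
}

max_diameter_2d <- function(mask, spacing_mm, plane_axes) {
  # plane_axes: the two in-plane axes; slices taken along the third
  slice_axis <- setdiff(1:3, plane_axes)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NA_real_)
  a1 <- plane_axes[1]; a2 <- plane_axes[2]
  best <- 0
  for (s in unique(idx[, slice_axis])) {
    pts <- idx[idx[, slice_axis] == s, , drop = FALSE]
    if (nrow(pts) < 2L) next
    cand <- pts[intersect(line_extreme_rows(pts, a1, a2),
                          line_extreme_rows(pts, a2, a1)), ,
                drop = FALSE]
    co <- cbind(cand[, a1] * spacing_mm[a1], cand[, a2] * spacing_mm[a2], 0)
    best <- max(best, cpp_max_pairwise_dist(co))
  }
  best
}

#' Morphological (shape) features of a segmentation
#'
#' Voxel-count volume (ml), face-counted surface area (mm^2), sphericity
#' `pi^(1/3) (6V)^(2/3) / A`, maximum 3D diameter (largest center-to-center
#' distance between mask voxels, the voxel-center Feret diameter), the
#' largest in-plane 2D diameter per anatomical plane (axial = fixed third
#' axis, coronal = fixed second, sagittal = fixed first), and elongation and
#' flatness from the principal axes of the voxel-center cloud.
#'
#' @param mask 3D logical array.
#' @param spacing_mm voxel spacing (mm); array axes are (sagittal, coronal,
#'   axial), i.e. slices along axis 3 are axial slices.
#' @return named numeric vector of 9 features.
#' @export
shape_features <- function(mask, spacing_mm) {
  check_mask(mask)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  nvox <- sum(mask)
  vox_mm3 <- prod(spacing_mm)
  V <- nvox * vox_mm3
  # exposed faces per axis
  d <- dim(mask)
  area <- 0
  face_area <- c(spacing_mm[2] * spacing_mm[3],
                 spacing_mm[1] * spacing_mm[3],
                 spacing_mm[1] * spacing_mm[2])
  for (ax in 1:3) {
    m1 <- aperm(mask, c(ax, setdiff(1:3, ax)))
    n1 <- dim(m1)[1]
    ext <- array(FALSE, dim(m1) + c(2L, 0L, 0L))
    ext[2:(n1 + 1L), , ] <- m1
    diffs <- ext[1:(n1 + 1L), , , drop = FALSE] != ext[2:(n1 + 2L), , ,
                                                       drop = FALSE]
    area <- area + sum(diffs) * face_area[ax]
  }
  sphericity <- pi^(1 / 3) * (6 * V)^(2 / 3) / area
  idx <- which(mask, arr.ind = TRUE)
  cand <- diameter_candidates_3d(idx)
  co <- sweep(cand, 2, spacing_mm, `*`)
  max3d <- if (nrow(co) >= 2L) cpp_max_pairwise_dist(co) else 0
  all_co <- mask_coords_mm(mask, spacing_mm)
  if (nrow(all_co) >= 2L) {
    ev <- sort(eigen(stats::cov(all_co), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev[ev < 0] <- 0
    elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
    flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1
  } else {
    elong <- 1; flat <- 1
  }
  c(volume_ml = V / 1000,
    surface_area_mm2 = area,
    sphericity = sphericity,
    max_diameter_3d = max3d,
    max_diameter_axial = max_diameter_2d(mask, spacing_mm, c(1L, 2L)),
    max_diameter_coronal = max_diameter_2d(mask, spacing_mm, c(1L, 3L)),
    max_diameter_sagittal = max_diameter_2d(mask, spacing_mm, c(2L, 3L)),
    elongation = elong,
    flatness = flat)
}
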