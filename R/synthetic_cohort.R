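#' Configuration of the synthetic imaging-survival cohort
#'
#' The generator emulates the study conditions the pipeline was designed
#' for: a cohort of segmented diffuse-glioma-like tumors on two co-registered
#' MRI-like sequences, clinical covariates tied to the imaging, and
#' right-censored overall-survival outcomes from a Weibull proportional-
#' hazards model with known (per-SD) log-hazard effect sizes.
#'
#' @param n_patients cohort size.
#' @param voxel_spacing_mm length-3 voxel spacing (mm).
#' @param grid_shape length-3 grid dimensions.
#' @param radius_mm_range range of per-axis tumor semi-axes (mm).
#' @param lobulation amplitude of the smooth spherical-harmonic radial
#'   perturbation of the ellipsoid (0 = exact ellipsoid).
#' @param blob_size_mm_range range of the intratumoral texture correlation
#'   length (mm): tumors are tiled with Voronoi cells of roughly this size,
#'   each of constant intensity, which directly controls run-length
#'   heterogeneity.
#' @param intensity_contrast per-sequence list: `background` mean, `tumor`
#'   offset, `texture_sd` of the per-cell intensities.
#' @param noise_sd additive Gaussian noise SD.
#' @param beta named log-hazard effect sizes; continuous drivers are
#'   standardized cohort-wise (per-SD effects), 0/1 indicators act as is.
#'   Recognized drivers: `max_diameter_3d`, `blob_size`,
#'   `log_preop_volume`, `astrocytoma`, `eor_partial`, `eor_complete`.
#' @param weibull_shape,weibull_scale baseline Weibull event-time
#'   parameters (scale in years).
#' @param event_fraction_target targeted fraction of observed events; the
#'   administrative censoring horizon is calibrated by bisection to hit it.
#'   `NA` disables censoring entirely.
#' @param dropout_rate probability of an independent uniform dropout on
#'   `(0, horizon)`.
#' @param eor_probs probabilities of biopsy / partial / complete resection.
#' @param seed master seed of the cohort.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 200,
                             voxel_spacing_mm = c(2, 2, 2),
                             grid_shape = c(48, 48, 48),
                             radius_mm_range = c(8, 15),
                             lobulation = 0.3,
                             blob_size_mm_range = c(4, 12),
                             intensity_contrast = list(
                               T1c = c(background = 100, tumor = 20,
                                       texture_sd = 15),
                               FLAIR = c(background = 80, tumor = 40,
                                         texture_sd = 15)),
                             noise_sd = 2,
                             beta = c(max_diameter_3d = 0.5,
                                      blob_size = 0.5,
                                      log_preop_volume = 0.3,
                                      astrocytoma = 0.7,
                                      eor_partial = -0.3,
                                      eor_complete = -0.7),
                             weibull_shape = 1.2,
                             weibull_scale = 12,
                             event_fraction_target = 0.25,
                             dropout_rate = 0.1,
                             eor_probs = c(biopsy = 0.09, partial = 0.70,
                                           complete = 0.21),
                             seed = 1L) {
  stopifnot(length(radius_mm_range) == 2, radius_mm_range[1] <= radius_mm_range[2],
            length(blob_size_mm_range) == 2,
            blob_size_mm_range[1] <= blob_size_mm_range[2],
            weibull_shape > 0, weibull_scale > 0, noise_sd >= 0,
            lobulation >= 0)
  cfg <- list(n_patients = as.integer(n_patients),
              voxel_spacing_mm = as.numeric(voxel_spacing_mm),
              grid_shape = as.integer(grid_shape),
              radius_mm_range = radius_mm_range,
              lobulation = lobulation,
              blob_size_mm_range = blob_size_mm_range,
              intensity_contrast = intensity_contrast,
              noise_sd = noise_sd, beta = beta,
              weibull_shape = weibull_shape, weibull_scale = weibull_scale,
              event_fraction_target = event_fraction_target,
              dropout_rate = dropout_rate, eor_probs = eor_probs,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  # grid must hold the largest (perturbed) tumor plus a 20 mm margin so the
  # 10-20 mm zone is never clipped by the volume border
  half_extent <- (cfg$grid_shape - 1) / 2 * cfg$voxel_spacing_mm
  r_eff <- max(radius_mm_range) * (1 + 1.5 * lobulation)
  if (any(r_eff + 20 > half_extent))
    stop("grid too small for the largest tumor plus a 20 mm margin",
         call. = FALSE)
  cfg
}

#' Strong-signal study configuration
#'
#' The cohort used for end-to-end synergy checks: larger imaging effect
#' sizes and a higher event fraction, so test-set concordance estimates are
#' informative at a 200-patient scale.
#'
#' @param n_patients cohort size.
#' @param seed master seed.
#' @return a `synthetic_config`.
#' @export
strong_signal_config <- function(n_patients = 200, seed = 1L) {
  synthetic_config(
    n_patients = n_patients,
    beta = c(max_diameter_3d = 1.0, blob_size = 0.8,
             log_preop_volume = 0.3, astrocytoma = 0.7,
             eor_partial = -0.3, eor_complete = -0.7),
    event_fraction_target = 0.5,
    seed = seed)
}

# real spherical-harmonic basis (l = 2 and 3) evaluated at unit vectors;
# u: n x 3 matrix
sh_basis <- function(u) {
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  cbind(x * y, y * z, x * z, x^2 - y^2, 3 * z^2 - 1,
        y * (3 * x^2 - y^2), x * y * z, y * (5 * z^2 - 1),
        z * (5 * z^2 - 3), x * (5 * z^2 - 1), z * (x^2 - y^2),
        x * (x^2 - 3 * y^2))
}

# deterministic quasi-uniform sphere sample used to normalize the
# perturbation to unit SD and to evaluate analytic shape statistics
fibonacci_sphere <- function(n = 500) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# radius of the perturbed ellipsoid along directions U (rows, unit vectors)
# for the spherical-harmonic coefficients `coef`; `s` is the unit-SD
# normalization constant of the field
perturbed_radius <- function(U, radius_mm, lobulation, coef, s) {
  r_ell <- 1 / sqrt((U[, 1] / radius_mm[1])^2 + (U[, 2] / radius_mm[2])^2 +
                    (U[, 3] / radius_mm[3])^2)
  if (lobulation == 0) return(r_ell)
  f <- (sh_basis(U) %*% coef) / s
  r_ell * pmax(0.25, 1 + lobulation * as.vector(f))
}

# analytic maximum Feret diameter, volume (ml) and bounding box of the
# perturbed shape a given (radius, lobulation, seed) will render -- the same
# SH coefficients and normalization as generate_tumor_mask, so the hazard
# drivers describe the tumor the images actually show
perturbed_shape_stats <- function(radius_mm, lobulation, seed) {
  if (lobulation == 0) {
    return(list(max_diameter = 2 * max(radius_mm),
                volume_ml = 4 / 3 * pi * prod(radius_mm) / 1000,
                bbox_lo = -radius_mm, bbox_hi = radius_mm))
  }
  U <- rbind(fibonacci_sphere(500), diag(3))
  Ufull <- rbind(U, -U)
  coef <- with_seed(seed, rnorm(12))
  s <- sd(sh_basis(fibonacci_sphere(500)) %*% coef)
  r <- perturbed_radius(Ufull, radius_mm, lobulation, coef, s)
  # exact direction-pair Feret search over surface samples r(u) u; a
  # direction can only enter the best pair if r(u) + max(r) reaches the
  # best antipodal diameter, which prunes the quadratic search hard
  n <- nrow(U)
  d0 <- max(r[seq_len(n)] + r[n + seq_len(n)])
  keep <- which(r >= d0 - max(r))
  rk <- r[keep]
  Uk <- Ufull[keep, , drop = FALSE]
  gram <- Uk %*% t(Uk)
  d2 <- outer(rk^2, rk^2, `+`) - 2 * outer(rk, rk) * gram
  pts <- Ufull * r
  list(max_diameter = sqrt(max(d2, d0^2)),
       volume_ml = mean(r^3) * 4 * pi / 3 / 1000,
       bbox_lo = apply(pts, 2, min), bbox_hi = apply(pts, 2, max))
}

# the per-patient seed of the intratumoral texture, shared between the
# table sampler and the image renderer
texture_seed <- function(cfg, i) derive_seed(cfg$seed, 5000 + i)

# realized Voronoi texture of one patient: seeded cell centers (mm,
# relative to the tumor center) over the analytic bounding box. The hazard
# driver is the realized mean cell size, so the survival signal lives in
# the texture the images actually show.
sample_texture <- function(bbox_lo, bbox_hi, blob_size_mm, seed) {
  with_seed(seed, {
    lo <- bbox_lo - blob_size_mm / 2
    hi <- bbox_hi + blob_size_mm / 2
    lambda <- prod(hi - lo) / blob_size_mm^3
    n_cells <- max(1L, rpois(1, lambda))
    centers <- cbind(runif(n_cells, lo[1], hi[1]),
                     runif(n_cells, lo[2], hi[2]),
                     runif(n_cells, lo[3], hi[3]))
    list(centers = centers, n_cells = n_cells,
         realized_cell_size = (prod(hi - lo) / n_cells)^(1 / 3))
  })
}

# voxel-center coordinates (mm) relative to the grid center, per axis
grid_axes_mm <- function(grid_shape, spacing_mm) {
  lapply(1:3, function(a)
    (seq_len(grid_shape[a]) - (grid_shape[a] + 1) / 2) * spacing_mm[a])
}

#' Generate a lobulated ellipsoidal tumor mask
#'
#' A star-shaped perturbed ellipsoid: the ellipsoid radius along each voxel
#' direction is modulated by `1 + lobulation * f(u)` where `f` is a random
#' low-order (l = 2, 3) spherical-harmonic field normalized to unit SD over
#' the sphere. The perturbation factor is clamped at 0.25 so the region
#' stays star-shaped (hence connected); if voxelization still fragments it,
#' the largest 26-connected component is kept.
#'
#' @param cfg a [synthetic_config()].
#' @param radius_mm length-3 semi-axes (mm).
#' @param lobulation perturbation amplitude.
#' @param seed integer seed.
#' @return logical 3D array.
#' @export
generate_tumor_mask <- function(cfg, radius_mm, lobulation = cfg$lobulation,
                                seed = cfg$seed) {
  if (any(radius_mm <= 0)) stop("radii must be positive", call. = FALSE)
  half_extent <- (cfg$grid_shape - 1) / 2 * cfg$voxel_spacing_mm
  if (any(max(radius_mm) * (1 + 1.5 * lobulation) + 20 > half_extent))
    stop("tumor plus 20 mm margin exceeds the grid", call. = FALSE)
  ax <- grid_axes_mm(cfg$grid_shape, cfg$voxel_spacing_mm)
  co <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  rho <- sqrt((co[, 1] / radius_mm[1])^2 + (co[, 2] / radius_mm[2])^2 +
              (co[, 3] / radius_mm[3])^2)
  if (lobulation > 0) {
    coef <- with_seed(seed, rnorm(12))
    ref <- sh_basis(fibonacci_sphere(500)) %*% coef
    s <- sd(ref)
    nrm <- sqrt(rowSums(co^2)); nrm[nrm == 0] <- 1
    f <- (sh_basis(co / nrm) %*% coef) / s
    fac <- pmax(0.25, 1 + lobulation * f)
  } else {
    fac <- 1
  }
  m <- array(rho <= fac, cfg$grid_shape)
  lab <- cpp_label_components(as.logical(m), dim(m))
  ncomp <- attr(lab, "n_components")
  if (ncomp > 1L) {
    main <- which.max(tabulate(lab, nbins = ncomp))
    m <- array(lab == main, cfg$grid_shape)
  }
  m
}

#' Brain mask of the synthetic head
#'
#' A large ellipsoid nearly filling the grid (one voxel clear of every
#' border), guaranteeing the 10-20 mm peritumoral band of a centered tumor
#' never touches the volume border.
#'
#' @param cfg a [synthetic_config()].
#' @return logical 3D array.
#' @export
generate_brain_mask <- function(cfg) {
  half_extent <- (cfg$grid_shape - 1) / 2 * cfg$voxel_spacing_mm
  r <- half_extent - cfg$voxel_spacing_mm
  ax <- grid_axes_mm(cfg$grid_shape, cfg$voxel_spacing_mm)
  co <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  rho <- sqrt((co[, 1] / r[1])^2 + (co[, 2] / r[2])^2 + (co[, 3] / r[3])^2)
  array(rho <= 1, cfg$grid_shape)
}

#' Synthesize a co-registered T1c/FLAIR-like image pair
#'
#' Intratumoral texture is piecewise constant over nearest-seed (Voronoi)
#' cells of Poisson-sampled centers with characteristic size
#' `blob_size_mm` (larger blobs = longer gray-level runs), plus additive
#' Gaussian noise; the background has a distinct mean per sequence inside
#' the brain and is 0 outside. `blob_size_mm = Inf` produces a single cell
#' (heterogeneity disabled).
#'
#' @param mask tumor mask (logical 3D array).
#' @param brain brain mask containing it.
#' @param blob_size_mm texture correlation length (mm).
#' @param cfg a [synthetic_config()].
#' @param seed integer seed.
#' @param texture optional precomputed cell layout (as produced internally
#'   by the cohort sampler: `centers` in mm relative to the tumor center).
#'   When given, the rendered texture is exactly the layout the survival
#'   simulator saw; when `NULL`, a layout is drawn from `seed`.
#' @return named list of image arrays, one per sequence.
#' @export
synthesize_mri_pair <- function(mask, brain, blob_size_mm, cfg,
                                seed = cfg$seed, texture = NULL) {
  check_mask(mask); check_mask(brain)
  if (any(mask & !brain)) stop("tumor mask not contained in brain",
                               call. = FALSE)
  if (!is.infinite(blob_size_mm) && blob_size_mm <= 0)
    stop("blob_size_mm must be positive", call. = FALSE)
  tum_co <- mask_coords_mm(mask, cfg$voxel_spacing_mm)
  with_seed(seed, {
    if (is.null(texture) &&
        (is.infinite(blob_size_mm) || nrow(tum_co) == 1L)) {
      cell <- rep(1L, nrow(tum_co))
      n_cells <- 1L
    } else {
      if (is.null(texture)) {
        lo <- apply(tum_co, 2, min) - blob_size_mm / 2
        hi <- apply(tum_co, 2, max) + blob_size_mm / 2
        lambda <- prod(hi - lo) / blob_size_mm^3
        n_cells <- max(1L, rpois(1, lambda))
        centers <- cbind(runif(n_cells, lo[1], hi[1]),
                         runif(n_cells, lo[2], hi[2]),
                         runif(n_cells, lo[3], hi[3]))
      } else {
        n_cells <- texture$n_cells
        # texture centers are relative to the tumor (= grid) center
        offset <- (dim(mask) + 1) / 2 * cfg$voxel_spacing_mm
        centers <- sweep(texture$centers, 2, offset, `+`)
      }
      cell <- cpp_nearest_center(tum_co, centers)
    }
    out <- list()
    for (sq in names(cfg$intensity_contrast)) {
      ic <- cfg$intensity_contrast[[sq]]
      img <- array(0, dim(mask))
      img[brain] <- ic[["background"]]
      cell_vals <- rnorm(n_cells, ic[["background"]] + ic[["tumor"]],
                         ic[["texture_sd"]])
      img[mask] <- cell_vals[cell]
      if (cfg$noise_sd > 0)
        img[brain] <- img[brain] + rnorm(sum(brain), 0, cfg$noise_sd)
      out[[sq]] <- img
    }
    out
  })
}

#' Simulate right-censored survival outcomes from known effect sizes
#'
#' Event times follow a Weibull proportional-hazards model: the baseline
#' Weibull(`shape`, `scale`) hazard is multiplied by `exp(beta . x)`, where
#' continuous drivers are standardized cohort-wise (per-SD effects) and 0/1
#' indicators enter as is. Censoring combines an administrative horizon --
#' calibrated by bisection so the realized event fraction matches
#' `event_fraction_target` -- with an independent uniform dropout.
#'
#' @param features data.frame containing every driver named in `cfg$beta`.
#' @param cfg a [synthetic_config()].
#' @param seed integer seed.
#' @return data.frame (`time_years`, `event`) with attributes
#'   `linear_predictor` and `horizon`.
#' @export
simulate_outcomes <- function(features, cfg, seed = cfg$seed) {
  if (cfg$weibull_shape <= 0 || cfg$weibull_scale <= 0)
    stop("Weibull parameters must be positive", call. = FALSE)
  drivers <- names(cfg$beta)
  missing <- setdiff(drivers, names(features))
  if (length(missing))
    stop("missing beta driver(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  n <- nrow(features)
  eta <- rep(0, n)
  for (d in drivers) {
    x <- features[[d]]
    if (!all(x %in% c(0, 1))) {
      s <- sd(x)
      x <- if (s > 0) (x - mean(x)) / s else rep(0, n)
    }
    eta <- eta + cfg$beta[[d]] * x
  }
  with_seed(seed, {
    u <- runif(n)
    t_event <- cfg$weibull_scale * (-log(u) / exp(eta))^(1 / cfg$weibull_shape)
    if (is.na(cfg$event_fraction_target)) {
      res <- data.frame(time_years = t_event, event = rep(1L, n))
      attr(res, "linear_predictor") <- eta
      attr(res, "horizon") <- Inf
      return(res)
    }
    has_dropout <- runif(n) < cfg$dropout_rate
    w <- runif(n)  # dropout time as a fraction of the horizon
    realized <- function(h) {
      cens <- pmin(h, ifelse(has_dropout, w * h, Inf))
      mean(t_event <= cens)
    }
    lo <- 1e-6; hi <- max(t_event) * 2
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (realized(mid) < cfg$event_fraction_target) lo <- mid else hi <- mid
    }
    h <- (lo + hi) / 2
    cens <- pmin(h, ifelse(has_dropout, w * h, Inf))
    event <- as.integer(t_event <= cens)
    res <- data.frame(time_years = pmin(t_event, cens), event = event)
    attr(res, "linear_predictor") <- eta
    attr(res, "horizon") <- h
    res
  })
}

# the per-patient seed of the tumor-shape field, shared between the table
# sampler (analytic drivers) and the mask renderer
mask_seed <- function(cfg, i) derive_seed(cfg$seed, 1000 + i)

# per-patient geometry and clinical covariates (no imaging); the hazard
# drivers are analytic statistics of the exact perturbed shape each
# patient's mask seed will render
sample_cohort_tables <- function(cfg) {
  n <- cfg$n_patients
  base <- with_seed(derive_seed(cfg$seed, 101), {
    radii <- matrix(runif(3 * n, cfg$radius_mm_range[1],
                          cfg$radius_mm_range[2]), ncol = 3)
    blob <- runif(n, cfg$blob_size_mm_range[1], cfg$blob_size_mm_range[2])
    subtype <- rbinom(n, 1, 0.5)  # 1 = astrocytoma
    eor <- sample(names(cfg$eor_probs), n, replace = TRUE,
                  prob = cfg$eor_probs)
    resid_frac <- runif(n, 0.05, 0.40)
    list(radii = radii, blob = blob, subtype = subtype, eor = eor,
         resid_frac = resid_frac)
  })
  geo <- lapply(seq_len(n), function(i)
    perturbed_shape_stats(base$radii[i, ], cfg$lobulation,
                          mask_seed(cfg, i)))
  textures <- lapply(seq_len(n), function(i)
    sample_texture(geo[[i]]$bbox_lo, geo[[i]]$bbox_hi, base$blob[i],
                   texture_seed(cfg, i)))
  preop <- vapply(geo, `[[`, numeric(1), "volume_ml")
  postop <- ifelse(base$eor == "complete", 0,
                   ifelse(base$eor == "biopsy", preop,
                          preop * base$resid_frac))
  drivers <- data.frame(
    max_diameter_3d = vapply(geo, `[[`, numeric(1), "max_diameter"),
    blob_size = vapply(textures, `[[`, numeric(1), "realized_cell_size"),
    log_preop_volume = log(preop),
    astrocytoma = base$subtype,
    eor_partial = as.integer(base$eor == "partial"),
    eor_complete = as.integer(base$eor == "complete"))
  clinical <- data.frame(
    id = sprintf("P%03d", seq_len(n)),
    preop_volume_ml = preop,
    postop_volume_ml = postop,
    extent_of_resection = base$eor,
    subtype = ifelse(base$subtype == 1, "astrocytoma", "oligodendroglioma"),
    stringsAsFactors = FALSE)
  list(radii = base$radii, blob = base$blob, textures = textures,
       drivers = drivers, clinical = clinical)
}

#' Generate a complete synthetic cohort
#'
#' Samples per-patient tumor geometry, derives clinical covariates from it
#' (preoperative volume from the segmentation, extent of resection with
#' fixed category probabilities and a consistent postoperative volume,
#' subtype acting only through its hazard effect), simulates outcomes, and
#' optionally renders the image pairs and masks. With `dir` given,
#' everything is written to disk (NIfTI volumes whose affine encodes the
#' voxel spacing; CSV clinical and outcome tables).
#'
#' @param cfg a [synthetic_config()].
#' @param dir optional output directory.
#' @param render_images if FALSE, only tables and true drivers are
#'   produced (fast; used for large purely tabular simulations).
#' @return list: `cfg`, `clinical`, `outcomes`, `drivers`,
#'   `linear_predictor`, and (if rendered) `patients` (each with `id`,
#'   `images`, `tumor`, `brain`, `spacing_mm`).
#' @export
generate_cohort <- function(cfg, dir = NULL, render_images = TRUE) {
  tabs <- sample_cohort_tables(cfg)
  outcomes <- simulate_outcomes(tabs$drivers, cfg,
                                seed = derive_seed(cfg$seed, 202))
  clinical <- tabs$clinical
  patients <- NULL
  if (render_images) {
    brain <- generate_brain_mask(cfg)
    patients <- vector("list", cfg$n_patients)
    for (i in seq_len(cfg$n_patients)) {
      mask <- generate_tumor_mask(cfg, tabs$radii[i, ],
                                  seed = mask_seed(cfg, i))
      imgs <- synthesize_mri_pair(mask, brain, tabs$blob[i], cfg,
                                  seed = texture_seed(cfg, i),
                                  texture = tabs$textures[[i]])
      patients[[i]] <- list(id = clinical$id[i], images = imgs,
                            tumor = mask, brain = brain,
                            spacing_mm = cfg$voxel_spacing_mm)
    }
    # clinical preoperative volume measured from the rendered segmentation
    clinical$preop_volume_ml <- vapply(patients, function(p)
      sum(p$tumor) * prod(cfg$voxel_spacing_mm) / 1000, numeric(1))
    clinical$postop_volume_ml <- ifelse(
      clinical$extent_of_resection == "complete", 0,
      ifelse(clinical$extent_of_resection == "biopsy",
             clinical$preop_volume_ml,
             pmin(clinical$postop_volume_ml, clinical$preop_volume_ml)))
  }
  out <- list(cfg = cfg, clinical = clinical,
              outcomes = cbind(data.frame(id = clinical$id,
                                          stringsAsFactors = FALSE),
                               outcomes),
              drivers = tabs$drivers,
              linear_predictor = attr(outcomes, "linear_predictor"),
              patients = patients)
  if (!is.null(dir)) write_cohort(out, dir)
  out
}

#' Write a generated cohort to disk
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0)
    stop("cannot write to output directory: ", dir, call. = FALSE)
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
            row.names = FALSE)
  write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"),
            row.names = FALSE)
  if (!is.null(cohort$patients)) {
    sp <- cohort$cfg$voxel_spacing_mm
    for (p in cohort$patients) {
      wr <- function(vol, name) {
        img <- RNifti::asNifti(vol * 1, pixdim = sp)
        RNifti::writeNifti(img,
                           file.path(dir, sprintf("%s_%s.nii.gz", name, p$id)))
      }
      wr(p$images$T1c, "t1c"); wr(p$images$FLAIR, "flair")
      wr(p$tumor, "tumor")
    }
    RNifti::writeNifti(RNifti::asNifti(cohort$patients[[1]]$brain * 1,
                                       pixdim = sp),
                       file.path(dir, "brain.nii.gz"))
  }
  invisible(dir)
}

#' Monte-Carlo oracle concordance of the generating model
#'
#' Simulates a large independent cohort from the same configuration and
#' computes the concordance of the true linear predictor against the
#' simulated outcomes -- the ceiling any fitted model can approach.
#'
#' @param cfg a [synthetic_config()].
#' @param n Monte-Carlo cohort size.
#' @param tau optional truncation horizon (years) for Uno's variant.
#' @param seed integer seed (independent of the study cohort).
#' @return list: `uno`, `uno_tau`, `harrell` oracle estimates.
#' @export
oracle_concordance <- function(cfg, n = 4000, tau = 5, seed = 999) {
  cfg2 <- cfg
  cfg2$n_patients <- as.integer(n)
  cfg2$seed <- derive_seed(seed, 7)
  tabs <- sample_cohort_tables(cfg2)
  outc <- simulate_outcomes(tabs$drivers, cfg2,
                            seed = derive_seed(seed, 8))
  eta <- attr(outc, "linear_predictor")
  km <- km_estimator(outc$time_years, outc$event)
  list(uno = uno_c(outc$time_years, outc$event, eta, km = km)$estimate,
       uno_tau = uno_c(outc$time_years, outc$event, eta, tau = tau,
                       km = km)$estimate,
       harrell = harrell_c(outc$time_years, outc$event, eta)$estimate)
}
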