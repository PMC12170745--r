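#' Signed Euclidean distance map of a tumor segmentation
#'
#' For voxels outside the mask the value is the center-to-center Euclidean
#' distance (mm) to the nearest mask voxel; for voxels inside the mask it is
#' minus the distance to the nearest background voxel. Anisotropic voxel
#' spacing is honoured exactly (separable exact squared-distance transform).
#'
#' @param mask 3D logical array (tumor segmentation).
#' @param spacing_mm numeric length-3 voxel spacing in mm.
#' @return numeric 3D array of signed distances in mm.
#' @export
distance_map <- function(mask, spacing_mm) {
  check_mask(mask)
  n_in <- sum(mask)
  if (n_in == 0L) stop("empty mask: distance map undefined", call. = FALSE)
  if (n_in == length(mask))
    stop("full mask: distance map undefined", call. = FALSE)
  dims <- dim(mask)
  d_out <- sqrt(cpp_edt_sq(as.logical(mask), dims, as.numeric(spacing_mm)))
  d_in <- sqrt(cpp_edt_sq(!mask, dims, as.numeric(spacing_mm)))
  d <- ifelse(mask, -d_in, d_out)
  array(d, dims)
}

#' Zone band specifications
#'
#' The four tumor-related volumetric zones: the tumor itself, the band
#' straddling the boundary (-5 to +5 mm), and two purely peritumoral bands
#' (0-10 mm and 10-20 mm outside the segmentation).
#'
#' @return a named list of zone specs (`name`, `inner_mm`, `outer_mm`).
#' @export
zone_specs <- function() {
  list(
    tumor     = list(name = "tumor",     inner_mm = NA_real_, outer_mm = NA_real_),
    band_pm5  = list(name = "band_pm5",  inner_mm = -5,       outer_mm = 5),
    ptz_0_10  = list(name = "ptz_0_10",  inner_mm = 0,        outer_mm = 10),
    ptz_10_20 = list(name = "ptz_10_20", inner_mm = 10,       outer_mm = 20)
  )
}

#' Extract one volumetric zone from a tumor segmentation
#'
#' Distance banding of the signed distance map `d`: the tumor zone is the
#' segmentation itself; `band_pm5` is `{-5 <= d <= +5}` (inclusive on both
#' sides); the outside bands are half-open `(inner, outer]`, so `ptz_0_10`
#' and `ptz_10_20` partition `{0 < d <= 20}`. Everything outside the tumor
#' is clipped to the brain mask. An empty result is returned flagged, not
#' raised as an error (tumors abutting the brain boundary can have empty
#' outer bands).
#'
#' @param tumor 3D logical tumor mask.
#' @param brain 3D logical brain mask (tumor must be contained in it).
#' @param spec one element of [zone_specs()].
#' @param spacing_mm voxel spacing (mm).
#' @param dmap optional precomputed [distance_map()] (saves recomputation
#'   when extracting several zones of the same tumor).
#' @return logical 3D array with attribute `empty` (TRUE if no voxels).
#' @export
extract_zone <- function(tumor, brain, spec, spacing_mm, dmap = NULL) {
  check_mask(tumor, "tumor"); check_mask(brain, "brain")
  check_same_geometry(tumor, brain, "tumor/brain masks")
  if (any(tumor & !brain)) stop("tumor mask extends outside brain mask",
                                call. = FALSE)
  if (identical(spec$name, "tumor")) {
    z <- tumor
  } else {
    if (!is.finite(spec$inner_mm) || !is.finite(spec$outer_mm) ||
        spec$inner_mm >= spec$outer_mm)
      stop("zone spec requires inner_mm < outer_mm", call. = FALSE)
    if (is.null(dmap)) dmap <- distance_map(tumor, spacing_mm)
    if (identical(spec$name, "band_pm5")) {
      z <- dmap >= spec$inner_mm & dmap <= spec$outer_mm
    } else {
      z <- dmap > spec$inner_mm & dmap <= spec$outer_mm
    }
    z <- z & brain
  }
  z <- array(z, dim(tumor))
  attr(z, "empty") <- !any(z)
  z
}

#' Extract all four zones at once
#'
#' @inheritParams extract_zone
#' @return named list of zone masks (see [extract_zone()]).
#' @export
extract_all_zones <- function(tumor, brain, spacing_mm) {
  dmap <- distance_map(tumor, spacing_mm)
  lapply(zone_specs(), function(sp)
    extract_zone(tumor, brain, sp, spacing_mm, dmap = dmap))
}
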