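#' Derive a child seed from a master seed
#'
#' Every random stage of the pipeline receives its own seed derived
#' deterministically from one master seed, so that a whole study run is a
#' pure function of that single integer.
#'
#' @param master integer master seed.
#' @param offset integer stage offset (distinct per stage).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, offset) {
  m <- as.numeric(master) %% 2147483647
  s <- (m * 48271 + as.numeric(offset) * 1013904223 + 17) %% 2147483562
  as.integer(s + 1)
}

# run `expr` under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# validate a 3D logical mask array
check_mask <- function(mask, name = "mask") {
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask))
    stop(sprintf("`%s` must be a 3D logical array", name), call. = FALSE)
  invisible(mask)
}

check_same_geometry <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("geometry mismatch between %s: %s vs %s", what,
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

# physical voxel-center coordinates (mm) of the TRUE voxels of a mask,
# as an n x 3 matrix
mask_coords_mm <- function(mask, spacing_mm) {
  idx <- which(mask, arr.ind = TRUE)
  sweep(idx, 2, spacing_mm, `*`)
}

#' Write a results record as canonical JSON
#'
#' Deterministic serialization (fixed precision-free number formatting,
#' stable key order as supplied) so that identical runs give byte-identical
#' files.
#'
#' @param x a list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(x, path) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                          na = "null", pretty = TRUE)
  writeLines(txt, path)
  invisible(path)
}
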