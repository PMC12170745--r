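#' Feature inventory and naming convention
#'
#' Column names follow `<zone>_<sequence|shape>_<class>_<feature>`:
#' 9 shape features per zone (sequence-independent) and 16 first-order plus
#' 16 run-length features per zone and sequence, over 4 zones and 2
#' sequences: 4 x (9 + 2 x 32) = 292 columns.
#'
#' @param zones character vector of zone names.
#' @param sequences character vector of sequence labels.
#' @return character vector of feature column names.
#' @export
feature_inventory <- function(zones = names(zone_specs()),
                              sequences = c("T1c", "FLAIR")) {
  unlist(lapply(zones, function(z) {
    c(paste(z, "shape", shape_feature_names(), sep = "_"),
      unlist(lapply(sequences, function(s) {
        c(paste(z, s, "firstorder", first_order_feature_names(), sep = "_"),
          paste(z, s, "glrlm", glrlm_feature_names(), sep = "_"))
      })))
  }), use.names = FALSE)
}

# features of one patient: named list(images = list(T1c=, FLAIR=),
# tumor =, brain =, spacing_mm =)
patient_features <- function(patient, spec = discretization_spec()) {
  zones <- extract_all_zones(patient$tumor, patient$brain,
                             patient$spacing_mm)
  seqs <- names(patient$images)
  out <- numeric(0)
  for (zn in names(zones)) {
    z <- zones[[zn]]
    if (isTRUE(attr(z, "empty"))) {
      nm <- feature_inventory(zones = zn, sequences = seqs)
      out <- c(out, setNames(rep(NA_real_, length(nm)), nm))
      next
    }
    sh <- shape_features(z, patient$spacing_mm)
    out <- c(out, setNames(sh, paste(zn, "shape", names(sh), sep = "_")))
    for (sq in seqs) {
      img <- patient$images[[sq]]
      check_same_geometry(img, z, "image/zone")
      fo <- first_order_features(img, z, spec)
      out <- c(out, setNames(fo, paste(zn, sq, "firstorder", names(fo),
                                       sep = "_")))
      lab <- discretize(img, z, spec)
      gl <- glrlm_features(lab, spec$n_bins)
      out <- c(out, setNames(gl, paste(zn, sq, "glrlm", names(gl),
                                       sep = "_")))
    }
  }
  out
}

#' Extract the cohort feature table
#'
#' One row per patient, columns per [feature_inventory()]; zones that are
#' empty for a patient yield explicit `NA` in all of that zone's columns.
#' Images are used unfiltered.
#'
#' @param patients list of patient records, each a list with elements
#'   `id`, `images` (named list of 3D arrays, e.g. `T1c`, `FLAIR`),
#'   `tumor`, `brain` (3D logical masks) and `spacing_mm`.
#' @param spec a [discretization_spec()].
#' @return data.frame with an `id` column plus one column per feature.
#' @export
extract_feature_table <- function(patients, spec = discretization_spec()) {
  rows <- lapply(patients, function(p) patient_features(p, spec))
  nm <- names(rows[[1]])
  for (r in rows) if (!identical(names(r), nm))
    stop("patients do not share a zone/sequence inventory", call. = FALSE)
  tab <- as.data.frame(do.call(rbind, rows))
  ids <- vapply(patients, function(p) as.character(p$id), character(1))
  cbind(data.frame(id = ids, stringsAsFactors = FALSE), tab)
}
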