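test_that("fixed-bin-count discretization follows the boundary rules", {
  img <- array(0:31, c(32, 1, 1))
  msk <- array(TRUE, c(32, 1, 1))
  lab <- discretize(img, msk, discretization_spec(32))
  expect_equal(as.vector(lab), 1:32)               # order-preserving bijection
  expect_equal(max(lab), 32L)                      # top bin inclusive
  const <- discretize(array(5, c(3, 1, 1)), array(TRUE, c(3, 1, 1)),
                      discretization_spec(32))
  expect_true(all(const == 1L))                    # degenerate range
})

test_that("run-length matrices match manual enumeration on tiny ROIs", {
  lab <- array(c(1L, 1L, 2L), c(3, 1, 1))
  P <- radsurv:::cpp_glrlm(lab, c(3L, 1L, 1L), 2L)[[1]]  # along the line
  expect_equal(P[1, 2], 1L)
  expect_equal(P[2, 1], 1L)
  f <- radsurv:::glrlm_from_matrix(P, n_voxels = 3)
  expect_equal(unname(f["rp"]), 2 / 3)
  expect_equal(unname(f["sre"]), (1 / 4 + 1) / 2)  # = 0.625
  lab2 <- array(1L, c(3, 1, 1))
  P2 <- radsurv:::cpp_glrlm(lab2, c(3L, 1L, 1L), 1L)[[1]]
  f2 <- radsurv:::glrlm_from_matrix(P2, n_voxels = 3)
  expect_equal(unname(f2["lre"]), 9)
  expect_equal(unname(f2["sre"]), 1 / 9)
  expect_equal(unname(f2["rp"]), 1 / 3)
})

test_that("GLRLM features match the brute-force run-enumeration oracle", {
  for (s in 1:8) {
    set.seed(500 + s)
    lab <- array(sample(0:4, 8^3, replace = TRUE), c(8, 8, 8))
    if (!any(lab > 0)) next
    mine <- glrlm_features(lab, 4)
    orac <- oracle_glrlm_features(lab)
    expect_equal(mine[names(orac)], orac, tolerance = 1e-12)
  }
})

test_that("GLRLM features match the frozen independent reference", {
  ref <- read.csv(test_path("fixtures", "glrlm_reference.csv"))
  f <- glrlm_features(reference_roi(), 4)
  expect_equal(unname(f[ref$feature]), ref$value, tolerance = 1e-10)
})

test_that("run-length conservation: total traversed voxels per direction", {
  set.seed(99)
  lab <- array(sample(0:3, 7^3, replace = TRUE), c(7, 7, 7))
  mats <- radsurv:::cpp_glrlm(lab, dim(lab), 3L)
  nvox <- sum(lab > 0)
  for (P in mats)
    expect_equal(sum(sweep(P, 2, seq_len(ncol(P)), `*`)), nvox)
})

test_that("first-order features follow their definitions", {
  img <- array(c(1, 2, 3, 4), c(4, 1, 1)); msk <- array(TRUE, c(4, 1, 1))
  f <- first_order_features(img, msk)
  expect_equal(unname(f["mean"]), 2.5)
  expect_equal(unname(f["range"]), 3)
  two <- array(c(0, 0, 10, 10), c(4, 1, 1))
  f2 <- first_order_features(two, msk, discretization_spec(2))
  expect_equal(unname(f2["entropy"]), 1)      # 1 bit
  expect_equal(unname(f2["uniformity"]), 0.5)
  cst <- first_order_features(array(7, c(4, 1, 1)), msk)
  expect_equal(unname(cst[c("variance", "entropy", "skewness", "kurtosis")]),
               c(0, 0, 0, 0))
})

test_that("shape features: analytic cases and brute-force diameters", {
  mm <- array(FALSE, c(5, 6, 2)); mm[1, 1, 1] <- TRUE; mm[4, 5, 1] <- TRUE
  expect_equal(unname(shape_features(mm, c(1, 1, 1))["max_diameter_3d"]), 5)
  m10 <- array(FALSE, c(5, 5, 5)); m10[which(array(TRUE, c(5,5,5)))[1:10]] <- TRUE
  expect_equal(unname(shape_features(m10, c(2, 2, 2))["volume_ml"]), 0.08)
  bf2d <- function(idx, ax, sl, sp) {
    best <- 0
    for (s in unique(idx[, sl])) {
      pts <- idx[idx[, sl] == s, , drop = FALSE]
      if (nrow(pts) > 1)
        best <- max(best, max(dist(cbind(pts[, ax[1]] * sp[ax[1]],
                                         pts[, ax[2]] * sp[ax[2]]))))
    }
    best
  }
  for (s in 1:8) {
    m <- random_mask(c(12, 12, 12), seed = 600 + s)
    sp <- c(1.5, 1, 2)
    sf <- shape_features(m, sp)
    idx <- which(m, arr.ind = TRUE)
    expect_equal(unname(sf["max_diameter_3d"]),
                 max(dist(sweep(idx, 2, sp, `*`))))
    expect_equal(unname(sf["max_diameter_axial"]), bf2d(idx, c(1, 2), 3, sp))
    expect_equal(unname(sf["max_diameter_coronal"]), bf2d(idx, c(1, 3), 2, sp))
    expect_equal(unname(sf["max_diameter_sagittal"]), bf2d(idx, c(2, 3), 1, sp))
  }
})

test_that("90-degree axial rotation leaves direction-averaged features put", {
  set.seed(77)
  img <- array(rnorm(12^3), c(12, 12, 12))
  m <- random_mask(c(12, 12, 12), seed = 78)
  sp <- c(1, 1, 2.5)
  rot <- function(a) { b <- aperm(a, c(2, 1, 3)); b[dim(b)[1]:1, , ] }
  spec <- discretization_spec(8)
  f1 <- glrlm_features(discretize(img, m, spec), 8)
  f2 <- glrlm_features(discretize(rot(img), rot(m), spec), 8)
  expect_equal(f1, f2, tolerance = 1e-9)
  s1 <- shape_features(m, sp); s2 <- shape_features(rot(m), sp)
  # the rotation maps the coronal plane onto the sagittal one; every other
  # feature is invariant
  swapped <- s2
  swapped["max_diameter_coronal"] <- s2[["max_diameter_sagittal"]]
  swapped["max_diameter_sagittal"] <- s2[["max_diameter_coronal"]]
  expect_equal(s1, swapped, tolerance = 1e-9)
})

test_that("intensity shift moves the mean and nothing texture-related", {
  set.seed(12)
  img <- array(rnorm(10^3), c(10, 10, 10))
  m <- random_mask(c(10, 10, 10), seed = 13)
  spec <- discretization_spec(16)
  f1 <- first_order_features(img, m, spec)
  f2 <- first_order_features(img + 11.5, m, spec)
  expect_equal(unname(f2["mean"] - f1["mean"]), 11.5)
  expect_equal(f1[c("variance", "entropy", "uniformity")],
               f2[c("variance", "entropy", "uniformity")])
  g1 <- glrlm_features(discretize(img, m, spec), 16)
  g2 <- glrlm_features(discretize(img + 11.5, m, spec), 16)
  expect_equal(g1, g2)
})

test_that("feature table has the declared inventory and missing contract", {
  expect_length(feature_inventory(), 292)
  sc <- get_small_cohort()
  ft <- sc$features
  expect_equal(ncol(ft), 293)  # id + 292 features
  sh_t1 <- grep("^tumor_shape_", names(ft), value = TRUE)
  expect_length(sh_t1, 9)
  # shape identical across sequences by construction (one shape set per zone)
  expect_length(grep("tumor_T1c_shape", names(ft)), 0)
  # a tumor tight against the brain boundary yields explicit NA zone rows
  cfg <- small_test_config()
  tumor <- generate_tumor_mask(cfg, c(6, 6, 6), seed = 5)
  d <- distance_map(tumor, cfg$voxel_spacing_mm)
  brain <- array(d <= 6, dim(tumor))  # no tissue beyond 6 mm
  p <- list(id = "x", images = list(T1c = array(rnorm(length(tumor)),
                                                dim(tumor)),
                                    FLAIR = array(rnorm(length(tumor)),
                                                  dim(tumor))),
            tumor = tumor, brain = brain, spacing_mm = cfg$voxel_spacing_mm)
  row <- radsurv:::patient_features(p)
  ptz_cols <- grep("^ptz_10_20_", names(row))
  expect_true(all(is.na(row[ptz_cols])))
  expect_false(anyNA(row[grep("^tumor_", names(row))]))
})
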