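test_that("spherical masks have the analytic volume and diameter", {
  cfg <- synthetic_config(grid_shape = c(64, 64, 64),
                          voxel_spacing_mm = c(1, 1, 1),
                          radius_mm_range = c(8, 10), lobulation = 0)
  m <- generate_tumor_mask(cfg, c(10, 10, 10), lobulation = 0, seed = 1)
  expect_lt(abs(sum(m) - 4 / 3 * pi * 10^3) / (4 / 3 * pi * 10^3), 0.05)
  d <- shape_features(m, c(1, 1, 1))["max_diameter_3d"]
  expect_lt(abs(d - 20), sqrt(3))   # within one voxel diagonal
  m2 <- generate_tumor_mask(cfg, c(10, 10, 10), lobulation = 0, seed = 1)
  expect_identical(m, m2)
})

test_that("masks are single connected components inside the brain", {
  cfg <- small_test_config()
  brain <- generate_brain_mask(cfg)
  for (s in 1:5) {
    m <- generate_tumor_mask(cfg, c(8, 6, 7), seed = s)
    lab <- radsurv:::cpp_label_components(as.logical(m), dim(m))
    expect_equal(attr(lab, "n_components"), 1L)
    expect_false(any(m & !brain))
    # 10-20 mm band must clear the volume border
    dm <- distance_map(m, cfg$voxel_spacing_mm)
    shell <- array(dm > 10 & dm <= 20, dim(m))
    border <- array(TRUE, dim(m))
    border[2:(dim(m)[1] - 1), 2:(dim(m)[2] - 1), 2:(dim(m)[3] - 1)] <- FALSE
    expect_false(any(shell & border))
  }
  expect_error(generate_tumor_mask(cfg, c(30, 30, 30), seed = 1),
               "exceeds the grid")
})

test_that("texture blob size drives the long-run feature monotonically", {
  cfg <- small_test_config(noise_sd = 0)
  m <- generate_tumor_mask(cfg, c(8, 8, 8), lobulation = 0, seed = 2)
  brain <- generate_brain_mask(cfg)
  blob_sizes <- c(2, 4, 6, 9, 14)
  lre <- sapply(blob_sizes, function(bs) {
    mean(sapply(1:10, function(s) {
      img <- synthesize_mri_pair(m, brain, bs, cfg, seed = 100 * s)$T1c
      lab <- discretize(img, m, discretization_spec(8))
      glrlm_features(lab, 8)[["lre"]]
    }))
  })
  expect_true(all(diff(lre) > 0))
})

test_that("single-blob noiseless tumors are internally constant", {
  cfg <- small_test_config(noise_sd = 0)
  m <- generate_tumor_mask(cfg, c(7, 7, 7), seed = 3)
  brain <- generate_brain_mask(cfg)
  imgs <- synthesize_mri_pair(m, brain, Inf, cfg, seed = 5)
  expect_equal(var(imgs$T1c[m]), 0)
  expect_equal(var(imgs$FLAIR[m]), 0)
  # distinct background means per sequence
  bg <- brain & !m
  expect_equal(unique(imgs$T1c[bg]), 100)
  expect_equal(unique(imgs$FLAIR[bg]), 80)
  imgs2 <- synthesize_mri_pair(m, brain, Inf, cfg, seed = 5)
  expect_identical(imgs, imgs2)
  expect_error(synthesize_mri_pair(m, brain, -1, cfg, seed = 1), "positive")
  expect_error(synthesize_mri_pair(brain, m, 5, cfg, seed = 1),
               "contained")
})

test_that("null effect sizes give chance-level concordance", {
  cfg <- synthetic_config(n_patients = 2000,
                          beta = c(max_diameter_3d = 0, blob_size = 0,
                                   log_preop_volume = 0, astrocytoma = 0,
                                   eor_partial = 0, eor_complete = 0),
                          seed = 5)
  tabs <- radsurv:::sample_cohort_tables(cfg)
  out <- simulate_outcomes(tabs$drivers, cfg, seed = 6)
  for (d in c("max_diameter_3d", "blob_size")) {
    h <- harrell_c(out$time_years, out$event, tabs$drivers[[d]])$estimate
    expect_lt(abs(h - 0.5), 0.03)
  }
})

test_that("censoring can be disabled and the exponential mean is exact", {
  cfg <- synthetic_config(n_patients = 5000, weibull_shape = 1,
                          weibull_scale = 10,
                          beta = c(max_diameter_3d = 0),
                          event_fraction_target = NA, seed = 8)
  drivers <- data.frame(max_diameter_3d = rep(0, 5000))
  out <- simulate_outcomes(drivers, cfg, seed = 9)
  expect_true(all(out$event == 1))
  expect_lt(abs(mean(out$time_years) - 10) / 10, 0.05)
  bad <- cfg; bad$weibull_shape <- -1
  expect_error(simulate_outcomes(drivers, bad, seed = 1), "positive")
  expect_error(simulate_outcomes(drivers[, 0, drop = FALSE], cfg, seed = 1),
               "missing beta driver")
})

test_that("the censoring horizon calibration hits the event target", {
  cfg <- synthetic_config(n_patients = 1000, event_fraction_target = 0.25,
                          seed = 10)
  tabs <- radsurv:::sample_cohort_tables(cfg)
  out <- simulate_outcomes(tabs$drivers, cfg, seed = 11)
  expect_lt(abs(mean(out$event) - 0.25), 0.05)
})

test_that("cohorts are complete, consistent and byte-identical per seed", {
  cfg <- small_test_config(n = 10, seed = 42)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  co1 <- generate_cohort(cfg, dir = d1)
  co2 <- generate_cohort(cfg, dir = d2)
  expect_length(co1$patients, 10)
  expect_equal(nrow(co1$clinical), 10)
  expect_equal(nrow(co1$outcomes), 10)
  expect_equal(length(list.files(d1, pattern = "^t1c_.*nii.gz$")), 10)
  expect_identical(readLines(file.path(d1, "clinical.csv")),
                   readLines(file.path(d2, "clinical.csv")))
  expect_identical(readLines(file.path(d1, "outcomes.csv")),
                   readLines(file.path(d2, "outcomes.csv")))
  # clinical invariants
  cl <- co1$clinical
  expect_true(all(cl$postop_volume_ml <= cl$preop_volume_ml + 1e-12))
  expect_true(all(cl$postop_volume_ml[cl$extent_of_resection == "complete"]
                  == 0))
  expect_true(all(cl$preop_volume_ml[cl$extent_of_resection == "biopsy"] ==
                  cl$postop_volume_ml[cl$extent_of_resection == "biopsy"]))
  # round trip through disk
  back <- load_cohort(d1)
  expect_equal(back$clinical$preop_volume_ml, cl$preop_volume_ml)
  expect_identical(back$patients[[3]]$tumor, co1$patients[[3]]$tumor)
  expect_error(load_cohort(file.path(d1, "nope")), "missing cohort input")
})

test_that("rendered texture matches the layout the hazard driver saw", {
  cfg <- small_test_config(n = 3, seed = 19, noise_sd = 0)
  co <- generate_cohort(cfg)
  # realized cell size is a deterministic function of the shared layout
  tabs <- radsurv:::sample_cohort_tables(cfg)
  expect_identical(co$drivers$blob_size,
                   vapply(tabs$textures, `[[`, numeric(1),
                          "realized_cell_size"))
  # a patient with a single texture cell renders a constant tumor interior
  one <- which(vapply(tabs$textures, `[[`, integer(1), "n_cells") == 1L)
  if (length(one)) {
    p <- co$patients[[one[1]]]
    expect_equal(var(p$images$T1c[p$tumor]), 0)
  }
})
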