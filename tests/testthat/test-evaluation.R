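test_that("Kaplan-Meier estimator matches hand product-limit computation", {
  km <- km_estimator(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$S_at(2.5), 0.5)
  km2 <- km_estimator(c(1, 2, 3), c(0, 0, 0))
  expect_equal(km2$S_at(c(0.5, 2, 10)), c(1, 1, 1))   # all censored
  # 6-subject worked set: events at 1, 3, 4, 6; censorings at 2, 5
  tm <- c(1, 2, 3, 4, 5, 6); ev <- c(1, 0, 1, 1, 0, 1)
  km3 <- km_estimator(tm, ev)
  expect_equal(km3$S_at(1), 5 / 6)
  expect_equal(km3$S_at(3.5), 5 / 6 * 3 / 4)
  expect_equal(km3$S_at(4), 5 / 6 * 3 / 4 * 2 / 3)
  expect_equal(km3$S_at(6), 0)
  for (t in c(0.5, 1, 2.5, 4, 5.5, 6))
    expect_equal(km3$S_at(t), oracle_km(tm, ev, t))
  # censoring distribution: events and censorings swapped
  for (t in c(0.5, 2, 4.5, 5))
    expect_equal(km3$G_at(t), oracle_km(tm, 1 - ev, t))
  expect_error(km_estimator(c(-1, 2), c(1, 1)), "negative")
})

test_that("Harrell's c handles the monotone and tied extremes", {
  tm <- c(5, 3, 8, 1, 9, 2); ev <- rep(1L, 6)
  expect_equal(harrell_c(tm, ev, -tm)$estimate, 1)   # anti-monotone risks
  expect_equal(harrell_c(tm, ev, tm)$estimate, 0)
  expect_equal(harrell_c(tm, ev, rep(1, 6))$estimate, 0.5)
})

test_that("with zero censoring Uno's c equals Harrell's c exactly", {
  for (s in 1:10) {
    set.seed(700 + s)
    n <- 100
    tm <- rexp(n); ev <- rep(1L, n); r <- rnorm(n)
    expect_identical(uno_c(tm, ev, r)$estimate, harrell_c(tm, ev, r)$estimate)
  }
})

test_that("Uno's c equals the brute-force IPCW double loop", {
  tm <- c(0.5, 1.1, 1.1, 2.0, 2.3, 3.1, 3.5, 4.2, 5.0, 6.1)
  ev <- c(1,   1,   0,   1,   0,   1,   1,   1,   1,   1)
  set.seed(71); r <- rnorm(10)
  expect_equal(uno_c(tm, ev, r)$estimate, oracle_uno(tm, ev, r),
               tolerance = 1e-12)
  expect_equal(uno_c(tm, ev, r, tau = 3)$estimate,
               oracle_uno(tm, ev, r, tau = 3), tolerance = 1e-12)
})

test_that("Uno's c agrees with the survival package's IPCW concordance", {
  set.seed(72)
  n <- 150
  tm <- rexp(n); ev <- rbinom(n, 1, 0.6); r <- rnorm(n) + tm
  mine <- uno_c(tm, ev, r)$estimate
  ref <- survival::concordance(survival::Surv(tm, ev) ~ r, reverse = TRUE,
                               timewt = "n/G2")$concordance
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("truncation below the first event is an error; weights stay finite", {
  tm <- c(2, 3, 4, 5); ev <- c(1, 1, 1, 1)
  expect_error(uno_c(tm, ev, 1:4, tau = 1), "no usable pairs")
  # left-limit evaluation keeps G positive at event times even under
  # heavy censoring (the event subject was still at risk at earlier
  # censoring times), so the IPCW weights remain finite
  tm2 <- c(1, 2, 2, 3); ev2 <- c(1, 0, 0, 1)
  km <- km_estimator(tm2, ev2)
  expect_true(all(km$G_at(tm2[ev2 == 1], left = TRUE) > 0))
  expect_s3_class(uno_c(tm2, ev2, c(4, 3, 2, 1)), "radsurv_cindex")
})

test_that("concordance is rank-based and sign-symmetric", {
  set.seed(73)
  n <- 200
  tm <- rexp(n); ev <- rbinom(n, 1, 0.7)
  r <- rnorm(n)
  expect_equal(uno_c(tm, ev, r)$estimate, uno_c(tm, ev, exp(r))$estimate)
  expect_equal(harrell_c(tm, ev, r)$estimate,
               1 - harrell_c(tm, ev, -r)$estimate)
  # random risks at large n sit near 1/2
  set.seed(74)
  n2 <- 2000
  tm2 <- rexp(n2); ev2 <- rbinom(n2, 1, 0.7); r2 <- rnorm(n2)
  expect_lt(abs(uno_c(tm2, ev2, r2)$estimate - 0.5), 0.03)
  expect_lt(abs(harrell_c(tm2, ev2, r2)$estimate - 0.5), 0.03)
})

test_that("bootstrap distributions are paired, seeded and complete", {
  set.seed(75)
  n <- 80
  tm <- rexp(n); ev <- rbinom(n, 1, 0.5)
  risks <- list(good = tm * -1 + rnorm(n, 0, 0.3), same = rnorm(n))
  risks$twin <- risks$good
  b1 <- bootstrap_distribution(tm, ev, risks, B = 200, seed = 9)
  b2 <- bootstrap_distribution(tm, ev, risks, B = 200, seed = 9)
  expect_identical(b1$good$values, b2$good$values)
  expect_length(b1$good$values, nrow(b1$good$indices))
  expect_identical(b1$good$values, b1$twin$values)  # identical risk vectors
  expect_equal(b1$good$median, median(b1$good$values))
  point <- uno_c(tm, ev, risks$good)$estimate
  expect_lt(abs(b1$good$median - point), 0.05)
})

test_that("paired signed-rank comparison follows its conventions", {
  set.seed(76)
  n <- 60
  tm <- rexp(n); ev <- rbinom(n, 1, 0.6)
  r <- rnorm(n)
  b <- bootstrap_distribution(tm, ev, list(m1 = r, m2 = r, m3 = r + 0),
                              B = 300, seed = 4)
  expect_equal(compare_distributions(b$m1, b$m2)$p_value, 1)  # all-zero diffs
  # a constant shift makes every signed difference agree
  bshift <- b$m1; bshift$values <- bshift$values + 0.05
  cmp <- compare_distributions(bshift, b$m2)
  expect_lt(cmp$p_value, 0.001)
  other <- bootstrap_distribution(tm, ev, list(m1 = r), B = 300, seed = 5)
  expect_error(compare_distributions(b$m1, other$m1), "not paired")
})
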