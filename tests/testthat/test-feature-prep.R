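test_that("z-score normalization is exact within the transformed set", {
  set.seed(21)
  tab <- data.frame(a = rnorm(40, 5, 2), b = runif(40), c = rep(3, 40))
  z <- zscore_normalize(tab)
  expect_lt(abs(mean(z$a)), 1e-12)
  expect_lt(abs(sd(z$a) - 1), 1e-12)
  expect_equal(attr(z, "constant_columns"), "c")
  expect_true(all(z$c == 0))
  expect_error(zscore_normalize(tab[1, ]), "2 rows")
  # test set transformed with its own statistics has its own zero means
  te <- data.frame(a = rnorm(20, 50, 9), b = runif(20, 5, 6), c = rep(3, 20))
  zte <- zscore_normalize(te)
  expect_lt(abs(mean(zte$a)), 1e-12)
  # reusing training statistics instead is the exposed switch
  zte2 <- zscore_normalize(te, center = attr(z, "center"),
                           scale = attr(z, "scale"))
  expect_gt(abs(mean(zte2$a)), 1)
})

test_that("variance filter removes strictly sub-threshold features", {
  # `edge` has sample variance exactly 0.015625 (binary-exact values)
  tab <- data.frame(konst = rep(1, 3),
                    edge = c(0, 0.125, 0.25),
                    wide = c(0, 1, 2))
  expect_identical(var(tab$edge), 0.015625)
  res <- variance_filter(tab, 0.01)
  expect_equal(res$removed, "konst")           # variance 0 < 0.01
  expect_true(all(c("edge", "wide") %in% res$keep))
  # a feature sitting exactly on the threshold is kept (strict <)
  res2 <- variance_filter(tab, 0.015625)
  expect_true("edge" %in% res2$keep)
  expect_true("konst" %in% res2$removed)
})

test_that("Spearman pruning removes the higher-mean-correlation member", {
  # rank-fixture: rho computed by hand from sum of squared rank differences
  f1 <- 1:10
  f2 <- c(1:8, 10, 9)               # rho(f1,f2) = 1 - 6*2/990  = 0.98788
  f3 <- c(3, 1, 2, 5, 4, 7, 6, 9, 8, 10)
  rho13 <- 1 - 6 * sum((rank(f3) - rank(f1))^2) / (10 * 99)  # 0.92727
  rho23 <- 1 - 6 * sum((rank(f3) - rank(f2))^2) / (10 * 99)  # 0.90303
  expect_equal(rho13, 1 - 72 / 990)
  expect_equal(rho23, 1 - 96 / 990)
  # mean |rho|: f1 = (0.98788 + 0.92727)/2 > f2 = (0.98788 + 0.90303)/2
  res <- spearman_prune(data.frame(f1 = f1, f2 = f2, f3 = f3), 0.95)
  expect_equal(res$removed$feature, "f1")
  expect_equal(sort(res$keep), c("f2", "f3"))
  expect_equal(res$removed$rho, 1 - 12 / 990)
})

test_that("pruning handles duplicates, no-op cases, and column order", {
  set.seed(31)
  x <- rnorm(50)
  tab <- data.frame(a = x, b = x, c = rnorm(50), d = rnorm(50))
  res <- spearman_prune(tab, 0.95)
  expect_length(intersect(c("a", "b"), res$keep), 1)
  lowcor <- data.frame(u = rnorm(50), v = rnorm(50), w = rnorm(50))
  expect_equal(spearman_prune(lowcor, 0.95)$keep, names(lowcor))
  # permutation invariance of the surviving set
  perm <- tab[, c("d", "b", "a", "c")]
  expect_setequal(spearman_prune(perm, 0.95)$keep, res$keep)
})

test_that("LASSO-Cox selection shrinks fully, is seeded, reports empties", {
  set.seed(41)
  n <- 120
  X <- as.data.frame(matrix(rnorm(n * 6), n))
  tm <- rexp(n); ev <- rbinom(n, 1, 0.7)
  big <- lasso_cox_select(X, tm, ev, lambda_grid = c(100, 50), seed = 1)
  expect_true(big$empty)
  expect_length(big$selected, 0)
  s1 <- lasso_cox_select(X, tm, ev, seed = 5)
  s2 <- lasso_cox_select(X, tm, ev, seed = 5)
  expect_identical(s1$selected, s2$selected)
  expect_error(lasso_cox_select(X, tm, rep(0, n)), "no events")
})

test_that("the cascade keeps its fixed order and disjoint removal sets", {
  set.seed(51)
  n <- 80
  raw <- data.frame(flat = rep(1, n) + rnorm(n, 0, 0.01),
                    sig = rnorm(n),
                    dup = NA, noise = rnorm(n))
  raw$dup <- raw$sig + rnorm(n, 0, 1e-4)
  eta <- raw$sig
  tm <- rexp(n, exp(eta)); ev <- rep(1L, n)
  norm <- zscore_normalize(raw)
  rep_ <- select_features(raw, norm, tm, ev, seed = 3)
  expect_true("flat" %in% rep_$removed_by_variance)
  expect_false("flat" %in% rep_$removed_by_correlation$feature)
  expect_length(intersect(rep_$removed_by_variance,
                          rep_$removed_by_correlation$feature), 0)
  expect_true(all(names(rep_$lasso_selected) %in%
                  setdiff(names(raw), c(rep_$removed_by_variance,
                                        rep_$removed_by_correlation$feature))))
})
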