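# Independent brute-force oracles used to validate the fast implementations.
# Each is written with a different mechanism than the code under test.

# all-pairs signed Euclidean distance (mm) -- O(n^2), small grids only
oracle_signed_distance <- function(mask, spacing_mm) {
  dims <- dim(mask)
  idx_all <- which(array(TRUE, dims), arr.ind = TRUE)
  co_all <- sweep(idx_all, 2, spacing_mm, `*`)
  co_in <- co_all[as.vector(mask), , drop = FALSE]
  co_out <- co_all[!as.vector(mask), , drop = FALSE]
  d2 <- function(a, b) {
    outer(rowSums(a^2), rep(1, nrow(b))) +
      outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  }
  d <- numeric(prod(dims))
  d[!as.vector(mask)] <- sqrt(pmax(0, apply(d2(co_out, co_in), 1, min)))
  d[as.vector(mask)] <- -sqrt(pmax(0, apply(d2(co_in, co_out), 1, min)))
  array(d, dims)
}

# run-length matrices by rle() over explicitly extracted grid lines
oracle_glrlm_mats <- function(labels) {
  dims <- dim(labels)
  dirs <- rbind(c(1,0,0), c(0,1,0), c(0,0,1),
                c(1,1,0), c(1,-1,0), c(1,0,1), c(1,0,-1),
                c(0,1,1), c(0,1,-1),
                c(1,1,1), c(1,1,-1), c(1,-1,1), c(1,-1,-1))
  n_lev <- max(labels)
  lapply(seq_len(nrow(dirs)), function(di) {
    d <- dirs[di, ]
    P <- matrix(0, n_lev, sum(dims))
    inb <- function(v) all(v >= 1 & v <= dims)
    for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
      v <- c(x, y, z)
      if (inb(v - d)) next  # not a line start
      seqv <- integer(0)
      w <- v
      while (inb(w)) { seqv <- c(seqv, labels[w[1], w[2], w[3]]); w <- w + d }
      r <- rle(seqv)
      for (k in seq_along(r$values))
        if (r$values[k] > 0)
          P[r$values[k], r$lengths[k]] <- P[r$values[k], r$lengths[k]] + 1
    }
    P
  })
}

# run-length features by explicit (g, l) summation loops
oracle_glrlm_features <- function(labels) {
  mats <- oracle_glrlm_mats(labels)
  nvox <- sum(labels > 0)
  per <- sapply(mats, function(P) {
    Nr <- sum(P)
    acc <- setNames(numeric(16),
                    c("sre","lre","gln","glnn","rln","rlnn","rp","glv",
                      "rlv","re","lglre","hglre","srlgle","srhgle",
                      "lrlgle","lrhgle"))
    mug <- 0; mul <- 0
    for (g in seq_len(nrow(P))) for (l in seq_len(ncol(P))) {
      mug <- mug + P[g, l] / Nr * g; mul <- mul + P[g, l] / Nr * l
    }
    for (g in seq_len(nrow(P))) for (l in seq_len(ncol(P))) {
      pgl <- P[g, l]
      if (pgl == 0) next
      acc["sre"] <- acc["sre"] + pgl / l^2
      acc["lre"] <- acc["lre"] + pgl * l^2
      acc["glv"] <- acc["glv"] + pgl / Nr * (g - mug)^2
      acc["rlv"] <- acc["rlv"] + pgl / Nr * (l - mul)^2
      acc["re"]  <- acc["re"] - pgl / Nr * log2(pgl / Nr)
      acc["lglre"] <- acc["lglre"] + pgl / g^2
      acc["hglre"] <- acc["hglre"] + pgl * g^2
      acc["srlgle"] <- acc["srlgle"] + pgl / (g^2 * l^2)
      acc["srhgle"] <- acc["srhgle"] + pgl * g^2 / l^2
      acc["lrlgle"] <- acc["lrlgle"] + pgl * l^2 / g^2
      acc["lrhgle"] <- acc["lrhgle"] + pgl * g^2 * l^2
    }
    for (g in seq_len(nrow(P))) acc["gln"] <- acc["gln"] + sum(P[g, ])^2
    for (l in seq_len(ncol(P))) acc["rln"] <- acc["rln"] + sum(P[, l])^2
    acc[c("sre","lre","gln","rln","lglre","hglre","srlgle","srhgle",
          "lrlgle","lrhgle")] <-
      acc[c("sre","lre","gln","rln","lglre","hglre","srlgle","srhgle",
            "lrlgle","lrhgle")] / Nr
    acc["glnn"] <- acc["gln"] / Nr
    acc["rlnn"] <- acc["rln"] / Nr
    acc["rp"] <- Nr / nvox
    acc
  })
  rowMeans(per)
}

# hand product-limit estimator: S(t) = prod_{t_k <= t} (1 - d_k / n_k)
oracle_km <- function(time, status, t, left = FALSE) {
  ut <- sort(unique(time[status == 1]))
  s <- 1
  for (tk in ut) {
    if (if (left) tk >= t else tk > t) break
    nk <- sum(time >= tk)
    dk <- sum(time == tk & status == 1)
    s <- s * (1 - dk / nk)
  }
  s
}

# explicit double-loop IPCW concordance
oracle_uno <- function(time, event, risk, tau = Inf) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] != 1 || time[i] >= tau) next
    g <- oracle_km(time, 1 - event, time[i], left = TRUE)
    w <- 1 / g^2
    for (j in seq_len(n)) {
      if (j == i) next
      usable <- time[j] > time[i] || (time[j] == time[i] && event[j] == 0)
      if (!usable) next
      conc <- if (risk[i] > risk[j]) 1 else if (risk[i] == risk[j]) 0.5 else 0
      num <- num + w * conc
      den <- den + w
    }
  }
  num / den
}

# random blob-like test mask: an ellipsoid plus salt noise, non-empty
random_mask <- function(dims, seed) {
  set.seed(seed)
  ctr <- dims / 2 + runif(3, -1, 1)
  r <- runif(3, dims[1] / 6, dims[1] / 3)
  idx <- which(array(TRUE, dims), arr.ind = TRUE)
  rho <- sqrt(((idx[, 1] - ctr[1]) / r[1])^2 + ((idx[, 2] - ctr[2]) / r[2])^2 +
              ((idx[, 3] - ctr[3]) / r[3])^2)
  m <- rho <= 1
  m[sample(length(m), round(0.02 * length(m)))] <- TRUE
  if (!any(m)) m[1] <- TRUE
  if (all(m)) m[1] <- FALSE
  array(m, dims)
}

# deterministic fixture ROI shared with the frozen external reference
reference_roi <- function() {
  lab <- array(0L, c(4, 4, 3))
  for (i in 0:3) for (j in 0:3) for (k in 0:2)
    lab[i + 1, j + 1, k + 1] <-
      if ((i + j + k) %% 7 == 0) 0L else (i * 7 + j * 3 + k * 5) %% 4 + 1L
  lab
}

# small rendered cohort configuration used across tests (small grid keeps
# feature extraction fast)
small_test_config <- function(n = 24, seed = 7, ...) {
  synthetic_config(n_patients = n, grid_shape = c(36, 36, 36),
                   radius_mm_range = c(6, 9), seed = seed, ...)
}

# one small rendered cohort shared across test files (built once per run)
.cohort_cache <- new.env(parent = emptyenv())
get_small_cohort <- function() {
  if (is.null(.cohort_cache$co)) {
    cfg <- small_test_config(
      n = 30, seed = 7,
      beta = c(max_diameter_3d = 1.0, blob_size = 0.8,
               log_preop_volume = 0.3, astrocytoma = 0.7,
               eor_partial = -0.3, eor_complete = -0.7),
      event_fraction_target = 0.5)
    .cohort_cache$co <- generate_cohort(cfg)
    .cohort_cache$ft <- extract_feature_table(.cohort_cache$co$patients)
  }
  list(cohort = .cohort_cache$co, features = .cohort_cache$ft)
}
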