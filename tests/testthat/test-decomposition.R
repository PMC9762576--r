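test_that("binning counts spikes into 2-ms bins with afferent-major layout", {
  sp <- tibble::tibble(
    trial = c(1L, 1L, 1L, 2L),
    class = "SA1",
    afferent = c(1L, 1L, 1L, 2L),
    time = c(0.0001, 0.0015, 0.0021, 0.1)
  )
  ds <- manual_dataset(sp, n_trials = 2, n_afferents = 2, duration_s = 0.5)
  R <- bin_raster(ds, bin_width_s = 0.002)
  n_t <- attr(R, "n_bins")
  expect_equal(n_t, 250)
  expect_equal(attr(R, "n_afferents"), 2)
  expect_equal(dim(unclass(R)), c(2, 500))
  expect_equal(R[1, 1], 2) # two spikes of afferent 1 in bin 1
  expect_equal(R[1, 2], 1)
  # afferent 2's block starts at column n_t + 1; 0.1 s -> bin 51
  expect_equal(R[2, n_t + 51], 1)
  expect_equal(sum(R), nrow(sp)) # conservation
  # empty dataset -> all zeros of the right shape
  ds0 <- manual_dataset(sp[0, ], n_trials = 3, n_afferents = 2)
  R0 <- bin_raster(ds0)
  expect_equal(dim(unclass(R0)), c(3, 500))
  expect_true(all(R0 == 0))
  # spikes outside the window are rejected
  ds_bad <- manual_dataset(dplyr::mutate(sp, time = time + 0.5), 2, 2)
  expect_error(bin_raster(ds_bad), "outside")
})

test_that("stratified splits are balanced, exhaustive and deterministic", {
  labels <- rep(1:10, each = 20)
  g <- stratified_split(labels, c(0.25, 0.75), seed = 3)
  expect_equal(sort(unique(g)), c(1, 2))
  for (lv in 1:10) {
    expect_equal(sum(g == 1 & labels == lv), 5)
    expect_equal(sum(g == 2 & labels == lv), 15)
  }
  expect_identical(g, stratified_split(labels, c(0.25, 0.75), seed = 3))
  expect_false(identical(g, stratified_split(labels, c(0.25, 0.75), seed = 4)))
  f <- stratified_folds(labels, k = 5, seed = 1)
  expect_equal(as.vector(table(f)), rep(40L, 5))
  for (lv in 1:10) expect_equal(as.vector(table(f[labels == lv])), rep(4L, 5))
  expect_error(stratified_split(labels, c(0.3, 0.3)), "sum to 1")
})

test_that("NMF recovers exact low-rank structure and explained variance behaves", {
  set.seed(101)
  h <- runif(30, 0.5, 2)
  w <- runif(40, 0, 1)
  R1 <- outer(h, w)
  fit <- fit_nmf(R1, K = 1, seed = 2)
  expect_gte(fit$explained_variance, 0.999)
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))
  expect_equal(dim(fit$H), c(30, 1))
  expect_equal(dim(fit$W), c(1, 40))

  # reconstruction error non-increasing in K (best of 5 restarts)
  R <- matrix(rpois(30 * 40, outer(h, w)), 30, 40)
  ev <- vapply(1:5, function(K) {
    best <- -Inf
    for (r in 1:5) {
      f <- suppressWarnings(fit_nmf(R, K, seed = r * 7 + K))
      best <- max(best, f$explained_variance)
    }
    best
  }, numeric(1))
  expect_true(all(diff(ev) >= -1e-6))

  # zero matrix: documented convention
  f0 <- fit_nmf(matrix(0, 5, 6), K = 2)
  expect_equal(f0$explained_variance, 1)
  expect_true(all(f0$H == 0))
  expect_error(fit_nmf(matrix(-1, 3, 3), 1), "non-negative")
  expect_error(fit_nmf(R1, 0), "K must")
  expect_error(fit_nmf(R1, 31), "K must")
  # determinism in the seed
  fa <- fit_nmf(R, 3, seed = 5)
  fb <- fit_nmf(R, 3, seed = 5)
  expect_identical(fa$W, fb$W)
})

test_that("module-count selection finds the underlying rank", {
  set.seed(202)
  # three well-separated non-negative components plus small noise
  make_rank_r <- function(r, M = 60, P = 90, noise = 0.01) {
    H <- matrix(0, M, r)
    for (k in seq_len(r)) H[seq((k - 1) * M / r + 1, k * M / r), k] <- runif(M / r, 1, 2)
    W <- matrix(0, r, P)
    for (k in seq_len(r)) W[k, seq((k - 1) * P / r + 1, k * P / r)] <- runif(P / r, 1, 2)
    pmax(H %*% W + matrix(rnorm(M * P, 0, noise), M, P), 0)
  }
  sel3 <- select_num_modules(make_rank_r(3), seed = 4)
  expect_equal(sel3$per_density$K_selected, 3)
  expect_equal(sel3$per_density$K_saturation, 3)

  # noiseless rank-1 saturates immediately
  R1 <- outer(runif(20, 1, 2), runif(30, 0, 1))
  sel1 <- select_num_modules(R1, seed = 1)
  expect_equal(sel1$per_density$K_selected, 1)

  # averaging across densities: threshold is the mean of saturation levels
  sel2 <- select_num_modules(list(a = make_rank_r(3), b = make_rank_r(2)), seed = 9)
  expect_equal(
    sel2$class_threshold,
    mean(sel2$per_density$saturation_level)
  )
  expect_equal(nrow(sel2$per_density), 2)
})

test_that("projection onto fixed modules is non-negative, exact and self-consistent", {
  set.seed(303)
  R <- matrix(rpois(20 * 60, 2), 20, 60)
  fit <- suppressWarnings(fit_nmf(R, 3, seed = 1))
  H_proj <- project_activations(R, fit$W)
  expect_true(all(H_proj >= 0))
  # projecting the training data reproduces (or improves on) the fit
  err_fit <- sum((R - fit$H %*% fit$W)^2)
  err_proj <- sum((R - H_proj %*% fit$W)^2)
  expect_lte(err_proj, err_fit + 1e-6)

  # a module equal to a trial's own row reconstructs it exactly
  W1 <- R[3, , drop = FALSE]
  H1 <- project_activations(R[3, , drop = FALSE], W1)
  expect_equal(as.numeric(H1), 1, tolerance = 1e-8)
  expect_error(project_activations(R[, 1:10], fit$W), "column dimension")
})

test_that("75-set projection explains variance close to the 25-set fit on stationary data", {
  set.seed(404)
  # stationary synthetic data: same latent structure in both halves
  H_true <- matrix(rexp(80 * 3), 80, 3)
  W_true <- matrix(runif(3 * 50), 3, 50)
  R <- matrix(rpois(80 * 50, H_true %*% W_true * 10), 80, 50)
  split <- stratified_split(rep(1:4, each = 20), c(0.25, 0.75), seed = 6)
  R25 <- R[split == 1, ]
  R75 <- R[split == 2, ]
  fit <- suppressWarnings(fit_nmf(R25, 3, seed = 8))
  H75 <- project_activations(R75, fit$W)
  ev75 <- 1 - sum((R75 - H75 %*% fit$W)^2) / sum(R75^2)
  expect_gt(ev75, fit$explained_variance - 0.10)
})

test_that("spatial NMF finds co-active groups and expands to K x T coefficients", {
  # two disjoint co-active afferent groups, 4 afferents, 10 bins
  n_t <- 10
  n_aff <- 4
  M <- 40
  set.seed(505)
  sp <- list()
  for (m in 1:M) {
    group <- if (m %% 2 == 0) 1:2 else 3:4
    times <- sort(runif(12, 0, 0.02 * n_t - 1e-4))
    sp[[m]] <- tibble::tibble(
      trial = m, class = "SA1",
      afferent = sample(group, 12, replace = TRUE), time = times
    )
  }
  ds <- manual_dataset(dplyr::bind_rows(sp), M, n_aff, duration_s = 0.02 * n_t)
  R <- bin_raster(ds, bin_width_s = 0.02)
  sn <- spatial_nmf(R, K_space = 2, seed = 3)
  expect_equal(dim(sn$W_space), c(2, n_aff))
  expect_equal(dim(sn$H_t), c(M, 2 * n_t))
  # each spatial module is supported on one group
  support <- sn$W_space > 0.25 * apply(sn$W_space, 1, max)
  groups <- apply(support, 1, function(s) paste(which(s), collapse = ","))
  expect_setequal(groups, c("1,2", "3,4"))

  # single afferent: 1x1 module, coefficients proportional to binned counts
  sp1 <- dplyr::filter(dplyr::bind_rows(sp), afferent == 1)
  ds1 <- manual_dataset(sp1, M, 1, duration_s = 0.02 * n_t)
  R1 <- bin_raster(ds1, bin_width_s = 0.02)
  sn1 <- spatial_nmf(R1, K_space = 1, seed = 1)
  expect_equal(dim(sn1$W_space), c(1, 1))
  scale <- as.numeric(sn1$W_space)
  expect_equal(sn1$H_t * scale, unclass(R1), tolerance = 1e-6,
               ignore_attr = TRUE)
})
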