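test_that("plugin mutual information matches direct evaluation on hand cases", {
  # perfect decoding of 4 equiprobable outcomes
  expect_equal(mutual_information(diag(10, 4)), 2)
  # independence (outer product) carries nothing
  indep <- outer(c(10, 20, 30), c(5, 10, 15))
  expect_lt(abs(mutual_information(indep)), 1e-12)
  # mixed 2x2 case against the independent oracle
  cm <- matrix(c(30, 10, 10, 30), 2)
  expect_equal(mutual_information(cm), oracle_mi(cm), tolerance = 1e-12)
  expect_equal(mutual_information(cm), 0.1887219, tolerance = 1e-6)
  # random matrices agree with the oracle too
  set.seed(7)
  for (i in 1:20) {
    cmr <- matrix(rpois(16, 5), 4)
    expect_equal(mutual_information(cmr), oracle_mi(cmr), tolerance = 1e-12)
  }
  expect_error(mutual_information(matrix(0, 2, 2)), "empty")
  expect_error(mutual_information(matrix(-1, 2, 2)), "non-negative")
})

test_that("stimulus entropy is log2 of the outcome count", {
  expect_equal(stimulus_entropy(4), 2)
  expect_equal(stimulus_entropy(10), log2(10))
  expect_equal(stimulus_entropy(5), log2(5))
  expect_error(stimulus_entropy(1), "S_n")
})

test_that("information is bounded by the stimulus entropy", {
  set.seed(8)
  for (i in 1:50) {
    S <- sample(2:8, 1)
    cm <- matrix(rpois(S * S, 3), S) + diag(sample(0:20, 1), S)
    I <- mutual_information(cm)
    expect_gte(I, -1e-12)
    expect_lte(I, stimulus_entropy(S) + 1e-12)
  }
})

test_that("complementary and redundant information obey their algebra", {
  expect_equal(complementary_information(1.2, 0.9), 0.3)
  expect_equal(complementary_information(1.0, 1.0), 0)
  expect_equal(redundant_information(0.5, 0.8, 1.0), 0.3)
  # fully complementary: I_all = I_ref + I_others
  expect_equal(redundant_information(0.4, 0.6, 1.0), 0)
  # identity I_comp + I_red = I_ref for arbitrary triples
  set.seed(9)
  for (i in 1:100) {
    I_ref <- runif(1, 0, 3)
    I_others <- runif(1, 0, 3)
    I_all <- runif(1, 0, 3)
    expect_equal(
      complementary_information(I_all, I_others) +
        redundant_information(I_ref, I_others, I_all),
      I_ref,
      tolerance = 1e-14
    )
  }
})

test_that("a class with no information adds no complementary information", {
  # the reference class contributes silent (all-zero) activation columns
  set.seed(10)
  n <- 160
  y <- rep(1:4, each = n / 4)
  H_informative <- matrix(rnorm(n * 3, mean = y), n, 3)
  H_silent <- matrix(0, n, 2)
  tr <- stratified_split(y, c(0.5, 0.5), seed = 1) == 1
  m_others <- train_decoder(H_informative[tr, ], y[tr], seed = 2)
  I_others <- mutual_information(
    confusion_matrix(m_others, H_informative[!tr, ], y[!tr])
  )
  H_all <- cbind(H_informative, H_silent)
  m_all <- train_decoder(H_all[tr, ], y[tr], seed = 2)
  I_all <- mutual_information(confusion_matrix(m_all, H_all[!tr, ], y[!tr]))
  expect_lt(abs(complementary_information(I_all, I_others)), 0.1)
})

test_that("saturation density follows its definition", {
  curve <- tibble::tibble(
    density = c(1, 5, 10, 20, 40),
    info_mean = c(0.2, 0.5, 0.79, 0.80, 0.80),
    info_sd = c(0, 0, 0, 0, 0)
  )
  expect_equal(saturation_density(curve, tolerance = 0.02)$saturation_density, 10)
  flat <- tibble::tibble(density = c(1, 5, 10), info_mean = c(0.5, 0.5, 0.5))
  expect_equal(saturation_density(flat, tolerance = 0.01)$saturation_density, 1)
  rising <- tibble::tibble(density = c(1, 5, 10), info_mean = c(0.1, 0.5, 0.9))
  expect_equal(saturation_density(rising, tolerance = 0.01)$saturation_density, 10)
  # default tolerance: max(top-density SD, 2% of entropy)
  curve$info_sd <- c(0, 0, 0, 0, 0.3)
  out <- saturation_density(curve, entropy_bits = 2)
  expect_equal(out$tolerance, 0.3)
  expect_equal(out$saturation_density, 5)
  expect_error(saturation_density(curve[c(2, 1, 3), ]), "increasing")
})

test_that("strategy comparison orders doubling against class addition", {
  info <- tibble::tibble(
    class_set = c("SA1", "SA1", "SA1+RA", "SA1+PC"),
    density_label = c("baseline", "double", "baseline", "baseline"),
    I_bits = c(1.0, 1.1, 1.4, 1.2)
  )
  v <- compare_strategies(info, "SA1")
  expect_equal(v$verdict, "add class")
  expect_equal(nrow(v$gains), 3)
  info$I_bits <- c(1.0, 1.6, 1.4, 1.2)
  expect_equal(compare_strategies(info, "SA1")$verdict, "increase density")
  info$I_bits <- c(1.0, 1.4, 1.4, 1.2)
  expect_equal(compare_strategies(info, "SA1")$verdict, "tie")
  expect_error(compare_strategies(info[1:2, ], "SA1"), "combined")
})
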