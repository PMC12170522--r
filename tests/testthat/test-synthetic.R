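test_that("generate_seed_spectra plants recoverable class structure", {
  # noiseless, scatter off: within-class rows identical
  g0 <- generate_seed_spectra(synthetic_spec(n_per_class = 5, d = 20,
                                             noise_sd = 0, scatter = FALSE,
                                             seed = 51))
  R <- g0$spectra$reflectance
  for (cls in levels(g0$spectra$labels)) {
    rows <- R[g0$spectra$labels == cls, , drop = FALSE]
    expect_equal(max(abs(sweep(rows, 2, rows[1, ]))), 0)
  }

  # scatter on, sigma = 0: MSC against a fixed reference collapses classes
  g1 <- generate_seed_spectra(synthetic_spec(n_per_class = 8, d = 20,
                                             noise_sd = 0, scatter = TRUE,
                                             seed = 52))
  corr <- msc(g1$spectra$reflectance,
              reference = msc_reference(g1$spectra))
  for (cls in levels(g1$spectra$labels)) {
    rows <- corr[g1$spectra$labels == cls, , drop = FALSE]
    expect_lt(max(abs(sweep(rows, 2, rows[1, ]))), 1e-8)
  }

  # class-mean difference at informative bands ~ planted effects
  spec <- synthetic_spec(n_per_class = 150, d = 30, n_informative = 4,
                         effect_size = 0.06, scatter = FALSE,
                         noise_sd = 0.01, seed = 53)
  g2 <- generate_seed_spectra(spec)
  info <- g2$truth$informative_bands
  R2 <- g2$spectra$reflectance
  y <- g2$spectra$labels
  for (cls in 2:3) {
    diff_obs <- colMeans(R2[as.integer(y) == cls, info, drop = FALSE]) -
      colMeans(R2[as.integer(y) == 1, info, drop = FALSE])
    planted <- g2$truth$effects[cls, info]
    tol <- 3 * spec$noise_sd / sqrt(spec$n_per_class) * 2
    expect_true(all(abs(diff_obs - planted) < tol))
  }

  # determinism and truth invariants
  g3 <- generate_seed_spectra(spec)
  expect_identical(g3$spectra$reflectance, g2$spectra$reflectance)
  expect_true(all(info >= 1 & info <= 30))
  expect_warning(generate_seed_spectra(
    synthetic_spec(n_per_class = 3, d = 10, effect_size = 0.01,
                   noise_sd = 0.02, seed = 54)), "recoverable")
})

test_that("generate_fs_benchmark plants informative and redundant columns", {
  b <- generate_fs_benchmark(n = 120, d = 8, n_informative = 2,
                             n_redundant = 2, class_sep = 4, seed = 55)
  expect_equal(b$truth$informative, 1:2)
  expect_equal(b$truth$redundant, 3:4)
  # redundant columns strongly correlate with their sources
  expect_gt(abs(cor(b$X[, 1], b$X[, 3])), 0.9)
  # a single huge-separation column gives 0 KNN error
  b1 <- generate_fs_benchmark(n = 100, d = 5, n_informative = 1,
                              class_sep = 10, seed = 56)
  mask <- c(TRUE, rep(FALSE, 4))
  expect_equal(knn_error(b1$X, b1$y, mask, fitness_config(seed = 56)), 0)
  # label permutation destroys the association
  set.seed(57)
  errp <- knn_error(b1$X, sample(b1$y), mask, fitness_config(seed = 57))
  expect_gt(errp, 0.25)
  # determinism
  b2 <- generate_fs_benchmark(n = 120, d = 8, n_informative = 2,
                              n_redundant = 2, class_sep = 4, seed = 55)
  expect_identical(b$X, b2$X)
  expect_error(generate_fs_benchmark(d = 4, n_informative = 3,
                                     n_redundant = 2), "n_informative")
})

test_that("exhaustive oracle enumerates the full landscape", {
  b <- generate_fs_benchmark(n = 80, d = 4, n_informative = 1,
                             class_sep = 10, seed = 58)
  fcfg <- fitness_config(seed = 58)
  orc <- exhaustive_oracle(b$X, b$y, fcfg)
  expect_equal(nrow(orc$landscape), 2^4 - 1)
  # perfectly predictive single column wins under alpha = 0.99
  expect_equal(which(orc$best_mask), 1L)
  expect_equal(orc$best_fitness, min(orc$landscape$fitness))
  # alpha = 1 minimizes error alone
  rw <- oracle_reweight(orc$landscape, alpha = 1, n_total = 4)
  expect_equal(rw$best_fitness, min(orc$landscape$error))
  expect_error(exhaustive_oracle(matrix(rnorm(20 * 13), 20), rep(1:2, 10),
                                 fcfg), "d_max")
})

test_that("oracle-optimal subset size shrinks as the size penalty grows", {
  b <- generate_fs_benchmark(n = 100, d = 6, n_informative = 2,
                             n_redundant = 1, class_sep = 1.5, seed = 59)
  orc <- exhaustive_oracle(b$X, b$y, fitness_config(seed = 59))
  alphas <- seq(0.99, 0.55, by = -0.04)
  sizes <- vapply(alphas,
                  function(a) oracle_reweight(orc$landscape, a, 6)$best_size,
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})
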