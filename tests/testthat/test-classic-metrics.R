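test_that("perfect within-unit agreement gives alpha exactly 1", {
  withr::with_seed(1, {
    m <- matrix(rep(rnorm(50, 0, 100), 4), nrow = 50)
  })
  expect_identical(krippendorff_alpha(m), 1)
  expect_identical(krippendorff_alpha(matrix_to_long(m)), 1)
})

test_that("alpha matches the brute-force pair-enumeration oracle", {
  # the spec'd 2x2 hand case
  m22 <- rbind(c(1, 2), c(2, 1))
  expect_equal(krippendorff_alpha(m22), alpha_bruteforce(m22),
               tolerance = 1e-12)
  withr::with_seed(17, {
    for (rep in 1:20) {
      nu <- sample(2:6, 1)
      nr <- sample(2:4, 1)
      m <- matrix(rnorm(nu * nr, 0, 10), nrow = nu)
      # random missingness, keeping at least one pairable unit
      m[runif(length(m)) < 0.2] <- NA
      ok <- sum(rowSums(!is.na(m)) >= 2) >= 1
      if (!ok) m[1, ] <- rnorm(nr)
      expect_equal(krippendorff_alpha(m), alpha_bruteforce(m),
                   tolerance = 1e-12)
    }
  })
})

test_that("alpha tolerates missing raters and obeys its invariances", {
  withr::with_seed(2, m <- matrix(rnorm(20, 0, 5), nrow = 5))
  with_empty <- cbind(m, NA)
  expect_equal(krippendorff_alpha(with_empty), krippendorff_alpha(m))
  # shift and rater-permutation invariance
  expect_equal(krippendorff_alpha(m + 1000), krippendorff_alpha(m),
               tolerance = 1e-9)
  expect_equal(krippendorff_alpha(m[, c(3, 1, 4, 2)]),
               krippendorff_alpha(m))
  # degenerate inputs error rather than returning a number
  expect_error(krippendorff_alpha(matrix(c(1, NA, NA, 2), nrow = 2)),
               "pairable")
  expect_error(krippendorff_alpha(matrix(5, nrow = 3, ncol = 2)),
               "undefined")
})

test_that("ICC(1,1) matches the direct ANOVA decomposition", {
  m <- rbind(c(9, 2), c(1, 5), c(8, 6))
  expect_equal(icc_oneway(m), icc_anova_oracle(m), tolerance = 1e-12)
  # unbalanced case against the oracle
  m2 <- rbind(c(10, 12, 11), c(20, 22, NA), c(31, 30, 29), c(39, NA, NA))
  expect_equal(icc_oneway(m2), icc_anova_oracle(m2), tolerance = 1e-12)
  # balanced case cross-checked against stats::aov mean squares
  withr::with_seed(4, m3 <- matrix(rnorm(24, rep(c(0, 10, 20, 5), 6), 2),
                                   nrow = 4))
  long <- matrix_to_long(m3)
  av <- summary(stats::aov(value ~ factor(unit), data = long))[[1]]
  msb <- av["factor(unit)", "Mean Sq"]
  msw <- av["Residuals", "Mean Sq"]
  expect_equal(icc_oneway(m3), (msb - msw) / (msb + (6 - 1) * msw),
               tolerance = 1e-10)
})

test_that("ICC is 1 for identical ratings within units and negative when
           within-unit variance dominates", {
  perfect <- matrix(rep(c(3, 7, 11), 2), nrow = 3)
  expect_equal(icc_oneway(perfect), 1)
  noisy <- rbind(c(-10, 10), c(-10.1, 10.1), c(-9.9, 9.9))
  expect_lt(icc_oneway(noisy), 0)
  expect_equal(icc_oneway(perfect + 500), icc_oneway(perfect))
})

test_that("pct_within_tolerance is an inclusive fraction, monotone in tol", {
  expect_equal(pct_within_tolerance(c(0, 5, -30), 10), 2 / 3)
  expect_equal(pct_within_tolerance(c(10, -10, 10), 10), 1)
  expect_equal(pct_within_tolerance(rnorm(100, 0, 50), 1e9), 1)
  expect_error(pct_within_tolerance(numeric(0), 10), "empty")
  expect_error(pct_within_tolerance(1:3, 0), "tol_ms")
  withr::with_seed(5, {
    dev <- rnorm(200, 0, 20)
    tols <- c(1, 2, 5, 10, 20, 50, 100)
    p <- vapply(tols, function(t) pct_within_tolerance(dev, t), 0)
    expect_true(all(diff(p) >= 0))
  })
})

sweep_study <- local({
  spec <- mixture_spec(c(1, 2, 10), c(0, 1, 0))
  em <- list(ponss = list(fast = spec, medium = spec, slow = spec),
             baseline = list(fast = spec, medium = spec, slow = spec))
  generate_study(generator_config(n_speakers = 2, trials_per_speaker = 6,
                                  error_model = em, quantization_prob = 0,
                                  seed = 31))
})

test_that("the identity tweak reproduces untweaked metrics and the
           zero-lambda tweak collapses disagreement", {
  res <- sensitivity_sweep(sweep_study$annotations,
                           lambda_grid = c(0, 1), noise_sd_grid = 0,
                           tolerances = 10, seed = 2, fit_config = NULL)
  dev <- compute_deviations(sweep_study$annotations)
  row1 <- res[res$lambda == 1, ]
  expect_equal(row1$pct_within_10,
               pct_within_tolerance(dev$deviation_ms, 10))
  row0 <- res[res$lambda == 0, ]
  expect_equal(row0$alpha, 1)
  expect_equal(row0$pct_within_10, 1)
})

test_that("alpha and ICC are insensitive where the mixture sigma scales
           with the injected error", {
  res <- sensitivity_sweep(sweep_study$annotations,
                           lambda_grid = c(0.5, 1, 2, 4), noise_sd_grid = 0,
                           seed = 5,
                           fit_config = test_pso(seed = 19))
  expect_lt(diff(range(res$alpha)), 0.001)
  expect_lt(diff(range(res$icc)), 0.001)
  base <- res$weighted_sigma[res$lambda == 1]
  ratio <- res$weighted_sigma / base
  expect_true(all(abs(ratio - res$lambda) <= 0.25 * res$lambda))
})

test_that("additive noise widens the fitted sigma but not alpha", {
  res <- sensitivity_sweep(sweep_study$annotations, lambda_grid = 1,
                           noise_sd_grid = c(0, 4), tolerances = 10,
                           seed = 9, fit_config = test_pso(seed = 23))
  expect_lt(diff(range(res$alpha)), 0.001)
  expect_gt(res$weighted_sigma[res$noise_sd == 4],
            res$weighted_sigma[res$noise_sd == 0] * 1.5)
  expect_lt(res$pct_within_10[res$noise_sd == 4],
            res$pct_within_10[res$noise_sd == 0])
})
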