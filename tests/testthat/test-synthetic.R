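test_that("generator_config validates its probability structure", {
  expect_error(generator_config(omission_probs = c(0.5, 0.1, 0, 0, 0, 0,
                                                   0, 0)),
               "non-decreasing")
  expect_error(generator_config(omission_probs = rep(0, 5)),
               "per prompted word")
  expect_error(generator_config(rejection_prob = 1.2), "probabilities")
  expect_error(generator_config(annotators = list(ponss = "p1")),
               "keyed by modality")
})

test_that("the same seed reproduces the study exactly", {
  cfg <- generator_config(n_speakers = 1, trials_per_speaker = 3, seed = 9)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_equal(s1$annotations, s2$annotations)
  expect_equal(s1$timing, s2$timing)
  expect_equal(s1$peak_counts, s2$peak_counts)
  s3 <- generate_study(generator_config(n_speakers = 1,
                                        trials_per_speaker = 3, seed = 10))
  expect_false(identical(s1$annotations$time_ms, s3$annotations$time_ms))
})

test_that("generated outputs satisfy the annotation and timing schemas", {
  study <- generate_study(generator_config(n_speakers = 2,
                                           trials_per_speaker = 3,
                                           seed = 4))
  expect_silent(validate_annotations(study$annotations))
  expect_silent(validate_timing(study$timing))
  # offsets never precede onsets for the same token/annotator/modality
  wide <- tidyr::pivot_wider(study$annotations,
                             names_from = "boundary",
                             values_from = "time_ms")
  expect_true(all(wide$offset >= wide$onset))
  # roughly 20% double triage and 5% rejection at the configured defaults
  expect_gt(mean(study$tokens$double_triaged, na.rm = TRUE), 0.05)
  expect_lt(mean(study$tokens$rejected, na.rm = TRUE), 0.2)
})

test_that("generated deviations reproduce the configured error scale", {
  spec <- mixture_spec(c(1.5, 4, 15), c(1, 0, 0))
  em <- list(ponss = list(fast = spec, medium = spec, slow = spec),
             baseline = list(fast = spec, medium = spec, slow = spec))
  study <- generate_study(generator_config(n_speakers = 4,
                                           trials_per_speaker = 12,
                                           error_model = em,
                                           quantization_prob = 0,
                                           seed = 6))
  dev_true <- study$annotations |>
    dplyr::left_join(study$true_boundaries,
                     by = c("token_id", "boundary"),
                     suffix = c("", "_true")) |>
    dplyr::mutate(dev = time_ms - time_ms_true)
  expect_gt(nrow(dev_true), 4000)
  expect_lt(abs(sd(dev_true$dev) - 1.5) / 1.5, 0.03)
})

test_that("keyboard-step quantization leaves modes at multiples of 20 ms", {
  spec <- mixture_spec(c(1, 4, 15), c(0.3, 0.4, 0.3))
  em <- list(ponss = list(fast = spec, medium = spec, slow = spec),
             baseline = list(fast = spec, medium = spec, slow = spec))
  base_cfg <- function(qp) {
    generator_config(n_speakers = 2, trials_per_speaker = 9,
                     error_model = em, quantization_prob = qp,
                     retrim_fraction = 1, seed = 13)
  }
  snapped_count <- function(study) {
    dev <- study$annotations |>
      dplyr::filter(modality == "ponss") |>
      dplyr::left_join(study$true_boundaries,
                       by = c("token_id", "boundary"),
                       suffix = c("", "_true")) |>
      dplyr::mutate(dev = time_ms - time_ms_true)
    sum(dev$dev != 0 & abs(dev$dev - round(dev$dev / 20) * 20) < 1e-9 &
          abs(dev$dev) >= 20)
  }
  with_q <- snapped_count(generate_study(base_cfg(0.3)))
  without_q <- snapped_count(generate_study(base_cfg(0)))
  expect_gt(with_q, 20)
  expect_equal(without_q, 0)
})

test_that("omission is suffix-biased and monotone in position", {
  cfg_none <- generator_config(omission_probs = rep(0, 8))
  withr::with_seed(1, {
    expect_equal(omission_positions(cfg_none), 1:8)
  })
  cfg_last <- generator_config(omission_probs = c(rep(0, 7), 1))
  withr::with_seed(2, {
    for (i in 1:20) expect_equal(omission_positions(cfg_last), 1:7)
  })
  cfg <- generator_config()
  withr::with_seed(3, {
    produced <- matrix(FALSE, nrow = 5000, ncol = 8)
    for (i in 1:5000) produced[i, omission_positions(cfg)] <- TRUE
    omit_rate <- 1 - colMeans(produced)
    # empirical monotonicity within binomial sampling error
    expect_true(all(diff(omit_rate) > -0.02))
  })
})

test_that("the generate -> deviations -> fit pipeline recovers the error
           scale", {
  spec <- mixture_spec(c(1, 4, 10), c(0.5, 0.35, 0.15))
  em <- list(ponss = list(fast = spec, medium = spec, slow = spec),
             baseline = list(fast = spec, medium = spec, slow = spec))
  target <- weighted_sigma(spec)
  errs <- vapply(1:5, function(s) {
    study <- generate_study(generator_config(n_speakers = 2,
                                             trials_per_speaker = 9,
                                             error_model = em,
                                             quantization_prob = 0,
                                             seed = 40 + s))
    dev <- compute_deviations(study$annotations)
    ws <- weighted_sigma(pso_fit(dev$deviation_ms, test_pso(seed = 50 + s)))
    abs(ws - target) / target
  }, 0)
  expect_lt(median(errs), 0.2)
})

test_that("generated timing pools reproduce configured mean word times", {
  study <- generate_study(generator_config(n_speakers = 3,
                                           trials_per_speaker = 9,
                                           seed = 23))
  words <- baseline_word_times(study$timing, study$good_words_per_trial)
  # log-normal mean exp(mu + s^2/2) with mu = log(20), s = 0.3
  expect_lt(abs(mean(words$total_seconds) - 20 * exp(0.3^2 / 2)) /
              (20 * exp(0.3^2 / 2)), 0.05)
  boot <- bootstrap_hours(words, n_good = 500, n_reps = 200, seed = 2)
  expect_lt(abs(mean(boot$hours) * 3600 / 500 -
                  mean(words$total_seconds)) / mean(words$total_seconds),
            0.02)
})
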