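make_timing <- function(unit_id, annotator_id, modality, task, dur,
                        outcome) {
  tibble::tibble(unit_id = unit_id, annotator_id = annotator_id,
                 modality = modality, task = task,
                 t_start_s = cumsum(c(0, head(dur, -1))),
                 t_end_s = cumsum(c(0, head(dur, -1))) + dur,
                 outcome = outcome)
}

test_that("baseline trial time is split equally over its good words", {
  timing <- make_timing("tr1", "b1", "baseline", "baseline_trial", 120,
                        "saved")
  recs <- baseline_word_times(timing, c(tr1 = 6))
  expect_equal(nrow(recs), 6)
  expect_equal(recs$total_seconds, rep(20, 6))
  expect_true(all(recs$accepted))

  one <- baseline_word_times(timing, c(tr1 = 1))
  expect_equal(one$total_seconds, 120)
})

test_that("baseline attribution stays per annotator and conserves time", {
  timing <- make_timing(c("tr1", "tr1"), c("b1", "b2"), "baseline",
                        "baseline_trial", c(120, 60), "saved")
  recs <- baseline_word_times(timing, c(tr1 = 4))
  expect_equal(nrow(recs), 8)
  by_ann <- vapply(c("b1", "b2"), function(a) {
    sum(recs$total_seconds[grepl(paste0("@", a), recs$word_id)])
  }, 0)
  expect_equal(unname(by_ann), c(120, 60))
  expect_equal(sum(recs$total_seconds), 180)
})

test_that("trials with zero good words are excluded and counted", {
  timing <- make_timing(c("tr1", "tr2"), "b1", "baseline",
                        "baseline_trial", c(100, 50), "saved")
  recs <- baseline_word_times(timing, c(tr1 = 2, tr2 = 0))
  expect_equal(nrow(recs), 2)
  expect_equal(attr(recs, "n_zero_word_trials"), 1)
})

test_that("ponss word time sums all passes across annotators and tasks", {
  timing <- make_timing(c("w1", "w1", "w1", "w2"),
                        c("p1", "p2", "p1", "p3"), "ponss",
                        c("triage", "triage", "retrim", "triage"),
                        c(3, 4, 10, 5),
                        c("accepted", "retrim_requested", "saved",
                          "rejected"))
  recs <- ponss_word_times(timing, c(w1 = TRUE, w2 = FALSE))
  expect_equal(recs$total_seconds[recs$word_id == "w1"], 17)
  expect_true(recs$accepted[recs$word_id == "w1"])
  expect_false(recs$accepted[recs$word_id == "w2"])
  # rejected words keep their cost
  expect_equal(recs$total_seconds[recs$word_id == "w2"], 5)
  expect_equal(sum(recs$total_seconds), sum(timing$t_end_s - timing$t_start_s))

  expect_error(ponss_word_times(timing, c(w1 = TRUE)), "w2.*no final status")

  zero <- make_timing("w9", "p1", "ponss", "triage", 0, "accepted")
  expect_warning(ponss_word_times(zero, c(w9 = TRUE)), "zero total")
})

make_pool <- function(n, rejected_n = 0, t = 10) {
  tibble::tibble(word_id = as.character(seq_len(n)), modality = "ponss",
                 total_seconds = t,
                 accepted = c(rep(FALSE, rejected_n),
                              rep(TRUE, n - rejected_n)))
}

test_that("bootstrap without rejections equals the plain n_good sum", {
  pool <- make_pool(8000)
  boot <- bootstrap_hours(pool, n_good = 5000, n_reps = 20, seed = 3)
  expect_true(all(boot$n_words_sampled == 5000))
  expect_equal(boot$hours, rep(5000 * 10 / 3600, 20))
  boot2 <- bootstrap_hours(pool, n_good = 5000, n_reps = 20, seed = 3)
  expect_equal(as.data.frame(boot), as.data.frame(boot2))
  expect_error(bootstrap_hours(make_pool(100), n_good = 200, n_reps = 2),
               "insufficient")
})

test_that("rejections inflate the expected replicate time by 1/(1-r)", {
  pool <- make_pool(20000, rejected_n = 1000) # exactly 5% rejected
  boot <- bootstrap_hours(pool, n_good = 5000, n_reps = 300, seed = 8)
  expect_true(all(boot$n_words_sampled >= 5000))
  expected <- (5000 / 0.95) * 10 / 3600
  expect_lt(abs(mean(boot$hours) - expected) / expected, 0.02)
})

test_that("replicate totals are translation-equivariant in per-word time", {
  pool <- make_pool(6000)
  b1 <- bootstrap_hours(pool, n_good = 4000, n_reps = 10, seed = 5)
  pool2 <- pool
  pool2$total_seconds <- pool2$total_seconds + 3
  b2 <- bootstrap_hours(pool2, n_good = 4000, n_reps = 10, seed = 5)
  expect_equal(b2$hours, b1$hours + 4000 * 3 / 3600, tolerance = 1e-10)
})

test_that("modality comparison yields difference, reduction and Cohen's d", {
  withr::with_seed(6, e <- rnorm(1000, 0, 2))
  e <- e - mean(e)
  a <- tibble::tibble(replicate = 1:1000, modality = "baseline",
                      hours = 48 + e)
  b <- tibble::tibble(replicate = 1:1000, modality = "ponss",
                      hours = 37 + e)
  same <- compare_modalities(a, a)
  expect_equal(same$mean_diff_hours, 0)
  expect_equal(same$pct_reduction, 0)
  expect_equal(same$cohens_d, 0)

  cmp <- compare_modalities(a, b)
  expect_equal(cmp$mean_diff_hours, 11, tolerance = 1e-10)
  expect_equal(cmp$pct_reduction, 100 * 11 / 48, tolerance = 1e-10)
  expect_equal(cmp$cohens_d, 11 / sd(e), tolerance = 1e-10)

  shifted <- a
  shifted$hours <- a$hours + 10
  cmp2 <- compare_modalities(shifted, a)
  expect_equal(cmp2$mean_diff_hours, 10, tolerance = 1e-10)
  expect_equal(cmp2$cohens_d, 10 / sd(a$hours), tolerance = 1e-6)
})
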