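# Shared fixtures and independent oracles, all built in code.

# Small annotation table: one token annotated in both modalities.
tiny_annotations <- function() {
  tibble::tibble(
    token_id = "t1_w1",
    trial_id = "t1", position = 1L, label = "snavel", speaker_id = "sp1",
    rate = "medium",
    modality = c("baseline", "baseline", "ponss"),
    annotator_id = c("a", "b", "c"),
    boundary = "onset",
    time_ms = c(100, 102, 104))
}

# A deviation pool with plenty of records in every modality x rate (x
# boundary) stratum, deviations drawn N(0, sd).
make_deviation_pool <- function(n_per_stratum = 400, sd = 5, seed = 42,
                                boundaries = c("onset", "offset")) {
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(modality = c("ponss", "baseline"),
                               rate = c("fast", "medium", "slow"),
                               boundary = boundaries,
                               i = seq_len(n_per_stratum))
    grid |>
      dplyr::mutate(
        token_id = sprintf("%s_%s_%s_%d", modality, rate, boundary, i),
        annotator_id = "a",
        deviation_ms = stats::rnorm(nrow(grid), 0, sd)) |>
      dplyr::select(-"i")
  })
}

# Brute-force Krippendorff interval alpha: explicit enumeration of all
# ordered within-unit pairs and all ordered pairs of pairable values.
alpha_bruteforce <- function(mat) {
  groups <- lapply(seq_len(nrow(mat)), function(i) mat[i, !is.na(mat[i, ])])
  groups <- groups[vapply(groups, length, 0L) >= 2]
  n <- sum(vapply(groups, length, 0L))
  d_obs_num <- 0
  for (v in groups) {
    m <- length(v)
    s <- 0
    for (i in seq_len(m)) for (j in seq_len(m)) if (i != j) {
      s <- s + (v[i] - v[j])^2
    }
    d_obs_num <- d_obs_num + s / (m - 1)
  }
  d_obs <- d_obs_num / n
  all_v <- unlist(groups)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    s <- s + (all_v[i] - all_v[j])^2
  }
  d_exp <- s / (n * (n - 1))
  1 - d_obs / d_exp
}

# Direct one-way ANOVA mean squares for the ICC oracle.
icc_anova_oracle <- function(mat) {
  groups <- lapply(seq_len(nrow(mat)), function(i) mat[i, !is.na(mat[i, ])])
  n_i <- vapply(groups, length, 0L)
  k <- length(groups)
  n_tot <- sum(n_i)
  grand <- mean(unlist(groups))
  msb <- sum(n_i * (vapply(groups, mean, 0) - grand)^2) / (k - 1)
  msw <- sum(unlist(lapply(groups, function(v) (v - mean(v))^2))) /
    (n_tot - k)
  n0 <- (n_tot - sum(n_i^2) / n_tot) / (k - 1)
  (msb - msw) / (msb + (n0 - 1) * msw)
}

# Long-format matrix for the agreement functions.
matrix_to_long <- function(mat) {
  tibble::tibble(
    unit = rep(seq_len(nrow(mat)), times = ncol(mat)),
    rater = rep(seq_len(ncol(mat)), each = nrow(mat)),
    value = as.vector(mat))
}

# Two-tier long-format TextGrid fixture text.
two_tier_textgrid <- function() {
  textgrid(0, 2.5, list(
    list(name = "words",
         intervals = data.frame(
           xmin = c(0, 0.5, 1.1, 1.6),
           xmax = c(0.5, 1.1, 1.6, 2.5),
           text = c("", "snavel", "wortel", ""))),
    list(name = "comments",
         intervals = data.frame(xmin = 0, xmax = 2.5, text = "ok"))))
}

expect_textgrid_equal <- function(a, b, tol = 1e-6) {
  expect_equal(a$xmin, b$xmin, tolerance = tol)
  expect_equal(a$xmax, b$xmax, tolerance = tol)
  expect_length(b$tiers, length(a$tiers))
  for (i in seq_along(a$tiers)) {
    expect_identical(a$tiers[[i]]$name, b$tiers[[i]]$name)
    expect_equal(a$tiers[[i]]$intervals$xmin, b$tiers[[i]]$intervals$xmin,
                 tolerance = tol)
    expect_equal(a$tiers[[i]]$intervals$xmax, b$tiers[[i]]$intervals$xmax,
                 tolerance = tol)
    expect_identical(a$tiers[[i]]$intervals$text,
                     b$tiers[[i]]$intervals$text)
  }
}

# Random valid single-tier textgrid for round-trip property tests.
random_textgrid <- function(n_intervals = 5) {
  cuts <- sort(runif(n_intervals - 1, 0, 10))
  edges <- c(0, cuts, 10)
  textgrid(0, 10, list(list(
    name = "words",
    intervals = data.frame(
      xmin = edges[-length(edges)], xmax = edges[-1],
      text = sample(c("", "snavel", "wortel", "vogel"), n_intervals,
                    replace = TRUE)))))
}

# Synthetic regression rows with a known generating structure, bypassing
# the (slow) swarm fitting: one row per grid cell x component.
make_sigma_rows <- function(beta_ponss = 0, beta_fast = 0, beta_slow = 0,
                            noise_sd = 0.3, seed = 1) {
  withr::with_seed(seed, {
    grid <- build_proportion_grid()
    base <- c(narrow = 1, medium = 4, wide = 15)
    rows <- tidyr::expand_grid(grid,
                               component = c("narrow", "medium", "wide"))
    rows |>
      dplyr::mutate(
        sigma = base[component] + beta_ponss * p_ponss +
          beta_fast * p_fast + beta_slow * p_slow +
          stats::rnorm(nrow(rows), 0, noise_sd),
        theta = 1 / 3, kl = stats::runif(nrow(rows), 0, 0.2),
        weight = theta * (1 - kl), particle = 1L)
  })
}

# Reduced-size PSO settings used throughout the tests; ample for the
# 6-dimensional problem.
test_pso <- function(seed = 1, n_particles = 20, max_iter = 300) {
  pso_config(n_particles = n_particles, max_iter = max_iter, seed = seed)
}
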