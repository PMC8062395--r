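# Proportion-varied subsets of the balanced deviation sample and the
# weighted regression of fitted sigmas on modality / speaking-rate
# composition.

#' The exhaustive proportion grid (252 cells)
#'
#' Crosses every speaking-rate composition in tenths (fast, medium and
#' slow proportions each between 0.1 and 0.8, summing to 1; 36
#' compositions) with the seven manual-annotation proportions 0.2 to 0.8
#' in steps of 0.1 (`p_ponss = 1 - p_manual`), giving 252 cells in a
#' deterministic order.
#'
#' @return A tibble with columns `subset_id`, `p_manual`, `p_ponss`,
#'   `p_fast`, `p_medium`, `p_slow`.
#' @examples
#' nrow(build_proportion_grid()) # 252
#' @export
build_proportion_grid <- function() {
  rates <- tidyr::expand_grid(f = 1:8, m = 1:8) |>
    mutate(s = 10L - .data$f - .data$m) |>
    filter(.data$s >= 1L, .data$s <= 8L)
  grid <- tidyr::expand_grid(p_manual = seq(0.2, 0.8, by = 0.1),
                             rates) |>
    mutate(p_ponss = 1 - .data$p_manual,
           p_fast = .data$f / 10, p_medium = .data$m / 10,
           p_slow = .data$s / 10) |>
    select("p_manual", "p_ponss", "p_fast", "p_medium", "p_slow") |>
    arrange(.data$p_manual, .data$p_fast, .data$p_medium)
  grid |> mutate(subset_id = sprintf("s%03d", dplyr::row_number()),
                 .before = 1)
}

#' Draw one proportion-matched subset of deviations
#'
#' Samples `size` records without replacement from the pooled deviation
#' sample so that the modality and speaking-rate margins match the cell's
#' proportions. Integer counts come from largest-remainder allocation
#' (modality first, then rates within each modality), so every allocated
#' count differs from the exact product by at most 1 and the counts sum
#' to `size`.
#'
#' @param sample Deviation tibble with `modality` and `rate` columns
#'   (typically a [balanced_sample()]).
#' @param cell One row of [build_proportion_grid()] (or any list with
#'   `p_ponss`, `p_fast`, `p_medium`, `p_slow`).
#' @param size Number of records in the subset.
#' @param seed Integer seed.
#' @return A tibble of `size` deviation records.
#' @export
draw_subset <- function(sample, cell, size, seed = NULL) {
  assert_cols(sample, c("modality", "rate", "deviation_ms"),
              "deviation sample")
  mod_n <- largest_remainder(size, c(ponss = cell$p_ponss,
                                     baseline = 1 - cell$p_ponss))
  rate_p <- c(fast = cell$p_fast, medium = cell$p_medium,
              slow = cell$p_slow)
  with_seed_or_not(seed, {
    parts <- purrr::map2(MODALITY_LEVELS, mod_n, function(mod, n_mod) {
      rate_n <- largest_remainder(n_mod, rate_p)
      purrr::map2(RATE_LEVELS, rate_n, function(rt, n_rt) {
        pool <- sample |> filter(.data$modality == mod, .data$rate == rt)
        if (nrow(pool) < n_rt) {
          abort(sprintf(
            "insufficient pool for stratum %s/%s: %d available, %d requested",
            mod, rt, nrow(pool), n_rt))
        }
        pool |> slice_sample(n = n_rt)
      }) |> dplyr::bind_rows()
    })
    dplyr::bind_rows(parts)
  })
}

#' Fit the mixture to every proportion cell and expand to regression rows
#'
#' For each grid cell: draws the proportion-matched subset (per-cell seed
#' derived deterministically from `seed`), fits the mixture by
#' [pso_fit()], and expands the *entire final swarm* -- one row per
#' particle per mixture component -- into the regression table. Each
#' row's weight is the particle's theta for that component multiplied by
#' `max(0, 1 - KL)`, so better-fitting particles and dominant components
#' carry more weight. Per-cell fit failures are recorded and skipped, and
#' the run continues.
#'
#' @param sample Pooled deviation sample.
#' @param grid Tibble of proportion cells (default the full 252-cell
#'   grid).
#' @param size Records per subset.
#' @param config A [pso_config()].
#' @param seed Master seed for subset draws and per-cell fit seeds.
#' @param best_only If `TRUE`, keep only each fit's best particle.
#' @return A tibble with columns `subset_id`, `particle`, `component`,
#'   `sigma`, `theta`, `kl`, `weight`, `p_ponss`, `p_fast`, `p_slow` (and
#'   an attribute `failures` listing failed cells, if any).
#' @export
fit_all_subsets <- function(sample, grid = build_proportion_grid(),
                            size = 600, config = pso_config(),
                            seed = 1L, best_only = FALSE) {
  failures <- character()
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    cell <- grid[i, ]
    out <- tryCatch({
      sub <- draw_subset(sample, cell, size,
                         seed = derive_seed(seed, 2L * i))
      cfg <- config
      cfg$seed <- derive_seed(seed, 2L * i + 1L)
      fit <- pso_fit(sub$deviation_ms, cfg)
      particles <- fit$particles
      if (best_only) particles <- particles[fit$best, , drop = FALSE]
      particles |>
        tidyr::pivot_longer(
          cols = dplyr::starts_with(c("theta_", "sigma_")),
          names_to = c(".value", "component"), names_sep = "_") |>
        mutate(subset_id = cell$subset_id,
               weight = .data$theta * pmax(0, 1 - .data$kl),
               p_ponss = cell$p_ponss, p_fast = cell$p_fast,
               p_slow = cell$p_slow) |>
        select("subset_id", "particle", "component", "sigma", "theta",
               "kl", "weight", "p_ponss", "p_fast", "p_slow")
    }, error = function(e) {
      failures <<- c(failures,
                     sprintf("%s: %s", cell$subset_id, conditionMessage(e)))
      NULL
    })
    out
  })
  res <- dplyr::bind_rows(rows)
  if (length(failures) > 0) {
    warn(sprintf("fit_all_subsets: %d cell(s) failed", length(failures)))
    attr(res, "failures") <- failures
  }
  res
}

#' Weighted regression of fitted sigmas on sample composition
#'
#' Weighted least squares of the fitted component sigmas on the subset
#' composition: linear predictors `p_ponss`, `p_fast` and `p_slow`
#' (`p_manual` and `p_medium` are omitted as they are entirely
#' determined by the included predictors), a sum-to-zero
#' (deviation-coded) factor for mixture component, and all linear x
#' component interactions. Row weights are `theta * max(0, 1 - KL)` from
#' [fit_all_subsets()]; zero-weight rows drop out.
#'
#' A coefficient on `p_ponss` is interpretable as the expected change in
#' fitted sigma (ms) moving from an all-baseline to an all-POnSS sample;
#' likewise `p_fast`/`p_slow` against an all-medium-rate sample.
#'
#' @param rows Output of [fit_all_subsets()].
#' @return A `sigma_wls` object wrapping the [stats::lm()] fit; use
#'   [tidy()] / [glance()] to extract coefficients.
#' @export
sigma_regression <- function(rows) {
  assert_cols(rows, c("component", "sigma", "weight", "p_ponss",
                      "p_fast", "p_slow"), "regression rows")
  for (v in c("p_ponss", "p_fast", "p_slow")) {
    if (length(unique(rows[[v]])) < 2) {
      abort(sprintf("sigma_regression: predictor %s has fewer than 2 distinct values", v))
    }
  }
  rows <- rows |> filter(.data$weight > 0)
  rows$component <- factor(rows$component, levels = COMPONENT_LEVELS)
  fit <- lm(sigma ~ (p_ponss + p_fast + p_slow) * component,
            data = rows, weights = weight,
            contrasts = list(component = "contr.sum"))
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("sigma_regression: rank-deficient design; collinear term(s): ",
                 paste(bad, collapse = ", ")))
  }
  structure(list(fit = fit, n_rows = nrow(rows)), class = "sigma_wls")
}

#' @export
print.sigma_wls <- function(x, ...) {
  cat(sprintf("<sigma_wls> weighted sigma regression on %d rows\n", x$n_rows))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Coefficients of the sigma regression
#'
#' @param x A `sigma_wls` object.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `se`, `statistic`.
#' @export
tidy.sigma_wls <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
         statistic = sm[, 3])
}

#' One-row fit summary of the sigma regression
#'
#' @param x A `sigma_wls` object.
#' @param ... Unused.
#' @return One-row tibble with `r_squared`, `residual_sigma`, `n_rows`.
#' @export
glance.sigma_wls <- function(x, ...) {
  sm <- summary(x$fit)
  tibble(r_squared = sm$r.squared, residual_sigma = sm$sigma,
         n_rows = x$n_rows)
}

#' Coefficient plot for the sigma regression
#'
#' @param object A `sigma_wls`.
#' @param ... Unused.
#' @return A ggplot dot-and-interval plot of estimates +/- 2 SE.
#' @export
autoplot.sigma_wls <- function(object, ...) {
  td <- tidy(object) |> filter(.data$term != "(Intercept)")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 2 * .data$se,
      xmax = .data$estimate + 2 * .data$se)) +
    ggplot2::labs(x = "estimate (ms) with ± 2 SE", y = NULL)
}
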