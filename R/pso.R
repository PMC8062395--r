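# Bounded global-best particle swarm optimization of the mixture
# parameters under the discretized symmetrized KL objective.

#' Particle swarm configuration
#'
#' Defaults follow standard constriction-coefficient practice: inertia
#' 0.7298 with cognitive and social accelerations of 1.49618, velocities
#' clamped to half the per-dimension search range, positions clamped to
#' the box bounds. Sixty particles for at most 2000 iterations is the
#' full-scale setting; reduced swarms (20 particles, a few hundred
#' iterations) are adequate for the low-dimensional problem and are used
#' throughout the test suite. The run stops early once the global best
#' has improved by less than `early_stop_tol` for `early_stop_patience`
#' consecutive iterations.
#'
#' @param n_particles Number of particles (>= 2).
#' @param max_iter Iteration cap (>= 1).
#' @param inertia,cognitive,social PSO velocity-update coefficients.
#' @param velocity_clamp_fraction Velocity limit as a fraction of each
#'   dimension's range.
#' @param early_stop_tol,early_stop_patience Early-stopping rule.
#' @param seed Integer seed for reproducible fits (`NULL` leaves the RNG
#'   stream alone).
#' @param binning [kl_binning()] used to discretize the objective.
#' @return A `pso_config` list.
#' @export
pso_config <- function(n_particles = 60, max_iter = 2000,
                       inertia = 0.7298, cognitive = 1.49618,
                       social = 1.49618, velocity_clamp_fraction = 0.5,
                       early_stop_tol = 1e-9, early_stop_patience = 200,
                       seed = NULL, binning = kl_binning()) {
  if (n_particles < 2) abort("pso_config: n_particles must be >= 2")
  if (max_iter < 1) abort("pso_config: max_iter must be >= 1")
  structure(list(n_particles = as.integer(n_particles),
                 max_iter = as.integer(max_iter), inertia = inertia,
                 cognitive = cognitive, social = social,
                 velocity_clamp_fraction = velocity_clamp_fraction,
                 early_stop_tol = early_stop_tol,
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = seed, binning = binning),
            class = "pso_config")
}

# Raw search space: three unnormalized component weights in [0, 1]
# followed by the three sigmas in their overlapping boxes. Weights are
# normalized to the theta simplex at evaluation time, which keeps the
# sum-to-one constraint exact without penalty terms.
pso_bounds <- function() {
  list(lower = c(0, 0, 0, SIGMA_LOWER), upper = c(1, 1, 1, SIGMA_UPPER))
}

# Normalize raw weights; degenerate (near-zero-sum) weight triples are
# reported so the caller can re-initialize the particle.
raw_to_theta <- function(w) {
  s <- sum(w)
  if (s < 1e-6) return(NULL)
  w / s
}

#' Fit the error mixture to a deviation sample by PSO
#'
#' Runs bounded global-best particle swarm optimization over the six raw
#' parameters (three unnormalized component weights, three sigmas) and
#' returns the complete final swarm -- every particle's mixture
#' parameters with its achieved KL -- not just the optimum, so downstream
#' regression can weight by fit quality across the swarm.
#'
#' @param sample Numeric vector of deviations (ms) or a data frame with a
#'   `deviation_ms` column. Samples under 50 values are accepted with a
#'   warning; the histogram discretization is unreliable that small.
#' @param config A [pso_config()].
#' @return A `mixture_fit` object: `particles` (tibble of
#'   theta/sigma/kl per particle in the final iteration), `best` (row
#'   index of the minimal KL), `best_spec` (a [mixture_spec()]),
#'   `kl_best`, `iterations_run`, `converged` (early-stop flag),
#'   `kl_trace` (global best per iteration, always non-increasing),
#'   `config`, plus the sample for plotting.
#' @examples
#' dev <- rmixture(500, mixture_spec(c(1, 4, 20), c(0.6, 0.3, 0.1)))
#' fit <- pso_fit(dev, pso_config(n_particles = 10, max_iter = 50, seed = 1))
#' glance(fit)
#' @export
pso_fit <- function(sample, config = pso_config()) {
  if (is.data.frame(sample)) sample <- sample$deviation_ms
  sample <- as.double(sample)
  if (length(sample) == 0) abort("pso_fit: empty sample")
  if (length(sample) < 50) {
    warn(sprintf("pso_fit: sample of %d < 50 values; fit may be unstable",
                 length(sample)))
  }
  binning <- config$binning
  obs <- observed_masses(sample, binning)
  bounds <- pso_bounds()
  lower <- bounds$lower; upper <- bounds$upper
  range <- upper - lower
  vmax <- config$velocity_clamp_fraction * range
  d <- length(lower)
  np <- config$n_particles

  objective <- function(pos) {
    theta <- raw_to_theta(pos[1:3])
    if (is.null(theta)) return(NA_real_)
    q <- model_masses(theta, pos[4:6], binning)
    kl_between_masses(obs, q, binning$eps)
  }

  run <- function() {
    pos <- matrix(runif(np * d, rep(lower, each = np), rep(upper, each = np)),
                  nrow = np)
    vel <- matrix(runif(np * d, rep(-vmax, each = np), rep(vmax, each = np)),
                  nrow = np)
    score <- apply(pos, 1, objective)
    # near-zero weight sums: re-draw until every particle evaluates
    for (tries in 1:100) {
      bad <- which(is.na(score))
      if (length(bad) == 0) break
      pos[bad, ] <- matrix(runif(length(bad) * d,
                                 rep(lower, each = length(bad)),
                                 rep(upper, each = length(bad))),
                           nrow = length(bad))
      score[bad] <- apply(pos[bad, , drop = FALSE], 1, objective)
    }
    if (anyNA(score) || all(!is.finite(score))) {
      abort("pso_fit: objective non-finite at all initial particles")
    }
    pbest_pos <- pos
    pbest_score <- score
    g <- which.min(pbest_score)
    gbest_pos <- pbest_pos[g, ]
    gbest_score <- pbest_score[g]
    stagnant <- 0L
    iter_run <- 0L
    converged <- FALSE
    trace <- double(config$max_iter)

    for (iter in seq_len(config$max_iter)) {
      iter_run <- iter
      r1 <- matrix(runif(np * d), nrow = np)
      r2 <- matrix(runif(np * d), nrow = np)
      vel <- config$inertia * vel +
        config$cognitive * r1 * (pbest_pos - pos) +
        config$social * r2 * (rep(1, np) %o% gbest_pos - pos)
      vel <- pmin(pmax(vel, rep(-vmax, each = np)), rep(vmax, each = np))
      pos <- pos + vel
      # clamp to bounds and kill the velocity component that ran out
      out_lo <- pos < rep(lower, each = np)
      out_hi <- pos > rep(upper, each = np)
      vel[out_lo | out_hi] <- 0
      pos <- pmin(pmax(pos, rep(lower, each = np)), rep(upper, each = np))

      score <- apply(pos, 1, objective)
      bad <- which(is.na(score))
      if (length(bad) > 0) {
        pos[bad, ] <- matrix(runif(length(bad) * d,
                                   rep(lower, each = length(bad)),
                                   rep(upper, each = length(bad))),
                             nrow = length(bad))
        score[bad] <- apply(pos[bad, , drop = FALSE], 1, objective)
        score[is.na(score)] <- Inf
      }
      improved <- score < pbest_score
      pbest_pos[improved, ] <- pos[improved, ]
      pbest_score[improved] <- score[improved]
      g <- which.min(pbest_score)
      if (gbest_score - pbest_score[g] < config$early_stop_tol) {
        stagnant <- stagnant + 1L
      } else {
        stagnant <- 0L
      }
      gbest_pos <- pbest_pos[g, ]
      gbest_score <- pbest_score[g]
      trace[iter] <- gbest_score
      if (stagnant >= config$early_stop_patience) {
        converged <- TRUE
        break
      }
    }
    list(pos = pos, score = score, iterations = iter_run,
         converged = converged, trace = trace[seq_len(iter_run)])
  }

  state <- with_seed_or_not(config$seed, run())

  thetas <- t(apply(state$pos[, 1:3, drop = FALSE], 1, function(w) {
    th <- raw_to_theta(w)
    if (is.null(th)) rep(NA_real_, 3) else th
  }))
  particles <- tibble(
    particle = seq_len(np),
    theta_narrow = thetas[, 1], theta_medium = thetas[, 2],
    theta_wide = thetas[, 3],
    sigma_narrow = state$pos[, 4], sigma_medium = state$pos[, 5],
    sigma_wide = state$pos[, 6],
    kl = state$score)
  best <- which.min(particles$kl)
  best_spec <- mixture_spec(
    sigma = unlist(particles[best, c("sigma_narrow", "sigma_medium",
                                     "sigma_wide")]),
    theta = unlist(particles[best, c("theta_narrow", "theta_medium",
                                     "theta_wide")]))
  structure(list(particles = particles, best = best, best_spec = best_spec,
                 kl_best = particles$kl[best],
                 iterations_run = state$iterations,
                 converged = state$converged, kl_trace = state$trace,
                 config = config, sample = sample),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<mixture_fit> %d particles, %d iteration(s)%s, best KL %.6g\n",
    nrow(x$particles), x$iterations_run,
    if (x$converged) " (early-stopped)" else "", x$kl_best))
  print(x$best_spec)
  invisible(x)
}

#' Tidy the final swarm of a mixture fit
#'
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @return One row per particle: thetas, sigmas, achieved KL, and the
#'   per-particle weighted sigma.
#' @export
tidy.mixture_fit <- function(x, ...) {
  x$particles |>
    mutate(weighted_sigma = .data$theta_narrow * .data$sigma_narrow +
             .data$theta_medium * .data$sigma_medium +
             .data$theta_wide * .data$sigma_wide)
}

#' One-row summary of a mixture fit
#'
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @return A tibble with the best KL, the weighted sigma of the best
#'   particle, iteration count, convergence flag and sample size.
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(kl_best = x$kl_best,
         weighted_sigma = weighted_sigma(x),
         iterations_run = x$iterations_run,
         converged = x$converged,
         n_particles = nrow(x$particles),
         n_obs = length(x$sample))
}

#' Plot a mixture fit over the deviation histogram
#'
#' @param object A `mixture_fit`.
#' @param ... Unused.
#' @return A ggplot object: the observed deviation histogram (density
#'   scale) with the best-particle mixture density overlaid.
#' @export
autoplot.mixture_fit <- function(object, ...) {
  binning <- object$config$binning
  xs <- seq(binning$lo, binning$hi, length.out = 400)
  dens <- tibble(x = xs, density = mixture_pdf(object$best_spec, xs))
  ggplot2::ggplot(tibble(deviation_ms = object$sample),
                  ggplot2::aes(x = .data$deviation_ms)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(.data$density)),
      binwidth = binning$width, boundary = 0,
      fill = "grey70", colour = NA) +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(x = .data$x, y = .data$density),
                       colour = "#2166ac", linewidth = 0.8) +
    ggplot2::coord_cartesian(xlim = c(binning$lo, binning$hi)) +
    ggplot2::labs(x = "deviation from median reference (ms)", y = "density",
                  title = sprintf("best fit: weighted sigma %.2f ms, KL %.4f",
                                  weighted_sigma(object), object$kl_best))
}
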