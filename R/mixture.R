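# Zero-mean three-Gaussian mixture model of segmentation error and the
# discretized symmetrized KL objective it is fitted under.

# Search bounds for the component standard deviations (ms). The regions
# deliberately overlap so the assignment of mass to components stays
# data-driven rather than being forced by the box constraints.
SIGMA_LOWER <- c(narrow = 1e-4, medium = 1.5, wide = 2.5)
SIGMA_UPPER <- c(narrow = 2, medium = 8, wide = 40)

#' Three-component zero-mean Gaussian mixture specification
#'
#' The segmentation-error model: all three Gaussians are centered at 0
#' (an annotation is unbiased relative to the pooled median by
#' construction), and the components differ only in spread. The narrow
#' component (`sigma` in `[0.0001, 2]` ms) captures boundaries on which
#' annotators essentially agree; the medium component (`[1.5, 8]` ms)
#' moderate disagreement; the wide component (`[2.5, 40]` ms) poor
#' segmentations far from the median. Mixing weights `theta` must sum
#' to 1.
#'
#' @param sigma Numeric length-3 vector of component standard deviations
#'   (ms), in narrow/medium/wide order.
#' @param theta Numeric length-3 vector of mixing proportions summing
#'   to 1.
#' @return An object of class `mixture_spec`.
#' @examples
#' spec <- mixture_spec(sigma = c(1, 4, 20), theta = c(0.6, 0.3, 0.1))
#' weighted_sigma(spec)
#' @export
mixture_spec <- function(sigma, theta) {
  sigma <- as.double(sigma)
  theta <- as.double(theta)
  if (length(sigma) != 3 || length(theta) != 3) {
    abort("mixture_spec needs exactly three sigmas and three thetas")
  }
  if (any(sigma < SIGMA_LOWER - 1e-12) || any(sigma > SIGMA_UPPER + 1e-12)) {
    abort(sprintf(
      "sigma out of bounds: narrow in [%g, %g], medium in [%g, %g], wide in [%g, %g] ms",
      SIGMA_LOWER[1], SIGMA_UPPER[1], SIGMA_LOWER[2], SIGMA_UPPER[2],
      SIGMA_LOWER[3], SIGMA_UPPER[3]))
  }
  if (any(theta < 0) || abs(sum(theta) - 1) > 1e-9) {
    abort("theta must be non-negative and sum to 1 (within 1e-9)")
  }
  structure(list(sigma = setNames(sigma, COMPONENT_LEVELS),
                 theta = setNames(theta, COMPONENT_LEVELS),
                 mu = setNames(c(0, 0, 0), COMPONENT_LEVELS)),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat("<mixture_spec> zero-mean 3-Gaussian mixture\n")
  cat(sprintf("  sigma (ms): narrow %.4g, medium %.4g, wide %.4g\n",
              x$sigma[1], x$sigma[2], x$sigma[3]))
  cat(sprintf("  theta:      narrow %.3f, medium %.3f, wide %.3f\n",
              x$theta[1], x$theta[2], x$theta[3]))
  cat(sprintf("  weighted sigma: %.4g ms\n", weighted_sigma(x)))
  invisible(x)
}

#' Mixture density, distribution and random draws
#'
#' `mixture_pdf()` evaluates `sum_i theta_i N(x; 0, sigma_i^2)`;
#' `mixture_cdf()` the corresponding distribution function;
#' `rmixture()` draws deviates by component sampling.
#'
#' @param spec A [mixture_spec()].
#' @param x Numeric vector of deviations (ms).
#' @return Densities / probabilities / draws as numeric vectors.
#' @export
mixture_pdf <- function(spec, x) {
  drop(vapply(seq_len(3),
              function(i) spec$theta[i] * dnorm(x, 0, spec$sigma[i]),
              numeric(length(x))) %*% rep(1, 3))
}

#' @rdname mixture_pdf
#' @export
mixture_cdf <- function(spec, x) {
  drop(vapply(seq_len(3),
              function(i) spec$theta[i] * pnorm(x, 0, spec$sigma[i]),
              numeric(length(x))) %*% rep(1, 3))
}

#' @rdname mixture_pdf
#' @param n Number of draws.
#' @export
rmixture <- function(n, spec) {
  comp <- sample.int(3, n, replace = TRUE, prob = spec$theta)
  rnorm(n, 0, spec$sigma[comp])
}

#' Weighted mixture sigma: the reliability statistic
#'
#' The theta-weighted sum of the fitted component sigmas,
#' `sum_i theta_i sigma_i` in ms. Smaller values mean annotations cluster
#' more tightly around the pooled median, i.e. higher reliability. For a
#' fitted swarm the statistic is computed on the best particle.
#'
#' @param x A [mixture_spec()] or a `mixture_fit` from [pso_fit()].
#' @return Weighted sigma in ms.
#' @export
weighted_sigma <- function(x) UseMethod("weighted_sigma")

#' @export
weighted_sigma.mixture_spec <- function(x) sum(x$theta * x$sigma)

#' @export
weighted_sigma.mixture_fit <- function(x) weighted_sigma(x$best_spec)

#' Discretization grid for the KL objective
#'
#' The observed sample and the fitted mixture are both reduced to
#' probability masses on a shared grid of `width`-ms bins spanning
#' `[lo, hi]` ms before the divergences are computed. Mass outside the
#' support (sample values or model tail probability) is folded into the
#' edge bins so both distributions keep total mass 1; every bin is then
#' floored at `eps` and renormalized so the divergences stay finite.
#'
#' @param width Bin width, ms.
#' @param lo,hi Support limits, ms.
#' @param eps Regularization floor for bin masses.
#' @return A `kl_binning` list.
#' @export
kl_binning <- function(width = 1, lo = -50, hi = 50, eps = 1e-9) {
  if (width <= 0 || hi <= lo) abort("invalid binning: need width > 0 and hi > lo")
  edges <- seq(lo, hi, by = width)
  if (abs(edges[length(edges)] - hi) > 1e-9) edges <- c(edges, hi)
  structure(list(width = width, lo = lo, hi = hi, eps = eps, edges = edges),
            class = "kl_binning")
}

# Observed bin masses for a deviation sample; values beyond the support
# are clamped into the edge bins.
observed_masses <- function(sample, binning) {
  if (all(sample < binning$lo | sample > binning$hi)) {
    abort("deviation sample lies entirely outside the KL support grid")
  }
  edges <- binning$edges
  idx <- findInterval(sample, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(edges) - 1L)
  tabulate(idx, nbins = length(edges) - 1L) / length(sample)
}

# Model bin masses from CDF differences, tails folded into edge bins.
model_masses <- function(theta, sigma, binning) {
  edges <- binning$edges
  cdf <- pnorm(outer(edges, sigma, "/")) %*% theta
  mass <- diff(drop(cdf))
  mass[1] <- mass[1] + drop(cdf)[1]
  mass[length(mass)] <- mass[length(mass)] + (1 - drop(cdf)[length(edges)])
  mass
}

# Symmetrized KL between two mass vectors, with floor-and-renormalize.
kl_between_masses <- function(p, q, eps) {
  p <- pmax(p, eps); p <- p / sum(p)
  q <- pmax(q, eps); q <- q / sum(q)
  (sum(p * log(p / q)) + sum(q * log(q / p))) / 2
}

#' Symmetrized KL objective between a deviation sample and a mixture
#'
#' Both the sample and the model are discretized on the shared bin grid
#' (see [kl_binning()]); the objective is the mean of the two directed
#' Kullback-Leibler divergences, `(KL(obs || fit) + KL(fit || obs)) / 2`,
#' in nats. Zero if and only if the discretized distributions coincide.
#'
#' @param sample Numeric vector of deviations (ms), or a data frame with
#'   a `deviation_ms` column.
#' @param spec A [mixture_spec()].
#' @param binning A [kl_binning()].
#' @return The objective value (non-negative, nats).
#' @export
kl_objective <- function(sample, spec, binning = kl_binning()) {
  if (is.data.frame(sample)) sample <- sample$deviation_ms
  if (length(sample) == 0) abort("kl_objective: empty sample")
  p <- observed_masses(sample, binning)
  q <- model_masses(spec$theta, spec$sigma, binning)
  kl_between_masses(p, q, binning$eps)
}
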