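#' Construct an agent genotype
#'
#' A genotype is a pair of real 2-vectors: `x`, the independent variables
#' (a male's displayed traits or a female's mating preferences, and the
#' coordinates at which the fitness landscape is evaluated), and `sigma`,
#' the strictly positive per-coordinate mutation standard deviations that
#' co-evolve with `x` (self-adaptation).
#'
#' @param x Numeric 2-vector of trait/preference values.
#' @param sigma Positive numeric 2-vector of mutation standard deviations.
#' @return An object of class `genotype`.
#' @export
genotype <- function(x, sigma) {
  if (length(x) != length(sigma)) {
    stop("`x` and `sigma` must have equal length")
  }
  if (any(sigma <= 0)) stop("`sigma` must be strictly positive")
  structure(list(x = as.numeric(x), sigma = as.numeric(sigma)),
            class = "genotype")
}

#' Variation operator parameters
#'
#' @param tau0 Global learning rate of the log-normal sigma update (shared
#'   normal draw); must be positive. See [default_taus()].
#' @param tau Coordinate-wise learning rate; must be positive.
#' @param mut_prob Probability that an offspring's genotype is mutated
#'   (whole genotype, both stages). Default 0.1.
#' @param rec_prob Probability that an offspring is produced by
#'   intermediate recombination rather than copying one parent.
#'   Default 0.8.
#' @return An object of class `variation_params`.
#' @export
variation_params <- function(tau0 = default_taus(2)[["tau0"]],
                             tau = default_taus(2)[["tau"]],
                             mut_prob = 0.1, rec_prob = 0.8) {
  stopifnot(tau0 > 0, tau > 0,
            mut_prob >= 0, mut_prob <= 1, rec_prob >= 0, rec_prob <= 1)
  structure(list(tau0 = tau0, tau = tau,
                 mut_prob = mut_prob, rec_prob = rec_prob),
            class = "variation_params")
}

#' Recommended self-adaptation learning rates
#'
#' Standard evolution-strategy recommendations for the two learning rates
#' of the log-normal mutation update:
#' \eqn{\tau_0 = 1/\sqrt{2n}} (shared across coordinates) and
#' \eqn{\tau = 1/\sqrt{2\sqrt{n}}} (per coordinate), where `n` is the
#' number of independent variables.
#'
#' @param n Number of independent variables (>= 1).
#' @return Named numeric vector with elements `tau0` and `tau`.
#' @examples
#' default_taus(2)  # tau0 = 0.5
#' @export
default_taus <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("`n` must be a single integer >= 1")
  }
  c(tau0 = 1 / sqrt(2 * n), tau = 1 / sqrt(2 * sqrt(n)))
}

#' Intermediate recombination of two genotypes
#'
#' Each offspring coordinate is an independent convex combination of the
#' parental coordinates, \eqn{x_i = \xi_i x_i^{(a)} + (1-\xi_i)
#' x_i^{(b)}} with a fresh uniform \eqn{\xi_i \sim U(0,1)} per coordinate.
#' The same construction, with independent draws, is applied to the
#' `sigma` vectors, so children always lie in the per-coordinate interval
#' spanned by the parents.
#'
#' @param parent_a,parent_b [genotype()] objects of equal dimension.
#' @param xi Optional list with numeric vectors `x` and `sigma` of mixing
#'   weights, overriding the random draws (used for deterministic checks).
#' @return A new `genotype`. Draws come from R's global RNG stream.
#' @export
recombine <- function(parent_a, parent_b, xi = NULL) {
  n <- length(parent_a$x)
  if (length(parent_b$x) != n) stop("parents have mismatched dimension")
  if (is.null(xi)) {
    xi <- list(x = stats::runif(n), sigma = stats::runif(n))
  }
  genotype(x = xi$x * parent_a$x + (1 - xi$x) * parent_b$x,
           sigma = xi$sigma * parent_a$sigma + (1 - xi$sigma) * parent_b$sigma)
}

#' Self-adaptive two-stage mutation of a genotype
#'
#' Stage one updates the strategy parameters log-normally,
#' \eqn{\sigma_i' = \sigma_i \exp(\tau_0 \xi + \tau \xi_i)} with one
#' shared draw \eqn{\xi \sim N(0,1)} and one per-coordinate draw
#' \eqn{\xi_i \sim N(0,1)}. Stage two perturbs the independent variables
#' with the freshly updated deviations,
#' \eqn{x_i' = x_i + \sigma_i' \xi_{x,i}}, \eqn{\xi_{x,i} \sim N(0,1)}.
#' The exponential form keeps `sigma` strictly positive for any draws.
#' The result is not clamped to any domain box; callers clamp via
#' [clamp_to_domain()].
#'
#' @param g A [genotype()].
#' @param params A [variation_params()] object (only `tau0`, `tau` used).
#' @param draws Optional list with elements `shared` (scalar), `per_coord`
#'   and `x` (vectors), overriding the normal draws for deterministic
#'   checks.
#' @return The mutated `genotype`.
#' @export
mutate_genotype <- function(g, params, draws = NULL) {
  n <- length(g$x)
  if (is.null(draws)) {
    draws <- list(shared = stats::rnorm(1), per_coord = stats::rnorm(n),
                  x = stats::rnorm(n))
  }
  sigma_new <- g$sigma * exp(params$tau0 * draws$shared +
                             params$tau * draws$per_coord)
  genotype(x = g$x + sigma_new * draws$x, sigma = sigma_new)
}

#' Produce one offspring genotype from two parents
#'
#' Applies the reproduction policy used by the simulator: with probability
#' `rec_prob` the offspring is the intermediate recombination of the two
#' parents (both `x` and `sigma`), otherwise it is a copy of one parent's
#' genotype chosen uniformly; then, with probability `mut_prob`, the
#' whole genotype is mutated ([mutate_genotype()]). Each offspring makes
#' its own independent draws.
#'
#' @inheritParams recombine
#' @param params A [variation_params()] object.
#' @return A new `genotype` (not clamped).
#' @export
offspring_genotype <- function(parent_a, parent_b, params) {
  g <- if (stats::runif(1) < params$rec_prob) {
    recombine(parent_a, parent_b)
  } else if (stats::runif(1) < 0.5) {
    parent_a
  } else {
    parent_b
  }
  if (stats::runif(1) < params$mut_prob) {
    g <- mutate_genotype(g, params)
  }
  g
}
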