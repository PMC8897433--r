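#' Draw negative binomial event counts
#'
#' Draws per-interval event counts from a negative binomial distribution in
#' the (mean, dispersion) parameterization used throughout the package:
#' mean `mu` and variance `mu + mu^2 / theta`. A `mu` of zero always yields
#' zero events.
#'
#' @param n Number of draws.
#' @param mu Expected number of events per interval (vectorized, >= 0).
#' @param theta Dispersion parameter (> 0); large `theta` approaches Poisson.
#' @return An integer vector of `n` non-negative counts.
#' @export
#' @examples
#' set.seed(1)
#' nb_draw(5, mu = 1.13, theta = 1.33)
nb_draw <- function(n, mu, theta) {
  if (!is.numeric(mu) || any(!is.finite(mu)) || any(mu < 0)) {
    abort("`mu` must be finite and >= 0.")
  }
  if (!is.numeric(theta) || any(!is.finite(theta)) || any(theta <= 0)) {
    abort("`theta` must be finite and > 0.")
  }
  rnbinom(n, mu = mu, size = theta)
}

# Per-trial NB maximum-likelihood fit in (mu, theta) form.
# The MLE of the NB mean is the sample mean; theta is the profile MLE via
# MASS::theta.ml. Underdispersed samples push theta to the Poisson boundary;
# they are capped at `theta_max`. All-zero samples have no information about
# theta: mu = 0 and theta = NA.
nb_fit <- function(counts, theta_max = 1e6) {
  counts <- counts[!is.na(counts)]
  if (length(counts) < 2L) abort("need at least 2 counts to fit.")
  mu <- mean(counts)
  if (mu == 0) {
    return(list(mu = 0, theta = NA_real_, n = length(counts)))
  }
  theta <- tryCatch(
    suppressWarnings(as.numeric(MASS::theta.ml(counts, mu, limit = 50))),
    error = function(e) theta_max
  )
  theta <- min(theta, theta_max)
  list(mu = mu, theta = theta, n = length(counts))
}

# P(X >= 1) for an NB(mu, theta) count
nb_occurrence_prob <- function(mu, theta) 1 - (theta / (theta + mu))^theta
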