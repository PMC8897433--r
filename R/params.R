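#' Field-estimated event-count parameters for Eciton hamatum bridges
#'
#' Reference negative binomial parameters for the number of ants joining and
#' leaving a bridge per 30-s gap interval, estimated from the field study of
#' dynamically stretched *Eciton hamatum* bridges (medians of per-trial
#' maximum-likelihood fits). During gap expansion ants join at a mean rate of
#' 1.13 events per interval and leave at 0.67; during contraction the rates
#' reverse (0.33 joining, 1.04 leaving). The dispersion `theta` follows the
#' ecology convention: variance = mu + mu^2 / theta.
#'
#' These values parameterize the fixed-probability baseline model; pass the
#' tibble to [baseline_model()].
#'
#' @return A tibble with columns `phase`, `kind`, `mu`, `theta`.
#' @seealso [baseline_model()], [fit_nb_counts()]
#' @export
#' @examples
#' eciton_event_params()
eciton_event_params <- function() {
  tibble(
    phase = rep(c("expansion", "contraction"), each = 2L),
    kind  = rep(c("join", "leave"), 2L),
    mu    = c(1.13, 0.67, 0.33, 1.04),
    theta = c(1.33, 1.98, 0.65, 8.10)
  )
}

#' Field-estimated deficit-response parameters
#'
#' Reference parameters of the nonlinear accumulator model: the equilibrium
#' packing density `rho_star` (0.51 ants per mm of gap, the density at which
#' joining and leaving are equally likely), and the slopes and dispersions of
#' the negative binomial regressions of per-interval event counts on the
#' deficit `delta = rho_star * gap - n_ants` (joins increase with deficit,
#' beta = 0.049; leaves decrease, beta = -0.067).
#'
#' The regression intercepts are not part of the published parameter set; they
#' must either be fitted from per-interval data with
#' [fit_deficit_regression()] or derived from per-phase event means with
#' [derive_deficit_intercepts()].
#'
#' @return A list with elements `rho_star` and a tibble `slopes` with columns
#'   `kind`, `beta`, `theta`.
#' @seealso [accumulator_model()], [derive_deficit_intercepts()]
#' @export
eciton_deficit_params <- function() {
  list(
    rho_star = 0.51,
    slopes = tibble(
      kind  = c("join", "leave"),
      beta  = c(0.049, -0.067),
      theta = c(0.773, 1.96)
    )
  )
}

#' Derive accumulator intercepts from per-phase event means
#'
#' The accumulator model needs intercepts `alpha` such that the expected event
#' count at deficit `delta` is `exp(alpha + beta * delta)`. When only
#' per-phase mean event rates are available (rather than per-interval deficit
#' data), the intercepts are recovered by moment matching: writing the
#' expansion-phase mean as the rate at a typical expansion deficit
#' `delta_e` and the contraction mean as the rate at a typical contraction
#' excess `delta_c`, and assuming the two lags are symmetric about equilibrium
#' (`delta_e + delta_c = 0`), the least-squares solution is
#' `alpha = log sqrt(mu_expansion * mu_contraction)` for each kind — the log
#' of the geometric mean of the two phase rates.
#'
#' @param event_params A tibble of per-phase NB parameters as returned by
#'   [eciton_event_params()] or assembled from [fit_nb_counts()] fits.
#' @return A named numeric vector with elements `join` and `leave`, the
#'   intercepts on the log scale.
#' @seealso [accumulator_model()], [eciton_accumulator_model()]
#' @export
#' @examples
#' derive_deficit_intercepts(eciton_event_params())
derive_deficit_intercepts <- function(event_params) {
  stopifnot(is.data.frame(event_params),
            all(c("phase", "kind", "mu") %in% names(event_params)))
  get_mu <- function(kind, phase) {
    mu <- event_params$mu[event_params$kind == kind & event_params$phase == phase]
    if (length(mu) != 1L || !is.finite(mu) || mu <= 0) {
      abort(sprintf("need one positive `mu` for kind '%s', phase '%s'", kind, phase))
    }
    mu
  }
  c(
    join  = mean(log(c(get_mu("join", "expansion"), get_mu("join", "contraction")))),
    leave = mean(log(c(get_mu("leave", "expansion"), get_mu("leave", "contraction"))))
  )
}
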