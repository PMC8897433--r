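#' Tidy and glance methods for fitted objects
#'
#' broom-style accessors: `tidy()` returns one row per estimated term (or
#' per component), `glance()` a one-row model summary.
#'
#' @param x A fitted antbridge object.
#' @param ... Unused.
#' @return A tibble.
#' @name antbridge-tidiers
NULL

#' @rdname antbridge-tidiers
#' @method tidy nb_event_model
#' @export
tidy.nb_event_model <- function(x, ...) {
  tibble(kind = x$kind, phase = x$phase, mu = x$mu, theta = x$theta,
         n_trials = nrow(x$per_trial))
}

#' @rdname antbridge-tidiers
#' @method tidy deficit_regression
#' @export
tidy.deficit_regression <- function(x, ...) {
  tibble(
    term = c("(Intercept)", "deficit"),
    estimate = c(x$alpha, x$beta),
    std.error = x$se
  )
}

#' @rdname antbridge-tidiers
#' @method glance deficit_regression
#' @export
glance.deficit_regression <- function(x, ...) {
  tibble(kind = x$kind, alpha = x$alpha, beta = x$beta, theta = x$theta,
         p.beta = x$p_beta, n = x$n_intervals)
}

#' @rdname antbridge-tidiers
#' @method tidy equilibrium_density
#' @export
tidy.equilibrium_density <- function(x, ...) {
  tibble(
    curve = c("join", "leave"),
    intercept = c(x$join_logit[1], x$leave_logit[1]),
    slope = c(x$join_logit[2], x$leave_logit[2])
  )
}

#' @rdname antbridge-tidiers
#' @method glance equilibrium_density
#' @export
glance.equilibrium_density <- function(x, ...) {
  tibble(rho_star = x$rho_star, n = x$n_intervals)
}

#' @rdname antbridge-tidiers
#' @method tidy hysteresis_result
#' @export
tidy.hysteresis_result <- function(x, ...) {
  tibble(
    extent = x$extent, area_between = x$area_between,
    area_upper = x$area_upper, sign_source = x$sign_source,
    metric = x$metric %||% NA_character_
  )
}

#' @rdname antbridge-tidiers
#' @method tidy resample_result
#' @export
tidy.resample_result <- function(x, ...) {
  tibble(
    signal = x$signal, kind = x$kind, phase = x$phase, window = x$window,
    observed = x$observed, null_mean = mean(x$null_means),
    q_low = x$q_low, q_high = x$q_high,
    p.value = x$p.value, significant = x$significant,
    n_events = x$n_events, n_resamples = x$n_resamples
  )
}

#' One-row summary of a simulation experiment
#'
#' @param x A `bridge_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return A tibble with the model family, simulation count, mean and
#'   negative/positive fractions of the hysteresis extent, and — for
#'   vibration schedules — the extreme and reached-zero fractions.
#' @method glance bridge_experiment
#' @export
glance.bridge_experiment <- function(x, ...) {
  tibble(
    family = x$model$family, n_sims = x$n_sims,
    mean_extent = if (!is.null(x$extents)) mean(x$extents, na.rm = TRUE) else NA_real_,
    frac_negative = x$frac_negative %||% NA_real_,
    frac_positive = x$frac_positive %||% NA_real_,
    frac_extreme = if (!is.null(x$vibration)) x$vibration$frac_extreme else NA_real_,
    frac_zero = if (!is.null(x$vibration)) x$vibration$frac_zero else NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
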