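#' Aggregate a trial into per-interval counts
#'
#' Collapses a trial's per-second structural series and event stream into one
#' row per gap interval: the gap, phase, and ant count at the start of the
#' interval, the numbers of joining and leaving events during it, and
#' whether any second of the interval is flagged broken. All fitting
#' operations work on this representation.
#'
#' @param trial A `trial_record`.
#' @param interval_s Interval length in seconds (default 30).
#' @return A tibble with columns `trial_id`, `interval`, `gap`, `phase`,
#'   `n_start`, `joins`, `leaves`, `broken`.
#' @export
interval_counts <- function(trial, interval_s = 30) {
  stopifnot(inherits(trial, "trial_record"))
  s <- trial$structural
  e <- trial$events
  idx <- s$time %/% interval_s
  starts <- !duplicated(idx)
  ev_idx <- if (nrow(e) > 0L) e$time %/% interval_s else integer()
  per <- tibble(
    trial_id = trial$trial_id,
    interval = idx[starts] + 1L,
    gap = s$gap[starts],
    phase = s$phase[starts],
    n_start = s$n_ants[starts],
    broken = as.logical(tapply(s$broken, idx, any))
  )
  count_kind <- function(kind) {
    k <- ev_idx[e$kind == kind]
    tab <- table(factor(k + 1L, levels = per$interval))
    as.integer(tab)
  }
  per$joins <- count_kind("join")
  per$leaves <- count_kind("leave")
  per[c("trial_id", "interval", "gap", "phase", "n_start", "joins", "leaves", "broken")]
}

# Accept per-interval data as: a single trial_record, a list of them, or a
# pre-aggregated data frame with the interval_counts() columns.
as_interval_data <- function(x, drop_broken_trials = TRUE,
                             broken_trial_threshold = 0.5) {
  if (inherits(x, "trial_record")) x <- list(x)
  if (is.data.frame(x)) {
    need <- c("gap", "phase", "n_start", "joins", "leaves")
    miss <- setdiff(need, names(x))
    if (length(miss) > 0L) {
      abort(sprintf("interval data missing column(s): %s", paste(miss, collapse = ", ")))
    }
    df <- as_tibble(x)
    if (!"broken" %in% names(df)) df$broken <- FALSE
    if (!"trial_id" %in% names(df)) df$trial_id <- "trial"
    return(df)
  }
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1), "trial_record")))
  per <- dplyr::bind_rows(purrr::map(x, interval_counts))
  if (drop_broken_trials) {
    frac <- dplyr::summarise(dplyr::group_by(per, .data$trial_id),
                             frac = mean(.data$broken), .groups = "drop")
    bad <- frac$trial_id[frac$frac > broken_trial_threshold]
    if (length(bad) > 0L) {
      warn(sprintf(
        "dropping mostly-broken trial(s): %s (broken fraction > %.0f%%)",
        paste(bad, collapse = ", "), 100 * broken_trial_threshold
      ))
      per <- per[!per$trial_id %in% bad, ]
    }
  }
  per
}

#' Fit per-phase negative binomial event-count distributions
#'
#' Fits the distribution of per-interval event counts of one kind in one
#' phase to a negative binomial, separately for each trial (mean `mu` by
#' maximum likelihood, dispersion `theta` by profile maximum likelihood),
#' and returns the across-trial medians — the procedure that parameterizes
#' the fixed-probability baseline model. Broken intervals are excluded, and
#' trials that are broken for most of their duration are dropped entirely.
#' Trials with all-zero counts carry no information about `theta`; their
#' dispersion is dropped from the median with a warning.
#'
#' @param trials A `trial_record`, a list of them, or a per-interval data
#'   frame (see [interval_counts()]).
#' @param kind `"join"` or `"leave"`.
#' @param phase `"expansion"` or `"contraction"`.
#' @param theta_max Cap for the dispersion of effectively Poisson samples.
#' @return An `nb_event_model`: list with `mu`, `theta` (across-trial
#'   medians), `kind`, `phase`, and a `per_trial` tibble of the individual
#'   fits.
#' @export
fit_nb_counts <- function(trials, kind = c("join", "leave"),
                          phase = c("expansion", "contraction"),
                          theta_max = 1e6) {
  kind <- match.arg(kind)
  phase <- match.arg(phase)
  per <- as_interval_data(trials)
  per <- per[per$phase == phase & !per$broken, ]
  col <- if (kind == "join") "joins" else "leaves"
  fits <- dplyr::group_map(dplyr::group_by(per, .data$trial_id), function(df, key) {
    if (nrow(df) < 2L) return(NULL)
    f <- nb_fit(df[[col]], theta_max = theta_max)
    tibble(trial_id = key$trial_id, mu = f$mu, theta = f$theta, n_intervals = f$n)
  })
  per_trial <- dplyr::bind_rows(fits)
  if (nrow(per_trial) == 0L) {
    abort(sprintf("no trial has >= 2 usable %s intervals.", phase))
  }
  if (anyNA(per_trial$theta)) {
    warn(sprintf(
      "theta undefined (all-zero counts) for trial(s) %s; dropped from the median.",
      paste(per_trial$trial_id[is.na(per_trial$theta)], collapse = ", ")
    ))
  }
  structure(list(
    mu = median(per_trial$mu),
    theta = median(per_trial$theta, na.rm = TRUE),
    kind = kind, phase = phase, per_trial = per_trial
  ), class = "nb_event_model")
}

#' @export
print.nb_event_model <- function(x, ...) {
  cat(sprintf("<nb_event_model: %s, %s: mu = %.3f, theta = %.3f (%d trials)>\n",
              x$kind, x$phase, x$mu, x$theta, nrow(x$per_trial)))
  invisible(x)
}

#' Refit leaving distributions for a delayed-leaving model
#'
#' If ants execute leave decisions `d` intervals after making them, leaving
#' events observed in the first `d` intervals of the contraction must
#' reflect decisions made during the expansion. This operation reassigns
#' those events to the expansion phase, trial by trial, and refits the
#' per-phase negative binomial leaving distributions. Joining distributions
#' are never delay-adjusted.
#'
#' @inheritParams fit_nb_counts
#' @param d Delay in intervals, between 1 and 6.
#' @return A list with `expansion` and `contraction` `nb_event_model`s (kind
#'   `"leave"`) and the delay `d`.
#' @seealso [delay_event_params()] to assemble a full parameter table for
#'   [delay_model()].
#' @export
apply_delay_reassignment <- function(trials, d, theta_max = 1e6) {
  if (!is.numeric(d) || length(d) != 1L || d != round(d) || d < 1 || d > 6) {
    abort("`d` must be an integer delay between 1 and 6 intervals (the delay model is only defined for d >= 1).")
  }
  per <- as_interval_data(trials)
  per <- dplyr::mutate(
    dplyr::group_by(per, .data$trial_id),
    contraction_rank = cumsum(.data$phase == "contraction"),
    phase = ifelse(.data$phase == "contraction" & .data$contraction_rank <= d,
                   "expansion", .data$phase)
  )
  per <- dplyr::select(dplyr::ungroup(per), -"contraction_rank")
  list(
    expansion = fit_nb_counts(per, kind = "leave", phase = "expansion",
                              theta_max = theta_max),
    contraction = fit_nb_counts(per, kind = "leave", phase = "contraction",
                                theta_max = theta_max),
    d = as.integer(d)
  )
}

#' Assemble delay-consistent event parameters
#'
#' Combines joining distributions fitted from the unmodified data with
#' leaving distributions refit under the delay reassignment, yielding the
#' parameter table a [delay_model()] of the same `d` requires.
#'
#' @inheritParams apply_delay_reassignment
#' @param join_params Optional tibble of join-phase NB parameters (columns
#'   `phase`, `kind`, `mu`, `theta`); fitted from `trials` when `NULL`.
#' @return A params tibble with a `delay_d` attribute.
#' @export
delay_event_params <- function(trials, d, join_params = NULL, theta_max = 1e6) {
  leaves <- apply_delay_reassignment(trials, d, theta_max = theta_max)
  if (is.null(join_params)) {
    join_params <- dplyr::bind_rows(purrr::map(
      c("expansion", "contraction"),
      function(ph) {
        f <- fit_nb_counts(trials, kind = "join", phase = ph, theta_max = theta_max)
        tibble(phase = ph, kind = "join", mu = f$mu, theta = f$theta)
      }
    ))
  }
  out <- dplyr::bind_rows(
    join_params[join_params$kind == "join", c("phase", "kind", "mu", "theta")],
    tibble(phase = c("expansion", "contraction"), kind = "leave",
           mu = c(leaves$expansion$mu, leaves$contraction$mu),
           theta = c(leaves$expansion$theta, leaves$contraction$theta))
  )
  attr(out, "delay_d") <- as.integer(d)
  out
}

#' Estimate the equilibrium packing density
#'
#' Fits logistic regressions of per-interval event occurrence (at least one
#' joining, respectively leaving, event) on packing density (ants per mm of
#' gap) and locates the density at which the two fitted probabilities are
#' equal — the equilibrium packing density `rho_star` at which an ant is as
#' likely to join as to leave. Intervals with zero gap (packing density
#' undefined) and broken intervals are excluded. The root is found on the
#' difference of the two linear predictors, bracketed within the observed
#' density range.
#'
#' @inheritParams fit_nb_counts
#' @return An `equilibrium_density`: list with `rho_star`, `join_logit` and
#'   `leave_logit` (each `c(intercept, slope)`), and the two `glm` fits.
#' @export
estimate_equilibrium_density <- function(trials) {
  per <- as_interval_data(trials)
  per <- per[!per$broken & per$gap > 0, ]
  if (nrow(per) < 4L) abort("too few usable intervals with gap > 0.")
  per$rho <- per$n_start / per$gap
  fit_j <- glm(I(joins >= 1) ~ rho, data = per, family = binomial())
  fit_l <- glm(I(leaves >= 1) ~ rho, data = per, family = binomial())
  cj <- coef(fit_j); cl <- coef(fit_l)
  f <- function(rho) (cj[1] + cj[2] * rho) - (cl[1] + cl[2] * rho)
  hi <- max(per$rho)
  if (f(0) * f(hi) > 0) {
    abort(sprintf(
      paste0("no equilibrium: joining and leaving probabilities do not ",
             "intersect within [0, %.3f] (join logit: %.3f %+.3f rho; ",
             "leave logit: %.3f %+.3f rho)."),
      hi, cj[1], cj[2], cl[1], cl[2]
    ))
  }
  root <- uniroot(f, c(0, hi), tol = 1e-12)$root
  structure(list(
    rho_star = root,
    join_logit = unname(cj), leave_logit = unname(cl),
    join_fit = fit_j, leave_fit = fit_l,
    n_intervals = nrow(per), rho_range = c(0, hi)
  ), class = "equilibrium_density")
}

#' @export
print.equilibrium_density <- function(x, ...) {
  cat(sprintf("<equilibrium_density: rho* = %.3f ants/mm (%d intervals)>\n",
              x$rho_star, x$n_intervals))
  cat(sprintf("  join logit: %.3f %+.3f rho\n", x$join_logit[1], x$join_logit[2]))
  cat(sprintf("  leave logit: %.3f %+.3f rho\n", x$leave_logit[1], x$leave_logit[2]))
  invisible(x)
}

#' Negative binomial regression of event counts on the deficit
#'
#' Computes the per-interval deficit `delta = rho_star * gap - n_start` (the
#' equilibrium ant count for the current gap minus the actual count at the
#' start of the interval; positive = too few ants) and fits a log-link
#' negative binomial regression of event counts on it. The dispersion
#' `theta` is estimated once per kind, constant across deficit values. The
#' fitted regressions parameterize the accumulator model.
#'
#' @inheritParams fit_nb_counts
#' @param rho_star Equilibrium packing density (ants/mm), e.g. from
#'   [estimate_equilibrium_density()].
#' @return A `deficit_regression`: list with `alpha` (intercept), `beta`
#'   (slope per ant of deficit), `theta`, `kind`, standard errors and the
#'   underlying `glm.nb` fit.
#' @export
fit_deficit_regression <- function(trials, rho_star, kind = c("join", "leave")) {
  kind <- match.arg(kind)
  assert_scalar_number(rho_star, "rho_star", lower = .Machine$double.eps)
  per <- as_interval_data(trials)
  per <- per[!per$broken, ]
  per$deficit <- rho_star * per$gap - per$n_start
  per$count <- if (kind == "join") per$joins else per$leaves
  if (nrow(per) < 10L) abort("too few usable intervals for a deficit regression.")
  if (sd(per$deficit) < 1e-8) {
    abort("degenerate deficit range: all deficits are (nearly) equal.")
  }
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(count ~ deficit, data = per)),
    error = function(e) {
      abort(sprintf(
        "deficit regression failed for kind '%s': %s (deficit range [%.2f, %.2f], mean count %.3f)",
        kind, conditionMessage(e), min(per$deficit), max(per$deficit), mean(per$count)
      ))
    }
  )
  sm <- summary(fit)
  structure(list(
    alpha = unname(coef(fit)[1]), beta = unname(coef(fit)[2]),
    theta = fit$theta, kind = kind,
    se = unname(sm$coefficients[, "Std. Error"]),
    p_beta = unname(sm$coefficients["deficit", "Pr(>|z|)"]),
    n_intervals = nrow(per), fit = fit
  ), class = "deficit_regression")
}

#' @export
print.deficit_regression <- function(x, ...) {
  cat(sprintf(
    "<deficit_regression: %s: mu(delta) = exp(%.3f %+.4f delta), theta = %.3f (%d intervals)>\n",
    x$kind, x$alpha, x$beta, x$theta, x$n_intervals
  ))
  invisible(x)
}

#' Dispersion profile of a deficit regression
#'
#' Diagnostic mirroring the residual check behind the constant-dispersion
#' assumption: bins the model frame by deficit and reports the mean and
#' variance of the Pearson residuals per bin. Roughly unit variances with no
#' trend across bins support a single `theta` for all deficit values.
#'
#' @param reg A `deficit_regression`.
#' @param bins Number of deficit bins (default 6).
#' @return A tibble with `bin`, `deficit_mid`, `n`, `resid_mean`,
#'   `resid_var`.
#' @export
deficit_dispersion_profile <- function(reg, bins = 6L) {
  stopifnot(inherits(reg, "deficit_regression"))
  mf <- reg$fit$model
  r <- residuals(reg$fit, type = "pearson")
  cut_pts <- quantile(mf$deficit, probs = seq(0, 1, length.out = bins + 1L))
  grp <- cut(mf$deficit, unique(cut_pts), include.lowest = TRUE)
  dplyr::summarise(
    dplyr::group_by(tibble(grp = grp, deficit = mf$deficit, r = r), .data$grp),
    deficit_mid = mean(.data$deficit), n = dplyr::n(),
    resid_mean = mean(.data$r), resid_var = var(.data$r),
    .groups = "drop"
  )
}
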