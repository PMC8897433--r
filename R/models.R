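#' Bridge model constructors
#'
#' The three stochastic models of ants joining and leaving a bridge share a
#' discrete-time skeleton: at every gap interval the numbers of joining and
#' leaving events are drawn from negative binomial distributions, and leaving
#' is clamped so the bridge never holds a negative number of ants.
#'
#' * **baseline** — fixed per-phase probabilities: joins and leaves are drawn
#'   from NB distributions whose (mu, theta) depend only on the phase
#'   (expansion or contraction).
#' * **delay** — as baseline, except that leave *decisions* drawn in interval
#'   `t` are executed `d` intervals later. The NB parameters must come from a
#'   delay-consistent refit ([apply_delay_reassignment()]), which counts
#'   early-contraction leaves as expansion decisions.
#' * **accumulator** — dynamic probabilities: the expected counts are
#'   log-linear in the deficit `delta = rho_star * gap - n_ants`, so a
#'   stretched bridge (positive deficit) attracts joiners and a slack bridge
#'   (excess ants) sheds them.
#'
#' @param params Tibble of per-phase NB parameters with columns `phase`,
#'   `kind`, `mu`, `theta` (see [eciton_event_params()]); rows for join/leave
#'   in both expansion and contraction are required.
#' @param d Leaving delay in gap intervals, between 1 and 6.
#' @param join,leave For the accumulator: lists (or [fit_deficit_regression()]
#'   results) with elements `alpha`, `beta`, `theta`.
#' @param rho_star Equilibrium packing density in ants per mm of gap.
#' @param clamp When leaving would push the count negative: `"post_join"`
#'   (default) clamps executed leaves to the interval-start count plus this
#'   interval's joins; `"start"` clamps to the interval-start count alone.
#' @return A `bridge_model` object.
#' @name bridge_models
NULL

new_bridge_model <- function(family, ..., clamp) {
  structure(list(family = family, ..., clamp = clamp), class = "bridge_model")
}

check_event_params <- function(params) {
  stopifnot(is.data.frame(params))
  need <- c("phase", "kind", "mu", "theta")
  if (!all(need %in% names(params))) {
    abort("`params` needs columns phase, kind, mu, theta.")
  }
  for (ph in c("expansion", "contraction")) {
    for (k in c("join", "leave")) {
      row <- params[params$phase == ph & params$kind == k, ]
      if (nrow(row) != 1L) abort(sprintf("`params` needs exactly one (%s, %s) row.", ph, k))
      if (!is.finite(row$mu) || row$mu < 0) abort("`mu` must be finite and >= 0.")
      if (!is.finite(row$theta) || row$theta <= 0) abort("`theta` must be finite and > 0.")
    }
  }
  params
}

param_lookup <- function(params, kind) {
  p <- params[params$kind == kind, ]
  list(
    mu = setNames(p$mu, p$phase),
    theta = setNames(p$theta, p$phase)
  )
}

#' @rdname bridge_models
#' @export
baseline_model <- function(params = eciton_event_params(),
                           clamp = c("post_join", "start")) {
  clamp <- match.arg(clamp)
  params <- check_event_params(params)
  new_bridge_model("baseline", params = params, clamp = clamp)
}

#' @rdname bridge_models
#' @export
delay_model <- function(params, d, clamp = c("post_join", "start")) {
  clamp <- match.arg(clamp)
  if (!is.numeric(d) || length(d) != 1L || d != round(d) || d < 1 || d > 6) {
    abort("`d` must be an integer delay between 1 and 6 intervals.")
  }
  params <- check_event_params(params)
  if (!is.null(attr(params, "delay_d")) && attr(params, "delay_d") != d) {
    abort(sprintf(
      "`params` were refit for a delay of %d intervals but `d` = %d.",
      attr(params, "delay_d"), d
    ))
  }
  new_bridge_model("delay", params = params, d = as.integer(d), clamp = clamp)
}

check_deficit_part <- function(x, name) {
  if (inherits(x, "deficit_regression")) {
    x <- list(alpha = x$alpha, beta = x$beta, theta = x$theta)
  }
  if (!is.list(x) || !all(c("alpha", "beta", "theta") %in% names(x))) {
    abort(sprintf("`%s` needs elements alpha, beta, theta.", name))
  }
  if (!is.finite(x$theta) || x$theta <= 0) abort(sprintf("`%s$theta` must be > 0.", name))
  if (!is.finite(x$alpha) || !is.finite(x$beta)) {
    abort(sprintf("`%s` alpha and beta must be finite.", name))
  }
  x[c("alpha", "beta", "theta")]
}

#' @rdname bridge_models
#' @export
accumulator_model <- function(join, leave, rho_star,
                              clamp = c("post_join", "start")) {
  clamp <- match.arg(clamp)
  assert_scalar_number(rho_star, "rho_star", lower = .Machine$double.eps)
  new_bridge_model("accumulator",
    join = check_deficit_part(join, "join"),
    leave = check_deficit_part(leave, "leave"),
    rho_star = rho_star, clamp = clamp
  )
}

#' Reference accumulator model for Eciton hamatum bridges
#'
#' Accumulator model assembled from the field-estimated deficit-regression
#' slopes and dispersions ([eciton_deficit_params()]) and intercepts derived
#' from the per-phase event means by symmetric-lag moment matching
#' ([derive_deficit_intercepts()]).
#'
#' @inheritParams bridge_models
#' @return A `bridge_model` of family `"accumulator"`.
#' @export
eciton_accumulator_model <- function(clamp = c("post_join", "start")) {
  dp <- eciton_deficit_params()
  alpha <- derive_deficit_intercepts(eciton_event_params())
  sl <- function(k) dp$slopes[dp$slopes$kind == k, ]
  accumulator_model(
    join = list(alpha = alpha[["join"]], beta = sl("join")$beta, theta = sl("join")$theta),
    leave = list(alpha = alpha[["leave"]], beta = sl("leave")$beta, theta = sl("leave")$theta),
    rho_star = dp$rho_star,
    clamp = match.arg(clamp)
  )
}

#' Expected event rate of an accumulator model at a given deficit
#'
#' Evaluates `exp(alpha + beta * deficit)`, the expected number of events per
#' 30-s interval at the given deviation from the equilibrium ant count
#' (positive deficit = too few ants).
#'
#' @param model An accumulator `bridge_model`.
#' @param deficit Numeric vector of deficits (ants).
#' @param kind `"join"` or `"leave"`.
#' @return Numeric vector of expected event counts.
#' @export
#' @examples
#' m <- eciton_accumulator_model()
#' predict_event_rate(m, deficit = c(0, 5, 10), kind = "join")
predict_event_rate <- function(model, deficit, kind = c("join", "leave")) {
  kind <- match.arg(kind)
  stopifnot(inherits(model, "bridge_model"))
  if (model$family != "accumulator") {
    abort("`predict_event_rate()` is defined for accumulator models.")
  }
  part <- model[[kind]]
  exp(part$alpha + part$beta * deficit)
}

#' @export
print.bridge_model <- function(x, ...) {
  cat(sprintf("<bridge_model: %s>\n", x$family))
  if (x$family %in% c("baseline", "delay")) {
    if (x$family == "delay") cat(sprintf("  leaving delay: %d intervals\n", x$d))
    p <- x$params
    for (i in seq_len(nrow(p))) {
      cat(sprintf("  %-11s %-5s mu = %.3f, theta = %.3f\n",
                  p$phase[i], p$kind[i], p$mu[i], p$theta[i]))
    }
  } else {
    cat(sprintf("  rho_star = %.3f ants/mm\n", x$rho_star))
    for (k in c("join", "leave")) {
      cat(sprintf("  %-5s alpha = %.3f, beta = %.3f, theta = %.3f\n",
                  k, x[[k]]$alpha, x[[k]]$beta, x[[k]]$theta))
    }
  }
  cat(sprintf("  leave clamp: %s\n", x$clamp))
  invisible(x)
}
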