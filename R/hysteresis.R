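#' Smooth expansion and contraction response curves
#'
#' Fits a LOESS local regression of a bridge metric against gap size
#' separately for the expansion and the contraction phase, and evaluates both
#' fits on a common uniform gap grid restricted to the range of gaps observed
#' in both phases. Vibration-phase and broken samples should be excluded
#' upstream.
#'
#' @param data A data frame with columns `gap`, `phase`, and the metric named
#'   by `value` (e.g. a [run_simulation()] trajectory or per-second trial
#'   samples).
#' @param value Column holding the metric (tidy evaluation; default
#'   `n_ants`).
#' @param span LOESS span (default 0.75).
#' @param grid_step Evaluation grid spacing in mm (default 0.5).
#' @param degree LOESS polynomial degree (default 2).
#' @param min_samples Minimum samples required per phase (default 10).
#' @return A `phase_curves` tibble with columns `gap`, `expansion`,
#'   `contraction`.
#' @export
#' @examples
#' traj <- run_simulation(baseline_model(), build_schedule(), seed = 1)
#' curves <- smooth_phase_curves(traj)
#' extent_of_hysteresis(curves)
smooth_phase_curves <- function(data, value = "n_ants", span = 0.75,
                                grid_step = 0.5, degree = 2,
                                min_samples = 10L) {
  stopifnot(is.data.frame(data), all(c("gap", "phase") %in% names(data)))
  value <- tidyselect_one(data, rlang::enquo(value), default = "n_ants")
  fits <- list()
  for (ph in c("expansion", "contraction")) {
    sub <- data[data$phase == ph & is.finite(data[[value]]), ]
    if (nrow(sub) < min_samples) {
      abort(sprintf("fewer than %d usable samples in the %s phase.", min_samples, ph))
    }
    fits[[ph]] <- sub
  }
  lo <- max(min(fits$expansion$gap), min(fits$contraction$gap))
  hi <- min(max(fits$expansion$gap), max(fits$contraction$gap))
  if (hi <= lo) abort("expansion and contraction gap ranges do not overlap.")
  grid <- seq(lo, hi, by = grid_step)
  smooth_one <- function(sub) {
    df <- data.frame(g = sub$gap, v = sub[[value]])
    fit <- loess(v ~ g, data = df, span = span, degree = degree)
    as.numeric(predict(fit, data.frame(g = grid)))
  }
  out <- tibble(
    gap = grid,
    expansion = smooth_one(fits$expansion),
    contraction = smooth_one(fits$contraction)
  )
  class(out) <- c("phase_curves", class(out))
  attr(out, "metric") <- value
  attr(out, "span") <- span
  out
}

# resolve a column given either a quosure (symbol or string) or default
tidyselect_one <- function(data, quo, default) {
  expr <- rlang::quo_get_expr(quo)
  name <- if (rlang::is_symbol(expr)) rlang::as_string(expr)
          else if (is.character(expr)) expr
          else if (is.null(expr)) default
          else rlang::as_string(expr)
  if (!name %in% names(data)) abort(sprintf("column `%s` not found.", name))
  name
}

#' Extent of hysteresis between phase curves
#'
#' The extent of hysteresis is the area between the smoothed expansion and
#' contraction curves, normalized by the area under the higher curve (the one
#' with the larger area under it). It is a unitless, signed proportion in
#' \[-1, 1\]: negative when the expansion curve is higher on average — i.e.,
#' when the area under the expansion curve is larger — and positive when the
#' contraction curve dominates, as observed in real bridges. Areas are
#' trapezoidal integrals over the common gap grid.
#'
#' @param curves A `phase_curves` tibble from [smooth_phase_curves()].
#' @return A `hysteresis_result` list with elements `extent`, `area_between`,
#'   `area_upper`, `sign_source` (`"contraction_higher"` or
#'   `"expansion_higher"`), and `reason` (`NA` unless the extent is
#'   undefined because both curves enclose zero area).
#' @export
extent_of_hysteresis <- function(curves) {
  stopifnot(is.data.frame(curves),
            all(c("gap", "expansion", "contraction") %in% names(curves)))
  ok <- is.finite(curves$expansion) & is.finite(curves$contraction)
  curves <- curves[ok, ]
  if (nrow(curves) < 2L) abort("need at least 2 finite grid points.")
  a_exp <- area_under(curves$gap, curves$expansion)
  a_con <- area_under(curves$gap, curves$contraction)
  a_between <- area_under(curves$gap, abs(curves$contraction - curves$expansion))
  a_upper <- max(a_exp, a_con)
  if (a_upper <= 0) {
    res <- list(extent = NA_real_, area_between = a_between, area_upper = a_upper,
                sign_source = NA_character_,
                reason = "both curves enclose zero area; extent undefined")
  } else {
    sgn <- if (a_con >= a_exp) 1 else -1
    res <- list(
      extent = sgn * a_between / a_upper,
      area_between = a_between, area_upper = a_upper,
      sign_source = if (sgn > 0) "contraction_higher" else "expansion_higher",
      reason = NA_character_
    )
  }
  res$metric <- attr(curves, "metric")
  res$span <- attr(curves, "span")
  structure(res, class = "hysteresis_result")
}

#' @export
print.hysteresis_result <- function(x, ...) {
  if (is.na(x$extent)) {
    cat(sprintf("<hysteresis_result: undefined (%s)>\n", x$reason))
  } else {
    cat(sprintf("<hysteresis_result: extent %.3f (%s)>\n", x$extent, x$sign_source))
  }
  invisible(x)
}

#' Hysteresis extent straight from phase-labelled samples
#'
#' Convenience wrapper: smooths the samples with [smooth_phase_curves()] and
#' measures the extent with [extent_of_hysteresis()].
#'
#' @inheritParams smooth_phase_curves
#' @param smooth Apply LOESS smoothing? `FALSE` skips smoothing for data that
#'   already hold one value per (gap, phase), interpolating the raw points on
#'   the common grid instead.
#' @return A `hysteresis_result`.
#' @export
hysteresis_extent <- function(data, value = "n_ants", span = 0.75,
                              grid_step = 0.5, smooth = TRUE) {
  value <- tidyselect_one(data, rlang::enquo(value), default = "n_ants")
  if (!smooth) {
    curves <- raw_phase_curves(data, value, grid_step)
    return(extent_of_hysteresis(curves))
  }
  extent_of_hysteresis(
    smooth_phase_curves(data, value = !!rlang::sym(value), span = span,
                        grid_step = grid_step)
  )
}

# unsmoothed variant: linear interpolation of per-(gap, phase) means
raw_phase_curves <- function(data, value, grid_step = 0.5) {
  agg <- dplyr::summarise(
    dplyr::group_by(data[data$phase %in% c("expansion", "contraction"), ],
                    .data$phase, .data$gap),
    v = mean(.data[[value]]), .groups = "drop"
  )
  e <- agg[agg$phase == "expansion", ]
  c_ <- agg[agg$phase == "contraction", ]
  lo <- max(min(e$gap), min(c_$gap)); hi <- min(max(e$gap), max(c_$gap))
  grid <- seq(lo, hi, by = grid_step)
  out <- tibble(
    gap = grid,
    expansion = stats::approx(e$gap, e$v, xout = grid)$y,
    contraction = stats::approx(c_$gap, c_$v, xout = grid)$y
  )
  class(out) <- c("phase_curves", class(out))
  attr(out, "metric") <- value
  out
}

# fast path used by run_experiment: samples as parallel vectors
extent_from_samples <- function(gap, value, phase, span = 0.75, grid_step = 0.5) {
  tryCatch({
    df <- tibble(gap = gap, n_ants = value, phase = phase)
    extent_of_hysteresis(
      smooth_phase_curves(df, span = span, grid_step = grid_step)
    )$extent
  }, error = function(e) NA_real_)
}

#' One-sample t-test on per-trial hysteresis extents
#'
#' Two-tailed one-sample t-test of the per-trial extents of hysteresis
#' against zero, the across-trial test used to establish that real bridges
#' are consistently hysteretic.
#'
#' @param extents Numeric vector of per-trial extents (length >= 2).
#' @param conf_level Confidence level (default 0.95).
#' @return A `hysteresis_test` tibble with columns `estimate`, `conf.low`,
#'   `conf.high`, `statistic`, `df`, `p.value`, `n`.
#' @export
#' @examples
#' hysteresis_ttest(c(0.31, 0.18, 0.4, 0.22, 0.35))
hysteresis_ttest <- function(extents, conf_level = 0.95) {
  extents <- extents[is.finite(extents)]
  if (length(extents) < 2L) abort("need at least 2 finite extents.")
  if (sd(extents) == 0) {
    abort(sprintf(
      "all extents equal %.4g: zero variance, the t-test is degenerate.", extents[1]
    ))
  }
  tt <- t.test(extents, mu = 0, conf.level = conf_level)
  out <- tibble(
    estimate = unname(tt$estimate),
    conf.low = tt$conf.int[1], conf.high = tt$conf.int[2],
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p.value = tt$p.value, n = length(extents)
  )
  class(out) <- c("hysteresis_test", class(out))
  out
}

#' Correlation between bridge volume and number of ants
#'
#' Pearson product–moment correlation of the per-second bridge volume against
#' the number of ants in the bridge, over non-broken seconds. In the field
#' trials this correlation is high (0.88–0.98), indicating a consistent
#' density of ants per unit bridge volume.
#'
#' @param trial A `trial_record`.
#' @return The Pearson correlation coefficient (scalar).
#' @export
correlate_volume_ants <- function(trial) {
  stopifnot(inherits(trial, "trial_record"))
  s <- trial$structural[!trial$structural$broken, ]
  if (nrow(s) < 3L) abort("need at least 3 non-broken seconds.")
  if (sd(s$volume) == 0 || sd(s$n_ants) == 0) {
    abort("zero variance in volume or n_ants: correlation undefined.")
  }
  cor(s$volume, s$n_ants)
}
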