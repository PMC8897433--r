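#' Construct a gap schedule
#'
#' A gap schedule is the sequence of gap sizes driving one trial or
#' simulation: one row per 30-s gap interval with the gap (mm) held during
#' that interval and the experimental phase. The standard
#' expansion–contraction protocol opens the gap from 0 to `max_gap` in `step`
#' increments (one per interval) and then closes it again:
#' `max_gap / step + 1` expansion intervals followed by `max_gap / step`
#' contraction intervals (61 intervals for the 30-mm, 1-mm default). The
#' vibration protocol inserts a block between the phases in which the gap
#' alternates between `max_gap - step` and `max_gap`, emulating small
#' momentary terrain shifts.
#'
#' @param protocol `"expansion_contraction"` or `"vibration"`.
#' @param max_gap Maximum gap size in mm (default 30). Must be a multiple of
#'   `step`.
#' @param step Gap change per interval in mm (default 1).
#' @param interval Interval duration in seconds (default 30).
#' @param vib_steps Number of vibration intervals; defaults to 60 (30 min)
#'   for the vibration protocol and 0 otherwise.
#' @return A `gap_schedule` tibble with columns `interval`, `gap`, `phase`,
#'   `duration`.
#' @seealso [gap_schedule()] for fully custom schedules.
#' @export
#' @examples
#' build_schedule()                      # 61 intervals, 0..30..0 mm
#' build_schedule("vibration", vib_steps = 10)
build_schedule <- function(protocol = c("expansion_contraction", "vibration"),
                           max_gap = 30, step = 1, interval = 30,
                           vib_steps = NULL) {
  protocol <- match.arg(protocol)
  assert_scalar_number(max_gap, "max_gap", lower = .Machine$double.eps)
  assert_scalar_number(step, "step", lower = .Machine$double.eps)
  assert_scalar_number(interval, "interval", lower = .Machine$double.eps)
  n_up <- max_gap / step
  if (abs(n_up - round(n_up)) > 1e-8) {
    abort("`max_gap` must be a multiple of `step`.")
  }
  n_up <- round(n_up)
  if (is.null(vib_steps)) {
    vib_steps <- if (protocol == "vibration") 60L else 0L
  }
  assert_scalar_number(vib_steps, "vib_steps", lower = 0)
  if (protocol == "vibration" && vib_steps < 1) {
    abort("the vibration protocol needs `vib_steps` >= 1.")
  }
  if (protocol == "expansion_contraction" && vib_steps != 0) {
    abort("`vib_steps` must be 0 for the expansion_contraction protocol.")
  }
  gap <- c(
    seq(0, max_gap, by = step),
    rep_len(c(max_gap - step, max_gap), vib_steps),
    seq(max_gap - step, 0, by = -step)
  )
  phase <- rep(PHASES, c(n_up + 1L, vib_steps, n_up))
  gap_schedule(gap, phase, duration = interval, step = step)
}

#' Assemble a gap schedule from raw gap and phase vectors
#'
#' Lower-level constructor for schedules that [build_schedule()] does not
#' cover (e.g. a constant-gap hold used to probe stationarity). Validates the
#' schedule invariants: non-negative gaps, a constant positive interval
#' duration, phase labels forming contiguous blocks in the order expansion,
#' vibration, contraction (each block optional), and consecutive gaps
#' differing by at most the schedule's step size.
#'
#' @param gap Numeric vector of gap sizes (mm), one per interval.
#' @param phase Character vector of phase labels, same length as `gap`.
#' @param duration Interval duration in seconds (default 30).
#' @param step Step size in mm that consecutive gaps may differ by; inferred
#'   as the smallest non-zero gap change when `NULL`.
#' @return A `gap_schedule` tibble.
#' @export
gap_schedule <- function(gap, phase, duration = 30, step = NULL) {
  if (length(gap) != length(phase) || length(gap) == 0L) {
    abort("`gap` and `phase` must be non-empty vectors of equal length.")
  }
  if (any(!is.finite(gap)) || any(gap < 0)) abort("gaps must be finite and >= 0.")
  if (!all(phase %in% PHASES)) {
    abort(sprintf("phase labels must be among: %s", paste(PHASES, collapse = ", ")))
  }
  blocks <- rle(phase)$values
  if (anyDuplicated(blocks) || !identical(blocks, PHASES[PHASES %in% blocks])) {
    abort("phases must form contiguous blocks in the order expansion, vibration, contraction.")
  }
  assert_scalar_number(duration, "duration", lower = .Machine$double.eps)
  deltas <- abs(diff(gap))
  if (is.null(step)) {
    step <- if (any(deltas > 0)) min(deltas[deltas > 0]) else 0
  }
  if (any(deltas > step + 1e-8)) {
    abort("consecutive gaps must differ by at most the schedule's step size.")
  }
  out <- tibble(
    interval = seq_along(gap),
    gap = as.numeric(gap),
    phase = as.character(phase),
    duration = duration
  )
  class(out) <- c("gap_schedule", class(out))
  attr(out, "step") <- step
  out
}

# Phase used for per-phase (linear-model) parameter lookup: vibration
# intervals take contraction parameters when the gap just decreased and
# expansion parameters when it increased (or held), since the linear models
# are defined only per phase.
effective_phase <- function(schedule) {
  ph <- schedule$phase
  d <- c(0, diff(schedule$gap))
  vib <- ph == "vibration"
  ph[vib] <- ifelse(d[vib] < 0, "contraction", "expansion")
  ph
}

# total scheduled time in seconds
schedule_span <- function(schedule) sum(schedule$duration)
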