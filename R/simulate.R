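# Vectorized simulation engine: all n_sims bridges advance together through
# the schedule. State is the ant count at the start of each interval; joins
# are applied before leaves, and executed leaves are clamped so counts never
# go negative (clamp rule set on the model).
simulate_engine <- function(model, schedule, n_sims, seed = NULL, n0 = 0L) {
  stopifnot(inherits(model, "bridge_model"))
  if (!inherits(schedule, "gap_schedule")) {
    schedule <- gap_schedule(schedule$gap, schedule$phase,
                             duration = schedule$duration[1],
                             step = attr(schedule, "step"))
  }
  if (!is.numeric(n_sims) || n_sims < 1) abort("`n_sims` must be >= 1.")
  n_sims <- as.integer(n_sims)
  if (!is.null(seed)) set.seed(seed)

  n_t <- nrow(schedule)
  gap <- schedule$gap
  eff <- effective_phase(schedule)
  N <- rep(as.numeric(n0), length.out = n_sims)

  n_mat <- matrix(0, n_sims, n_t)
  joins_drawn <- matrix(0L, n_sims, n_t)
  leaves_drawn <- matrix(0L, n_sims, n_t)
  joins_mat <- matrix(0L, n_sims, n_t)
  leaves_mat <- matrix(0L, n_sims, n_t)

  family <- model$family
  if (family %in% c("baseline", "delay")) {
    pj <- param_lookup(model$params, "join")
    pl <- param_lookup(model$params, "leave")
  }
  d <- if (family == "delay") model$d else 0L

  for (t in seq_len(n_t)) {
    ph <- eff[t]
    if (family == "accumulator") {
      delta <- model$rho_star * gap[t] - N
      j <- nb_draw(n_sims, mu = exp(model$join$alpha + model$join$beta * delta),
                   theta = model$join$theta)
      l_drawn <- nb_draw(n_sims, mu = exp(model$leave$alpha + model$leave$beta * delta),
                         theta = model$leave$theta)
      l_due <- l_drawn
    } else {
      j <- nb_draw(n_sims, mu = pj$mu[[ph]], theta = pj$theta[[ph]])
      l_drawn <- nb_draw(n_sims, mu = pl$mu[[ph]], theta = pl$theta[[ph]])
      # delay model: decisions drawn now execute d intervals later; the
      # queue is empty at the start of the run
      l_due <- if (family == "delay") {
        if (t > d) leaves_drawn[, t - d] else rep(0L, n_sims)
      } else {
        l_drawn
      }
    }
    cap <- if (model$clamp == "post_join") N + j else N
    l_exec <- pmin(l_due, cap)
    N <- N + j - l_exec

    n_mat[, t] <- N
    joins_drawn[, t] <- j
    leaves_drawn[, t] <- l_drawn
    joins_mat[, t] <- j
    leaves_mat[, t] <- as.integer(l_exec)
  }

  list(
    schedule = schedule, n = n_mat,
    joins_drawn = joins_drawn, leaves_drawn = leaves_drawn,
    joins = joins_mat, leaves = leaves_mat,
    seed = seed, model = model
  )
}

#' Simulate one bridge trajectory
#'
#' Runs a single discrete-time simulation of a bridge model over a gap
#' schedule. The bridge starts empty; at every interval joining and leaving
#' events are drawn from the model's negative binomial distributions, joins
#' are applied first, and executed leaves are clamped so the ant count never
#' goes negative. Both the raw draws and the executed (post-clamp) counts are
#' recorded so alternative clamping rules can be replayed.
#'
#' @param model A `bridge_model` (see [baseline_model()], [delay_model()],
#'   [accumulator_model()]).
#' @param schedule A `gap_schedule` (see [build_schedule()]).
#' @param seed Optional integer seed; identical (model, schedule, seed) give
#'   bit-identical trajectories.
#' @param n0 Ant count at the start of the run (0 in the study design).
#' @return A `bridge_trajectory` tibble with one row per interval: `interval`,
#'   `gap`, `phase`, `joins_drawn`, `leaves_drawn` (pre-clamp; leave
#'   *decisions* for the delay model), `joins`, `leaves` (executed), and
#'   `n_ants` (count at the end of the interval).
#' @export
#' @examples
#' traj <- run_simulation(baseline_model(), build_schedule(), seed = 1)
#' tail(traj, 3)
run_simulation <- function(model, schedule, seed = NULL, n0 = 0L) {
  res <- simulate_engine(model, schedule, n_sims = 1L, seed = seed, n0 = n0)
  out <- tibble(
    interval = res$schedule$interval,
    gap = res$schedule$gap,
    phase = res$schedule$phase,
    joins_drawn = res$joins_drawn[1, ],
    leaves_drawn = res$leaves_drawn[1, ],
    joins = res$joins[1, ],
    leaves = res$leaves[1, ],
    n_ants = res$n[1, ]
  )
  class(out) <- c("bridge_trajectory", class(out))
  attr(out, "model_id") <- model$family
  attr(out, "seed") <- seed
  out
}

#' Run a simulation experiment
#'
#' Simulates `n_sims` bridges over a schedule and summarizes them: the mean
#' ant count per interval, the per-simulation hysteresis extent (for
#' schedules with both an expansion and a contraction phase), the fractions
#' of simulations with negative and positive hysteresis, and — when the
#' schedule contains a vibration block — the fraction of simulations that at
#' some vibration interval become "extreme" (fewer than 5 or more than 25
#' ants) and the fraction that reach zero ants during vibration.
#'
#' @inheritParams run_simulation
#' @param n_sims Number of simulations (>= 1).
#' @param span LOESS span used for the hysteresis extent (see
#'   [extent_of_hysteresis()]).
#' @param grid_step Gap grid spacing (mm) for the smoothed phase curves.
#' @param compute_extents Compute per-simulation hysteresis extents? Defaults
#'   to `TRUE` when the schedule has both phases.
#' @param keep_trajectories Keep the full tidy trajectory table? Defaults to
#'   `TRUE` for `n_sims <= 100`.
#' @param extreme_range Ant-count band outside which a vibration-phase bridge
#'   counts as extreme (default `c(5, 25)`).
#' @return A `bridge_experiment` object; see [glance.bridge_experiment()].
#' @export
#' @examples
#' ex <- run_experiment(baseline_model(), build_schedule(), n_sims = 50, seed = 1)
#' glance(ex)
run_experiment <- function(model, schedule, n_sims, seed = NULL,
                           span = 0.75, grid_step = 0.5,
                           compute_extents = NULL, keep_trajectories = NULL,
                           extreme_range = c(5, 25)) {
  res <- simulate_engine(model, schedule, n_sims = n_sims, seed = seed)
  sched <- res$schedule
  has_both <- all(c("expansion", "contraction") %in% sched$phase)
  if (is.null(compute_extents)) compute_extents <- has_both
  if (is.null(keep_trajectories)) keep_trajectories <- n_sims <= 100L

  extents <- NULL
  if (compute_extents) {
    if (!has_both) abort("hysteresis extents need both expansion and contraction phases.")
    extents <- vapply(seq_len(nrow(res$n)), function(i) {
      extent_from_samples(sched$gap, res$n[i, ], sched$phase,
                          span = span, grid_step = grid_step)
    }, numeric(1))
  }

  vib <- NULL
  vib_idx <- which(sched$phase == "vibration")
  if (length(vib_idx) > 0L) {
    nv <- res$n[, vib_idx, drop = FALSE]
    extreme <- rowSums(nv < extreme_range[1] | nv > extreme_range[2]) > 0
    zero <- rowSums(nv == 0) > 0
    vib <- list(
      frac_extreme = mean(extreme),
      frac_zero = mean(zero),
      vib_steps = length(vib_idx)
    )
  }

  mean_curve <- tibble(
    interval = sched$interval, gap = sched$gap, phase = sched$phase,
    mean_n = colMeans(res$n)
  )

  trajectories <- NULL
  if (keep_trajectories) {
    n_t <- nrow(sched)
    trajectories <- tibble(
      simulation = rep(seq_len(n_sims), each = n_t),
      interval = rep(sched$interval, n_sims),
      gap = rep(sched$gap, n_sims),
      phase = rep(sched$phase, n_sims),
      joins_drawn = as.vector(t(res$joins_drawn)),
      leaves_drawn = as.vector(t(res$leaves_drawn)),
      joins = as.vector(t(res$joins)),
      leaves = as.vector(t(res$leaves)),
      n_ants = as.vector(t(res$n))
    )
  }

  structure(list(
    model = model, schedule = sched, n_sims = as.integer(n_sims), seed = seed,
    span = span, extents = extents,
    frac_negative = if (!is.null(extents)) mean(extents < 0, na.rm = TRUE),
    frac_positive = if (!is.null(extents)) mean(extents > 0, na.rm = TRUE),
    vibration = vib, mean_curve = mean_curve,
    final_n = res$n[, ncol(res$n)],
    total_joins = rowSums(res$joins), total_leaves = rowSums(res$leaves),
    trajectories = trajectories
  ), class = "bridge_experiment")
}

#' @export
print.bridge_experiment <- function(x, ...) {
  cat(sprintf("<bridge_experiment: %s model, %d simulations, %d intervals>\n",
              x$model$family, x$n_sims, nrow(x$schedule)))
  if (!is.null(x$extents)) {
    cat(sprintf("  mean extent of hysteresis: %.3f (%.1f%% negative)\n",
                mean(x$extents, na.rm = TRUE), 100 * x$frac_negative))
  }
  if (!is.null(x$vibration)) {
    cat(sprintf("  vibration (%d intervals): %.1f%% extreme, %.1f%% reached zero\n",
                x$vibration$vib_steps, 100 * x$vibration$frac_extreme,
                100 * x$vibration$frac_zero))
  }
  invisible(x)
}
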