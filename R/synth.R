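#' Configuration for the synthetic trial generator
#'
#' Bundles every knob of the synthetic field-trial generator. The defaults
#' emulate the conditions of the field study: ten complete trials on the
#' 61-interval expansion–contraction schedule (1 mm per 30 s, 30 mm
#' maximum), events generated by the accumulator model with the
#' field-estimated parameters, bridge volume of about 57 mm^3 per ant with
#' noise scaled to a volume–ant correlation of 0.93 (the midpoint of the
#' observed 0.88–0.98 range), tautness decreasing with the excess of ants,
#' autocorrelated platform traffic with bridge flow tied to it, a positive
#' performance elevation in the 10 s before joining events (the joining cue
#' found in the field), no tautness effect before leaving events (none was
#' found), and brief broken periods in most trials.
#'
#' @param n_trials Number of trials (default 10).
#' @param model Generating `bridge_model` (default
#'   [eciton_accumulator_model()]).
#' @param schedule Gap schedule (default [build_schedule()]).
#' @param v_per_ant Mean bridge volume per ant, mm^3 (default 57).
#' @param volume_ants_r Target Pearson correlation between volume and ant
#'   count; the volume noise sd is solved from it (default 0.93). Use 1 for
#'   noiseless volume.
#' @param tautness_base,tautness_slope,tautness_sd Tautness model: base
#'   level, decrease per excess ant, and noise sd.
#' @param platform_mean,platform_ar,platform_sd AR(1) platform optical flow
#'   (px/frame): mean, autocorrelation, innovation sd.
#' @param bridge_intercept,bridge_slope,bridge_sd Bridge flow regression on
#'   the summed platform flows, plus residual sd.
#' @param join_cue_effect Performance elevation (px/frame) added to bridge
#'   flow during the `join_cue_window` seconds before each joining event
#'   (default 2.25; set 0 for null-cue data).
#' @param join_cue_window Seconds of pre-join elevation (default 10).
#' @param leave_tautness_effect Tautness depression before leaving events
#'   (default 0: the field data show no such effect).
#' @param break_rate Expected number of broken periods per trial (Poisson).
#' @param break_min,break_max Broken-period duration range in seconds.
#' @param seed Integer seed; a fixed seed makes [generate_dataset()] output
#'   byte-identical.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_trials = 10,
                         model = eciton_accumulator_model(),
                         schedule = build_schedule(),
                         v_per_ant = 57, volume_ants_r = 0.93,
                         tautness_base = 0.5, tautness_slope = 0.02,
                         tautness_sd = 0.03,
                         platform_mean = 20, platform_ar = 0.8,
                         platform_sd = 4,
                         bridge_intercept = 2, bridge_slope = 0.45,
                         bridge_sd = 1.5,
                         join_cue_effect = 2.25, join_cue_window = 10,
                         leave_tautness_effect = 0,
                         break_rate = 0.8, break_min = 20, break_max = 60,
                         seed = 1L) {
  stopifnot(inherits(model, "bridge_model"), inherits(schedule, "gap_schedule"))
  assert_scalar_number(n_trials, "n_trials", lower = 0)
  assert_scalar_number(v_per_ant, "v_per_ant", lower = 0)
  assert_scalar_number(volume_ants_r, "volume_ants_r", lower = 1e-6, upper = 1)
  for (nm in c("tautness_sd", "platform_sd", "bridge_sd", "break_rate")) {
    assert_scalar_number(get(nm), nm, lower = 0)
  }
  assert_scalar_number(platform_ar, "platform_ar", lower = -1, upper = 1)
  assert_scalar_number(join_cue_window, "join_cue_window", lower = 1)
  if (break_max < break_min || break_min < 0) {
    abort("need 0 <= break_min <= break_max.")
  }
  structure(list(
    n_trials = as.integer(n_trials), model = model, schedule = schedule,
    v_per_ant = v_per_ant, volume_ants_r = volume_ants_r,
    tautness_base = tautness_base, tautness_slope = tautness_slope,
    tautness_sd = tautness_sd,
    platform_mean = platform_mean, platform_ar = platform_ar,
    platform_sd = platform_sd,
    bridge_intercept = bridge_intercept, bridge_slope = bridge_slope,
    bridge_sd = bridge_sd,
    join_cue_effect = join_cue_effect, join_cue_window = join_cue_window,
    leave_tautness_effect = leave_tautness_effect,
    break_rate = break_rate, break_min = break_min, break_max = break_max,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# rho_star used to derive per-second deficit for tautness; falls back to the
# field estimate for linear generating models
synth_rho_star <- function(cfg) {
  if (cfg$model$family == "accumulator") cfg$model$rho_star else eciton_deficit_params()$rho_star
}

#' Generate one synthetic trial
#'
#' Simulates the configured bridge model over the schedule, scatters each
#' interval's joining and leaving events at uniform offsets within the
#' interval (matching the observed within-interval uniformity of real
#' events), and derives the three data streams of a field trial from the
#' resulting ant-count series: structural metrics (volume proportional to
#' ant count with noise solved from the target correlation, cross-section,
#' tautness decreasing with the excess of ants), optional broken periods,
#' and an optical-flow series with the configured cue effects injected.
#' Because a simulation may end with ants still in the bridge, a forced
#' disassembly tail (one leaving event per second, flagged broken so that
#' every analysis excludes it) is appended to balance the join/leave totals,
#' as real trials are balanced by construction.
#'
#' Uses the current RNG state; call [generate_dataset()] (which seeds once
#' from `cfg$seed`) for reproducible multi-trial datasets.
#'
#' @param cfg A [synth_config()].
#' @param trial_index Index used for the trial id.
#' @return A validated `trial_record` with a `ground_truth` attribute
#'   listing per-trial event totals, broken periods and the tail length.
#' @export
generate_trial <- function(cfg, trial_index = 1L) {
  stopifnot(inherits(cfg, "synth_config"))
  sched <- cfg$schedule
  interval_s <- sched$duration[1]
  traj <- run_simulation(cfg$model, sched)

  # event times: distinct half-second offsets, uniform within the interval
  slots <- seq(0.25, interval_s - 0.25, by = 0.5)
  ev <- purrr::pmap_dfr(
    list(traj$interval, traj$joins, traj$leaves),
    function(iv, j, l) {
      k <- j + l
      if (k == 0L) return(NULL)
      if (k > length(slots)) abort("more events than half-second slots in an interval.")
      off <- sort(sample(slots, k))
      # order join/leave labels randomly but never let the count go negative
      kinds <- sample(rep(c("join", "leave"), c(j, l)))
      tibble(time = (iv - 1L) * interval_s + off, kind = kinds)
    }
  )
  if (is.null(ev) || nrow(ev) == 0L) {
    ev <- tibble(time = numeric(), kind = character())
  }
  # reorder kinds within the whole trial so the running count stays >= 0:
  # process in time order, swapping a leave with the next join if needed
  if (nrow(ev) > 0L) {
    ev <- ev[order(ev$time), ]
    kinds <- ev$kind
    n <- 0L
    for (i in seq_along(kinds)) {
      if (kinds[i] == "leave" && n == 0L) {
        nx <- if (i < length(kinds)) which(kinds[(i + 1L):length(kinds)] == "join")[1] else NA_integer_
        if (is.na(nx)) abort("unbalanced events: leave with no later join.")
        kinds[c(i, i + nx)] <- c("join", "leave")
      }
      n <- n + if (kinds[i] == "join") 1L else -1L
    }
    ev$kind <- kinds
  }

  span <- schedule_span(sched)
  n_end <- sum(ev$kind == "join") - sum(ev$kind == "leave")
  tail_len <- n_end
  if (n_end > 0L) {
    ev <- dplyr::bind_rows(ev, tibble(
      time = span + seq_len(n_end) - 0.5, kind = "leave"
    ))
  }

  total_s <- span + tail_len
  sec <- seq_len(total_s) - 1L
  signed <- ifelse(ev$kind == "join", 1L, -1L)
  n_ants <- vapply(sec, function(t) sum(signed[ev$time < t]), integer(1))
  iv_of_sec <- pmin(sec %/% interval_s + 1L, nrow(sched))
  gap <- sched$gap[iv_of_sec]
  phase <- sched$phase[iv_of_sec]
  in_tail <- sec >= span
  gap[in_tail] <- 0
  phase[in_tail] <- "contraction"

  # broken periods + disassembly tail (flagged broken so stats exclude it)
  broken <- rep(FALSE, total_s)
  n_breaks <- rpois(1, cfg$break_rate)
  breaks <- NULL
  if (n_breaks > 0L) {
    starts <- sort(runif(n_breaks, 0, span - cfg$break_max))
    durs <- runif(n_breaks, cfg$break_min, cfg$break_max)
    for (b in seq_len(n_breaks)) {
      broken[sec >= starts[b] & sec <= starts[b] + durs[b]] <- TRUE
    }
    breaks <- tibble(start_s = starts, end_s = starts + durs)
  }
  broken[in_tail] <- TRUE

  # structural metrics
  if (cfg$volume_ants_r >= 1) {
    vol_sd <- 0
  } else {
    sd_n <- sd(n_ants)
    if (sd_n == 0) {
      abort("target volume-ants correlation unreachable: ant count has zero variance (any correlation in (0, 1) is infeasible).")
    }
    vol_sd <- cfg$v_per_ant * sd_n * sqrt(1 / cfg$volume_ants_r^2 - 1)
  }
  volume <- cfg$v_per_ant * n_ants + rnorm(total_s, 0, vol_sd)
  cross_section <- volume / pmax(gap, 5)
  excess <- n_ants - synth_rho_star(cfg) * gap
  tautness <- cfg$tautness_base - cfg$tautness_slope * excess +
    rnorm(total_s, 0, cfg$tautness_sd)
  if (cfg$leave_tautness_effect != 0) {
    lv <- ev$time[ev$kind == "leave" & ev$time < span]
    for (t in lv) {
      w <- sec >= t - cfg$join_cue_window & sec < t
      tautness[w] <- tautness[w] - cfg$leave_tautness_effect
    }
  }

  structural <- tibble(
    time = sec, gap = gap, phase = phase, volume = volume, n_ants = n_ants,
    cross_section = cross_section, tautness = tautness, broken = broken
  )

  # optical flow per 10 s, AR(1) platforms, linear bridge response + cue
  t0 <- seq(0, total_s - 10, by = 10)
  ar1 <- function(n) {
    x <- numeric(n)
    x[1] <- cfg$platform_mean + rnorm(1, 0, cfg$platform_sd)
    for (i in seq_len(n - 1L)) {
      x[i + 1L] <- cfg$platform_mean +
        cfg$platform_ar * (x[i] - cfg$platform_mean) + rnorm(1, 0, cfg$platform_sd)
    }
    pmax(x, 0)
  }
  fa <- ar1(length(t0)); fb <- ar1(length(t0))
  fbridge <- cfg$bridge_intercept + cfg$bridge_slope * (fa + fb) +
    rnorm(length(t0), 0, cfg$bridge_sd)
  if (cfg$join_cue_effect != 0) {
    jn <- ev$time[ev$kind == "join"]
    for (t in jn) {
      hit <- t0 + 10 > t - cfg$join_cue_window & t0 < t
      fbridge[hit] <- fbridge[hit] + cfg$join_cue_effect
    }
  }
  flow <- tibble(
    t0 = t0, flow_bridge = pmax(fbridge, 0),
    flow_platform_a = fa, flow_platform_b = fb
  )

  trial <- trial_record(
    sprintf("synth_trial_%02d", trial_index),
    structural, ev[order(ev$time), ], flow,
    validate = TRUE
  )
  attr(trial, "ground_truth") <- list(
    n_joins = sum(ev$kind == "join"), n_leaves = sum(ev$kind == "leave"),
    tail_leaves = tail_len, breaks = breaks,
    model_family = cfg$model$family
  )
  trial
}

#' Generate a synthetic dataset with a ground-truth ledger
#'
#' Seeds the RNG once from `cfg$seed` and generates `cfg$n_trials` trials
#' plus a machine-readable ledger of the generating parameters and injected
#' effects, for use as test assertions: with a fixed seed the output is
#' byte-identical across calls.
#'
#' @param cfg A [synth_config()].
#' @return A list with `trials` (list of `trial_record`s) and `ledger` (a
#'   list holding the configuration and per-trial ground truth).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  trials <- purrr::map(seq_len(cfg$n_trials), function(i) generate_trial(cfg, i))
  per_trial <- purrr::map(trials, function(tr) {
    gt <- attr(tr, "ground_truth")
    c(list(trial_id = tr$trial_id), gt[c("n_joins", "n_leaves", "tail_leaves")])
  })
  ledger <- list(
    seed = cfg$seed, n_trials = cfg$n_trials,
    model = cfg$model[setdiff(names(cfg$model), "params")],
    model_params = if (!is.null(cfg$model$params)) as.data.frame(cfg$model$params),
    join_cue_effect = cfg$join_cue_effect,
    join_cue_window = cfg$join_cue_window,
    leave_tautness_effect = cfg$leave_tautness_effect,
    v_per_ant = cfg$v_per_ant, volume_ants_r = cfg$volume_ants_r,
    trials = per_trial
  )
  list(trials = trials, ledger = ledger)
}
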