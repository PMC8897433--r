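#' Assemble a trial record
#'
#' A `trial_record` bundles the three data streams extracted from one field
#' (or synthetic) trial:
#'
#' * `structural` — per-second series: `time` (s from trial start), `gap`
#'   (mm), `phase`, `volume` (mm^3), `n_ants`, `cross_section` (mm^2),
#'   `tautness` (relative height of the side-view center of mass), and a
#'   `broken` flag marking seconds during which the bridge was broken or
#'   recovering (excluded from every downstream statistic).
#' * `events` — timestamped joining/leaving events: `time` (s), `kind`
#'   (`"join"` or `"leave"`).
#' * `flow` — optional per-10-s optical-flow series: `t0`, `flow_bridge`,
#'   `flow_platform_a`, `flow_platform_b` (px/frame).
#'
#' Invariants checked by [validate_trial()]: non-negative ant counts, the
#' per-second count changing only through events (by one per event), equal
#' totals of joining and leaving events (every trial starts and ends with an
#' empty bridge), event times inside the recorded span, and a uniform,
#' non-overlapping 10-s flow grid with non-negative flows.
#'
#' @param trial_id Trial identifier string.
#' @param structural,events,flow Data frames as described above (`flow` may
#'   be `NULL`).
#' @param validate Run [validate_trial()] (default `TRUE`).
#' @return A `trial_record` object.
#' @export
trial_record <- function(trial_id, structural, events, flow = NULL,
                         validate = TRUE) {
  out <- structure(
    list(trial_id = as.character(trial_id),
         structural = as_tibble(structural),
         events = as_tibble(events),
         flow = if (!is.null(flow)) as_tibble(flow)),
    class = "trial_record"
  )
  if (validate) validate_trial(out)
  out
}

STRUCTURAL_COLS <- c("time", "gap", "phase", "volume", "n_ants",
                     "cross_section", "tautness", "broken")
EVENT_COLS <- c("time", "kind")
FLOW_COLS <- c("t0", "flow_bridge", "flow_platform_a", "flow_platform_b")

#' Validate a trial record
#'
#' Checks the structural, event and flow invariants described in
#' [trial_record()]; called by [read_trial()] and the synthetic generator.
#'
#' @param trial A `trial_record`.
#' @return The trial, invisibly; aborts with a format or integrity error
#'   otherwise.
#' @export
validate_trial <- function(trial) {
  stopifnot(inherits(trial, "trial_record"))
  s <- trial$structural
  miss <- setdiff(STRUCTURAL_COLS, names(s))
  if (length(miss) > 0L) {
    abort(sprintf("structural data missing mandatory column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (any(s$n_ants < 0)) {
    abort("integrity error: negative n_ants in structural data.")
  }
  if (!all(s$phase %in% PHASES)) abort("unknown phase label in structural data.")
  if (!is.logical(s$broken)) abort("`broken` must be logical.")
  if (is.unsorted(s$time, strictly = TRUE)) {
    abort("structural `time` must be strictly increasing.")
  }

  e <- trial$events
  miss <- setdiff(EVENT_COLS, names(e))
  if (length(miss) > 0L) {
    abort(sprintf("event data missing mandatory column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (!all(e$kind %in% c("join", "leave"))) abort("event kind must be join or leave.")
  n_join <- sum(e$kind == "join"); n_leave <- sum(e$kind == "leave")
  if (n_join != n_leave) {
    abort(sprintf(
      "integrity error: %d joining but %d leaving events; totals must be equal.",
      n_join, n_leave
    ))
  }
  span <- range(s$time)
  if (nrow(e) > 0L && (any(e$time < span[1]) || any(e$time > span[2] + 1))) {
    abort("integrity error: event times outside the recorded span.")
  }
  # the per-second count must follow the events: n_ants at second t equals
  # the net number of events strictly before t
  if (nrow(s) > 0L) {
    signed <- ifelse(e$kind == "join", 1L, -1L)
    expected <- vapply(s$time, function(t) sum(signed[e$time < t]), integer(1))
    if (!all(expected == s$n_ants)) {
      bad <- which(expected != s$n_ants)[1]
      abort(sprintf(
        "integrity error: n_ants at t = %g is %d but events imply %d.",
        s$time[bad], s$n_ants[bad], expected[bad]
      ))
    }
  }

  f <- trial$flow
  if (!is.null(f)) {
    miss <- setdiff(FLOW_COLS, names(f))
    if (length(miss) > 0L) {
      abort(sprintf("flow data missing mandatory column(s): %s",
                    paste(miss, collapse = ", ")))
    }
    if (any(f[FLOW_COLS[-1]] < 0)) abort("flows must be >= 0.")
    if (nrow(f) > 1L && any(diff(f$t0) != 10)) {
      abort("flow intervals must form a uniform, non-overlapping 10-s grid.")
    }
  }
  invisible(trial)
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record: %s, %d s, %d events%s>\n",
              x$trial_id, nrow(x$structural), nrow(x$events),
              if (is.null(x$flow)) "" else sprintf(", %d flow intervals", nrow(x$flow))))
  invisible(x)
}

#' Write and read a trial bundle
#'
#' A trial is stored as a directory of tidy CSV files — `structural.csv`,
#' `events.csv` and (when present) `flow.csv` — with snake_case headers,
#' comma separators, `.` decimals and times in seconds from trial start. The
#' directory name is the trial id. `read_trial()` validates every invariant
#' on the way in, so any `trial_record` obtained from disk satisfies the
#' join/leave balance and non-negativity guarantees.
#'
#' @param trial A `trial_record`.
#' @param path Directory for the bundle (created if needed).
#' @return `write_trial()` returns `path` invisibly; `read_trial()` returns a
#'   validated `trial_record`.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "trial_record"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(trial$structural, file.path(path, "structural.csv"))
  readr::write_csv(trial$events, file.path(path, "events.csv"))
  if (!is.null(trial$flow)) {
    readr::write_csv(trial$flow, file.path(path, "flow.csv"))
  }
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  if (!dir.exists(path)) abort(sprintf("no trial bundle at '%s'.", path))
  read_one <- function(file, cols) {
    fp <- file.path(path, file)
    if (!file.exists(fp)) abort(sprintf("format error: missing %s.", file))
    df <- readr::read_csv(fp, show_col_types = FALSE, progress = FALSE)
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0L) {
      abort(sprintf("format error: %s missing column(s): %s",
                    file, paste(miss, collapse = ", ")))
    }
    df
  }
  structural <- read_one("structural.csv", STRUCTURAL_COLS)
  events <- read_one("events.csv", EVENT_COLS)
  flow <- if (file.exists(file.path(path, "flow.csv"))) {
    read_one("flow.csv", FLOW_COLS)
  }
  trial_record(basename(path), structural, events, flow, validate = TRUE)
}

#' Write and read simulated trajectories
#'
#' Serializes a list of [run_simulation()] trajectories sharing one schedule
#' into a single tidy CSV: one row per (simulation, timestep) with the
#' timestep, gap size, phase, numbers of joining and leaving events, and the
#' state of the bridge, plus the simulation id and seed. Rows are ordered by
#' simulation id then timestep, so identical inputs give byte-identical
#' files.
#'
#' @param trajs A list of `bridge_trajectory` tibbles (possibly empty).
#' @param path Output CSV path.
#' @return `write_trajectories()` returns `path` invisibly;
#'   `read_trajectories()` returns the tidy tibble.
#' @export
write_trajectories <- function(trajs, path) {
  stopifnot(is.list(trajs))
  cols <- c("simulation", "seed", "timestep", "gap", "phase",
            "joins", "leaves", "n_ants")
  if (length(trajs) == 0L) {
    empty <- as_tibble(setNames(
      list(integer(), integer(), integer(), numeric(), character(),
           integer(), integer(), numeric()), cols))
    readr::write_csv(empty, path)
    return(invisible(path))
  }
  ref <- trajs[[1]]
  for (tr in trajs) {
    stopifnot(is.data.frame(tr))
    if (!identical(tr$gap, ref$gap) || !identical(tr$phase, ref$phase)) {
      abort("all trajectories must share the same gap schedule.")
    }
  }
  rows <- purrr::imap(trajs, function(tr, i) {
    seed <- attr(tr, "seed")
    tibble(
      simulation = as.integer(i),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      timestep = tr$interval, gap = tr$gap, phase = tr$phase,
      joins = tr$joins, leaves = tr$leaves, n_ants = tr$n_ants
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$simulation, .data$timestep)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) abort(sprintf("no trajectory file at '%s'.", path))
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(phase = readr::col_character()))
}

#' Write and read model parameter files
#'
#' Round-trips the package's fitted parameter sets (per-phase NB event
#' models, deficit regressions, equilibrium density) through a nested
#' key-value YAML file, the single configuration format consumed by the
#' simulator constructors.
#'
#' @param params A named list of parameters.
#' @param path YAML file path.
#' @return `write_model_params()` returns `path` invisibly;
#'   `read_model_params()` returns the named list.
#' @export
write_model_params <- function(params, path) {
  yaml::write_yaml(params, path)
  invisible(path)
}

#' @rdname write_model_params
#' @export
read_model_params <- function(path) {
  if (!file.exists(path)) abort(sprintf("no parameter file at '%s'.", path))
  yaml::read_yaml(path)
}
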