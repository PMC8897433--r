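# Fixtures built in code: no data files are shipped.

# Per-interval event-count table mimicking a set of field event records,
# with phase-dependent NB counts drawn from `params` (no clamping — the
# level at which the NB fitting operations consume data).
make_count_table <- function(params, n_trials, seed,
                             schedule = build_schedule()) {
  set.seed(seed)
  look <- function(kind, phase) {
    params[params$kind == kind & params$phase == phase, ]
  }
  purrr::map_dfr(seq_len(n_trials), function(i) {
    draw <- function(kind) {
      vapply(schedule$phase, function(ph) {
        p <- look(kind, ph)
        nb_draw(1, p$mu, p$theta)
      }, numeric(1))
    }
    tibble::tibble(
      trial_id = sprintf("t%02d", i), interval = schedule$interval,
      gap = schedule$gap, phase = schedule$phase, n_start = 0,
      joins = draw("join"), leaves = draw("leave"), broken = FALSE
    )
  })
}

# Minimal valid hand-made trial: 120 s, two 30-s expansion intervals then
# two contraction ones, 2 joins and 2 leaves.
tiny_trial <- function(volume_fun = function(n) 57 * n,
                       tautness = 0.5, flow = NULL, broken_secs = integer()) {
  sec <- 0:119
  events <- tibble::tibble(
    time = c(10.5, 20.5, 70.5, 80.5),
    kind = c("join", "join", "leave", "leave")
  )
  n_ants <- vapply(sec, function(t) {
    sum(events$time < t & events$kind == "join") -
      sum(events$time < t & events$kind == "leave")
  }, integer(1))
  structural <- tibble::tibble(
    time = sec,
    gap = rep(c(5, 6, 5, 4), each = 30),
    phase = rep(c("expansion", "contraction"), each = 60),
    volume = volume_fun(n_ants),
    n_ants = n_ants,
    cross_section = volume_fun(n_ants) / 5,
    tautness = tautness,
    broken = sec %in% broken_secs
  )
  trial_record("tiny", structural, events, flow)
}

# Valid trial for cue analyses: `n_join` joining events at distinct random
# seconds of a 600-s expansion block, matched leaves in a terminal
# contraction block, iid platform flows, and an optional bridge-flow
# elevation in the `window` seconds before each join. Because observed join
# times are a uniform random subset of the same candidate seconds the null
# redraws from, the type-I rate of the resampling test is exactly calibrated
# on this fixture.
toy_cue_trial <- function(n_join = 20, effect = 0, window = 5,
                          tautness_sd = 0.02, id = "toy") {
  n_exp <- 600L
  total <- 720L
  sec <- seq_len(total) - 1L
  join_sec <- sort(sample((window + 2L):(n_exp - 10L), n_join))
  events <- tibble::tibble(
    time = c(join_sec - 0.5, n_exp + 20 + seq_len(n_join) - 0.5),
    kind = rep(c("join", "leave"), each = n_join)
  )
  n_ants <- vapply(sec, function(t) {
    sum(events$time < t & events$kind == "join") -
      sum(events$time < t & events$kind == "leave")
  }, integer(1))
  structural <- tibble::tibble(
    time = sec, gap = 15,
    phase = rep(c("expansion", "contraction"), c(n_exp, total - n_exp)),
    volume = 57 * n_ants, n_ants = n_ants, cross_section = 57 * n_ants / 15,
    tautness = 0.5 + rnorm(total, 0, tautness_sd), broken = FALSE
  )
  t0 <- seq(0, total - 10, by = 10)
  fa <- runif(length(t0), 10, 30)
  fb <- runif(length(t0), 10, 30)
  fbridge <- 2 + 0.45 * (fa + fb) + rnorm(length(t0), 0, 1.5)
  if (effect != 0) {
    for (t in join_sec - 0.5) {
      hit <- t0 + 10 > t - window & t0 < t
      fbridge[hit] <- fbridge[hit] + effect
    }
  }
  flow <- tibble::tibble(
    t0 = t0, flow_bridge = pmax(fbridge, 0),
    flow_platform_a = fa, flow_platform_b = fb
  )
  trial_record(id, structural, events, flow)
}

expect_between <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
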