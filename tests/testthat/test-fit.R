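test_that("interval aggregation recovers counts, gaps and start states", {
  tr <- tiny_trial()
  per <- interval_counts(tr)
  expect_equal(nrow(per), 4L)
  expect_equal(per$joins, c(2L, 0L, 0L, 0L))
  expect_equal(per$leaves, c(0L, 0L, 2L, 0L))
  expect_equal(per$n_start, c(0L, 2L, 2L, 0L))
  expect_equal(per$gap, c(5, 6, 5, 4))
  expect_false(any(per$broken))
  # a broken second anywhere in an interval marks the whole interval
  tb <- tiny_trial(broken_secs = 35L)
  expect_equal(interval_counts(tb)$broken, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("median NB fits recover the generating parameters", {
  params <- tibble::tibble(
    phase = rep(c("expansion", "contraction"), each = 2),
    kind = rep(c("join", "leave"), 2),
    mu = c(0.8, 0.5, 0.8, 0.5), theta = c(1.5, 2, 1.5, 2)
  )
  ct <- make_count_table(params, 10, seed = 5)
  f <- fit_nb_counts(ct, "join", "expansion")
  expect_lt(abs(f$mu - 0.8), 0.12)
  expect_lt(abs(f$theta - 1.5), 0.8)
  expect_equal(nrow(f$per_trial), 10L)

  # median-of-fits is invariant to trial ordering
  set.seed(99)
  ct_shuffled <- ct[sample(nrow(ct)), ]
  f2 <- fit_nb_counts(ct_shuffled, "join", "expansion")
  expect_equal(f2$mu, f$mu)
  expect_equal(f2$theta, f$theta)
})

test_that("all-zero trials are dropped from the dispersion median with a warning", {
  params <- tibble::tibble(
    phase = rep(c("expansion", "contraction"), each = 2),
    kind = rep(c("join", "leave"), 2),
    mu = c(2, 1, 1, 1), theta = rep(2, 4)
  )
  ct <- make_count_table(params, 4, seed = 6)
  ct$joins[ct$trial_id == "t01"] <- 0L
  expect_warning(f <- fit_nb_counts(ct, "join", "expansion"), "t01")
  expect_false(anyNA(f$theta))
  expect_true(is.na(f$per_trial$theta[f$per_trial$trial_id == "t01"]))
})

test_that("mostly-broken trials are excluded like in the field analysis", {
  cfg <- synth_config(n_trials = 2, model = baseline_model(), seed = 44,
                      break_rate = 0)
  ds <- generate_dataset(cfg)
  # flag most of trial 2 broken
  ds$trials[[2]]$structural$broken[1:1700] <- TRUE
  expect_warning(f <- fit_nb_counts(ds$trials, "join", "expansion"),
                 "mostly-broken")
  expect_equal(unique(f$per_trial$trial_id), "synth_trial_01")
})

test_that("delay reassignment moves early-contraction leaves and conserves mass", {
  expect_error(apply_delay_reassignment(list(), 0), "d >= 1")
  expect_error(apply_delay_reassignment(list(), 7), "between 1 and 6")

  # single trial, all leaves in the first d contraction intervals
  sched <- build_schedule()
  d <- 3L
  ct <- tibble::tibble(
    trial_id = "t1", interval = sched$interval, gap = sched$gap,
    phase = sched$phase, n_start = 0, joins = 1L, leaves = 0L, broken = FALSE
  )
  first_con <- which(ct$phase == "contraction")[1:d]
  ct$leaves[first_con] <- 2L
  # the emptied contraction leave distribution warns about its dispersion
  expect_warning(re <- apply_delay_reassignment(ct, d), "all-zero")
  # contraction leaves all reassigned away
  expect_equal(re$contraction$mu, 0)
  # expansion now holds all 6 leave events over 31 + d intervals
  expect_equal(re$expansion$mu, 6 / (31 + d))
  expect_equal(re$expansion$per_trial$n_intervals, 31L + d)
  # totals conserved: mu * intervals sums to the original leave count
  expect_equal(re$expansion$mu * (31 + d) + re$contraction$mu * (30 - d),
               sum(ct$leaves))
})

test_that("equilibrium density sits where join and leave probabilities cross", {
  # symmetric logits around rho0: the intersection is rho0
  set.seed(77)
  rho0 <- 0.5; k <- 3
  rho <- runif(4000, 0, 1.2)
  per <- tibble::tibble(
    trial_id = "t1", interval = seq_along(rho), gap = 10,
    phase = "expansion", n_start = rho * 10,
    joins = rbinom(4000, 1, plogis(-k * (rho - rho0))),
    leaves = rbinom(4000, 1, plogis(k * (rho - rho0))),
    broken = FALSE
  )
  eq <- estimate_equilibrium_density(per)
  expect_lt(abs(eq$rho_star - rho0), 0.07)
  expect_lt(eq$join_logit[2], 0)
  expect_gt(eq$leave_logit[2], 0)

  # fitted probabilities are equal at the root to solver tolerance
  pj <- plogis(eq$join_logit[1] + eq$join_logit[2] * eq$rho_star)
  pl <- plogis(eq$leave_logit[1] + eq$leave_logit[2] * eq$rho_star)
  expect_lt(abs(pj - pl), 1e-6)

  # grid brute force at 1e-4 resolution agrees with the root solver
  grid <- seq(0, max(per$n_start / per$gap), 1e-4)
  diffp <- abs(plogis(eq$join_logit[1] + eq$join_logit[2] * grid) -
                 plogis(eq$leave_logit[1] + eq$leave_logit[2] * grid))
  expect_lt(abs(grid[which.min(diffp)] - eq$rho_star), 1e-3)

  # non-intersecting curves report a no-equilibrium error with both fits
  per2 <- per
  per2$joins <- rbinom(4000, 1, 0.9)
  per2$leaves <- rbinom(4000, 1, 0.05)
  expect_error(estimate_equilibrium_density(per2), "no equilibrium")
})

test_that("deficit regressions recover parameters with shrinking bias", {
  gen <- function(n, seed) {
    set.seed(seed)
    deficit <- runif(n, -15, 8)
    tibble::tibble(
      trial_id = "t1", interval = seq_len(n), gap = 20,
      phase = "expansion", n_start = 0.51 * 20 - deficit,
      joins = nb_draw(n, exp(0.2 + 0.05 * deficit), 1), leaves = 0L,
      broken = FALSE
    )
  }
  f600 <- fit_deficit_regression(gen(600, 1), 0.51, "join")
  expect_lt(abs(f600$alpha - 0.2), 0.15)
  expect_lt(abs(f600$beta - 0.05), 0.02)
  expect_lt(abs(f600$theta - 1), 0.4)
  f6000 <- fit_deficit_regression(gen(6000, 2), 0.51, "join")
  expect_lt(abs(f6000$beta - 0.05), 0.006)
  expect_lt(abs(f6000$alpha - 0.2), 0.05)

  # counts independent of the deficit: slope indistinguishable from zero
  null <- gen(600, 3)
  set.seed(4)
  null$joins <- nb_draw(600, 1.2, 1)
  fn <- fit_deficit_regression(null, 0.51, "join")
  expect_lt(abs(fn$beta), 3 * fn$se[2])

  # degenerate deficit range
  flat <- gen(100, 5)
  flat$n_start <- 5
  flat$gap <- 20
  flat$n_start <- 0.51 * 20 - 2   # constant deficit
  expect_error(fit_deficit_regression(flat, 0.51, "join"), "degenerate")
})

test_that("the dispersion profile flags no trend under constant theta", {
  set.seed(8)
  deficit <- runif(2000, -12, 8)
  per <- tibble::tibble(
    trial_id = "t1", interval = seq_along(deficit), gap = 20,
    phase = "expansion", n_start = 0.51 * 20 - deficit,
    joins = nb_draw(2000, exp(0.1 + 0.05 * deficit), 1.5), leaves = 0L,
    broken = FALSE
  )
  f <- fit_deficit_regression(per, 0.51, "join")
  prof <- deficit_dispersion_profile(f)
  expect_equal(sum(prof$n), 2000L)
  # Pearson residual variance stays near 1 in every deficit bin
  expect_true(all(prof$resid_var > 0.5 & prof$resid_var < 2))
})
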