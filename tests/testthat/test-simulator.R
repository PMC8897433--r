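test_that("trajectories never go negative and conserve events", {
  sched <- build_schedule()
  for (m in list(baseline_model(), eciton_accumulator_model())) {
    traj <- run_simulation(m, sched, seed = 4)
    expect_equal(nrow(traj), 61L)
    expect_true(all(traj$n_ants >= 0))
    expect_equal(tail(traj$n_ants, 1), sum(traj$joins) - sum(traj$leaves))
    # executed leaves never exceed what was available
    n_start <- c(0, head(traj$n_ants, -1))
    expect_true(all(traj$leaves <= n_start + traj$joins))
    expect_true(all(traj$leaves <= traj$leaves_drawn) ||
                  m$family == "delay")
  }
})

test_that("identical seed, model and schedule give bit-identical runs", {
  sched <- build_schedule()
  m <- baseline_model()
  expect_identical(run_simulation(m, sched, seed = 99),
                   run_simulation(m, sched, seed = 99))
  e1 <- run_experiment(m, sched, n_sims = 20, seed = 99)
  e2 <- run_experiment(m, sched, n_sims = 20, seed = 99)
  expect_identical(e1$extents, e2$extents)
  expect_identical(e1$trajectories, e2$trajectories)
})

test_that("a zero-rate model produces an identically empty bridge", {
  p <- eciton_event_params()
  p$mu <- 0
  traj <- run_simulation(baseline_model(p), build_schedule(), seed = 1)
  expect_true(all(traj$n_ants == 0))
  expect_true(all(traj$joins == 0))
})

test_that("leaves are clamped at an empty bridge", {
  # joins impossible, leaves very likely: the count must pin at zero
  p <- eciton_event_params()
  p$mu[p$kind == "join"] <- 0
  p$mu[p$kind == "leave"] <- 5
  traj <- run_simulation(baseline_model(p), build_schedule(), seed = 2)
  expect_true(all(traj$n_ants == 0))
  expect_true(all(traj$leaves == 0))
  expect_gt(sum(traj$leaves_drawn), 0)
})

test_that("baseline draws are Markovian in phase only", {
  # same seed, different starting count: the pre-clamp draws are identical
  sched <- build_schedule()
  m <- baseline_model()
  t0 <- run_simulation(m, sched, seed = 31, n0 = 0)
  t50 <- run_simulation(m, sched, seed = 31, n0 = 50)
  expect_identical(t0$joins_drawn, t50$joins_drawn)
  expect_identical(t0$leaves_drawn, t50$leaves_drawn)
})

test_that("delay model executes leave decisions d intervals later", {
  ct <- make_count_table(eciton_event_params(), 6, seed = 13)
  d <- 3L
  dp <- delay_event_params(ct, d, join_params = eciton_event_params())
  traj <- run_simulation(delay_model(dp, d), build_schedule(), seed = 8)
  # the queue is empty at start: nothing can execute in the first d intervals
  expect_true(all(traj$leaves[seq_len(d)] == 0))
  # each execution is the decision drawn d intervals earlier, up to clamping
  n_t <- nrow(traj)
  n_start <- c(0, head(traj$n_ants, -1))
  due <- c(rep(0, d), head(traj$leaves_drawn, n_t - d))
  expect_equal(traj$leaves, pmin(due, n_start + traj$joins))
  # conservation: executions = decisions - queue remainder - clamp losses
  remainder <- sum(tail(traj$leaves_drawn, d))
  clamp_loss <- sum(due - traj$leaves)
  expect_equal(sum(traj$leaves), sum(traj$leaves_drawn) - remainder - clamp_loss)
})

test_that("accumulator rates follow the log-linear link", {
  m <- eciton_accumulator_model()
  # ratio of expected joins at deficits 10 and 0 is exp(10 * beta) exactly
  expect_equal(predict_event_rate(m, 10, "join") / predict_event_rate(m, 0, "join"),
               exp(0.49))
  expect_equal(predict_event_rate(m, 5, "join") / predict_event_rate(m, 0, "join"),
               exp(5 * 0.049))
  # a 20-mm bridge with 7 ants at rho* = 0.51 is 3.2 ants short
  expect_equal(0.51 * 20 - 7, 3.2)
})

test_that("accumulator self-corrects towards its stationary deficit", {
  m <- eciton_accumulator_model()
  # root of mu_join(delta) = mu_leave(delta)
  delta_star <- (m$leave$alpha - m$join$alpha) / (m$join$beta - m$leave$beta)
  sched <- gap_schedule(rep(20, 250), rep("vibration", 250))
  res <- antbridge:::simulate_engine(m, sched, n_sims = 200, seed = 14)
  deficits <- m$rho_star * 20 - res$n[, 51:250]
  expect_lt(abs(mean(deficits) - delta_star), 1.5)
})

test_that("mean expansion size responds monotonically to the joining slope", {
  base <- eciton_accumulator_model()
  hot <- accumulator_model(
    join = list(alpha = base$join$alpha, beta = 0.09, theta = base$join$theta),
    leave = base$leave, rho_star = base$rho_star
  )
  sched <- build_schedule()
  exp_idx <- sched$phase == "expansion"
  n_base <- antbridge:::simulate_engine(base, sched, 400, seed = 15)$n
  n_hot <- antbridge:::simulate_engine(hot, sched, 400, seed = 15)$n
  expect_gt(mean(n_hot[, exp_idx]), mean(n_base[, exp_idx]))
})

test_that("single-simulation experiments reduce to the trajectory statistics", {
  sched <- build_schedule()
  ex <- run_experiment(baseline_model(), sched, n_sims = 1, seed = 77)
  traj <- run_simulation(baseline_model(), sched, seed = 77)
  expect_equal(ex$mean_curve$mean_n, traj$n_ants)
  expect_length(ex$extents, 1L)
  expect_equal(ex$extents,
               hysteresis_extent(traj, n_ants)$extent)
})

test_that("model constructors validate their inputs", {
  expect_error(baseline_model(eciton_event_params()[1:3, ]), "exactly one")
  expect_error(delay_model(eciton_event_params(), d = 0), "between 1 and 6")
  expect_error(delay_model(eciton_event_params(), d = 7), "between 1 and 6")
  p <- eciton_event_params(); p$theta[1] <- -1
  expect_error(baseline_model(p), "theta")
  expect_error(accumulator_model(list(alpha = 0, beta = 1, theta = -1),
                                 list(alpha = 0, beta = -1, theta = 1), 0.5),
               "theta")
  # params refit for one delay cannot silently power another
  ct <- make_count_table(eciton_event_params(), 4, seed = 3)
  dp <- delay_event_params(ct, 2, join_params = eciton_event_params())
  expect_error(delay_model(dp, 3), "refit")
})
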