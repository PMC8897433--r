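test_that("performance is the residual from the platform-flow regression", {
  # bridge flow exactly on the fitted line: residuals are identically zero
  t0 <- seq(0, 110, 10)
  flow <- tibble::tibble(
    t0 = t0,
    flow_platform_a = seq(10, 21, 1), flow_platform_b = seq(20, 9, -1) * 0 + 15,
    flow_bridge = 2 + 0.5 * (seq(10, 21, 1) + 15)
  )
  perf <- compute_performance(flow)
  expect_lt(max(abs(perf$performance)), 1e-10)

  # small-case algebra oracle: residuals equal (I - H) y from the hat matrix
  set.seed(3)
  fa <- runif(12, 5, 30); fb <- runif(12, 5, 30)
  y <- 1 + 0.4 * (fa + fb) + rnorm(12)
  flow2 <- tibble::tibble(t0 = t0, flow_bridge = y,
                          flow_platform_a = fa, flow_platform_b = fb)
  X <- cbind(1, fa + fb)
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  expect_equal(compute_performance(flow2)$performance,
               as.numeric((diag(12) - H) %*% y))
  # residuals sum to ~0 by construction
  expect_lt(abs(sum(compute_performance(flow2)$performance)), 1e-9)

  # degenerate predictor variance
  flow3 <- flow2
  flow3$flow_platform_a <- 10; flow3$flow_platform_b <- 12
  expect_error(compute_performance(flow3), "degenerate")
})

test_that("broken flow intervals are excluded before the regression", {
  set.seed(12)
  tr <- toy_cue_trial(n_join = 15)
  tr_b <- tr
  tr_b$structural$broken[101:140] <- TRUE   # kills flow intervals 11..14
  perf <- compute_performance(tr_b)
  expect_false(any(perf$t0 %in% c(100, 110, 120, 130)))
})

test_that("event-preceding means match a brute-force enumeration", {
  set.seed(23)
  tr <- toy_cue_trial(n_join = 5, effect = 0, window = 5)
  w <- 5
  obs <- event_preceding_mean(tr, "join", "expansion", window = w)
  # independent enumeration: refit the regression, spread residuals over
  # seconds, average the w whole seconds before each event
  f <- tr$flow
  fit <- lm(flow_bridge ~ I(flow_platform_a + flow_platform_b), data = f)
  res <- stats::residuals(fit)
  per_sec <- res[tr$structural$time %/% 10 + 1]
  ev <- tr$events[tr$events$kind == "join", ]
  means <- vapply(ev$time, function(t) {
    s <- ceiling(t)
    mean(per_sec[(s - w):(s - 1) + 1])
  }, numeric(1))
  expect_equal(obs, mean(means))

  # one event, constant (zero) performance
  expect_error(event_preceding_mean(tr, "join", "contraction"), "no usable")
})

test_that("resampling is reproducible and centred on the candidate mean", {
  set.seed(31)
  tr <- toy_cue_trial(n_join = 25, effect = 0)
  r1 <- resample_null(tr, "join", "expansion", n_resamples = 400, seed = 5)
  r2 <- resample_null(tr, "join", "expansion", n_resamples = 400, seed = 5)
  expect_identical(r1$null_means, r2$null_means)
  expect_length(r1$null_means, 400L)

  # law of total expectation: the null means average to the candidate mean
  pieces <- antbridge:::cue_pieces(tr, "join", "expansion", 10, "performance", "sum")
  cand_mean <- mean(pieces$W[pieces$candidates])
  mc_se <- sd(r1$null_means) / sqrt(length(r1$null_means))
  expect_lt(abs(mean(r1$null_means) - cand_mean), 5 * mc_se + 1e-8)
})

test_that("a constant cue signal can never look significant", {
  set.seed(41)
  tr <- toy_cue_trial(n_join = 12, tautness_sd = 0)
  r <- tautness_resample(tr, "contraction", n_resamples = 300, seed = 2)
  expect_equal(r$observed, 0.5)
  expect_true(all(r$null_means == 0.5))
  expect_false(r$significant)
  expect_equal(r$p.value, 1)
})

test_that("an injected pre-join performance elevation is detected", {
  set.seed(51)
  tr <- toy_cue_trial(n_join = 25, effect = 8, window = 10)
  r <- resample_null(tr, "join", "expansion", window = 10,
                     n_resamples = 1000, seed = 3)
  expect_true(r$significant)
  expect_gt(r$observed, r$q_high)
  expect_lt(r$p.value, 0.01)
})

test_that("an injected low-tautness signal before leaving is detected", {
  set.seed(52)
  cfg <- synth_config(n_trials = 2, leave_tautness_effect = 0.4,
                      break_rate = 0, seed = 52)
  ds <- generate_dataset(cfg)
  r <- tautness_resample(ds$trials, "contraction", n_resamples = 500, seed = 4)
  expect_true(r$significant)
  expect_lt(r$observed, r$q_low)
})

test_that("window sensitivity reduces to the basic test for one window", {
  set.seed(61)
  tr <- toy_cue_trial(n_join = 20, effect = 6, window = 10)
  tab <- window_sensitivity(tr, "join", "expansion", windows = c(5, 10, 20),
                            n_resamples = 300, seed = 9)
  expect_equal(nrow(tab), 3L)
  # a strong broad effect shows up at every window
  expect_true(all(tab$significant))
  single <- window_sensitivity(tr, "join", "expansion", windows = 10,
                               n_resamples = 300, seed = 9)
  ref <- resample_null(tr, "join", "expansion", window = 10,
                       n_resamples = 300, seed = 9)
  expect_equal(single$observed, ref$observed)
  expect_equal(single$p.value, ref$p.value)
})

test_that("fewer candidate seconds than events is an error", {
  # 14 joins whose shared 10-s window is intact, but only 13 non-broken
  # seconds qualify as resampling candidates
  sec <- 0:299
  ev <- tibble::tibble(
    time = c(29 + seq_len(14) * 0.05, 210 + seq_len(14) - 0.5),
    kind = rep(c("join", "leave"), each = 14)
  )
  n_ants <- vapply(sec, function(t) {
    sum(ev$time < t & ev$kind == "join") - sum(ev$time < t & ev$kind == "leave")
  }, integer(1))
  st <- tibble::tibble(
    time = sec, gap = 15,
    phase = rep(c("expansion", "contraction"), c(200, 100)),
    volume = 57 * n_ants, n_ants = n_ants, cross_section = n_ants,
    tautness = 0.5 + sec / 1000,
    broken = sec < 200 & !(sec %in% 18:40)
  )
  tr <- trial_record("few", st, ev)
  expect_error(
    resample_null(tr, "join", "expansion", n_resamples = 10, signal = "tautness"),
    "fewer candidate"
  )
})

test_that("event-timing uniformity matches a hand-computed KS statistic", {
  # three usable events at offsets 5, 15, 29 of their 30-s intervals:
  # D = max(|1/3 - 5/30|, |2/3 - 15/30|, |2/3 - 29/30|) = 0.3
  sec <- 0:119
  events <- tibble::tibble(
    time = c(5, 15, 29, 45),
    kind = c("join", "join", "leave", "leave")
  )
  n_ants <- vapply(sec, function(t) {
    sum(events$time < t & events$kind == "join") -
      sum(events$time < t & events$kind == "leave")
  }, integer(1))
  structural <- tibble::tibble(
    time = sec, gap = 5, phase = rep(c("expansion", "contraction"), each = 60),
    volume = 57 * n_ants, n_ants = n_ants, cross_section = n_ants,
    tautness = 0.5, broken = sec %in% 40:50
  )
  tr <- trial_record("ks", structural, events)
  u <- event_timing_uniformity(tr)
  expect_equal(u$n_events, 3L)
  expect_equal(u$statistic, 0.3)

  # all events at interval starts: strongly non-uniform
  ev2 <- tibble::tibble(time = c(0, 30, 60, 90), kind = c("join", "join", "leave", "leave"))
  n2 <- vapply(sec, function(t) {
    sum(ev2$time < t & ev2$kind == "join") - sum(ev2$time < t & ev2$kind == "leave")
  }, integer(1))
  st2 <- structural
  st2$n_ants <- n2; st2$volume <- 57 * n2; st2$broken <- FALSE
  tr2 <- trial_record("ks2", st2, ev2)
  expect_lt(event_timing_uniformity(tr2)$p.value, 0.05)

  # genuinely uniform offsets are not flagged
  set.seed(81)
  tr3 <- toy_cue_trial(n_join = 40)
  expect_gt(event_timing_uniformity(tr3)$p.value, 0.001)
})
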