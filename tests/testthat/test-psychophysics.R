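test_that("Weibull psychometric function has the right asymptotes and midpoint", {
  expect_equal(weibull_p_correct(-20, -1.5), 0.5, tolerance = 1e-8)
  expect_equal(weibull_p_correct(20, -1.5), 0.98, tolerance = 1e-8)
  # at threshold: guess + (1 - guess - lapse)(1 - e^-1)
  expect_equal(weibull_p_correct(-1.5, -1.5),
               0.5 + 0.48 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(weibull_p_correct(-1.5, -1.5), 0.8034, tolerance = 1e-4)
  # monotone in intensity over the informative range
  x <- seq(-2.2, -1.2, by = 0.01)
  expect_true(all(diff(weibull_p_correct(x, -1.5)) > 0))
})

test_that("the transformed staircase steps and counts reversals correctly", {
  st <- staircase_init(start_deg = 0.1)
  expect_equal(st$level_log10, -1)
  # two consecutive correct responses -> one 0.5 log-decade step down
  st <- staircase_step(st, TRUE)
  expect_equal(st$level_log10, -1) # no move after a single correct
  st <- staircase_step(st, TRUE)
  expect_equal(st$level_log10, -1.5)
  expect_equal(10^st$level_log10, 0.0316, tolerance = 1e-3)
  # an incorrect response moves up by the current step and flips direction
  st <- staircase_step(st, FALSE)
  expect_equal(st$level_log10, -1.0)
  expect_equal(st$reversals[1], 1L) # exactly one reversal recorded
  # phase advances 0.5 -> 0.1 after three reversals, ends after three more
  st2 <- staircase_init()
  pattern <- rep(c(TRUE, TRUE, FALSE), 20)
  for (resp in pattern) {
    if (st2$finished) break
    st2 <- staircase_step(st2, resp)
  }
  expect_true(st2$finished)
  expect_equal(st2$phase, 2L)
  expect_equal(st2$reversals, c(3L, 3L))
})

test_that("convergence staircase lands near a deterministic observer's threshold", {
  # rule-following observer: correct iff intensity above threshold
  det_obs <- structure(
    list(true_threshold_log10 = -2, slope = Inf, guess = 0, lapse = 0,
         fixation_break_rate = 0),
    class = "observer_model")
  state <- staircase_init()
  n <- 0L
  while (!state$finished && n < 500) {
    correct <- state$level_log10 > -2
    state <- staircase_step(state, correct)
    n <- n + 1L
  }
  expect_true(state$finished)
  expect_lt(abs(state$level_log10 - (-2)), 0.3)
  # seeded trajectories are reproducible
  obs <- observer_model(-1.5, fixation_break_rate = 0)
  a <- run_convergence(obs, seed = 5)
  b <- run_convergence(obs, seed = 5)
  expect_identical(a, b)
})

test_that("convergence trial counts sit in the empirical band", {
  obs <- observer_model(-1.5, fixation_break_rate = 0)
  n_trials <- vapply(1:100, function(i) {
    suppressWarnings(run_convergence(obs, seed = i)$n_trials)
  }, numeric(1))
  m <- mean(n_trials)
  expect_gte(m, 10)
  expect_lte(m, 30)
})

test_that("two-down one-up equilibrium: drift down requires p^2 > 1/2", {
  # constant-p observer: the staircase drifts down iff p > 0.7071
  drift <- function(p, seed) {
    set.seed(seed)
    st <- staircase_init(start_deg = 0.1)
    st$reversals_per_phase <- c(1000L, 1000L) # keep stepping
    suppressWarnings( # level clamping at the bounds is expected here
      for (i in 1:400) st <- staircase_step(st, runif(1) < p)
    )
    st$level_log10 - (-1)
  }
  expect_lt(median(vapply(1:10, function(s) drift(0.8, s), numeric(1))), 0)
  expect_gt(median(vapply(1:10, function(s) drift(0.6, s), numeric(1))), 0)
})

test_that("QUEST posterior updates are normalized and order-invariant", {
  q0 <- quest_init(-1.5)
  expect_equal(sum(q0$posterior), 1, tolerance = 1e-12)
  expect_equal(quest_mean(q0), -1.5, tolerance = 1e-9) # prior mean
  trials <- data.frame(x = c(-1.4, -1.7, -1.6, -1.2),
                       correct = c(TRUE, FALSE, TRUE, TRUE))
  qa <- q0
  for (i in seq_len(nrow(trials))) {
    qa <- quest_update(qa, trials$x[i], trials$correct[i])
    expect_equal(sum(qa$posterior), 1, tolerance = 1e-12)
  }
  qb <- q0
  for (i in rev(seq_len(nrow(trials)))) {
    qb <- quest_update(qb, trials$x[i], trials$correct[i])
  }
  expect_equal(qa$posterior, qb$posterior, tolerance = 1e-12)
  # one correct at the prior mode pulls the mean down
  q1 <- quest_update(q0, -1.5, TRUE)
  expect_lt(quest_mean(q1), quest_mean(q0))
})

test_that("QUEST placement rules invert the assumed Weibull", {
  q <- quest_init(-1.5)
  x30 <- quest_next_level(q, 0.3)
  x70 <- quest_next_level(q, 0.7)
  expect_lt(x30, x70)
  # brute-force inversion oracle on a fine intensity grid
  target <- 0.5 + 0.3 * (1 - 0.5 - 0.02)
  grid_x <- seq(-4, 1, by = 1e-4)
  perf <- weibull_p_correct(grid_x, quest_mean(q))
  x30_oracle <- grid_x[which.min(abs(perf - target))]
  expect_lt(abs(x30 - x30_oracle), 2e-4)
  # translation equivariance of the placement rule
  q_shift <- quest_init(-1.3)
  expect_equal(quest_next_level(q_shift, 0.3) - x30, 0.2, tolerance = 1e-9)
})

test_that("dual QUEST books exactly n successful trials and logs rejections", {
  obs <- observer_model(-1.5, fixation_break_rate = 0.138)
  res <- run_dual_quest(obs, initial_log10 = -1.4, n_trials = 50, seed = 31)
  expect_equal(res$n_successful, 50L)
  expect_equal(sum(!res$trials$rejected_fixation), 50L)
  expect_equal(sum(res$trials$rejected_fixation), res$n_rejected)
  # attempted > successful whenever any rejection occurred
  expect_gt(nrow(res$trials), 50)
  # both sampling rules used about half the time
  succ <- res$trials[!res$trials$rejected_fixation, ]
  expect_equal(sum(succ$quantile_rule == 0.3), 25L)
  expect_equal(sum(succ$quantile_rule == 0.7), 25L)
})

test_that("dual QUEST recovers the true threshold", {
  errs <- vapply(1:40, function(i) {
    obs <- observer_model(-1.5, fixation_break_rate = 0)
    conv <- run_convergence(obs, seed = i)
    res <- run_dual_quest(obs, conv$initial_level_log10, n_trials = 50,
                          seed = 1000 + i)
    abs(res$threshold_log10 - (-1.5))
  }, numeric(1))
  expect_lt(median(errs), 0.15)
  # near-deterministic observer: estimate within a few grid steps of truth
  det <- observer_model(-1.8, slope = 40, guess = 0.5, lapse = 1e-4,
                        fixation_break_rate = 0)
  res_det <- run_dual_quest(det, initial_log10 = -1.7, n_trials = 80,
                            seed = 5, lapse = 1e-4)
  expect_lt(abs(res_det$threshold_log10 - (-1.8)), 0.05)
})

test_that("threshold recovery bias shrinks as trials accumulate", {
  med_err <- vapply(c(20L, 80L, 320L), function(n_tr) {
    errs <- vapply(1:25, function(i) {
      obs <- observer_model(-1.5, fixation_break_rate = 0)
      res <- run_dual_quest(obs, initial_log10 = -1.3, n_trials = n_tr,
                            seed = 7000 + 13 * i + n_tr)
      abs(res$threshold_log10 - (-1.5))
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) <= 0))
})

test_that("a full session yields 600 successful trials over 12 conditions", {
  observers <- make_observer_set(seed = 2)
  sess <- run_full_session(observers, seed = 3)
  expect_equal(sess$n_successful_total, 600L)
  thr <- sess$thresholds
  expect_equal(nrow(thr), 12L)
  expect_equal(nrow(unique(thr[c("quadrant", "pedestal_deg")])), 12L)
  expect_true(all(thr$n_trials == 50L))
  expect_setequal(unique(thr$pedestal), c("near", "fixation", "far"))
})

test_that("far-pedestal observers yield higher recovered thresholds", {
  hits <- vapply(1:20, function(i) {
    observers <- make_observer_set(
      threshold_means_deg = c(near = 0.02, fixation = 0.02, far = 0.08),
      between_sd_log10 = 0.05, seed = i)
    sess <- run_full_session(observers, seed = 100 + i)
    thr <- sess$thresholds
    mean(thr$threshold_log10[thr$pedestal == "far"]) >
      mean(thr$threshold_log10[thr$pedestal == "fixation"])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
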