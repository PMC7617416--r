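#' Weibull psychometric function for a 2AFC observer
#'
#' Probability of a correct response at log10 stimulus intensity `x_log10`:
#' `guess + (1 - guess - lapse) * (1 - exp(-10^(slope * (x - threshold))))`.
#' For a 2AFC near/far judgment the chance rate is 0.5.
#'
#' @param x_log10 Stimulus intensity, log10 degrees of relative disparity.
#' @param threshold_log10 Threshold parameter on the same scale.
#' @param slope Weibull slope (beta).
#' @param guess Chance rate (gamma); 0.5 for 2AFC.
#' @param lapse Lapse rate (delta).
#' @return Probability of a correct response.
#' @export
weibull_p_correct <- function(x_log10, threshold_log10, slope = 3.5,
                              guess = 0.5, lapse = 0.02) {
  guess + (1 - guess - lapse) *
    (1 - exp(-10^(slope * (x_log10 - threshold_log10))))
}

#' Simulated stereoacuity observer
#'
#' A Weibull observer with a true log10 threshold, plus a Bernoulli
#' fixation-break process that rejects trials independently of the stimulus.
#'
#' @param true_threshold_log10 Log10 of the true relative-disparity
#'   threshold (deg).
#' @param slope,guess,lapse Weibull parameters.
#' @param fixation_break_rate Per-trial probability of rejection in [0, 1).
#' @return An `observer_model`.
#' @export
observer_model <- function(true_threshold_log10, slope = 3.5, guess = 0.5,
                           lapse = 0.02, fixation_break_rate = 0.138) {
  if (guess < 0 || guess >= 1 - lapse || lapse < 0) {
    stop("need 0 <= guess < 1 - lapse <= 1", call. = FALSE)
  }
  if (fixation_break_rate < 0 || fixation_break_rate >= 1) {
    stop("`fixation_break_rate` must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(true_threshold_log10 = true_threshold_log10, slope = slope,
         guess = guess, lapse = lapse,
         fixation_break_rate = fixation_break_rate),
    class = "observer_model"
  )
}

observer_respond <- function(observer, x_log10) {
  p <- weibull_p_correct(x_log10, observer$true_threshold_log10,
                         observer$slope, observer$guess, observer$lapse)
  stats::runif(1) < p
}

#' Initialize a two-down one-up convergence staircase
#'
#' Level moves down one step after two consecutive correct responses and up
#' one step after any incorrect response, in log10 units. The step is 0.5
#' log decades for the first three reversals and 0.1 log decades for the
#' next three; the staircase terminates at the sixth reversal.
#'
#' @param start_deg Starting relative disparity (deg), default 0.1.
#' @param steps_log10 Step sizes per phase (log decades).
#' @param reversals_per_phase Reversals before the phase advances / ends.
#' @param bounds_log10 Clamping bounds for the level (log10 deg).
#' @return A `staircase_state`.
#' @export
staircase_init <- function(start_deg = 0.1, steps_log10 = c(0.5, 0.1),
                           reversals_per_phase = c(3L, 3L),
                           bounds_log10 = c(-4, 0)) {
  structure(
    list(level_log10 = log10(start_deg), steps_log10 = steps_log10,
         reversals_per_phase = reversals_per_phase, phase = 1L,
         reversals = c(0L, 0L), consecutive_correct = 0L,
         last_direction = 0L, finished = FALSE, clamped = FALSE,
         bounds_log10 = bounds_log10, history = numeric(0)),
    class = "staircase_state"
  )
}

#' Advance the convergence staircase by one trial
#'
#' @param state A `staircase_state`.
#' @param correct Logical response on the current trial.
#' @return The updated `staircase_state`; `finished` becomes `TRUE` at the
#'   final reversal and `level_log10` then holds the reversal level.
#' @export
staircase_step <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"))
  if (state$finished) return(state)
  step <- state$steps_log10[state$phase]
  move <- 0L
  if (correct) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= 2L) {
      move <- -1L
      state$consecutive_correct <- 0L
    }
  } else {
    move <- 1L
    state$consecutive_correct <- 0L
  }
  state$history <- c(state$history, state$level_log10)
  if (move != 0L) {
    if (state$last_direction != 0L && move != state$last_direction) {
      state$reversals[state$phase] <- state$reversals[state$phase] + 1L
      if (state$reversals[state$phase] >= state$reversals_per_phase[state$phase]) {
        if (state$phase < length(state$steps_log10)) {
          state$phase <- state$phase + 1L
        } else {
          state$finished <- TRUE # level at the final reversal is retained
          state$last_direction <- move
          return(state)
        }
      }
    }
    state$last_direction <- move
    new_level <- state$level_log10 + move * step
    lo <- state$bounds_log10[1]; hi <- state$bounds_log10[2]
    if (new_level < lo || new_level > hi) {
      new_level <- min(max(new_level, lo), hi)
      state$clamped <- TRUE
      warning("staircase level clamped to bounds", call. = FALSE)
    }
    state$level_log10 <- new_level
  }
  state
}

#' Run the convergence staircase against a simulated observer
#'
#' @param observer An `observer_model`.
#' @param start_deg Starting disparity (deg).
#' @param max_trials Safety cap on trial count.
#' @param seed Optional integer seed.
#' @return list: `initial_level_log10` (level at the final reversal),
#'   `n_trials`, `levels_log10` (per-trial levels).
#' @export
run_convergence <- function(observer, start_deg = 0.1, max_trials = 1000L,
                            seed = NULL) {
  with_seed(seed, {
    state <- staircase_init(start_deg = start_deg)
    n <- 0L
    while (!state$finished && n < max_trials) {
      correct <- observer_respond(observer, state$level_log10)
      state <- staircase_step(state, correct)
      n <- n + 1L
    }
    list(initial_level_log10 = state$level_log10, n_trials = n,
         levels_log10 = state$history)
  })
}

#' Initialize a QUEST posterior
#'
#' Discretized Bayesian posterior over candidate log10 thresholds under an
#' assumed Weibull psychometric function, with a Gaussian prior centered on
#' `initial_log10`.
#'
#' @param initial_log10 Prior mean (log10 deg), e.g. the convergence-stage
#'   result.
#' @param prior_sd Gaussian prior SD in log10 units.
#' @param grain Grid spacing of the posterior support.
#' @param range_log10 Half-width of the support around `initial_log10`.
#' @param slope,guess,lapse Assumed Weibull parameters.
#' @return A `quest_state`.
#' @export
quest_init <- function(initial_log10, prior_sd = 1.0, grain = 0.002,
                       range_log10 = 2.5, slope = 3.5, guess = 0.5,
                       lapse = 0.02) {
  support <- seq(initial_log10 - range_log10, initial_log10 + range_log10,
                 by = grain)
  prior <- stats::dnorm(support, mean = initial_log10, sd = prior_sd)
  prior <- prior / sum(prior)
  structure(
    list(support = support, posterior = prior, slope = slope, guess = guess,
         lapse = lapse, n_trials = 0L,
         history = data.frame(x_log10 = numeric(0), correct = logical(0))),
    class = "quest_state"
  )
}

#' Bayesian update of the QUEST posterior after one trial
#'
#' Multiplies the posterior by the Weibull likelihood of the observed
#' response at intensity `x_log10` and renormalizes.
#'
#' @param state A `quest_state`.
#' @param x_log10 Presented intensity (log10 deg).
#' @param correct Logical response.
#' @return The updated `quest_state`.
#' @export
quest_update <- function(state, x_log10, correct) {
  stopifnot(inherits(state, "quest_state"))
  p <- weibull_p_correct(x_log10, state$support, state$slope, state$guess,
                         state$lapse)
  lik <- if (correct) p else 1 - p
  post <- state$posterior * lik
  z <- sum(post)
  if (z <= 0 || !is.finite(z)) {
    stop("QUEST posterior underflow: zero mass after update", call. = FALSE)
  }
  state$posterior <- post / z
  state$n_trials <- state$n_trials + 1L
  state$history <- rbind(state$history,
                         data.frame(x_log10 = x_log10, correct = correct))
  state
}

#' Posterior mean threshold estimate
#' @param state A `quest_state`.
#' @return Posterior mean of the log10 threshold.
#' @export
quest_mean <- function(state) {
  sum(state$support * state$posterior)
}

#' Next test intensity at a sampling quantile
#'
#' Inverts the assumed Weibull at the current posterior-mean threshold to
#' find the intensity at which performance equals
#' `guess + quantile * (1 - guess - lapse)`. Sampling half the trials at
#' the 0.3 point and half at the 0.7 point straddles the psychometric
#' slope.
#'
#' @param state A `quest_state`.
#' @param quantile Sampling quantile in (0, 1); 0.3 or 0.7 in practice.
#' @return Intensity in log10 degrees.
#' @export
quest_next_level <- function(state, quantile) {
  stopifnot(quantile > 0, quantile < 1)
  # q = 1 - exp(-10^(slope (x - T)))  =>  x = T + log10(-log(1 - q)) / slope
  quest_mean(state) + log10(-log(1 - quantile)) / state$slope
}

#' Run the dual-QUEST estimation stage for one condition
#'
#' Presents `n_trials` successful trials: half sampled at the 30% and half
#' at the 70% point of the assumed Weibull (assignment randomly permuted).
#' Fixation-break rejections (Bernoulli with the observer's rate) are
#' logged, discarded without updating the posterior, and replaced, so
#' exactly `n_trials` successful trials contribute. The threshold estimate
#' is the posterior mean.
#'
#' @param observer An `observer_model`.
#' @param initial_log10 Starting value (convergence-stage result).
#' @param n_trials Number of successful trials (default 50).
#' @param quantiles Sampling quantiles for the two interleaved rules.
#' @param seed Optional integer seed.
#' @param ... Passed to [quest_init()].
#' @return list: `threshold_log10`, `threshold_deg`, `n_successful`,
#'   `n_rejected`, `trials` (data.frame log), `state`.
#' @export
run_dual_quest <- function(observer, initial_log10, n_trials = 50L,
                           quantiles = c(0.3, 0.7), seed = NULL, ...) {
  with_seed(seed, {
    state <- quest_init(initial_log10, ...)
    half <- n_trials %/% 2L
    rule <- sample(rep(quantiles, c(half, n_trials - half)))
    log_rows <- list()
    n_rejected <- 0L
    for (i in seq_len(n_trials)) {
      x <- quest_next_level(state, rule[i])
      # replace fixation-break rejections until the trial succeeds
      while (stats::runif(1) < observer$fixation_break_rate) {
        n_rejected <- n_rejected + 1L
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(trial_index = NA_integer_, stage = "quest",
                     level_log10 = x, quantile_rule = rule[i],
                     correct = NA, rejected_fixation = TRUE)
      }
      correct <- observer_respond(observer, x)
      state <- quest_update(state, x, correct)
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(trial_index = i, stage = "quest", level_log10 = x,
                   quantile_rule = rule[i], correct = correct,
                   rejected_fixation = FALSE)
    }
    est <- quest_mean(state)
    list(threshold_log10 = est, threshold_deg = 10^est,
         n_successful = n_trials, n_rejected = n_rejected,
         trials = do.call(rbind, log_rows), state = state)
  })
}

#' Conditions of the stereoacuity session
#'
#' The 12 conditions crossing four retinotopic quadrant locations with
#' three pedestal disparities (near -0.4, fixation 0, far +0.4 deg;
#' negative disparity = near).
#'
#' @return data.frame: `quadrant`, `pedestal_deg`, `pedestal`.
#' @export
condition_grid <- function() {
  out <- expand.grid(quadrant = c("UL", "UR", "LL", "LR"),
                     pedestal_deg = c(-0.4, 0, 0.4),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$pedestal <- c("near", "fixation", "far")[match(out$pedestal_deg,
                                                     c(-0.4, 0, 0.4))]
  out
}

#' Simulate a full 12-condition stereoacuity session
#'
#' For each condition: a two-down one-up convergence staircase from 0.1 deg,
#' then `n_trials` successful dual-QUEST trials starting from the final
#' reversal level. Second-stage trials are interleaved across conditions in
#' randomized order (each condition keeps its own staircase).
#'
#' @param observers List of 12 `observer_model`s, ordered as
#'   [condition_grid()], or a single observer used for all conditions.
#' @param n_trials Successful trials per condition (default 50).
#' @param seed Integer seed.
#' @return list: `thresholds` (12-row data.frame with `quadrant`,
#'   `pedestal_deg`, `pedestal`, `threshold_log10`, `threshold_deg`,
#'   `n_trials`, `n_rejected`, `n_convergence_trials`),
#'   `n_successful_total`, `trial_order`.
#' @export
run_full_session <- function(observers, n_trials = 50L, seed = 1L) {
  grid <- condition_grid()
  n_cond <- nrow(grid)
  if (inherits(observers, "observer_model")) {
    observers <- rep(list(observers), n_cond)
  }
  stopifnot(length(observers) == n_cond)
  with_seed(seed, {
    # stage 1: per-condition convergence
    conv <- lapply(seq_len(n_cond), function(i) {
      run_convergence(observers[[i]])
    })
    # stage 2: interleaved dual QUEST, one shared randomized trial order
    states <- lapply(seq_len(n_cond), function(i) {
      quest_init(conv[[i]]$initial_level_log10)
    })
    half <- n_trials %/% 2L
    rules <- lapply(seq_len(n_cond), function(i) {
      sample(rep(c(0.3, 0.7), c(half, n_trials - half)))
    })
    done <- integer(n_cond)
    rejected <- integer(n_cond)
    order_vec <- sample(rep(seq_len(n_cond), each = n_trials))
    for (cond in order_vec) {
      done[cond] <- done[cond] + 1L
      x <- quest_next_level(states[[cond]], rules[[cond]][done[cond]])
      while (stats::runif(1) < observers[[cond]]$fixation_break_rate) {
        rejected[cond] <- rejected[cond] + 1L
      }
      correct <- observer_respond(observers[[cond]], x)
      states[[cond]] <- quest_update(states[[cond]], x, correct)
    }
    est <- vapply(states, quest_mean, numeric(1))
    thresholds <- cbind(
      grid,
      data.frame(threshold_log10 = est, threshold_deg = 10^est,
                 n_trials = done, n_rejected = rejected,
                 n_convergence_trials = vapply(conv, `[[`, numeric(1),
                                               "n_trials"))
    )
    list(thresholds = thresholds,
         n_successful_total = sum(done), trial_order = order_vec)
  })
}
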