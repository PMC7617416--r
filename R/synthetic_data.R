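#' Generate a ground-truth vertex population
#'
#' Draws per-vertex true tuning parameters with the generative structure
#' the analysis assumes: preferred disparities from a uniform distribution
#' on the stimulus range, optionally mixed with symmetric modes at
#' +/-0.15 deg (where empirical distributions peak in higher visual areas),
#' and tuning widths following a quadratic width-vs-|mu| relationship
#' `width = c + a mu^2 + scatter`, floored at 0.1 deg (the
#' non-physiological limit). Vertices are labelled with one of nine visual
#' areas, a hemisphere, and a visual-field quadrant.
#'
#' @param n Number of vertices.
#' @param mu_range Preferred-disparity range (deg).
#' @param mode_weight Fraction of vertices drawn from Gaussian modes at
#'   `+/-mode_deg` instead of the uniform component.
#' @param mode_deg,mode_sd Location and SD of the symmetric modes (deg).
#' @param width_relation `c(c, a, scatter)`: intercept (deg), quadratic
#'   coefficient (deg^-1), and SD of Gaussian width scatter (deg).
#' @param width_floor Minimum width (deg).
#' @param beta_range Range of true response amplitudes (signal units).
#' @param noise_sd Additive noise SD attached to each vertex (signal units).
#' @param areas Visual area labels to cycle over.
#' @param seed Integer seed.
#' @return data.frame of ground-truth vertices: `vertex_id`, `participant`,
#'   `area`, `hemisphere`, `quadrant`, `true_mu`, `true_sigma`,
#'   `true_width`, `true_beta`, `noise_sd`.
#' @export
make_vertex_population <- function(n, mu_range = c(-0.3, 0.3),
                                   mode_weight = 0, mode_deg = 0.15,
                                   mode_sd = 0.05,
                                   width_relation = c(c = 0.3, a = 4, scatter = 0.05),
                                   width_floor = 0.1,
                                   beta_range = c(0.8, 1.2),
                                   noise_sd = 0.5, seed = 1L) {
  if (mode_weight < 0 || mode_weight > 1) {
    stop("`mode_weight` must be in [0, 1]", call. = FALSE)
  }
  if (width_relation[1] <= 0 || width_relation[2] < 0 || width_relation[3] < 0) {
    stop("`width_relation` must have c > 0, a >= 0, scatter >= 0", call. = FALSE)
  }
  quadrants <- c("UL", "UR", "LL", "LR")
  with_seed(seed, {
    from_mode <- stats::runif(n) < mode_weight
    mu <- stats::runif(n, mu_range[1], mu_range[2])
    if (any(from_mode)) {
      sign_m <- sample(c(-1, 1), sum(from_mode), replace = TRUE)
      mu[from_mode] <- pmin(pmax(
        sign_m * mode_deg + stats::rnorm(sum(from_mode), sd = mode_sd),
        mu_range[1]), mu_range[2])
    }
    width <- width_relation[1] + width_relation[2] * mu^2 +
      stats::rnorm(n, sd = width_relation[3])
    width <- pmax(width, width_floor)
    quadrant <- quadrants[(seq_len(n) - 1L) %% 4L + 1L]
    data.frame(
      vertex_id = seq_len(n),
      participant = 1L,
      area = rep_len(visual_areas(), n),
      hemisphere = ifelse(quadrant %in% c("UL", "LL"), "RH", "LH"),
      quadrant = quadrant,
      true_mu = mu,
      true_sigma = width / 4,
      true_width = width,
      true_beta = stats::runif(n, beta_range[1], beta_range[2]),
      noise_sd = noise_sd,
      stringsAsFactors = FALSE
    )
  })
}

#' The nine visual areas used throughout the package
#' @return Character vector of area labels.
#' @export
visual_areas <- function() {
  c("V1", "V2", "V3", "V4", "VOC", "V3A/B", "V7", "LOC", "V5/hMT+")
}

#' Simulate BOLD time series for a vertex population
#'
#' Per-vertex signal on the TR grid:
#' `beta * (drive convolved with HRF) + baseline + N(0, noise_sd)`, where
#' the drive is the Gaussian tuning response to the quadrant's disparity
#' sequence (zero during rest frames). The default sequence is 13 cycles of
#' 20 steps padded with 8 rest frames, i.e. 268 frames at TR 1.355 s.
#'
#' @param population Output of [make_vertex_population()].
#' @param seq A `disparity_sequence`; default built from the population
#'   seed with the standard run configuration.
#' @param hrf An `hrf_model`; default canonical [double_gamma_hrf()].
#' @param baseline Additive offset (signal units).
#' @param seed Integer seed for the noise draws.
#' @return A `timeseries_set`: `vertex_id`, `signals` (vertices x frames
#'   matrix), `quadrant`, `area`, `hemisphere`, `tr_s`, plus the generating
#'   `population`, `seq` and snr summary.
#' @export
make_session <- function(population, seq = NULL, hrf = NULL, baseline = 100,
                         seed = 1L) {
  stopifnot(nrow(population) > 0)
  if (is.null(seq)) {
    seq <- build_sequence(log_disparity_levels(), n_cycles = 13L,
                          tr_s = 1.355, seed = seed, rest_frames = 8L)
  }
  if (is.null(hrf)) hrf <- double_gamma_hrf(tr_s = seq$tr_s)
  n_frames <- ncol(seq$disparity)
  n <- nrow(population)
  signals <- matrix(NA_real_, n, n_frames)
  clean_sd <- numeric(n)
  with_seed(seed, {
    for (v in seq_len(n)) {
      d <- seq$disparity[population$quadrant[v], ]
      drive <- rep(0, n_frames)
      ok <- !is.na(d)
      drive[ok] <- gaussian_tuning(d[ok], population$true_mu[v],
                                   population$true_sigma[v])
      clean <- population$true_beta[v] * convolve_truncate(drive, hrf$kernel) +
        baseline
      clean_sd[v] <- stats::sd(clean)
      signals[v, ] <- clean +
        stats::rnorm(n_frames, sd = population$noise_sd[v])
    }
  })
  structure(
    list(vertex_id = population$vertex_id,
         signals = signals,
         quadrant = population$quadrant,
         area = population$area,
         hemisphere = population$hemisphere,
         tr_s = seq$tr_s,
         population = population,
         seq = seq,
         snr = clean_sd / pmax(population$noise_sd, .Machine$double.eps)),
    class = "timeseries_set"
  )
}

#' @export
print.timeseries_set <- function(x, ...) {
  cat(sprintf("timeseries_set: %d vertices x %d frames (TR %.3f s)\n",
              nrow(x$signals), ncol(x$signals), x$tr_s))
  invisible(x)
}

#' Generate a 12-condition observer set
#'
#' Draws one Weibull observer per (quadrant x pedestal) condition.
#' Per-condition true thresholds are log-normal around pedestal-specific
#' means; the far-pedestal mean is configurable above the fixation and near
#' means (stereoacuity is empirically worst at far pedestals).
#'
#' @param threshold_means_deg Named numeric: mean true threshold (deg) per
#'   pedestal (`near`, `fixation`, `far`).
#' @param between_sd_log10 Between-condition threshold SD in log10 units.
#' @param fixation_break_rate Shared per-trial rejection probability.
#' @param slope,guess,lapse Weibull parameters for every observer.
#' @param seed Integer seed.
#' @return list of 12 `observer_model`s ordered as [condition_grid()], with
#'   attribute `"conditions"` holding the grid and the true thresholds.
#' @export
make_observer_set <- function(threshold_means_deg = c(near = 0.03,
                                                      fixation = 0.03,
                                                      far = 0.06),
                              between_sd_log10 = 0.15,
                              fixation_break_rate = 0.138,
                              slope = 3.5, guess = 0.5, lapse = 0.02,
                              seed = 1L) {
  if (any(threshold_means_deg <= 0)) {
    stop("threshold means must be positive", call. = FALSE)
  }
  grid <- condition_grid()
  with_seed(seed, {
    mean_log10 <- log10(threshold_means_deg[grid$pedestal])
    true_log10 <- stats::rnorm(nrow(grid), mean = mean_log10,
                               sd = between_sd_log10)
    observers <- lapply(true_log10, function(t) {
      observer_model(t, slope = slope, guess = guess, lapse = lapse,
                     fixation_break_rate = fixation_break_rate)
    })
    grid$true_threshold_log10 <- true_log10
    attr(observers, "conditions") <- grid
    observers
  })
}
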