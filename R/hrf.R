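#' Double-gamma hemodynamic response function
#'
#' Samples a difference-of-gamma-densities kernel on the TR grid and rescales
#' it to unit peak. This is the canonical parametric HRF shape: a positive
#' response peaking ~6 s after the neural event followed by a shallow
#' undershoot peaking ~16 s.
#'
#' @param peak_delay_s Time-to-peak of the positive lobe (s).
#' @param undershoot_delay_s Time-to-peak of the undershoot (s).
#' @param peak_disp,undershoot_disp Dispersion (gamma scale) of each lobe (s).
#' @param undershoot_ratio Undershoot amplitude relative to the peak.
#' @param tr_s Sampling interval (s).
#' @param duration_s Kernel support; must cover the undershoot (>= 24 s).
#' @return An `hrf_model`: shape parameters plus `kernel`, the sampled
#'   response with `max(kernel) == 1`.
#' @examples
#' h <- double_gamma_hrf()
#' h$tr_s * (which.max(h$kernel) - 1) # ~6 s
#' @export
double_gamma_hrf <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                             peak_disp = 1, undershoot_disp = 1,
                             undershoot_ratio = 1 / 6,
                             tr_s = 1.355, duration_s = 32) {
  if (duration_s < 24) stop("`duration_s` must be >= 24 s", call. = FALSE)
  if (peak_delay_s <= 0 || undershoot_delay_s <= 0 ||
      peak_disp <= 0 || undershoot_disp <= 0) {
    stop("HRF shape parameters must be positive", call. = FALSE)
  }
  t <- seq(0, duration_s, by = tr_s)
  kernel <- stats::dgamma(t, shape = peak_delay_s / peak_disp, scale = peak_disp) -
    undershoot_ratio *
      stats::dgamma(t, shape = undershoot_delay_s / undershoot_disp,
                    scale = undershoot_disp)
  kernel <- kernel / max(kernel)
  structure(
    list(
      peak_delay_s = peak_delay_s, undershoot_delay_s = undershoot_delay_s,
      peak_disp = peak_disp, undershoot_disp = undershoot_disp,
      undershoot_ratio = undershoot_ratio,
      tr_s = tr_s, duration_s = duration_s, kernel = kernel,
      converged = TRUE
    ),
    class = "hrf_model"
  )
}

# boxcar(2.5 s ON) convolved with a candidate HRF, amplitude fitted by OLS
hrf_block_prediction <- function(theta, t_grid, on_s, tr_s, duration_s) {
  h <- double_gamma_hrf(peak_delay_s = theta[1], undershoot_delay_s = theta[2],
                        undershoot_ratio = theta[3], tr_s = tr_s,
                        duration_s = duration_s)
  # zero pre-stimulus history: the window starts at the block onset
  box <- c(0, as.numeric(t_grid < on_s))
  convolve_truncate(box, h$kernel)[-1L]
}

#' Estimate a participant HRF from a block design
#'
#' Fits the double-gamma delay and undershoot-ratio parameters to the
#' event-locked average response of a block-design run (e.g. 2.5 s ON,
#' 30 s OFF full-field checkerboard) by least squares, with the amplitude
#' profiled out in closed form. If the optimizer fails, the canonical
#' kernel is returned with `converged = FALSE`.
#'
#' @param block_ts Signal vector on the TR grid.
#' @param onsets Block onset times (s); at least 3 ON blocks required.
#' @param tr_s Sampling interval (s).
#' @param on_s Block (stimulus ON) duration in seconds.
#' @param window_s Length of the event-locked averaging window (s).
#' @return An `hrf_model` with fitted parameters and a `converged` flag.
#' @export
estimate_hrf <- function(block_ts, onsets, tr_s = 1.355, on_s = 2.5,
                         window_s = 30) {
  if (length(onsets) < 3) stop("need >= 3 ON blocks to estimate an HRF", call. = FALSE)
  n_win <- floor(window_s / tr_s) + 1L
  onset_idx <- round(onsets / tr_s) + 1L
  segs <- vapply(onset_idx, function(i) {
    s <- block_ts[i:(i + n_win - 1L)]
    s - s[1L] # baseline at block onset
  }, numeric(n_win))
  avg <- rowMeans(segs)
  t_grid <- (seq_len(n_win) - 1L) * tr_s

  obj <- function(theta) {
    if (theta[1] <= 1 || theta[2] <= theta[1] || theta[3] < 0) return(1e12)
    pred <- hrf_block_prediction(theta, t_grid, on_s, tr_s, duration_s = 32)
    amp <- sum(pred * avg) / sum(pred * pred)
    sum((avg - amp * pred)^2)
  }
  fit <- tryCatch(
    stats::optim(c(6, 16, 1 / 6), obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-10, maxit = 1000)),
    error = function(e) NULL
  )
  canonical <- double_gamma_hrf(tr_s = tr_s)
  if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e12) {
    canonical$converged <- FALSE
    return(canonical)
  }
  out <- double_gamma_hrf(peak_delay_s = fit$par[1],
                          undershoot_delay_s = fit$par[2],
                          undershoot_ratio = fit$par[3], tr_s = tr_s)
  out$rss <- fit$value
  out
}

# Causal convolution truncated to the length of x. The pre-run history is
# assumed at steady state (drive held at x[1]), so a constant drive maps to
# a constant response with no onset transient.
convolve_truncate <- function(x, kernel) {
  n <- length(x)
  L <- length(kernel)
  padded <- c(rep(x[1], L - 1L), x)
  z <- stats::convolve(padded, rev(kernel), type = "open")
  z[L:(n + L - 1L)]
}

#' Zero-phase band-pass filter
#'
#' FFT-domain filter retaining frequency components in `[low_hz, high_hz]`.
#' The DC component is removed (output is mean-zero) and the filter is
#' exactly zero-phase, as appropriate for slow periodic fMRI regressor
#' analyses.
#'
#' @param ts Signal vector sampled at `1 / tr_s` Hz.
#' @param low_hz,high_hz Pass-band edges (Hz); defaults 0.02-0.2 Hz.
#' @param tr_s Sampling interval (s).
#' @return Filtered, mean-zero signal of the same length.
#' @export
bandpass <- function(ts, low_hz = 0.02, high_hz = 0.2, tr_s = 1.355) {
  nyq <- 1 / (2 * tr_s)
  if (low_hz <= 0 || low_hz >= high_hz) {
    stop("need 0 < low_hz < high_hz", call. = FALSE)
  }
  if (high_hz >= nyq) {
    stop(sprintf("`high_hz` (%.3g) must be below the Nyquist frequency (%.3g Hz)",
                 high_hz, nyq), call. = FALSE)
  }
  n <- length(ts)
  freqs <- (seq_len(n) - 1L) / (n * tr_s)
  freqs <- pmin(freqs, 1 / tr_s - freqs) # fold to [0, nyquist]
  keep <- freqs >= low_hz & freqs <= high_hz
  Re(stats::fft(stats::fft(ts) * keep, inverse = TRUE)) / n
}
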