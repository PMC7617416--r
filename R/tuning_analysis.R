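#' Constrained quadratic fit of width against |preferred disparity|
#'
#' Least-squares fit of `y = c + a * x^2` with `a >= 0`, i.e. a second-order
#' polynomial constrained to have its minimum at `x = 0`. With no linear
#' term the model has two parameters, the same count as a straight line.
#' The fit depends on `x` only through `x^2`, so signed and absolute
#' preferred disparities give identical results.
#'
#' @param x Preferred disparity (deg); typically its modulus.
#' @param y Tuning width (deg).
#' @return list: `coefficients = c(c, a)`, `rss`, `fitted`.
#' @export
fit_constrained_poly <- function(x, y) {
  if (length(x) < 3) stop("need >= 3 points", call. = FALSE)
  x2 <- x^2
  fit <- stats::lm(y ~ x2)
  co <- unname(stats::coef(fit))
  if (co[2] < 0) { # enforce the minimum-at-zero constraint (a >= 0)
    co <- c(mean(y), 0)
  }
  fitted <- co[1] + co[2] * x2
  list(coefficients = c(c = co[1], a = co[2]),
       rss = sum((y - fitted)^2), fitted = fitted)
}

#' Straight-line fit of width against preferred disparity
#'
#' Ordinary least squares `y = intercept + slope * x`.
#'
#' @inheritParams fit_constrained_poly
#' @return list: `coefficients = c(intercept, slope)`, `rss`, `fitted`.
#' @export
fit_line <- function(x, y) {
  if (length(x) < 3) stop("need >= 3 points", call. = FALSE)
  if (stats::var(x) == 0) stop("constant `x`: singular design", call. = FALSE)
  fit <- stats::lm(y ~ x)
  co <- unname(stats::coef(fit))
  list(coefficients = c(intercept = co[1], slope = co[2]),
       rss = sum(stats::resid(fit)^2), fitted = unname(stats::fitted(fit)))
}

#' Small-sample Akaike information criterion for a least-squares fit
#'
#' `AICc = n log(rss / n) + 2k + 2k(k + 1)/(n - k - 1)`, with additive
#' constants dropped (they cancel in any comparison on the same data).
#' For two models with equal `k`, the difference reduces to
#' `n log(rss1 / rss2)`.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n Number of observations (> k + 1).
#' @param k Number of fitted parameters.
#' @return AICc value.
#' @export
aicc_ls <- function(rss, n, k) {
  if (rss <= 0) stop("`rss` must be > 0", call. = FALSE)
  if (n <= k + 1) stop("`n` must exceed k + 1", call. = FALSE)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weight of the first of two models
#'
#' Two-model Akaike weight: `1 / (1 + exp(-delta / 2))`, where `delta` is
#' the AICc advantage of the first model (second minus first).
#'
#' @param delta AICc difference (positive favors the first model).
#' @return Probability in (0, 1).
#' @export
akaike_probability <- function(delta) {
  1 / (1 + exp(-delta / 2))
}

#' Compare the constrained quadratic against a straight line
#'
#' Fits both models of tuning width versus |preferred disparity|, computes
#' AICc for each (both have k = 2 parameters), and reports
#' `delta_aicc = aicc_line - aicc_poly` (positive: quadratic is the better
#' model) together with the Akaike probability that the quadratic is the
#' better choice.
#'
#' @param x Preferred disparity (deg); the modulus is taken internally.
#' @param y Tuning width (deg).
#' @return An object of class `model_comparison`.
#' @export
compare_models <- function(x, y) {
  x <- abs(x)
  poly <- fit_constrained_poly(x, y)
  line <- fit_line(x, y)
  n <- length(x)
  k <- 2L
  aicc_poly <- aicc_ls(poly$rss, n, k)
  aicc_line <- aicc_ls(line$rss, n, k)
  delta <- aicc_line - aicc_poly
  structure(
    list(poly_coeffs = poly$coefficients, line_coeffs = line$coefficients,
         rss_poly = poly$rss, rss_line = line$rss, n = n, k = k,
         aicc_poly = aicc_poly, aicc_line = aicc_line,
         delta_aicc = delta, poly_probability = akaike_probability(delta)),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(
    "model_comparison (n = %d): dAICc = %.3g, P(quadratic better) = %.4g\n",
    x$n, x$delta_aicc, x$poly_probability))
  invisible(x)
}

#' Histogram of preferred disparities
#'
#' Counts thresholded vertices in equal-width disparity bins (default 50
#' bins on [-0.3, +0.3] deg; bins are right-open except the last), split by
#' any stratification columns present, e.g. area and participant.
#'
#' @param fits Thresholded vertex table with column `mu_deg`.
#' @param n_bins Number of bins.
#' @param range Bin range in degrees.
#' @param by Character vector of stratification columns (present in `fits`).
#' @return data.frame: stratification columns, `bin`, `bin_center`, `count`.
#' @export
preferred_disparity_histogram <- function(fits, n_bins = 50L,
                                          range = c(-0.3, 0.3),
                                          by = intersect("area", names(fits))) {
  edges <- seq(range[1], range[2], length.out = n_bins + 1L)
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  bin_of <- function(mu) {
    b <- findInterval(mu, edges, rightmost.closed = TRUE)
    pmin(pmax(b, 1L), n_bins)
  }
  strata <- if (length(by)) interaction(fits[by], drop = TRUE)
            else factor(rep("all", nrow(fits)))
  out <- do.call(rbind, lapply(levels(strata), function(s) {
    sub <- fits[strata == s, , drop = FALSE]
    counts <- tabulate(bin_of(sub$mu_deg), nbins = n_bins)
    df <- data.frame(bin = seq_len(n_bins), bin_center = centers,
                     count = counts)
    for (col in rev(by)) df <- cbind(stats::setNames(sub[1L, col, drop = FALSE],
                                                     col), df, row.names = NULL)
    df
  }))
  rownames(out) <- NULL
  out
}

#' Proportion of disparity-significant vertices per area
#'
#' For each visual area, the percentage of vertices whose model fit
#' survives `r2 > 0.1`, separately for correlated and anticorrelated
#' stimulation, relative to the number of vertices with `r2 >= 0` under the
#' correlated stimulus (the common baseline of "activated" vertices).
#'
#' @param fits_corr,fits_anticorr Unthresholded vertex tables (same vertex
#'   population, fitted independently per condition).
#' @param r2_min Significance threshold on `r2`.
#' @return data.frame: `area`, `n_baseline`, `pct_correlated`,
#'   `pct_anticorrelated` (NA where the baseline is empty).
#' @export
proportion_significant <- function(fits_corr, fits_anticorr, r2_min = 0.1) {
  areas <- sort(unique(fits_corr$area))
  out <- lapply(areas, function(a) {
    corr <- fits_corr[fits_corr$area == a, ]
    anti <- fits_anticorr[fits_anticorr$area == a, ]
    denom <- sum(!is.na(corr$r2) & corr$r2 >= 0)
    pct <- function(tab) {
      if (denom == 0) return(NA_real_)
      100 * sum(!is.na(tab$r2) & tab$r2 > r2_min) / denom
    }
    data.frame(area = a, n_baseline = denom,
               pct_correlated = pct(corr), pct_anticorrelated = pct(anti))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Participant QC: preferred-disparity clustering check
#'
#' Flags a participant whose fitted preferred disparities pile up at a
#' single pair of symmetric values (e.g. +/-0.23 deg) — a signature of
#' vergence drift at stimulus extremes or of fitting failure rather than of
#' genuine disparity tuning. The fraction of vertices within `band_deg` of
#' the dominant symmetric mode pair is compared with `frac_threshold`.
#'
#' @param fits Thresholded vertex table with `mu_deg`.
#' @param band_deg Half-width of the capture band around each mode (deg).
#' @param frac_threshold Flag when the captured fraction exceeds this.
#' @return list: `flagged` (logical), `fraction`, `mode_deg` (the dominant
#'   |mode|), `n`.
#' @export
qc_preferred_disparity_clustering <- function(fits, band_deg = 0.02,
                                              frac_threshold = 0.85) {
  mu <- fits$mu_deg[!is.na(fits$mu_deg)]
  n <- length(mu)
  if (n == 0) {
    return(list(flagged = FALSE, fraction = 0, mode_deg = NA_real_, n = 0L))
  }
  # scan candidate symmetric mode pairs on a fine magnitude grid
  cand <- seq(0, max(abs(mu)), by = band_deg / 2)
  frac <- vapply(cand, function(m) {
    mean(abs(mu - m) <= band_deg | abs(mu + m) <= band_deg)
  }, numeric(1))
  i <- which.max(frac)
  list(flagged = frac[i] > frac_threshold, fraction = frac[i],
       mode_deg = cand[i], n = n)
}

#' Gaussian width conversion factors
#'
#' Closed-form factors relating the tuning SD (sigma) of a Gaussian
#' disparity tuning curve to other width measures:
#' \itemize{
#'   \item `fwhm_factor`: full width at half height / sigma
#'     (`2 sqrt(2 ln 2)`, about 2.35);
#'   \item `disparity_scale_factor`: multiplier taking sigma to the
#'     neurophysiological "disparity scale" (reciprocal disparity frequency
#'     of a Gabor tuning fit), i.e. twice the FWHM factor, about 4.7;
#'   \item `width_scale_ratio`: the ratio of the +/-2 sigma tuning width
#'     (4 sigma) to the disparity scale, `4 / (2 fwhm_factor)`, about 0.85.
#' }
#'
#' @return Named numeric vector with the three factors.
#' @export
width_conversions <- function() {
  fwhm <- 2 * sqrt(2 * log(2))
  c(fwhm_factor = fwhm,
    disparity_scale_factor = 2 * fwhm,
    width_scale_ratio = 4 / (2 * fwhm))
}
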