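#' Gaussian disparity tuning curve
#'
#' Response of a vertex with preferred disparity `mu` and tuning standard
#' deviation `sigma` to a presented disparity `d`:
#' `exp(-(d - mu)^2 / (2 sigma^2))`, peaking at 1 when `d == mu`.
#'
#' @param d Disparity (deg); vectorized.
#' @param mu Preferred disparity (deg).
#' @param sigma Tuning standard deviation (deg), > 0.
#' @return Unitless response in (0, 1].
#' @export
gaussian_tuning <- function(d, mu, sigma) {
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  exp(-(d - mu)^2 / (2 * sigma^2))
}

#' Candidate parameter grid for the exhaustive search stage
#'
#' Default: 100 preferred disparities uniform on [-0.3, +0.3] deg crossed
#' with 100 tuning SDs geometric on [0.025, 1.5] deg, i.e. 10,000 candidate
#' model predictions. Candidates are ordered by sigma then |mu| so that the
#' first correlation maximum implements the tie-break (smaller sigma, then
#' smaller |mu|).
#'
#' @param n_mu,n_sigma Number of grid values per parameter.
#' @param mu_range Preferred-disparity range (deg).
#' @param sigma_range Tuning-SD range (deg), geometric spacing.
#' @return A `grid_spec`: data.frame `candidates` (mu, sigma) plus the
#'   generating vectors.
#' @export
prf_grid <- function(n_mu = 100L, n_sigma = 100L,
                     mu_range = c(-0.3, 0.3), sigma_range = c(0.025, 1.5)) {
  mu_values <- seq(mu_range[1], mu_range[2], length.out = n_mu)
  sigma_values <- exp(seq(log(sigma_range[1]), log(sigma_range[2]),
                          length.out = n_sigma))
  cand <- expand.grid(mu = mu_values, sigma = sigma_values,
                      KEEP.OUT.ATTRS = FALSE)
  cand <- cand[order(cand$sigma, abs(cand$mu), cand$mu), ]
  rownames(cand) <- NULL
  structure(
    list(mu_values = mu_values, sigma_values = sigma_values,
         candidates = cand, total = nrow(cand)),
    class = "grid_spec"
  )
}

#' Predicted BOLD response for one tuning curve
#'
#' Neural drive `gaussian_tuning(d_q(t), mu, sigma)` (zero during rest
#' frames) convolved with the HRF kernel, truncated to the run length and
#' mean-centered. Amplitude and offset are not applied here; they are
#' profiled out by least squares during fitting.
#'
#' @param seq A `disparity_sequence`.
#' @param quadrant One of `"UL"`, `"UR"`, `"LL"`, `"LR"`.
#' @param mu,sigma Tuning parameters (deg); `sigma > 0`.
#' @param hrf An `hrf_model`.
#' @return Mean-centered prediction vector, one value per frame.
#' @export
predict_bold <- function(seq, quadrant, mu, sigma, hrf) {
  stopifnot(inherits(seq, "disparity_sequence"), inherits(hrf, "hrf_model"))
  if (!quadrant %in% rownames(seq$disparity)) {
    stop(sprintf("quadrant '%s' not present in sequence", quadrant), call. = FALSE)
  }
  d <- seq$disparity[quadrant, ]
  drive <- ifelse(is.na(d), 0, gaussian_tuning(ifelse(is.na(d), 0, d), mu, sigma))
  pred <- convolve_truncate(drive, hrf$kernel)
  pred - mean(pred)
}

# Precompute the mean-centered, unit-norm prediction matrix for a grid and
# one quadrant. Exploits the small number of distinct disparity levels:
# tuning responses are evaluated once per (candidate, level) and expanded
# to the frame grid before a single banded convolution pass.
grid_predictions <- function(seq, quadrant, grid, hrf) {
  d <- seq$disparity[quadrant, ]
  lev <- sort(unique(d[!is.na(d)]))
  cand <- grid$candidates
  # candidates x levels tuning responses
  G <- exp(-(outer(cand$mu, lev, "-"))^2 / (2 * cand$sigma^2))
  frame_idx <- match(d, lev) # NA for rest frames
  drive <- matrix(0, nrow(cand), length(d))
  ok <- !is.na(frame_idx)
  drive[, ok] <- G[, frame_idx[ok], drop = FALSE]
  # causal convolution as multiplication by a banded lower-triangular
  # matrix, plus the steady-state pre-run contribution of the first frame
  # (matches convolve_truncate)
  n <- length(d)
  k <- hrf$kernel
  C <- matrix(0, n, n)
  for (j in seq_along(k)) {
    idx <- seq_len(n - j + 1L)
    C[cbind(idx + j - 1L, idx)] <- k[j]
  }
  w <- rev(cumsum(rev(k)))[-1L] # w[t] = sum_{j > t} k[j], t = 1..L-1
  w <- w[seq_len(min(length(w), n))]
  pre <- matrix(0, nrow(drive), n)
  pre[, seq_along(w)] <- drive[, 1L] %o% w
  P <- drive %*% t(C) + pre
  P <- P - rowMeans(P)
  nrm <- sqrt(rowSums(P^2))
  nrm[nrm == 0] <- Inf # flat predictions can never win the correlation search
  P / nrm
}

#' Exhaustive grid-search stage of the pRF fit
#'
#' For each vertex, finds the `(mu, sigma)` candidate whose HRF-convolved
#' prediction has the largest Pearson correlation with the vertex signal.
#' Ties are broken toward smaller `sigma`, then smaller `|mu|`. Vertices
#' with constant signal have undefined correlation and are flagged unfit.
#'
#' @param ts_set A `timeseries_set` (see [make_session()]).
#' @param seq A `disparity_sequence`.
#' @param hrf An `hrf_model`.
#' @param grid A `grid_spec`; default `prf_grid()`.
#' @param neighbors Optional list of integer vectors: for each vertex, the
#'   indices of its graph neighbors. When supplied, stage-1 correlations are
#'   computed on signals averaged with their neighbors (a stand-in for
#'   surface-based smoothing); the returned seeds still index the original
#'   vertices.
#' @return data.frame: `vertex_id`, `mu_seed`, `sigma_seed`, `seed_r`
#'   (Pearson r at the seed; `-Inf` for unfit vertices).
#' @export
grid_fit <- function(ts_set, seq, hrf, grid = prf_grid(), neighbors = NULL) {
  stopifnot(inherits(ts_set, "timeseries_set"))
  sig <- ts_set$signals # vertices x frames
  if (!is.null(neighbors)) {
    sm <- sig
    for (v in seq_len(nrow(sig))) {
      idx <- c(v, neighbors[[v]])
      sm[v, ] <- colMeans(sig[idx, , drop = FALSE])
    }
    sig <- sm
  }
  cand <- grid$candidates
  out <- data.frame(vertex_id = ts_set$vertex_id,
                    mu_seed = NA_real_, sigma_seed = NA_real_,
                    seed_r = -Inf)
  for (q in unique(ts_set$quadrant)) {
    vsel <- which(ts_set$quadrant == q)
    P <- grid_predictions(seq, q, grid, hrf) # candidates x frames, unit norm
    S <- sig[vsel, , drop = FALSE]
    S <- S - rowMeans(S)
    nrm <- sqrt(rowSums(S^2))
    defined <- nrm > 0
    S[defined, ] <- S[defined, , drop = FALSE] / nrm[defined]
    R <- P %*% t(S) # candidates x vertices correlation matrix
    best <- apply(R, 2L, which.max) # first max = tie-break by candidate order
    out$mu_seed[vsel] <- cand$mu[best]
    out$sigma_seed[vsel] <- cand$sigma[best]
    out$seed_r[vsel] <- R[cbind(best, seq_along(vsel))]
    out$seed_r[vsel[!defined]] <- -Inf
  }
  out
}

# OLS of y on a mean-centered prediction: returns beta, baseline, rss, r2.
profile_amplitude <- function(y, pred) {
  ssp <- sum(pred^2)
  if (ssp == 0) {
    base <- mean(y)
    rss <- sum((y - base)^2)
    return(list(beta = 0, baseline = base, rss = rss,
                r2 = ifelse(rss == 0, 1, 0)))
  }
  beta <- sum(pred * y) / ssp
  baseline <- mean(y) # pred is mean-zero
  resid <- y - baseline - beta * pred
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  list(beta = beta, baseline = baseline, rss = rss,
       r2 = if (tss > 0) 1 - rss / tss else ifelse(rss == 0, 1, -Inf))
}

#' Nonlinear refinement stage of the pRF fit
#'
#' Refines a grid seed by derivative-free simplex minimization of the
#' residual sum of squares over `(mu, sigma)`, with amplitude and baseline
#' solved in closed form at every evaluation. Bounds are enforced by
#' clamping inside the objective. `r2` is computed against the supplied
#' (unsmoothed) signal.
#'
#' @param ts Signal vector for one vertex.
#' @param seq A `disparity_sequence`.
#' @param quadrant Quadrant label of the vertex.
#' @param hrf An `hrf_model`.
#' @param seed Numeric `c(mu, sigma)` starting point.
#' @param mu_bounds,sigma_bounds Box constraints (deg).
#' @param reltol,maxit Simplex convergence controls.
#' @return A one-row data.frame (`prf_fit` row): `mu`, `sigma`, `beta`,
#'   `baseline`, `r2`, `width` (= 4 sigma), `converged`.
#' @export
refine_fit <- function(ts, seq, quadrant, hrf, seed,
                       mu_bounds = c(-0.6, 0.6), sigma_bounds = c(0.01, 3),
                       reltol = 1e-10, maxit = 500L) {
  clamp <- function(x, b) pmin(pmax(x, b[1]), b[2])
  obj <- function(par) {
    mu <- clamp(par[1], mu_bounds)
    sigma <- clamp(par[2], sigma_bounds)
    pred <- predict_bold(seq, quadrant, mu, sigma, hrf)
    profile_amplitude(ts, pred)$rss
  }
  fit <- tryCatch(
    stats::optim(seed, obj, method = "Nelder-Mead",
                 control = list(reltol = reltol, maxit = maxit)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    par <- seed
    converged <- FALSE
  } else {
    par <- fit$par
    converged <- fit$convergence == 0
  }
  mu <- clamp(par[1], mu_bounds)
  sigma <- clamp(par[2], sigma_bounds)
  # guard: never return a fit worse than the seed
  if (!is.null(fit)) {
    seed_rss <- obj(seed)
    if (fit$value > seed_rss) {
      mu <- clamp(seed[1], mu_bounds)
      sigma <- clamp(seed[2], sigma_bounds)
      converged <- FALSE
    }
  }
  pred <- predict_bold(seq, quadrant, mu, sigma, hrf)
  amp <- profile_amplitude(ts, pred)
  data.frame(mu = mu, sigma = sigma, beta = amp$beta, baseline = amp$baseline,
             r2 = amp$r2, width = 4 * sigma, converged = converged)
}

#' Fit disparity tuning curves for a set of vertices
#'
#' Runs the full two-stage procedure: exhaustive grid search for a seed,
#' then nonlinear refinement per vertex. Returns a vertex table in the
#' package's standard layout.
#'
#' @inheritParams grid_fit
#' @param filter Logical; apply the 0.02-0.2 Hz band-pass to signals before
#'   fitting (predictions are fitted to whatever signal is supplied).
#' @return data.frame with columns `vertex_id`, `area`, `hemisphere`,
#'   `quadrant`, `condition`, `mu_deg`, `sigma_deg`, `beta`, `baseline`,
#'   `r2`, `width_deg`, `converged`.
#' @export
fit_prf <- function(ts_set, seq, hrf, grid = prf_grid(), neighbors = NULL,
                    filter = FALSE) {
  stopifnot(inherits(ts_set, "timeseries_set"))
  if (filter) {
    ts_set$signals <- t(apply(ts_set$signals, 1L, bandpass,
                              tr_s = ts_set$tr_s))
  }
  seeds <- grid_fit(ts_set, seq, hrf, grid, neighbors)
  n <- nrow(seeds)
  rows <- vector("list", n)
  for (v in seq_len(n)) {
    if (!is.finite(seeds$seed_r[v])) {
      rows[[v]] <- data.frame(mu = NA_real_, sigma = NA_real_, beta = NA_real_,
                              baseline = NA_real_, r2 = -Inf, width = NA_real_,
                              converged = FALSE)
      next
    }
    rows[[v]] <- refine_fit(ts_set$signals[v, ], seq, ts_set$quadrant[v], hrf,
                            c(seeds$mu_seed[v], seeds$sigma_seed[v]))
  }
  fits <- do.call(rbind, rows)
  data.frame(
    vertex_id = ts_set$vertex_id,
    area = ts_set$area,
    hemisphere = ts_set$hemisphere,
    quadrant = ts_set$quadrant,
    condition = if (seq$correlation_flag == "correlated") "corr" else "anticorr",
    mu_deg = fits$mu, sigma_deg = fits$sigma, beta = fits$beta,
    baseline = fits$baseline, r2 = fits$r2, width_deg = fits$width,
    converged = fits$converged,
    stringsAsFactors = FALSE
  )
}

#' Apply goodness-of-fit and width inclusion thresholds
#'
#' Retains vertices with `r2 > r2_min` (strict) and tuning width
#' `width_deg > width_min` (strict). Widths at or below 0.1 deg are treated
#' as non-physiological fitting artifacts. Counts at each stage are
#' attached for bookkeeping.
#'
#' @param fits Vertex table with `r2` and `width_deg` columns.
#' @param r2_min Goodness-of-fit threshold (default 0.1).
#' @param width_min Width threshold in degrees (default 0.1).
#' @return The filtered table, with attribute `"stage_counts"`:
#'   `c(total, pass_r2, pass_r2_width)`.
#' @export
apply_thresholds <- function(fits, r2_min = 0.1, width_min = 0.1) {
  stopifnot(all(c("r2", "width_deg") %in% names(fits)))
  pass_r2 <- !is.na(fits$r2) & fits$r2 > r2_min
  pass_both <- pass_r2 & !is.na(fits$width_deg) & fits$width_deg > width_min
  out <- fits[pass_both, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stage_counts") <- c(total = nrow(fits),
                                 pass_r2 = sum(pass_r2),
                                 pass_r2_width = sum(pass_both))
  out
}
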