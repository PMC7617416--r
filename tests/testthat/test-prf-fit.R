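test_that("Gaussian tuning curve has the closed-form peak and spread", {
  expect_equal(gaussian_tuning(0.12, 0.12, 0.2), 1)
  expect_equal(gaussian_tuning(0.12 + 0.2, 0.12, 0.2), exp(-0.5))
  expect_equal(gaussian_tuning(0.12 - 0.2, 0.12, 0.2), exp(-0.5))
  expect_error(gaussian_tuning(0, 0, -1), "sigma")
  # full width at half height / sigma = 2 sqrt(2 ln 2)
  sigma <- 0.17
  half_d <- sigma * sqrt(2 * log(2))
  expect_equal(gaussian_tuning(half_d, 0, sigma), 0.5)
  expect_equal(2 * half_d / sigma, 2.35, tolerance = 0.005)
})

test_that("predictions saturate for very broad tuning and lag the drive", {
  s <- short_sequence()
  h <- canonical_hrf()
  p_broad <- predict_bold(s, "UL", 0, 10, h)
  p_narrow <- predict_bold(s, "UL", 0, 0.1, h)
  expect_lt(stats::var(p_broad), 0.01 * stats::var(p_narrow))
  # prediction is mean-centered
  expect_lt(abs(mean(p_narrow)), 1e-12)
  # scale the drive: Pearson correlation with any target is unchanged
  target <- p_narrow + rnorm(length(p_narrow), sd = 0.1)
  expect_equal(cor(p_narrow, target), cor(3.7 * p_narrow, target))
  # HRF delay: the convolved response to an isolated drive peaks later
  drive <- gaussian_tuning(ifelse(is.na(s$disparity["UL", ]), 0,
                                  s$disparity["UL", ]), 0, 0.1)
  lag <- which.max(stats::ccf(p_narrow, drive, lag.max = 10,
                              plot = FALSE)$acf) - 11
  expect_gte(lag, 2) # roughly the HRF peak delay in TRs (~4)
  expect_error(predict_bold(s, "XX", 0, 0.1, h), "quadrant")
})

test_that("grid search recovers on-grid parameters exactly and reports grid size", {
  grid <- prf_grid()
  expect_equal(grid$total, 10000L)
  expect_equal(length(grid$mu_values), 100L)
  expect_equal(length(grid$sigma_values), 100L)

  s <- short_sequence(n_cycles = 6)
  h <- canonical_hrf()
  small <- prf_grid(n_mu = 15, n_sigma = 12)
  pop <- make_vertex_population(8, noise_sd = 0, seed = 3)
  # overwrite truths with on-grid values
  set.seed(3)
  idx_mu <- sample(seq_len(15), 8, replace = TRUE)
  idx_sg <- sample(seq_len(12), 8, replace = TRUE)
  pop$true_mu <- small$mu_values[idx_mu]
  pop$true_sigma <- small$sigma_values[idx_sg]
  ts <- make_session(pop, s, h, seed = 4)
  seeds <- grid_fit(ts, s, h, small)
  expect_equal(seeds$mu_seed, pop$true_mu, tolerance = 1e-12)
  expect_equal(seeds$sigma_seed, pop$true_sigma, tolerance = 1e-12)
})

test_that("grid search matches an independent exhaustive-search oracle", {
  s <- short_sequence(n_cycles = 5)
  h <- canonical_hrf()
  grid <- prf_grid(n_mu = 12, n_sigma = 10)
  pop <- make_vertex_population(20, noise_sd = 0, seed = 31)
  clean <- make_session(pop, s, h, seed = 31)
  pop$noise_sd <- 0.7 * apply(clean$signals, 1, sd)
  ts <- make_session(pop, s, h, seed = 32)

  fast <- grid_fit(ts, s, h, grid)
  oracle <- oracle_grid_search(ts, s, h, grid)
  expect_equal(fast$mu_seed, oracle$mu, tolerance = 1e-12)
  expect_equal(fast$sigma_seed, oracle$sigma, tolerance = 1e-12)
})

test_that("constant signals are flagged unfit rather than fitted", {
  s <- short_sequence()
  h <- canonical_hrf()
  pop <- make_vertex_population(2, noise_sd = 0, seed = 1)
  ts <- make_session(pop, s, h, seed = 1)
  ts$signals[2, ] <- 3.3
  seeds <- grid_fit(ts, s, h, prf_grid(10, 10))
  expect_true(is.finite(seeds$seed_r[1]))
  expect_identical(seeds$seed_r[2], -Inf)
  fits <- fit_prf(ts, s, h, prf_grid(10, 10))
  expect_identical(fits$r2[2], -Inf)
  expect_equal(nrow(apply_thresholds(fits)), 1L)
})

test_that("refinement recovers off-grid parameters from noiseless signals", {
  s <- short_sequence(n_cycles = 6)
  h <- canonical_hrf()
  truth <- list(mu = 0.073, sigma = 0.11, beta = 1.4, baseline = 80)
  clean <- truth$beta *
    disparityprf:::convolve_truncate(
      gaussian_tuning(s$disparity["LL", ], truth$mu, truth$sigma), h$kernel) +
    truth$baseline
  fit <- refine_fit(clean, s, "LL", h, seed = c(0.05, 0.15))
  expect_lt(abs(fit$mu - truth$mu), 1e-3)
  expect_lt(abs(fit$sigma - truth$sigma), 1e-3)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(fit$beta, truth$beta, tolerance = 1e-3)
  expect_equal(fit$width, 4 * fit$sigma)
})

test_that("refinement never degrades the seed fit", {
  s <- short_sequence(n_cycles = 4)
  h <- canonical_hrf()
  pop <- make_vertex_population(5, noise_sd = 0, seed = 8)
  clean <- make_session(pop, s, h, seed = 8)
  pop$noise_sd <- 1.0 * apply(clean$signals, 1, sd)
  ts <- make_session(pop, s, h, seed = 9)
  grid <- prf_grid(10, 10)
  seeds <- grid_fit(ts, s, h, grid)
  for (v in 1:5) {
    y <- ts$signals[v, ]
    seed_pred <- predict_bold(s, ts$quadrant[v], seeds$mu_seed[v],
                              seeds$sigma_seed[v], h)
    seed_r2 <- disparityprf:::profile_amplitude(y, seed_pred)$r2
    fit <- refine_fit(y, s, ts$quadrant[v], h,
                      c(seeds$mu_seed[v], seeds$sigma_seed[v]))
    expect_gte(fit$r2, seed_r2 - 1e-12)
  }
})

test_that("fitted width always equals four sigma and r2 drops with noise", {
  s <- short_sequence(n_cycles = 5)
  h <- canonical_hrf()
  pop <- make_vertex_population(12, noise_sd = 0, seed = 13)
  clean <- make_session(pop, s, h, seed = 13)
  base_sd <- apply(clean$signals, 1, sd)
  med_r2 <- vapply(c(0.2, 0.8, 2.0), function(frac) {
    pop$noise_sd <- frac * base_sd
    ts <- make_session(pop, s, h, seed = 14)
    fits <- fit_prf(ts, s, h, prf_grid(20, 20))
    expect_equal(fits$width_deg, 4 * fits$sigma_deg)
    median(fits$r2)
  }, numeric(1))
  expect_true(all(diff(med_r2) < 0))
})

test_that("inclusion thresholds follow strict r2 and width rules", {
  toy <- data.frame(
    r2 = c(0.05, 0.2, 0.2, 0.1, 0.11),
    width_deg = c(0.5, 0.05, 0.5, 0.5, 0.101)
  )
  toy$mu_deg <- 0
  kept <- apply_thresholds(toy)
  expect_equal(nrow(kept), 2L)
  expect_equal(attr(kept, "stage_counts"),
               c(total = 5L, pass_r2 = 3L, pass_r2_width = 2L))
  # strictness at the boundary: r2 = 0.1 and width = 0.1 are excluded
  expect_false(any(kept$r2 == 0.1))

  empty <- apply_thresholds(toy[0, ])
  expect_equal(nrow(empty), 0L)
  expect_equal(unname(attr(empty, "stage_counts")), c(0L, 0L, 0L))

  # monotone filtering: survivors are a subset of the r2-only filter
  r2_only <- toy[!is.na(toy$r2) & toy$r2 > 0.1, ]
  expect_true(all(rownames(kept) %in% rownames(r2_only) |
                    kept$r2 %in% r2_only$r2))
})

test_that("stage-1 neighbor smoothing averages signals but r2 uses originals", {
  s <- short_sequence(n_cycles = 5)
  h <- canonical_hrf()
  pop <- make_vertex_population(4, noise_sd = 0, seed = 17)
  pop$quadrant <- "UL"
  pop$hemisphere <- "RH"
  pop$true_mu <- rep(0.1, 4)
  pop$true_sigma <- rep(0.2, 4)
  clean <- make_session(pop, s, h, seed = 17)
  pop$noise_sd <- 2 * apply(clean$signals, 1, sd)
  ts <- make_session(pop, s, h, seed = 18)
  neighbors <- list(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  with_sm <- grid_fit(ts, s, h, prf_grid(20, 20), neighbors = neighbors)
  # all vertices share the same smoothed signal -> identical seeds
  expect_equal(length(unique(with_sm$mu_seed)), 1L)
  expect_equal(length(unique(with_sm$sigma_seed)), 1L)
})
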