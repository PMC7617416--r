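# Shared fixtures, built in code at test time.

default_levels <- function() log_disparity_levels(20, 0.01, 0.3)

short_sequence <- function(n_cycles = 4L, seed = 1L, rest_frames = 0L) {
  build_sequence(default_levels(), n_cycles = n_cycles, tr_s = 1.355,
                 seed = seed, rest_frames = rest_frames)
}

canonical_hrf <- function(tr_s = 1.355) double_gamma_hrf(tr_s = tr_s)

# Small synthetic session with optional per-vertex noise scaled to the
# noiseless signal SD.
small_session <- function(n = 10L, noise_frac = 0, seed = 21L, ...) {
  pop <- make_vertex_population(n, noise_sd = 0, seed = seed, ...)
  if (noise_frac > 0) {
    clean <- make_session(pop, seed = seed)
    pop$noise_sd <- noise_frac * apply(clean$signals, 1, stats::sd)
  }
  make_session(pop, seed = seed + 1L)
}

# Independent brute-force exhaustive grid search: per-vertex loop over
# candidates with plain cor(), same tie-break (first max in candidate order).
oracle_grid_search <- function(ts_set, seq, hrf, grid) {
  cand <- grid$candidates
  out <- data.frame(mu = numeric(nrow(ts_set$signals)),
                    sigma = numeric(nrow(ts_set$signals)))
  for (v in seq_len(nrow(ts_set$signals))) {
    y <- ts_set$signals[v, ]
    best_r <- -Inf
    best_i <- NA_integer_
    for (i in seq_len(nrow(cand))) {
      p <- predict_bold(ts_set$seq, ts_set$quadrant[v], cand$mu[i],
                        cand$sigma[i], hrf)
      r <- suppressWarnings(stats::cor(p, y))
      if (is.finite(r) && r > best_r) {
        best_r <- r
        best_i <- i
      }
    }
    out$mu[v] <- cand$mu[best_i]
    out$sigma[v] <- cand$sigma[best_i]
  }
  out
}

# Rank-then-Pearson Spearman oracle with average ranks for ties.
oracle_spearman <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}
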