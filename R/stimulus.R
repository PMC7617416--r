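#' Log-scaled signed disparity levels
#'
#' Builds the set of signed disparity values presented during a stimulation
#' cycle: `n_steps / 2` magnitudes geometrically spaced between `d_min_mag`
#' and `d_max_mag`, mirrored about zero. Geometric spacing concentrates
#' sampling at small disparities, where tuning is narrowest; zero itself is
#' never a level (log spacing is undefined at 0).
#'
#' @param n_steps Even integer, total number of signed levels (default 20).
#' @param d_min_mag Smallest disparity magnitude in degrees (> 0).
#' @param d_max_mag Largest disparity magnitude in degrees.
#' @return An object of class `disparity_levels` with fields
#'   `signed_levels` (sorted ascending), `d_min_mag`, `d_max_mag`, `n_steps`.
#' @examples
#' lv <- log_disparity_levels(20, 0.01, 0.3)
#' range(lv$signed_levels) # -0.3 0.3
#' @export
log_disparity_levels <- function(n_steps = 20L, d_min_mag = 0.01, d_max_mag = 0.3) {
  if (n_steps < 2 || n_steps %% 2 != 0) {
    stop("`n_steps` must be an even integer >= 2", call. = FALSE)
  }
  if (d_min_mag <= 0) {
    stop("`d_min_mag` must be > 0: log spacing is undefined at 0", call. = FALSE)
  }
  if (d_min_mag >= d_max_mag) {
    stop("`d_min_mag` must be smaller than `d_max_mag`", call. = FALSE)
  }
  m <- n_steps %/% 2L
  mags <- exp(seq(log(d_min_mag), log(d_max_mag), length.out = m))
  structure(
    list(
      signed_levels = sort(c(-mags, mags)),
      d_min_mag = d_min_mag,
      d_max_mag = d_max_mag,
      n_steps = as.integer(n_steps)
    ),
    class = "disparity_levels"
  )
}

#' Build a disparity stimulation sequence
#'
#' Generates the per-quadrant signed disparity time course used as the pRF
#' regressor. Each cycle presents every signed level exactly once per
#' quadrant: magnitudes ramp small -> large -> small (a full disparity
#' oscillation), with two quadrants at positive (far) and two at negative
#' (near) disparity on every frame, so the total disparity per frame is
#' exactly zero. The two-positive / two-negative assignment is drawn
#' pseudorandomly for each cycle and negated on the down-ramp, so each
#' quadrant covers both signs of every magnitude within a cycle.
#'
#' @param levels A `disparity_levels` object.
#' @param n_cycles Number of oscillation cycles (>= 1).
#' @param frames_per_step Frames (TRs) spent on each step (>= 1).
#' @param tr_s Repetition time in seconds.
#' @param correlation_flag `"correlated"` or `"anticorrelated"`. Metadata
#'   only: the disparity regressor is identical for both stimulus types.
#' @param seed Integer seed for the cycle-wise sign assignment.
#' @param rest_frames Trailing rest frames (disparity `NA`, zero drive)
#'   appended after the last cycle, e.g. to pad a 13-cycle run to the full
#'   268-volume acquisition.
#' @return A `disparity_sequence`: `times` (s), `disparity` (4 x T matrix,
#'   rows UL/UR/LL/LR), `correlation_flag`, `tr_s`, `cycle_index` (NA for
#'   rest frames), `levels`, `seed`.
#' @export
build_sequence <- function(levels, n_cycles = 13L, frames_per_step = 1L,
                           tr_s = 1.355, correlation_flag = c("correlated", "anticorrelated"),
                           seed = 1L, rest_frames = 0L) {
  stopifnot(inherits(levels, "disparity_levels"))
  if (n_cycles < 1) stop("`n_cycles` must be >= 1", call. = FALSE)
  if (frames_per_step < 1) stop("`frames_per_step` must be >= 1", call. = FALSE)
  correlation_flag <- match.arg(correlation_flag)

  mags <- sort(unique(abs(levels$signed_levels)))
  m <- length(mags)
  ramp <- c(mags, rev(mags))             # small -> large -> small oscillation
  ramp_sign <- rep(c(1, -1), each = m)   # down-ramp negates quadrant signs

  quadrants <- c("UL", "UR", "LL", "LR")
  steps_per_cycle <- 2L * m
  n_frames <- n_cycles * steps_per_cycle * frames_per_step

  disparity <- matrix(NA_real_, nrow = 4L, ncol = n_frames,
                      dimnames = list(quadrants, NULL))
  cycle_index <- integer(n_frames)

  with_seed(seed, {
    for (cy in seq_len(n_cycles)) {
      pos <- sample.int(4L, 2L)          # quadrants at far disparity on up-ramp
      sign_q <- rep(-1, 4L)
      sign_q[pos] <- 1
      block <- (sign_q %o% ramp_sign) * matrix(ramp, 4L, steps_per_cycle, byrow = TRUE)
      block <- block[, rep(seq_len(steps_per_cycle), each = frames_per_step), drop = FALSE]
      idx <- ((cy - 1L) * steps_per_cycle * frames_per_step + 1L):
        (cy * steps_per_cycle * frames_per_step)
      disparity[, idx] <- block
      cycle_index[idx] <- cy
    }
  })

  if (rest_frames > 0) {
    disparity <- cbind(disparity, matrix(NA_real_, 4L, rest_frames))
    cycle_index <- c(cycle_index, rep(NA_integer_, rest_frames))
  }
  total <- ncol(disparity)
  structure(
    list(
      times = (seq_len(total) - 1L) * tr_s,
      disparity = disparity,
      correlation_flag = correlation_flag,
      tr_s = tr_s,
      cycle_index = cycle_index,
      levels = levels,
      seed = as.integer(seed)
    ),
    class = "disparity_sequence"
  )
}

#' @export
print.disparity_sequence <- function(x, ...) {
  cat(sprintf(
    "disparity_sequence: %d frames (TR %.3f s), %d cycles, %s, %d levels [%.3g, %.3g] deg\n",
    ncol(x$disparity), x$tr_s, max(x$cycle_index, na.rm = TRUE),
    x$correlation_flag, x$levels$n_steps, -x$levels$d_max_mag, x$levels$d_max_mag
  ))
  invisible(x)
}

#' Write / read a stimulus sequence as TSV + JSON sidecar
#'
#' Long-format TSV with columns `frame_index`, `time_s`, `quadrant`,
#' `disparity_deg`, `cycle_index`; the sidecar (same path with `.json`
#' appended) stores `tr_s`, `correlation_flag`, `seed` and the level set.
#'
#' @param seq A `disparity_sequence`.
#' @param path Output TSV path.
#' @return `path`, invisibly (writer); a `disparity_sequence` (reader).
#' @export
write_stimulus_tsv <- function(seq, path) {
  stopifnot(inherits(seq, "disparity_sequence"))
  n <- ncol(seq$disparity)
  df <- data.frame(
    frame_index = rep(seq_len(n), each = 4L),
    time_s = rep(seq$times, each = 4L),
    quadrant = rep(rownames(seq$disparity), times = n),
    disparity_deg = as.vector(seq$disparity),
    cycle_index = rep(seq$cycle_index, each = 4L)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(tr_s = seq$tr_s, correlation_flag = seq$correlation_flag,
         seed = seq$seed, n_steps = seq$levels$n_steps,
         d_min_mag = seq$levels$d_min_mag, d_max_mag = seq$levels$d_max_mag),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_stimulus_tsv
#' @export
read_stimulus_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  quadrants <- c("UL", "UR", "LL", "LR")
  n <- max(df$frame_index)
  disparity <- matrix(NA_real_, 4L, n, dimnames = list(quadrants, NULL))
  for (q in quadrants) {
    sub <- df[df$quadrant == q, ]
    disparity[q, sub$frame_index] <- sub$disparity_deg
  }
  cycle_index <- rep(NA_integer_, n)
  first <- df[df$quadrant == quadrants[1L], ]
  cycle_index[first$frame_index] <- first$cycle_index
  structure(
    list(
      times = (seq_len(n) - 1L) * side$tr_s,
      disparity = disparity,
      correlation_flag = side$correlation_flag,
      tr_s = side$tr_s,
      cycle_index = cycle_index,
      levels = log_disparity_levels(side$n_steps, side$d_min_mag, side$d_max_mag),
      seed = as.integer(side$seed)
    ),
    class = "disparity_sequence"
  )
}
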