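vertex_table_required_cols <- c("vertex_id", "area", "hemisphere", "quadrant",
                                "condition", "mu_deg", "sigma_deg", "beta",
                                "baseline", "r2", "width_deg")

#' Write / read a vertex parameter table
#'
#' Tab-separated, UTF-8, '.' decimal. The reader validates the required
#' schema and preserves any extra columns.
#'
#' @param fits Vertex table (see [fit_prf()]).
#' @param path TSV path.
#' @return `path`, invisibly (writer); the table (reader).
#' @export
write_vertex_table <- function(fits, path) {
  missing <- setdiff(vertex_table_required_cols, names(fits))
  if (length(missing)) {
    stop(sprintf("vertex table missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  utils::write.table(fits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vertex_table
#' @export
read_vertex_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(vertex_table_required_cols, names(tab))
  if (length(missing)) {
    stop(sprintf("vertex table missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  tab
}

#' Write / read a threshold table
#'
#' @param thresholds 12-row data.frame from [run_full_session()].
#' @param path TSV path.
#' @return `path`, invisibly (writer); the table (reader).
#' @export
write_threshold_table <- function(thresholds, path) {
  utils::write.table(thresholds, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_threshold_table
#' @export
read_threshold_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end pipeline in one list, suitable
#' for serialization to JSON and lossless round-tripping.
#'
#' @param n_vertices Vertices in the synthetic population.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A named list of stage configurations.
#' @export
default_config <- function(n_vertices = 200L, seed = 1L) {
  list(
    seed = as.integer(seed),
    stimulus = list(n_steps = 20L, d_min_mag = 0.01, d_max_mag = 0.3,
                    n_cycles = 13L, tr_s = 1.355, rest_frames = 8L),
    population = list(n = as.integer(n_vertices), noise_sd = 0.5,
                      width_relation = c(c = 0.3, a = 4, scatter = 0.05)),
    fit = list(n_mu = 100L, n_sigma = 100L, r2_min = 0.1, width_min = 0.1),
    quest = list(n_trials = 50L),
    correlate = list(n_areas = 9L)
  )
}

#' Run the full synthetic-data pipeline
#'
#' Executes stimulus simulation -> session simulation -> pRF fitting ->
#' thresholding -> tuning analysis -> psychophysics simulation ->
#' resolution limits -> brain-behavior correlation, and returns a run
#' report with staged vertex counts and all seeds. With `out_dir` set,
#' intermediate tables are written as TSV/JSON.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Optional output directory.
#' @return list report: `config`, `stage_counts`, `model_comparison`,
#'   `thresholds`, `resolution`, `correlations`, `fits`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  seed <- config$seed
  st <- config$stimulus
  levels <- log_disparity_levels(st$n_steps, st$d_min_mag, st$d_max_mag)
  seq <- build_sequence(levels, n_cycles = st$n_cycles, tr_s = st$tr_s,
                        seed = seed, rest_frames = st$rest_frames)
  hrf <- double_gamma_hrf(tr_s = st$tr_s)

  pop <- make_vertex_population(config$population$n,
                                width_relation = config$population$width_relation,
                                noise_sd = config$population$noise_sd,
                                seed = seed + 1L)
  ts_set <- make_session(pop, seq, hrf, seed = seed + 2L)

  grid <- prf_grid(config$fit$n_mu, config$fit$n_sigma)
  fits <- fit_prf(ts_set, seq, hrf, grid)
  fits$participant <- pop$participant
  kept <- apply_thresholds(fits, config$fit$r2_min, config$fit$width_min)
  counts <- attr(kept, "stage_counts")

  comparison <- if (nrow(kept) >= 3 && stats::var(abs(kept$mu_deg)) > 0) {
    compare_models(kept$mu_deg, kept$width_deg)
  } else NULL

  observers <- make_observer_set(seed = seed + 3L)
  session <- run_full_session(observers, n_trials = config$quest$n_trials,
                              seed = seed + 4L)
  thresholds <- session$thresholds
  thresholds$participant <- 1L

  binned <- bin_by_pedestal(kept)
  res <- resolution_table(binned)
  correlations <- lapply(intersect(visual_areas(), unique(res$area)),
                         function(a) {
    match_and_correlate(res, thresholds, a,
                        n_areas = config$correlate$n_areas)
  })

  report <- list(config = config,
                 stage_counts = counts,
                 n_successful_trials = session$n_successful_total,
                 model_comparison = comparison,
                 thresholds = thresholds,
                 resolution = res,
                 correlations = correlations,
                 fits = fits)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_stimulus_tsv(seq, file.path(out_dir, "stimulus.tsv"))
    write_vertex_table(fits, file.path(out_dir, "fits.tsv"))
    write_threshold_table(thresholds, file.path(out_dir, "thresholds.tsv"))
    utils::write.table(res, file.path(out_dir, "resolution.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed,
           stage_counts = as.list(counts),
           n_successful_trials = session$n_successful_total,
           delta_aicc = comparison$delta_aicc %||% NA,
           poly_probability = comparison$poly_probability %||% NA),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}
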