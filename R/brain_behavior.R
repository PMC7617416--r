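#' Assign vertices to pedestal bins by preferred disparity
#'
#' Vertices with preferred disparity below -0.1 deg are assigned to the
#' "near" pedestal, those between -0.1 and +0.1 deg (boundaries inclusive)
#' to "fixation", and those above +0.1 deg to "far", matching the pedestal
#' disparities of the psychophysical task.
#'
#' @param fits Thresholded vertex table with `mu_deg`.
#' @param boundary_deg Bin boundary magnitude (deg).
#' @return `fits` with an added `pedestal` column.
#' @export
bin_by_pedestal <- function(fits, boundary_deg = 0.1) {
  mu <- fits$mu_deg
  fits$pedestal <- ifelse(mu < -boundary_deg, "near",
                          ifelse(mu > boundary_deg, "far", "fixation"))
  fits
}

#' Disparity resolution limit of a width sample
#'
#' The 10% quantile of the tuning widths in a matched cell, taken as the
#' sharpest population tuning available there. Quantiles use linear
#' interpolation between order statistics with plotting positions
#' `(k - 1) / (n - 1)`. The median is returned alongside for the
#' robustness variant.
#'
#' @param widths Numeric vector of tuning widths (deg), non-empty.
#' @param prob Quantile level (default 0.1).
#' @return list: `q10`, `median`, `n`.
#' @export
resolution_limit <- function(widths, prob = 0.1) {
  widths <- widths[!is.na(widths)]
  if (length(widths) == 0) stop("empty width sample: missing cell", call. = FALSE)
  list(q10 = unname(stats::quantile(widths, prob, type = 7)),
       median = unname(stats::median(widths)), n = length(widths))
}

#' Per-cell resolution-limit table
#'
#' Splits a thresholded, pedestal-binned vertex table by participant, area,
#' hemifield cell and pedestal bin and computes the 10% quantile and median
#' width for every non-empty cell. Empty cells are dropped (absent rows),
#' mirroring missing-point bookkeeping in the correlation analysis.
#'
#' @param fits Vertex table with `participant`, `area`, `quadrant`,
#'   `pedestal`, `width_deg` columns (see [bin_by_pedestal()]).
#' @param cell_by Columns defining the hemifield cell (default `quadrant`,
#'   i.e. 2 vertical x 2 horizontal cells).
#' @return data.frame: keys plus `q10_width`, `median_width`, `n_vertices`.
#' @export
resolution_table <- function(fits, cell_by = "quadrant") {
  keys <- c("participant", "area", cell_by, "pedestal")
  stopifnot(all(c(keys, "width_deg") %in% names(fits)))
  split_f <- interaction(fits[keys], drop = TRUE)
  rows <- lapply(split(fits, split_f), function(sub) {
    rl <- resolution_limit(sub$width_deg)
    cbind(sub[1L, keys, drop = FALSE],
          data.frame(q10_width = rl$q10, median_width = rl$median,
                     n_vertices = rl$n))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlate resolution limits with stereoacuity thresholds
#'
#' Joins the per-cell resolution table with the per-condition threshold
#' table on (participant, hemifield cell, pedestal) and computes the
#' Spearman rank correlation (average ranks for ties, two-sided p) within
#' one visual area, Bonferroni-corrected for the number of areas tested.
#'
#' @param resolution Output of [resolution_table()].
#' @param thresholds data.frame with `participant`, the cell column(s),
#'   `pedestal`, and `threshold_deg` (or `threshold_log10`).
#' @param area Visual area to test.
#' @param n_areas Bonferroni correction factor (default 9).
#' @param cell_by Hemifield-cell key column(s) shared by both tables.
#' @param metric Resolution metric: `"q10_width"` or `"median_width"`.
#' @return list: `area`, `rho`, `p_raw`, `p_bonf`, `n`. When fewer than 3
#'   pairs match, `rho` and the p values are `NA`.
#' @export
match_and_correlate <- function(resolution, thresholds, area, n_areas = 9L,
                                cell_by = "quadrant", metric = "q10_width") {
  keys <- c("participant", cell_by, "pedestal")
  res <- resolution[resolution$area == area, , drop = FALSE]
  merged <- merge(res, thresholds, by = keys)
  y <- if ("threshold_deg" %in% names(merged)) merged$threshold_deg
       else merged$threshold_log10
  x <- merged[[metric]]
  n <- nrow(merged)
  if (n < 3) {
    return(list(area = area, rho = NA_real_, p_raw = NA_real_,
                p_bonf = NA_real_, n = n))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(area = area, rho = unname(ct$estimate), p_raw = ct$p.value,
       p_bonf = min(1, n_areas * ct$p.value), n = n)
}

#' End-to-end linkage recovery check
#'
#' Validates the brain-behavior stage on synthetic cohorts: participants'
#' per-cell 10% quantile widths are generated directly, thresholds are a
#' monotone function of the linked area's resolution limit (plus log-normal
#' noise) and unrelated to all other areas. The check reports, per
#' replicate, whether the linked area attains the largest Spearman rho and
#' whether all unlinked areas stay nonsignificant after Bonferroni
#' correction.
#'
#' @param n_participants Cohort size.
#' @param areas Visual area labels; the first is the linked area.
#' @param link_slope Slope of the log-threshold on q10-width map.
#' @param noise_sd_log10 SD of threshold noise in log10 units.
#' @param n_replicates Number of seeded cohorts.
#' @param seed Integer seed.
#' @return list: `detection_rate` (fraction of replicates where the linked
#'   area has the largest rho), `null_fpr` (fraction of unlinked area tests
#'   with `p_bonf <= 0.05`), `rho_linked`, `rho_unlinked` (medians).
#' @export
synthetic_linkage_check <- function(n_participants = 9L,
                                    areas = c("V1", "V2", "V3"),
                                    link_slope = 1.0, noise_sd_log10 = 0.1,
                                    n_replicates = 100L, seed = 1L) {
  grid <- condition_grid()
  with_seed(seed, {
    hit <- logical(n_replicates)
    null_sig <- 0L
    null_tests <- 0L
    rho_l <- numeric(n_replicates)
    rho_u <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      cells <- expand.grid(participant = seq_len(n_participants),
                           cell = seq_len(nrow(grid)),
                           KEEP.OUT.ATTRS = FALSE)
      res <- do.call(rbind, lapply(areas, function(a) {
        data.frame(participant = cells$participant,
                   area = a,
                   quadrant = grid$quadrant[cells$cell],
                   pedestal = grid$pedestal[cells$cell],
                   q10_width = stats::runif(nrow(cells), 0.1, 1.0),
                   median_width = NA_real_, n_vertices = 1L)
      }))
      linked <- res[res$area == areas[1L], ]
      thr_log10 <- -1.5 + link_slope * (linked$q10_width - 0.55) +
        stats::rnorm(nrow(linked), sd = noise_sd_log10)
      thresholds <- data.frame(participant = linked$participant,
                               quadrant = linked$quadrant,
                               pedestal = linked$pedestal,
                               threshold_log10 = thr_log10,
                               threshold_deg = 10^thr_log10)
      cors <- lapply(areas, function(a) {
        match_and_correlate(res, thresholds, a, n_areas = length(areas))
      })
      rho <- vapply(cors, `[[`, numeric(1), "rho")
      hit[r] <- which.max(rho) == 1L
      p_bonf_u <- vapply(cors[-1L], `[[`, numeric(1), "p_bonf")
      null_sig <- null_sig + sum(p_bonf_u <= 0.05)
      null_tests <- null_tests + length(p_bonf_u)
      rho_l[r] <- rho[1L]
      rho_u[r] <- stats::median(rho[-1L])
    }
    list(detection_rate = mean(hit),
         null_fpr = null_sig / null_tests,
         rho_linked = stats::median(rho_l),
         rho_unlinked = stats::median(rho_u))
  })
}
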