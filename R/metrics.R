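# align a track with a ground-truth trajectory and return per-frame
# Euclidean errors for the tracked (non-missing) frames
tracked_errors <- function(track, gt) {
  if (nrow(track) != nrow(gt))
    stop("track and ground truth must have one row per frame")
  ok <- !track$missing
  sqrt((track$u_mm[ok] - gt$u_mm[ok])^2 +
       (track$v_mm[ok] - gt$v_mm[ok])^2)
}

#' Tracking success rate
#'
#' Percentage of *tracked* frames whose 2D Euclidean distance to the
#' ground truth is strictly below the threshold (default 2 mm). Missing
#' frames are excluded from both numerator and denominator; they are
#' reported separately by [compute_missing()]. With zero tracked frames
#' the rate is undefined and `NA` is returned.
#'
#' @param track a [track_sequence()] result.
#' @param gt ground-truth trajectory (simulator truth or
#'   [estimate_ground_truth()] output) with `u_mm`, `v_mm`, one row per
#'   frame.
#' @param threshold success threshold in mm (strict `<`).
#' @return TSR in percent, or `NA` if no frame was tracked.
#' @export
compute_tsr <- function(track, gt, threshold = 2) {
  err <- tracked_errors(track, gt)
  if (length(err) == 0) return(NA_real_)
  100 * mean(err < threshold)
}

#' Root-mean-square tracking error
#'
#' `sqrt(sum_i ||x_i - x_t||^2 / N_tr)` over the `N_tr` tracked frames,
#' with 2D Euclidean per-frame errors; missing frames are excluded.
#'
#' @inheritParams compute_tsr
#' @return RMSE in mm, or `NA` if no frame was tracked.
#' @export
compute_rmse <- function(track, gt) {
  err <- tracked_errors(track, gt)
  if (length(err) == 0) return(NA_real_)
  sqrt(mean(err^2))
}

#' Percentage of missing frames
#'
#' `100 * (number of frames not tracked) / (total frames)`.
#'
#' @param track a [track_sequence()] result.
#' @return Missing percentage.
#' @export
compute_missing <- function(track) {
  100 * mean(track$missing)
}

#' All tracking metrics for one track
#'
#' @inheritParams compute_tsr
#' @return A `metric_report` list: `tsr`, `rmse`, `missing`, `n_tracked`,
#'   `n_total`, `threshold`.
#' @export
track_metrics <- function(track, gt, threshold = 2) {
  structure(list(tsr = compute_tsr(track, gt, threshold),
                 rmse = compute_rmse(track, gt),
                 missing = compute_missing(track),
                 n_tracked = sum(!track$missing),
                 n_total = nrow(track), threshold = threshold),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("TSR %.1f%% (<%g mm), RMSE %.2f mm, missing %.1f%% (%d/%d tracked)\n",
              x$tsr, x$threshold, x$rmse, x$missing, x$n_tracked,
              x$n_total))
  invisible(x)
}

#' Paired Wilcoxon signed-rank comparison
#'
#' Two-sided Wilcoxon matched-pair signed-rank test between per-case
#' metric values (cases are replicates x band-pass settings, or patients).
#' The exact null distribution is used for n <= 25 pairs, the normal
#' approximation with continuity correction above. When every difference
#' is zero the comparison is degenerate and `p = 1` is reported with
#' `degenerate = TRUE`.
#'
#' @param metric_a,metric_b equal-length (>= 5) numeric vectors, paired by
#'   case.
#' @return List: `p_value`, `statistic` (V), `median_a`, `median_b`,
#'   `degenerate`.
#' @export
paired_signed_rank <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b))
    stop("paired vectors must have equal length")
  if (length(metric_a) < 5) stop("need at least 5 pairs")
  d <- metric_a - metric_b
  if (all(d == 0)) {
    return(list(p_value = 1, statistic = NA_real_,
                median_a = median(metric_a), median_b = median(metric_b),
                degenerate = TRUE))
  }
  ht <- suppressWarnings(
    wilcox.test(metric_a, metric_b, paired = TRUE,
                exact = sum(d != 0) <= 25, correct = TRUE)
  )
  list(p_value = ht$p.value, statistic = unname(ht$statistic),
       median_a = median(metric_a), median_b = median(metric_b),
       degenerate = FALSE)
}
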