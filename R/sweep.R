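#' Apply one noise-reduction technique to a high/low projection pair
#'
#' Produces the dual-energy soft-tissue image a tracker would see under
#' the given technique: `"unprocessed"` (plain weighted log subtraction),
#' `"SS"` (simple smoothing), `"ACNR"`, `"NC"` (noise-clipped high-energy
#' image then WLS), or `"NC-ACNR"`.
#'
#' @param I_H,I_L intensity matrices of one projection pair.
#' @param technique one of `"unprocessed"`, `"SS"`, `"ACNR"`, `"NC"`,
#'   `"NC-ACNR"`.
#' @param de_params a [de_params()].
#' @param nr_params an [nr_params()].
#' @param angle_deg,time_s frame metadata carried on the result.
#' @return A `de_image` (kind `"soft_tissue"`, technique as requested).
#' @export
apply_technique <- function(I_H, I_L, technique,
                            de_params = detrack::de_params(),
                            nr_params = detrack::nr_params(),
                            angle_deg = NA_real_, time_s = NA_real_) {
  technique <- match.arg(technique,
                         c("unprocessed", "SS", "ACNR", "NC", "NC-ACNR"))
  out <- switch(technique,
    unprocessed = wls_soft_tissue(I_H, I_L, de_params, angle_deg, time_s),
    SS = simple_smoothing(I_H, I_L, de_params, nr_params, angle_deg, time_s),
    ACNR = acnr(wls_soft_tissue(I_H, I_L, de_params, angle_deg, time_s),
                wls_bone(I_H, I_L, de_params, angle_deg, time_s), nr_params),
    NC = {
      o <- wls_soft_tissue(noise_clip(I_H, I_L, nr_params), I_L, de_params,
                           angle_deg, time_s)
      o$technique <- "NC"
      o
    },
    `NC-ACNR` = nc_acnr(I_H, I_L, de_params, nr_params, angle_deg, time_s)
  )
  out
}

#' Configuration for the band-pass / technique evaluation sweep
#'
#' One sweep evaluates every combination of noise-reduction technique and
#' band-pass setting on `n_replicates` fresh noise realizations of one
#' simulated arc. Replicates play the role of the paired cases (standing
#' in for patients) in downstream signed-rank comparisons.
#'
#' @param techniques subset of `"unprocessed"`, `"SS"`, `"ACNR"`, `"NC"`,
#'   `"NC-ACNR"`.
#' @param sigma_low_grid band-pass `sigma_low` values in mm.
#' @param sigma_high_multipliers `sigma_high = multiplier * sigma_low`;
#'   all > 1. The default 4 x 4 grid spans the published sweep.
#' @param n_replicates number of noise realizations.
#' @param base_seed integer; the replicate seed is derived
#'   deterministically from `(base_seed, replicate)`.
#' @param gt_source `"simulator"` scores against the exact simulated
#'   trajectory; `"kalman"` scores against the Kalman-filter estimate
#'   computed from the track itself (the clinical procedure).
#' @param phantom,motion,acquisition,de_params,nr_params,search,kf
#'   module parameter blocks; `NULL` acquisition seed fields are ignored
#'   (seeds come from `base_seed`).
#' @param threshold TSR success threshold in mm.
#' @return A `sweep_config` object.
#' @export
sweep_config <- function(techniques = c("unprocessed", "SS", "ACNR", "NC",
                                        "NC-ACNR"),
                         sigma_low_grid = c(0.2, 0.4, 0.6, 0.8),
                         sigma_high_multipliers = c(2, 3, 4, 5),
                         n_replicates = 1, base_seed = 1,
                         gt_source = c("simulator", "kalman"),
                         phantom = default_phantom(),
                         motion = motion_model(),
                         acquisition = acquisition_spec(),
                         de_params = detrack::de_params(),
                         nr_params = detrack::nr_params(),
                         search = search_config(), kf = NULL,
                         threshold = 2) {
  gt_source <- match.arg(gt_source)
  techniques <- match.arg(techniques, several.ok = TRUE,
                          c("unprocessed", "SS", "ACNR", "NC", "NC-ACNR"))
  if (length(sigma_low_grid) == 0 || length(sigma_high_multipliers) == 0)
    stop("grids must be non-empty")
  if (any(sigma_high_multipliers <= 1)) stop("multipliers must be > 1")
  structure(list(techniques = techniques, sigma_low_grid = sigma_low_grid,
                 sigma_high_multipliers = sigma_high_multipliers,
                 n_replicates = as.integer(n_replicates),
                 base_seed = as.integer(base_seed), gt_source = gt_source,
                 phantom = phantom, motion = motion,
                 acquisition = acquisition, de_params = de_params,
                 nr_params = nr_params, search = search, kf = kf,
                 threshold = threshold),
            class = "sweep_config")
}

# deterministic per-replicate seed, kept well below 2^31
replicate_seed <- function(base_seed, replicate) {
  (abs(base_seed) %% 1000000L) * 1009L + replicate
}

#' Run the full evaluation sweep
#'
#' For every (replicate, technique, sigma_low, sigma_high) cell: simulate
#' (or reuse) the replicate's noisy dual-energy sequence, apply the
#' technique, track over the band-pass setting, resolve the ground truth
#' per `gt_source`, and compute the metrics. Failures in a cell are
#' recorded in the `status` column and the sweep continues. Rerunning with
#' an identical configuration reproduces the table exactly.
#'
#' @param cfg a [sweep_config()].
#' @param out_csv optional path; rows are appended incrementally so long
#'   sweeps are resumable/inspectable.
#' @param quiet suppress per-cell progress output.
#' @return A `sweep_result` data.frame: `replicate`, `technique`,
#'   `sigma_low_mm`, `sigma_high_mm`, `tsr_pct`, `rmse_mm`, `missing_pct`,
#'   `n_tracked`, `n_total`, `seed`, `status`.
#' @export
run_sweep <- function(cfg, out_csv = NULL, quiet = TRUE) {
  stopifnot(inherits(cfg, "sweep_config"))
  bank <- generate_templates(
    cfg$phantom, angles = seq(floor(cfg$acquisition$arc_start),
                              ceiling(cfg$acquisition$arc_stop)),
    de_params = cfg$de_params,
    detector_shape = cfg$acquisition$detector_shape,
    pixel_spacing = cfg$acquisition$pixel_spacing,
    detector_fwhm = cfg$acquisition$detector_fwhm)
  search <- cfg$search
  if (is.null(search$search_half_width))
    search$search_half_width <-
      max_tumor_radius(cfg$phantom) + max(cfg$motion$amplitude) + 5
  rows <- list()
  first_write <- TRUE
  for (rep_i in seq_len(cfg$n_replicates)) {
    seed <- replicate_seed(cfg$base_seed, rep_i)
    acq <- cfg$acquisition
    acq$seed <- seed
    seqn <- simulate_sequence(cfg$phantom, cfg$motion, acq)
    for (tech in cfg$techniques) {
      de_frames <- lapply(seq_along(seqn$frames), function(k) {
        apply_technique(seqn$frames[[k]]$high, seqn$frames[[k]]$low, tech,
                        cfg$de_params, cfg$nr_params,
                        angle_deg = seqn$meta$angle_deg[k],
                        time_s = seqn$meta$time_s[k])
      })
      for (sl in cfg$sigma_low_grid) for (m in cfg$sigma_high_multipliers) {
        sh <- m * sl
        row <- data.frame(replicate = rep_i, technique = tech,
                          sigma_low_mm = sl, sigma_high_mm = sh,
                          tsr_pct = NA_real_, rmse_mm = NA_real_,
                          missing_pct = NA_real_, n_tracked = NA_integer_,
                          n_total = length(de_frames), seed = seed,
                          status = "ok", stringsAsFactors = FALSE)
        res <- tryCatch({
          bp <- bandpass_params(sl, sh)
          tr <- track_sequence(de_frames, bank, search, bp,
                               spec = cfg$phantom, motion = cfg$motion)
          tr$time_s <- seqn$meta$time_s
          gt <- if (cfg$gt_source == "simulator") seqn$gt else
            estimate_ground_truth(tr, cfg$kf)
          m_ <- track_metrics(tr, gt, cfg$threshold)
          row$tsr_pct <- m_$tsr
          row$rmse_mm <- m_$rmse
          row$missing_pct <- m_$missing
          row$n_tracked <- m_$n_tracked
          row
        }, error = function(e) {
          row$status <- paste("error:", conditionMessage(e))
          row
        })
        if (!quiet)
          message(sprintf("rep %d %s sl=%.1f sh=%.1f: TSR %.1f", rep_i,
                          tech, sl, sh, res$tsr_pct))
        rows[[length(rows) + 1]] <- res
        if (!is.null(out_csv)) {
          utils::write.table(res, out_csv, sep = ",", append = !first_write,
                             col.names = first_write, row.names = FALSE)
          first_write <- FALSE
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Summarize a sweep
#'
#' Box-plot style statistics per technique across grid settings and
#' replicates (min, Q1, median, mean, Q3, max of TSR and RMSE), per-cell
#' means across replicates, and the best setting per technique. "Best" is
#' the argmax-TSR cell among settings that track at least half the frames
#' (mean missing below 50%) — TSR over a handful of surviving frames is
#' not meaningful; if no cell qualifies, all cells are considered.
#'
#' @param results a [run_sweep()] table.
#' @return List with data.frames `by_technique`, `by_cell`, and `best`
#'   (the best band-pass setting per technique by mean TSR).
#' @export
summarize_sweep <- function(results) {
  ok <- results[results$status == "ok" & is.finite(results$tsr_pct), ]
  qs <- function(x) c(min = min(x), q1 = unname(quantile(x, 0.25)),
                      median = median(x), mean = mean(x),
                      q3 = unname(quantile(x, 0.75)), max = max(x))
  by_tech <- do.call(rbind, lapply(split(ok, ok$technique), function(d) {
    data.frame(technique = d$technique[1],
               as.list(stats::setNames(qs(d$tsr_pct),
                                       paste0("tsr_", names(qs(d$tsr_pct))))),
               as.list(stats::setNames(qs(d$rmse_mm),
                                       paste0("rmse_", names(qs(d$rmse_mm))))),
               missing_mean = mean(d$missing_pct))
  }))
  cell_key <- interaction(ok$technique, ok$sigma_low_mm, ok$sigma_high_mm,
                          drop = TRUE)
  by_cell <- do.call(rbind, lapply(split(ok, cell_key), function(d) {
    data.frame(technique = d$technique[1], sigma_low_mm = d$sigma_low_mm[1],
               sigma_high_mm = d$sigma_high_mm[1],
               tsr_pct = mean(d$tsr_pct), rmse_mm = mean(d$rmse_mm),
               missing_pct = mean(d$missing_pct),
               n_replicates = nrow(d))
  }))
  rownames(by_cell) <- NULL
  best <- do.call(rbind, lapply(split(by_cell, by_cell$technique),
                                function(d) {
    el <- d[d$missing_pct < 50, , drop = FALSE]
    if (nrow(el) == 0) el <- d
    el[which.max(el$tsr_pct), ]
  }))
  rownames(best) <- NULL
  list(by_technique = by_tech, by_cell = by_cell, best = best)
}

#' Paired comparison of two techniques across the sweep grid
#'
#' Pairs rows by (replicate, sigma_low, sigma_high) and applies the
#' Wilcoxon matched-pair signed-rank test to TSR and RMSE.
#'
#' @param results a [run_sweep()] table containing both techniques.
#' @param technique_a,technique_b technique names to compare.
#' @return List with `n_pairs`, `tsr` and `rmse` (each a
#'   [paired_signed_rank()] result; for TSR, `median_a > median_b` with a
#'   small p-value favors `technique_a`).
#' @export
compare_techniques <- function(results, technique_a, technique_b) {
  ok <- results[results$status == "ok", ]
  a <- ok[ok$technique == technique_a, ]
  b <- ok[ok$technique == technique_b, ]
  key <- function(d) paste(d$replicate, d$sigma_low_mm, d$sigma_high_mm)
  common <- intersect(key(a), key(b))
  a <- a[match(common, key(a)), ]
  b <- b[match(common, key(b)), ]
  # cells where a technique tracked nothing have undefined TSR/RMSE and
  # cannot be paired
  cmp <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    paired_signed_rank(x[ok], y[ok])
  }
  list(n_pairs = length(common),
       technique_a = technique_a, technique_b = technique_b,
       tsr = cmp(a$tsr_pct, b$tsr_pct),
       rmse = cmp(a$rmse_mm, b$rmse_mm))
}
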