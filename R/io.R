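#' Write / read a projection sequence as 16-bit TIFF plus metadata CSV
#'
#' Frames are stored one per file (`frame_000001.tif`, ...) as 16-bit
#' grayscale TIFF. Intensities are linearly scaled into the 16-bit range;
#' the per-sequence scale factor is recorded in the metadata CSV
#' (`frames.csv`: frame_index, pair_index, energy_label, angle_deg,
#' time_s, scale) so counts can be recovered exactly up to quantization.
#' The ground-truth trajectory goes to `gt.csv` (frame_index, time_s,
#' angle_deg, u_mm, v_mm).
#'
#' @param seqn a [simulate_sequence()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sequence <- function(seqn, dir) {
  stopifnot(inherits(seqn, "projection_sequence"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mx <- max(vapply(seqn$frames, function(f) max(f$high, f$low), numeric(1)))
  scale <- 65535 / mx
  meta <- vector("list", 2 * length(seqn$frames))
  fi <- 0
  for (k in seq_along(seqn$frames)) {
    for (energy in c("high", "low")) {
      fi <- fi + 1
      img <- seqn$frames[[k]][[energy]]
      tiff::writeTIFF(round(img * scale) / 65535,
                      file.path(dir, sprintf("frame_%06d.tif", fi)),
                      bits.per.sample = 16, compression = "none")
      meta[[fi]] <- data.frame(frame_index = fi, pair_index = k,
                               energy_label = energy,
                               angle_deg = seqn$meta$angle_deg[k],
                               time_s = seqn$meta$time_s[k], scale = scale)
    }
  }
  write.csv(do.call(rbind, meta), file.path(dir, "frames.csv"),
            row.names = FALSE)
  write.csv(seqn$gt, file.path(dir, "gt.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_sequence
#' @return `read_sequence()`: a `projection_sequence` (without the
#'   generating specifications; intensities recovered via the stored
#'   scale).
#' @export
read_sequence <- function(dir) {
  meta <- read.csv(file.path(dir, "frames.csv"))
  gtf <- file.path(dir, "gt.csv")
  gt <- if (file.exists(gtf)) read.csv(gtf) else NULL
  pairs <- sort(unique(meta$pair_index))
  frames <- vector("list", length(pairs))
  for (k in seq_along(pairs)) {
    rows <- meta[meta$pair_index == pairs[k], ]
    fr <- list()
    for (i in seq_len(nrow(rows))) {
      img <- tiff::readTIFF(file.path(
        dir, sprintf("frame_%06d.tif", rows$frame_index[i])))
      fr[[rows$energy_label[i]]] <- img * 65535 / rows$scale[i]
    }
    frames[[k]] <- fr
  }
  pm <- meta[meta$energy_label == "high", c("pair_index", "time_s",
                                            "angle_deg")]
  rownames(pm) <- NULL
  structure(list(frames = frames, meta = pm, gt = gt, spec = NULL,
                 motion = NULL, acq = NULL, noise = NA),
            class = "projection_sequence")
}

#' Write / read a template bank (float TIFFs plus an index CSV)
#'
#' @param bank a [generate_templates()] bank.
#' @param dir output directory.
#' @export
write_template_bank <- function(bank, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- vector("list", length(bank$angles))
  for (i in seq_along(bank$angles)) {
    e <- bank$templates[[i]]
    # TIFF samples live in [0, 1]; record the linear map per template
    off <- min(e$pixels)
    sc <- max(e$pixels) - off
    if (sc == 0) sc <- 1
    tiff::writeTIFF((e$pixels - off) / sc,
                    file.path(dir, sprintf("template_%03d.tif",
                                           round(bank$angles[i]))),
                    bits.per.sample = 32, compression = "none")
    idx[[i]] <- data.frame(angle_deg = bank$angles[i],
                           offset_row_px = e$offset_px["row"],
                           offset_col_px = e$offset_px["col"],
                           ref_u_mm = e$ref_u_mm, ref_v_mm = e$ref_v_mm,
                           crop_row0 = unname(e$crop["row0"]),
                           crop_col0 = unname(e$crop["col0"]),
                           foot_row0 = unname(e$foot["row0"]),
                           foot_col0 = unname(e$foot["col0"]),
                           foot_nrow = unname(e$foot["nrow"]),
                           foot_ncol = unname(e$foot["ncol"]),
                           offset = off, scale = sc,
                           pixel_spacing_mm = bank$pixel_spacing)
  }
  write.csv(do.call(rbind, idx), file.path(dir, "index.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' @rdname write_template_bank
#' @export
read_template_bank <- function(dir) {
  idx <- read.csv(file.path(dir, "index.csv"))
  templates <- vector("list", nrow(idx))
  names(templates) <- as.character(idx$angle_deg)
  for (i in seq_len(nrow(idx))) {
    px <- tiff::readTIFF(file.path(dir, sprintf("template_%03d.tif",
                                                round(idx$angle_deg[i]))))
    px <- px * idx$scale[i] + idx$offset[i]
    templates[[i]] <- list(
      pixels = px,
      foot = c(row0 = idx$foot_row0[i], col0 = idx$foot_col0[i],
               nrow = idx$foot_nrow[i], ncol = idx$foot_ncol[i]),
      offset_px = c(row = idx$offset_row_px[i], col = idx$offset_col_px[i]),
      ref_u_mm = idx$ref_u_mm[i], ref_v_mm = idx$ref_v_mm[i],
      crop = c(row0 = idx$crop_row0[i], col0 = idx$crop_col0[i]))
  }
  structure(list(templates = templates, angles = idx$angle_deg,
                 pixel_spacing = idx$pixel_spacing_mm[1],
                 detector_shape = NULL),
            class = "template_bank")
}

#' Write / read a track result CSV
#'
#' Columns: frame_index, angle_deg, tracked_u_mm, tracked_v_mm, ncc_peak,
#' missing (0/1).
#'
#' @param track a [track_sequence()] result.
#' @param path CSV path.
#' @export
write_track <- function(track, path) {
  out <- data.frame(frame_index = track$frame_index,
                    angle_deg = track$angle_deg,
                    tracked_u_mm = track$u_mm, tracked_v_mm = track$v_mm,
                    ncc_peak = track$ncc_peak,
                    missing = as.integer(track$missing))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  d <- read.csv(path)
  out <- data.frame(frame_index = d$frame_index, angle_deg = d$angle_deg,
                    u_mm = d$tracked_u_mm, v_mm = d$tracked_v_mm,
                    ncc_peak = d$ncc_peak, missing = d$missing == 1)
  class(out) <- c("track_result", "data.frame")
  out
}

#' Build a sweep configuration from a YAML file
#'
#' The document's top-level keys mirror the module parameter blocks:
#' `phantom` (tumor_center, tumor_semiaxes, n_clutter), `motion`,
#' `acquisition`, `subtraction`, `noise_reduction`, `tracking`
#' (search_half_width, ncc_threshold, expected_position_source), `kalman`
#' (dt, q, r_var, p0) and `sweep` (techniques, sigma_low_grid,
#' sigma_high_multipliers, n_replicates, base_seed, gt_source, threshold).
#' Missing keys keep package defaults.
#'
#' @param path YAML file path.
#' @return A [sweep_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(block, f) do.call(f, if (is.null(block)) list() else block)
  phantom <- take(y$phantom, default_phantom)
  motion <- take(y$motion, motion_model)
  acq <- take(y$acquisition, acquisition_spec)
  dep <- take(y$subtraction, de_params)
  nrp <- take(y$noise_reduction, nr_params)
  search <- take(y$tracking, search_config)
  kf <- if (is.null(y$kalman)) NULL else do.call(kf_config, y$kalman)
  sw <- if (is.null(y$sweep)) list() else y$sweep
  do.call(sweep_config, c(sw, list(phantom = phantom, motion = motion,
                                   acquisition = acq, de_params = dep,
                                   nr_params = nrp, search = search,
                                   kf = kf)))
}
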