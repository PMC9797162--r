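#' Respiratory tumor motion model
#'
#' In-plane periodic displacement of the tumor around its planning
#' (reference) position. Two waveforms are available: `"cos"`, the plain
#' cosine `s(t) = cos(2*pi*t/period + phase)`, and `"cos4"`, the
#' end-exhale-weighted breathing surrogate
#' `s(t) = cos(pi*t/period + phase/2)^4` commonly used for lung motion
#' (the target dwells near `s = 0`, exhale, and makes brief excursions to
#' `s = 1`, inhale). The displacement at time `t` is
#' `amplitude * s(t) + baseline_drift * t`, per in-plane axis `(u, v)`.
#'
#' Defaults (8 mm superior-inferior, 2 mm lateral, 4 s period) reflect
#' typical free-breathing motion of early-stage upper/middle-lobe lung
#' tumors.
#'
#' @param amplitude length-2 motion amplitude in mm per in-plane axis
#'   `(u, v)`; nonnegative.
#' @param period breathing period in s; positive.
#' @param phase phase offset in rad.
#' @param waveform `"cos"` or `"cos4"`.
#' @param baseline_drift length-2 drift in mm/s per axis.
#' @return A `motion_model` object.
#' @export
motion_model <- function(amplitude = c(2, 8), period = 4, phase = 0,
                         waveform = c("cos4", "cos"),
                         baseline_drift = c(0, 0)) {
  waveform <- match.arg(waveform)
  stopifnot(length(amplitude) == 2, length(baseline_drift) == 2)
  if (period <= 0) stop("period must be > 0")
  if (any(amplitude < 0)) stop("amplitude must be >= 0")
  structure(list(amplitude = as.numeric(amplitude), period = period,
                 phase = phase, waveform = waveform,
                 baseline_drift = as.numeric(baseline_drift)),
            class = "motion_model")
}

#' In-plane tumor displacement at given times
#'
#' @param motion a [motion_model()].
#' @param t numeric vector of times in s.
#' @return Matrix with one row per time and columns `u`, `v` (mm).
#' @export
motion_displacement <- function(motion, t) {
  s <- switch(motion$waveform,
    cos  = cos(2 * pi * t / motion$period + motion$phase),
    cos4 = cos(pi * t / motion$period + motion$phase / 2)^4
  )
  cbind(u = motion$amplitude[1] * s + motion$baseline_drift[1] * t,
        v = motion$amplitude[2] * s + motion$baseline_drift[2] * t)
}

#' Acquisition geometry and exposure for a dual-energy arc
#'
#' Defaults follow the clinical protocol emulated by the simulator:
#' 15 high/low pairs per second, 450 pairs over a 180 degree gantry arc,
#' with the tube current balanced so the two energies deposit comparable
#' air fluence. Detector size and pixel spacing are not dictated by that
#' protocol; the defaults (256 x 256 pixels at 0.5 mm/pixel) keep runs
#' desk-scale while resolving the smallest band-pass kernel (0.2 mm) at
#' 0.4 pixel.
#'
#' @param frame_rate pairs per second.
#' @param arc_start,arc_stop gantry arc limits in degrees.
#' @param n_pairs number of high/low pairs (>= 1).
#' @param fluence_high,fluence_low expected photons/pixel in air.
#' @param pixel_spacing mm/pixel at the tracking plane.
#' @param detector_shape detector size in pixels, `c(rows, cols)`.
#' @param detector_fwhm detector point-spread FWHM in mm (Gaussian),
#'   applied after photon counting as in a scintillator/readout chain, so
#'   it correlates the quantum noise the way a real imager's MTF does;
#'   0 disables it.
#' @param seed integer seed for the Poisson noise.
#' @return An `acquisition_spec` object.
#' @export
acquisition_spec <- function(frame_rate = 15, arc_start = 0, arc_stop = 180,
                             n_pairs = 450, fluence_high = 3000,
                             fluence_low = 3000, pixel_spacing = 0.5,
                             detector_shape = c(256, 256),
                             detector_fwhm = 1, seed = 1) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  if (fluence_high <= 0 || fluence_low <= 0) stop("fluences must be > 0")
  if (pixel_spacing <= 0) stop("pixel_spacing must be > 0")
  if (detector_fwhm < 0) stop("detector_fwhm must be >= 0")
  structure(list(frame_rate = frame_rate, arc_start = arc_start,
                 arc_stop = arc_stop, n_pairs = as.integer(n_pairs),
                 fluence_high = fluence_high, fluence_low = fluence_low,
                 pixel_spacing = pixel_spacing,
                 detector_shape = as.integer(detector_shape),
                 detector_fwhm = detector_fwhm,
                 seed = as.integer(seed)),
            class = "acquisition_spec")
}

# Gaussian detector point-spread; fwhm in mm, 0 = identity
apply_detector_psf <- function(image, fwhm, pixel_spacing) {
  if (is.null(fwhm) || fwhm <= 0) return(image)
  gaussian_filter(image, fwhm / (2 * sqrt(2 * log(2))) / pixel_spacing)
}

# projected (u, v) position of the (first) tumor primitive's center at a
# gantry angle, before motion displacement
tumor_reference_uv <- function(spec, angle_deg) {
  tum <- Filter(function(p) p$material == "tumor", spec$materials)
  if (length(tum) == 0) stop("phantom has no tumor primitive")
  cen <- tum[[1]]$center
  th <- angle_deg * pi / 180
  c(u = -cen[1] * sin(th) + cen[2] * cos(th), v = cen[3])
}

#' Simulate a dual-energy projection sequence with known tumor motion
#'
#' Generates `n_pairs` high/low-energy projection pairs along the gantry
#' arc. Both frames of a pair share one gantry angle and one motion state
#' (fast kV switching); the high frame uses `fluence_high`, the low frame
#' `fluence_low`. The returned ground truth records the exact projected
#' tumor-center position per frame.
#'
#' @param spec a [phantom_spec()].
#' @param motion a [motion_model()].
#' @param acq an [acquisition_spec()].
#' @param noise add Poisson photon noise (seeded from `acq$seed`)?
#' @return A `projection_sequence`: list with `frames` (list of
#'   `list(high, low)` intensity matrices), `meta` (data.frame: pair_index,
#'   time_s, angle_deg), `gt` (data.frame: frame_index, time_s, angle_deg,
#'   u_mm, v_mm), and the three input specifications.
#' @export
simulate_sequence <- function(spec, motion, acq, noise = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(motion, "motion_model"),
            inherits(acq, "acquisition_spec"))
  n <- acq$n_pairs
  t_s <- (seq_len(n) - 1) / acq$frame_rate
  angles <- if (n == 1) acq$arc_start else
    seq(acq$arc_start, acq$arc_stop, length.out = n)
  disp <- motion_displacement(motion, t_s)
  frames <- vector("list", n)
  gt_u <- gt_v <- numeric(n)
  for (k in seq_len(n)) {
    off <- disp[k, ]
    hi <- project(spec, angles[k], "high", tumor_offset = off,
                  fluence = acq$fluence_high,
                  detector_shape = acq$detector_shape,
                  pixel_spacing = acq$pixel_spacing)
    lo <- project(spec, angles[k], "low", tumor_offset = off,
                  fluence = acq$fluence_low,
                  detector_shape = acq$detector_shape,
                  pixel_spacing = acq$pixel_spacing)
    if (noise) {
      hi <- add_noise(hi, seed = acq$seed + 2L * k)
      lo <- add_noise(lo, seed = acq$seed + 2L * k + 1L)
    }
    hi <- apply_detector_psf(hi, acq$detector_fwhm, acq$pixel_spacing)
    lo <- apply_detector_psf(lo, acq$detector_fwhm, acq$pixel_spacing)
    frames[[k]] <- list(high = hi, low = lo)
    ref <- tumor_reference_uv(spec, angles[k])
    gt_u[k] <- ref["u"] + off[1]
    gt_v[k] <- ref["v"] + off[2]
  }
  structure(list(
    frames = frames,
    meta = data.frame(pair_index = seq_len(n), time_s = t_s,
                      angle_deg = angles),
    gt = data.frame(frame_index = seq_len(n), time_s = t_s,
                    angle_deg = angles, u_mm = gt_u, v_mm = gt_v),
    spec = spec, motion = motion, acq = acq, noise = noise
  ), class = "projection_sequence")
}

#' @export
print.projection_sequence <- function(x, ...) {
  cat("Dual-energy projection sequence:", length(x$frames), "pairs,",
      "arc", x$acq$arc_start, "to", x$acq$arc_stop, "deg,",
      paste0(x$acq$detector_shape, collapse = "x"), "px at",
      x$acq$pixel_spacing, "mm/px,",
      if (x$noise) "Poisson noise" else "noise-free", "\n")
  invisible(x)
}
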