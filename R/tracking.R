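#' Band-pass (difference-of-Gaussians) filter parameters
#'
#' The matching step filters both template and image with
#' `G(sigma_low) - G(sigma_high)`: the narrow Gaussian suppresses
#' pixel-level noise, subtracting the wide one removes coarse background.
#' Sigmas are millimeters at the tracking plane and are divided by the
#' pixel spacing at filter time. The canonical sweep varies `sigma_low`
#' from 0.2 to 0.8 mm in 0.2 mm steps with `sigma_high` a 2-5 multiple of
#' `sigma_low`.
#'
#' @param sigma_low,sigma_high Gaussian widths in mm,
#'   `0 < sigma_low < sigma_high`.
#' @return A `bandpass_params` object.
#' @export
bandpass_params <- function(sigma_low = 0.4, sigma_high = 1.6) {
  if (sigma_low <= 0) stop("sigma_low must be > 0")
  if (sigma_high <= sigma_low) stop("sigma_high must exceed sigma_low")
  structure(list(sigma_low = sigma_low, sigma_high = sigma_high),
            class = "bandpass_params")
}

#' Apply the difference-of-Gaussians band-pass filter
#'
#' @param image numeric matrix.
#' @param params a [bandpass_params()].
#' @param pixel_spacing mm/pixel used to convert the sigmas to pixels.
#' @return Filtered matrix (zero-mean for constant input).
#' @export
bandpass <- function(image, params, pixel_spacing) {
  stopifnot(inherits(params, "bandpass_params"), pixel_spacing > 0)
  gaussian_filter(image, params$sigma_low / pixel_spacing) -
    gaussian_filter(image, params$sigma_high / pixel_spacing)
}

#' Search configuration for template matching
#'
#' @param search_half_width half-width of the search region in mm per axis
#'   (template-center displacements from the expected position). The
#'   default, `NULL`, lets [track_sequence()] derive it as
#'   tumor max radius + motion amplitude + 5 mm margin.
#' @param ncc_threshold minimum peak NCC for a frame to count as tracked;
#'   below it the frame is declared missing. In `[-1, 1]`.
#' @param expected_position_source `"static_reference"` centers the search
#'   on the planning (reference-phase) tumor position for the frame's
#'   angle; `"previous_frame"` follows the last tracked position.
#' @param subpixel use 3-point parabolic sub-pixel peak refinement
#'   (integer-pixel localization by default).
#' @return A `search_config` object.
#' @export
search_config <- function(search_half_width = NULL, ncc_threshold = 0.5,
                          expected_position_source = c("static_reference",
                                                       "previous_frame"),
                          subpixel = FALSE) {
  expected_position_source <- match.arg(expected_position_source)
  if (!is.null(search_half_width) && search_half_width <= 0)
    stop("search_half_width must be > 0")
  if (ncc_threshold < -1 || ncc_threshold > 1)
    stop("ncc_threshold must be in [-1, 1]")
  structure(list(search_half_width = search_half_width,
                 ncc_threshold = ncc_threshold,
                 expected_position_source = expected_position_source,
                 subpixel = subpixel),
            class = "search_config")
}

# projected half-extents (u, v) in mm of the union of tumor primitives
tumor_projected_halfwidth <- function(spec, angle_deg) {
  th <- angle_deg * pi / 180
  hu <- hv <- 0
  for (p in spec$materials) {
    if (p$material != "tumor") next
    if (p$type == "ellipsoid") {
      hu <- max(hu, sqrt((p$semiaxes[1] * sin(th))^2 +
                         (p$semiaxes[2] * cos(th))^2))
      hv <- max(hv, p$semiaxes[3])
    } else {
      hw <- prim_halfwidth(p)
      hu <- max(hu, sqrt((hw[1] * sin(th))^2 + (hw[2] * cos(th))^2))
      hv <- max(hv, hw[3])
    }
  }
  c(u = hu, v = hv)
}

max_tumor_radius <- function(spec) {
  r <- 0
  for (p in spec$materials)
    if (p$material == "tumor") r <- max(r, prim_halfwidth(p))
  r
}

#' Generate per-degree tumor templates from the phantom
#'
#' For each angle, the template is the noise-free dual-energy soft-tissue
#' projection (weighted log subtraction of unit-fluence high/low
#' projections) of the tumor plus its local context, at the motion model's
#' reference phase (zero displacement), cropped to the projected tumor
#' bounding box plus a margin. This is the simulator's analog of templates
#' rendered from the planning CT. The tumor-center offset inside each
#' template and the reference (planning) position in mm are recorded.
#'
#' @param spec a [phantom_spec()] containing a tumor primitive.
#' @param angles integer-spaced template angles in degrees (default every
#'   1 degree over 0..180).
#' @param de_params a [de_params()]; templates are built with the same
#'   subtraction weights as the tracked images.
#' @param detector_shape,pixel_spacing detector geometry (must match the
#'   sequences the bank will be used on).
#' @param margin crop margin around the projected tumor bounding box, mm.
#' @param context_pad extra surrounding context kept with each template,
#'   in mm (clipped at the detector border). The band-pass filter is
#'   applied to the padded template and the result cropped back to the
#'   template footprint, so template and image see the same anatomical
#'   context under the filter instead of reflected template edges; 16 mm
#'   covers the 4-sigma support of the largest canonical `sigma_high`
#'   (4 mm).
#' @param detector_fwhm detector point-spread FWHM in mm; must match the
#'   acquisition the bank will be used on.
#' @return A `template_bank`: list with `templates` (named by angle; each
#'   has `pixels` (the padded projection), `foot` (footprint row0, col0,
#'   nrow, ncol inside `pixels`), `offset_px` 0-based fractional
#'   (row, col) tumor-center offset inside the footprint, `ref_u_mm`,
#'   `ref_v_mm`, `crop` 1-based detector indices (row0, col0) of the
#'   footprint), plus `pixel_spacing` and `angles`.
#' @export
generate_templates <- function(spec, angles = 0:180,
                               de_params = detrack::de_params(),
                               detector_shape = c(256, 256),
                               pixel_spacing = 0.5, margin = 5,
                               context_pad = 16, detector_fwhm = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  nv <- detector_shape[1]
  nu <- detector_shape[2]
  pad <- ceiling(context_pad / pixel_spacing)
  templates <- vector("list", length(angles))
  names(templates) <- as.character(angles)
  for (idx in seq_along(angles)) {
    ang <- angles[idx]
    ref <- unname(tumor_reference_uv(spec, ang))
    hw <- unname(tumor_projected_halfwidth(spec, ang)) + margin
    j0 <- floor(u_to_col(ref[1] - hw[1], nu, pixel_spacing))
    j1 <- ceiling(u_to_col(ref[1] + hw[1], nu, pixel_spacing))
    i0 <- floor(v_to_row(ref[2] - hw[2], nv, pixel_spacing))
    i1 <- ceiling(v_to_row(ref[2] + hw[2], nv, pixel_spacing))
    if (j0 < 1 || j1 > nu || i0 < 1 || i1 > nv ||
        ref[1] < col_to_u(1, nu, pixel_spacing) ||
        ref[1] > col_to_u(nu, nu, pixel_spacing))
      stop("tumor projects outside the detector at angle ", ang)
    jp0 <- max(1, j0 - pad); jp1 <- min(nu, j1 + pad)
    ip0 <- max(1, i0 - pad); ip1 <- min(nv, i1 + pad)
    u_mm <- col_to_u(jp0:jp1, nu, pixel_spacing)
    v_mm <- row_to_v(ip0:ip1, nv, pixel_spacing)
    hi <- apply_detector_psf(project(spec, ang, "high", u_mm = u_mm,
                                     v_mm = v_mm),
                             detector_fwhm, pixel_spacing)
    lo <- apply_detector_psf(project(spec, ang, "low", u_mm = u_mm,
                                     v_mm = v_mm),
                             detector_fwhm, pixel_spacing)
    # noise-free unit-fluence projections are strictly positive, so the
    # count-domain log floor does not apply here
    px <- log(hi) - de_params$w_ST * log(lo)
    templates[[idx]] <- list(
      pixels = px,
      foot = c(row0 = i0 - ip0 + 1, col0 = j0 - jp0 + 1,
               nrow = i1 - i0 + 1, ncol = j1 - j0 + 1),
      offset_px = c(row = v_to_row(ref[2], nv, pixel_spacing) - i0,
                    col = u_to_col(ref[1], nu, pixel_spacing) - j0),
      ref_u_mm = ref[1], ref_v_mm = ref[2],
      crop = c(row0 = i0, col0 = j0)
    )
  }
  structure(list(templates = templates, angles = as.numeric(angles),
                 pixel_spacing = pixel_spacing,
                 detector_shape = as.integer(detector_shape)),
            class = "template_bank")
}

# band-pass a bank entry on its padded support and crop to the footprint
filter_template <- function(entry, bp, pixel_spacing) {
  f <- bandpass(entry$pixels, bp, pixel_spacing)
  r0 <- entry$foot["row0"]; c0 <- entry$foot["col0"]
  f[r0:(r0 + entry$foot["nrow"] - 1),
    c0:(c0 + entry$foot["ncol"] - 1), drop = FALSE]
}

#' @export
print.template_bank <- function(x, ...) {
  sz <- dim(x$templates[[1]]$pixels)
  cat("Template bank:", length(x$templates), "angles (",
      min(x$angles), "-", max(x$angles), "deg ), ~", sz[1], "x", sz[2],
      "px at", x$pixel_spacing, "mm/px\n")
  invisible(x)
}

# nearest template entry for a frame angle
bank_lookup <- function(bank, angle_deg) {
  i <- which.min(abs(bank$angles - angle_deg))
  if (abs(bank$angles[i] - angle_deg) > 0.5 + 1e-9)
    stop("no template within 0.5 degree of frame angle ", angle_deg)
  list(entry = bank$templates[[i]], angle = bank$angles[i])
}

#' Normalized cross-correlation surface
#'
#' Computes, at each valid placement of `template` inside `image`, the
#' normalized cross-correlation
#' `sum((I - mean(I)) * (T - mean(T))) / sqrt(sum((I - mean(I))^2) *
#' sum((T - mean(T))^2))` over the template footprint, using the local
#' image window mean and variance. Values lie in `[-1, 1]`; a
#' zero-variance image window yields 0, a zero-variance template is an
#' error.
#'
#' @param image numeric matrix (search region).
#' @param template numeric matrix, strictly smaller than `image`.
#' @return Matrix of size `(nrow(image) - nrow(template) + 1) x
#'   (ncol(image) - ncol(template) + 1)`; element `(i, j)` corresponds to
#'   the template's top-left pixel placed at `image[i, j]`.
#' @export
ncc_map <- function(image, template) {
  if (nrow(template) > nrow(image) || ncol(template) > ncol(image))
    stop("template must not exceed the search region")
  if (stats::var(as.vector(template)) == 0) stop("zero-variance template")
  cpp_ncc_map(image, template)
}

# peak location in row-major scan order (first occurrence on ties)
peak_rowmajor <- function(surface) {
  best <- max(surface)
  hits <- which(surface == best, arr.ind = TRUE)
  ord <- order(hits[, 1], hits[, 2])
  c(row = unname(hits[ord[1], 1]), col = unname(hits[ord[1], 2]),
    value = best)
}

# 3-point parabolic refinement along one axis; returns fractional shift
parabolic_shift <- function(m1, m0, p1) {
  den <- m1 - 2 * m0 + p1
  if (den >= 0) return(0)  # not a local maximum
  max(-0.5, min(0.5, 0.5 * (m1 - p1) / den))
}

#' Track the tumor on one dual-energy frame
#'
#' Band-pass filters the search window (expected position +/- the search
#' half-width) and the frame's template with identical parameters, computes
#' the NCC surface, and reports the peak: if it falls below the NCC
#' threshold the frame is missing, otherwise the tracked position is the
#' peak placement plus the template's tumor-center offset, in mm. Ties are
#' broken by first occurrence in row-major scan order. A search window
#' partly outside the image is clipped; one fully outside yields a missing
#' frame.
#'
#' @param de_image a `de_image` (with its `angle_deg` set) or a plain
#'   matrix plus `angle_deg`.
#' @param bank a [generate_templates()] bank.
#' @param expected expected tumor position `c(u, v)` in mm.
#' @param cfg a [search_config()]; its `search_half_width` must be set.
#' @param bp a [bandpass_params()].
#' @param angle_deg frame angle (taken from `de_image` if missing).
#' @param filtered_template optional pre-band-passed template matrix
#'   (internal caching across frames); computed on the fly if `NULL`.
#' @return One-row data.frame: `angle_deg`, `template_angle`, `u_mm`,
#'   `v_mm` (NA when missing), `ncc_peak`, `missing`.
#' @export
track_frame <- function(de_image, bank, expected, cfg, bp,
                        angle_deg = NULL, filtered_template = NULL) {
  if (inherits(de_image, "de_image")) {
    if (is.null(angle_deg)) angle_deg <- de_image$angle_deg
    img <- de_image$pixels
  } else img <- de_image
  if (is.null(cfg$search_half_width))
    stop("cfg$search_half_width must be set")
  spacing <- bank$pixel_spacing
  lk <- bank_lookup(bank, angle_deg)
  tpl <- lk$entry
  nv <- nrow(img)
  nu <- ncol(img)
  th <- unname(tpl$foot["nrow"])
  tw <- unname(tpl$foot["ncol"])
  hw_px <- cfg$search_half_width / spacing

  miss <- function(peak = NA_real_) data.frame(
    angle_deg = angle_deg, template_angle = lk$angle,
    u_mm = NA_real_, v_mm = NA_real_, ncc_peak = peak, missing = TRUE)

  # template top-left placements whose center covers expected +/- half-width
  ec <- u_to_col(expected[1], nu, spacing)
  er <- v_to_row(expected[2], nv, spacing)
  tl_col <- c(floor(ec - hw_px), ceiling(ec + hw_px)) - tpl$offset_px["col"]
  tl_row <- c(floor(er - hw_px), ceiling(er + hw_px)) - tpl$offset_px["row"]
  tl_col <- c(max(1, round(tl_col[1])), min(nu - tw + 1, round(tl_col[2])))
  tl_row <- c(max(1, round(tl_row[1])), min(nv - th + 1, round(tl_row[2])))
  if (tl_col[1] > tl_col[2] || tl_row[1] > tl_row[2]) return(miss())

  # window covering all placements, extracted with a filter-support pad
  wr <- c(tl_row[1], tl_row[2] + th - 1)
  wc <- c(tl_col[1], tl_col[2] + tw - 1)
  pad <- ceiling(4 * bp$sigma_high / spacing) + 1
  pr <- c(max(1, wr[1] - pad), min(nv, wr[2] + pad))
  pc <- c(max(1, wc[1] - pad), min(nu, wc[2] + pad))
  win <- bandpass(img[pr[1]:pr[2], pc[1]:pc[2], drop = FALSE], bp, spacing)
  win <- win[(wr[1] - pr[1] + 1):(wr[2] - pr[1] + 1),
             (wc[1] - pc[1] + 1):(wc[2] - pc[1] + 1), drop = FALSE]
  ftpl <- if (!is.null(filtered_template)) filtered_template else
    filter_template(tpl, bp, spacing)

  surf <- cpp_ncc_map(win, ftpl)
  pk <- peak_rowmajor(surf)
  if (!is.finite(pk["value"]) || pk["value"] < cfg$ncc_threshold)
    return(miss(unname(pk["value"])))
  ri <- unname(pk["row"])
  ci <- unname(pk["col"])
  dr <- dc <- 0
  if (isTRUE(cfg$subpixel)) {
    if (ri > 1 && ri < nrow(surf))
      dr <- parabolic_shift(surf[ri - 1, ci], surf[ri, ci], surf[ri + 1, ci])
    if (ci > 1 && ci < ncol(surf))
      dc <- parabolic_shift(surf[ri, ci - 1], surf[ri, ci], surf[ri, ci + 1])
  }
  row_c <- wr[1] + ri - 1 + dr + tpl$offset_px["row"]
  col_c <- wc[1] + ci - 1 + dc + tpl$offset_px["col"]
  data.frame(angle_deg = angle_deg, template_angle = lk$angle,
             u_mm = unname(col_to_u(col_c, nu, spacing)),
             v_mm = unname(row_to_v(row_c, nv, spacing)),
             ncc_peak = unname(pk["value"]), missing = FALSE)
}

#' Track the tumor over a sequence of dual-energy frames
#'
#' Applies [track_frame()] to every frame. The expected position follows
#' `cfg$expected_position_source`: the static planning reference (the
#' bank's recorded reference position for the frame's angle) or the
#' previously tracked position. If `cfg$search_half_width` is `NULL` it is
#' derived from `spec` and `motion` as tumor max radius + motion
#' amplitude + 5 mm.
#'
#' @param frames list of `de_image` objects (or matrices) with angles.
#' @param bank a [generate_templates()] bank.
#' @param cfg a [search_config()].
#' @param bp a [bandpass_params()].
#' @param angles numeric vector of frame angles (required when `frames`
#'   are plain matrices).
#' @param spec,motion optional [phantom_spec()] / [motion_model()] used to
#'   derive the default search half-width.
#' @return A `track_result` data.frame: `frame_index`, `angle_deg`,
#'   `template_angle`, `u_mm`, `v_mm`, `ncc_peak`, `missing`.
#' @export
track_sequence <- function(frames, bank, cfg = search_config(),
                           bp = bandpass_params(), angles = NULL,
                           spec = NULL, motion = NULL) {
  if (is.null(cfg$search_half_width)) {
    if (is.null(spec))
      stop("provide cfg$search_half_width or spec (+ motion)")
    amp <- if (is.null(motion)) 0 else max(motion$amplitude)
    cfg$search_half_width <- max_tumor_radius(spec) + amp + 5
  }
  if (is.null(angles))
    angles <- vapply(frames, function(f) f$angle_deg, numeric(1))
  # cache band-passed templates per bank angle (identical for all frames)
  fcache <- new.env(parent = emptyenv())
  rows <- vector("list", length(frames))
  prev <- NULL
  for (k in seq_along(frames)) {
    lk <- bank_lookup(bank, angles[k])
    key <- as.character(lk$angle)
    if (is.null(fcache[[key]]))
      fcache[[key]] <- filter_template(lk$entry, bp, bank$pixel_spacing)
    expected <- c(lk$entry$ref_u_mm, lk$entry$ref_v_mm)
    if (cfg$expected_position_source == "previous_frame" && !is.null(prev))
      expected <- prev
    r <- track_frame(frames[[k]], bank, expected, cfg, bp,
                     angle_deg = angles[k],
                     filtered_template = fcache[[key]])
    if (!r$missing) prev <- c(r$u_mm, r$v_mm)
    rows[[k]] <- r
  }
  out <- do.call(rbind, rows)
  out <- cbind(frame_index = seq_along(frames), out)
  class(out) <- c("track_result", "data.frame")
  out
}

#' @export
print.track_result <- function(x, ...) {
  n <- nrow(x)
  nm <- sum(x$missing)
  cat("Track result:", n, "frames,", nm, "missing (",
      sprintf("%.1f%%", 100 * nm / n), ")\n")
  if (any(!x$missing))
    cat("median peak NCC:",
        sprintf("%.3f", stats::median(x$ncc_peak[!x$missing])), "\n")
  invisible(x)
}
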