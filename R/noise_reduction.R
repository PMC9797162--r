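#' Spatial filters with reflect padding
#'
#' Small 2D filters used by the noise-reduction and band-pass steps. All of
#' them pad by reflection (edge pixel duplicated), which avoids the edge
#' darkening that zero padding would feed into normalized cross-correlation
#' near image borders.
#'
#' `median_filter()` takes an odd kernel size. `box_filter()` accepts even
#' sizes (the 20 x 20 averaging kernel used for the anticorrelated-noise
#' high-pass is even as published); for even `k` the kernel origin is at
#' index `floor(k/2)` (0-based), i.e. the window sits half a pixel toward
#' the top-left, a fixed convention so results are reproducible.
#' `gaussian_filter()` takes the standard deviation in pixels and truncates
#' the kernel at 4 sigma.
#'
#' @param x numeric matrix.
#' @param k kernel size in pixels.
#' @param sigma Gaussian standard deviation in pixels.
#' @return Filtered matrix of the same shape.
#' @export
median_filter <- function(x, k) {
  if (k < 1 || k %% 2 != 1) stop("median kernel size must be odd and >= 1")
  if (k == 1) return(x)
  cpp_medfilt2(x, as.integer(k))
}

#' @rdname median_filter
#' @export
box_filter <- function(x, k) {
  if (k < 1) stop("kernel size must be >= 1")
  kern <- rep(1 / k, k)
  anchor <- as.integer(floor(k / 2))
  cpp_sepfilt2(x, kern, anchor, kern, anchor)
}

#' @rdname median_filter
#' @export
gaussian_filter <- function(x, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  kern <- exp(-((-r:r)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  cpp_sepfilt2(x, kern, r, kern, r)
}

#' Noise-reduction parameters for dual-energy images
#'
#' Houses the published kernel sizes and weight: a 3 x 3 median filter for
#' simple smoothing of the high-energy image, a 20 x 20 averaging filter
#' for the anticorrelated-noise high-pass, noise-cancellation weight
#' `w_n = 0.35`, and a 17 x 17 median filter for the noise-clipping
#' background estimate.
#'
#' @param ss_kernel simple-smoothing median size (odd).
#' @param acnr_kernel averaging-filter size for the ACNR high-pass.
#' @param w_n ACNR noise-cancellation weight (>= 0).
#' @param nc_kernel noise-clipping median background size (odd).
#' @return An `nr_params` object.
#' @export
nr_params <- function(ss_kernel = 3, acnr_kernel = 20, w_n = 0.35,
                      nc_kernel = 17) {
  if (ss_kernel %% 2 != 1 || nc_kernel %% 2 != 1)
    stop("median kernel sizes must be odd")
  if (w_n < 0) stop("w_n must be >= 0")
  structure(list(ss_kernel = as.integer(ss_kernel),
                 acnr_kernel = as.integer(acnr_kernel), w_n = w_n,
                 nc_kernel = as.integer(nc_kernel)),
            class = "nr_params")
}

#' Simple smoothing: median-filter the high-energy image before WLS
#'
#' Smooths `I_H` with a small median filter (default 3 x 3) and then forms
#' the soft-tissue DE image; the unfiltered low-energy projection keeps the
#' high-frequency information. Most of the DE image noise originates in the
#' high-energy component, which motivates filtering only that image.
#'
#' @inheritParams wls_soft_tissue
#' @param de_params a [de_params()].
#' @param nr_params an [nr_params()].
#' @return A `de_image` with technique `"SS"`.
#' @export
simple_smoothing <- function(I_H, I_L, de_params = detrack::de_params(),
                             nr_params = detrack::nr_params(),
                             angle_deg = NA_real_, time_s = NA_real_) {
  check_pair_shapes(I_H, I_L)
  out <- wls_soft_tissue(median_filter(I_H, nr_params$ss_kernel), I_L,
                         de_params, angle_deg, time_s)
  out$technique <- "SS"
  out
}

#' Anticorrelated noise reduction (ACNR)
#'
#' Quantum noise is anticorrelated between the DE soft-tissue and bone
#' images (both derive from the same two projections with weights of
#' opposite sign). ACNR therefore adds a weighted high-pass version of the
#' complementary bone image to the soft-tissue image:
#' `I_DEST + w_n * (I_DEB - box(I_DEB))`, with `w_n = 0.35` by default.
#' The box high-pass removes bone structure from the complementary image,
#' leaving mostly the (anticorrelated) noise.
#'
#' @param I_DEST soft-tissue `de_image` (from [wls_soft_tissue()]).
#' @param I_DEB bone `de_image` (from [wls_bone()]).
#' @param nr_params an [nr_params()].
#' @return A `de_image` with technique `"ACNR"`.
#' @export
acnr <- function(I_DEST, I_DEB, nr_params = detrack::nr_params()) {
  stopifnot(inherits(I_DEST, "de_image"), inherits(I_DEB, "de_image"))
  if (I_DEST$kind != "soft_tissue" || I_DEB$kind != "bone")
    stop("acnr expects a soft_tissue image and its complementary bone image")
  if (!identical(dim(I_DEST$pixels), dim(I_DEB$pixels)))
    stop("shape mismatch")
  hp <- I_DEB$pixels - box_filter(I_DEB$pixels, nr_params$acnr_kernel)
  out <- I_DEST
  out$pixels <- I_DEST$pixels + nr_params$w_n * hp
  out$technique <- "ACNR"
  out
}

#' Noise clipping of the high-energy image
#'
#' Real structures have higher contrast at low energy (photoelectric
#' effect), so any pixel whose high-energy contrast exceeds the low-energy
#' contrast is attributed to noise and clipped. With median-filter
#' backgrounds `median(I_H)` and `median(I_L)` (17 x 17 by default):
#' threshold `Th = I_L - median(I_L)`; wherever
#' `I_H - median(I_H) > Th`, the pixel is replaced by `Th + median(I_H)`.
#' The rule is signed and one-sided, exactly as published; a symmetric
#' variant that clips contrast magnitude on both sides is available via
#' `symmetric = TRUE` (off by default).
#'
#' @inheritParams simple_smoothing
#' @param symmetric also clip pixels whose contrast is more negative than
#'   the low-energy contrast (off by default).
#' @return The clipped high-energy intensity matrix.
#' @export
noise_clip <- function(I_H, I_L, nr_params = detrack::nr_params(),
                       symmetric = FALSE) {
  check_pair_shapes(I_H, I_L)
  bg_H <- median_filter(I_H, nr_params$nc_kernel)
  bg_L <- median_filter(I_L, nr_params$nc_kernel)
  Th <- I_L - bg_L
  out <- I_H
  over <- (I_H - bg_H) > Th
  out[over] <- (Th + bg_H)[over]
  if (symmetric) {
    under <- (I_H - bg_H) < -Th
    out[under] <- (-Th + bg_H)[under]
  }
  out
}

#' Noise clipping followed by ACNR
#'
#' Composes the two techniques: clip the high-energy image, rebuild both DE
#' images from the clipped `I_H` by weighted log subtraction, then apply
#' anticorrelated noise reduction. Equivalent to calling [noise_clip()],
#' [wls_soft_tissue()] / [wls_bone()] and [acnr()] in sequence.
#'
#' @inheritParams simple_smoothing
#' @return A `de_image` with technique `"NC-ACNR"`.
#' @export
nc_acnr <- function(I_H, I_L, de_params = detrack::de_params(),
                    nr_params = detrack::nr_params(),
                    angle_deg = NA_real_, time_s = NA_real_) {
  Ih <- noise_clip(I_H, I_L, nr_params)
  st <- wls_soft_tissue(Ih, I_L, de_params, angle_deg, time_s)
  bn <- wls_bone(Ih, I_L, de_params, angle_deg, time_s)
  out <- acnr(st, bn, nr_params)
  out$technique <- "NC-ACNR"
  out
}
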