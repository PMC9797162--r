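#' Dual-energy subtraction parameters
#'
#' Weights for weighted logarithmic subtraction (WLS). The defaults,
#' `w_ST = 0.42` and `w_B = 0.70`, are the empirically established values
#' for 60/120 kVp chest imaging; with [default_phantom()] they are also the
#' analytically exact cancellation weights (see
#' [true_cancellation_weight()]). `log_floor` (default 1 detector count)
#' replaces smaller intensities before the logarithm so that zero pixels
#' cannot produce infinities; at typical fluences of 1e3-1e4 counts it has
#' no visible effect.
#'
#' @param w_ST soft-tissue image weight (> 0); multiplies `ln I_L` in the
#'   soft-tissue image (bone-cancelling weight).
#' @param w_B bone image weight (> 0); multiplies `ln I_L` in the bone
#'   image (soft-tissue-cancelling weight).
#' @param log_floor minimum intensity substituted before taking logs (> 0).
#' @return A `de_params` object.
#' @export
de_params <- function(w_ST = 0.42, w_B = 0.70, log_floor = 1) {
  if (w_ST <= 0 || w_B <= 0) stop("weights must be > 0")
  if (log_floor <= 0) stop("log_floor must be > 0")
  structure(list(w_ST = w_ST, w_B = w_B, log_floor = log_floor),
            class = "de_params")
}

new_de_image <- function(pixels, kind, technique, angle_deg = NA_real_,
                         time_s = NA_real_) {
  structure(list(pixels = pixels, kind = kind, technique = technique,
                 angle_deg = angle_deg, time_s = time_s),
            class = "de_image")
}

#' @export
print.de_image <- function(x, ...) {
  cat("DE", x$kind, "image (", x$technique, "), ",
      nrow(x$pixels), "x", ncol(x$pixels), " px\n", sep = "")
  invisible(x)
}

check_pair_shapes <- function(I_H, I_L) {
  if (!identical(dim(I_H), dim(I_L))) stop("shape mismatch between I_H and I_L")
  if (any(I_H < 0) || any(I_L < 0)) stop("intensities must be nonnegative")
}

#' Weighted logarithmic subtraction
#'
#' Forms the dual-energy soft-tissue image `ln I_H - w_ST * ln I_L`
#' (bone suppressed) or the bone image `-ln I_H + w_B * ln I_L`
#' (soft tissue suppressed), pixelwise, after clamping intensities at
#' `log_floor`.
#'
#' @param I_H,I_L high- and low-energy intensity matrices of equal shape.
#' @param params a [de_params()].
#' @param angle_deg,time_s optional frame metadata carried on the result.
#' @return A `de_image` (pixels in log units) of kind `"soft_tissue"` or
#'   `"bone"`, technique `"unprocessed"`.
#' @examples
#' p <- de_params()
#' wls_soft_tissue(matrix(exp(2), 2, 2), matrix(exp(1), 2, 2),
#'                 de_params(w_ST = 0.5))$pixels  # 2 - 0.5 = 1.5
#' @export
wls_soft_tissue <- function(I_H, I_L, params = de_params(),
                            angle_deg = NA_real_, time_s = NA_real_) {
  check_pair_shapes(I_H, I_L)
  px <- log(pmax(I_H, params$log_floor)) -
    params$w_ST * log(pmax(I_L, params$log_floor))
  new_de_image(px, "soft_tissue", "unprocessed", angle_deg, time_s)
}

#' @rdname wls_soft_tissue
#' @export
wls_bone <- function(I_H, I_L, params = de_params(),
                     angle_deg = NA_real_, time_s = NA_real_) {
  check_pair_shapes(I_H, I_L)
  px <- -log(pmax(I_H, params$log_floor)) +
    params$w_B * log(pmax(I_L, params$log_floor))
  new_de_image(px, "bone", "unprocessed", angle_deg, time_s)
}
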