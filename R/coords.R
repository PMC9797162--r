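#' Detector pixel / millimeter conversions
#'
#' The tracking plane uses a single convention, applied everywhere in the
#' package: images are matrices with `row = v` (superior-inferior axis,
#' increasing with row index) and `col = u` (lateral axis). Millimeter
#' coordinates are measured from the detector center, so pixel `(i, j)`
#' (1-based) maps to `u = (j - 1 - (nc - 1)/2) * spacing` and
#' `v = (i - 1 - (nr - 1)/2) * spacing`. CSV files written by the package
#' use 0-based pixel indices.
#'
#' @param j,i 1-based column / row index (may be fractional).
#' @param u,v millimeter coordinate from the detector center.
#' @param n number of columns (for `u`) or rows (for `v`).
#' @param spacing pixel spacing in mm/pixel.
#' @return The converted coordinate (numeric, possibly fractional).
#' @keywords internal
#' @name coords
NULL

#' @rdname coords
col_to_u <- function(j, n, spacing) (j - 1 - (n - 1) / 2) * spacing

#' @rdname coords
u_to_col <- function(u, n, spacing) u / spacing + (n - 1) / 2 + 1

#' @rdname coords
row_to_v <- function(i, n, spacing) (i - 1 - (n - 1) / 2) * spacing

#' @rdname coords
v_to_row <- function(v, n, spacing) v / spacing + (n - 1) / 2 + 1
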