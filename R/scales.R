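#' Derive the octave-spaced operator scale scheme
#'
#' The operator bank is built from the canvas size by three construction rules:
#' the coarsest center diameter is half the canvas (`d_1 = side_px / 2`) and
#' each further scale halves it (a 1-octave size step); the band-pass peak is
#' always 4 cycles per center diameter (`f_k = 4 * side_px / d_k` cycles per
#' image), so the pass-band scales with the window; and the number of selected
#' windows satisfies `N_k * d_k = side_px` (the summed diameters of the
#' selected areas tile the image diameter). For a 256-px canvas this yields
#' d = 128, 64, 32, 16 px; f = 8, 16, 32, 64 cpi; N = 2, 4, 8, 16.
#'
#' @param side_px side of the square canvas in pixels; must be divisible by
#'   `2^n_scales`.
#' @param n_scales number of octave-spaced scales (default 4).
#' @return A tibble with one row per scale: `k`, `d_px` (center diameter),
#'   `f_cpi` (band-pass peak, cycles/image), `bandwidth_oct`, `n_windows`,
#'   `ring_width_px` (surround ring width, equal to `d_px`), `margin_px`
#'   (border excluded from extremum search, `d_px / 2`), `side_px`.
#' @export
operator_scales <- function(side_px = 256, n_scales = 4) {
  if (n_scales < 1) stop("`n_scales` must be at least 1", call. = FALSE)
  if (side_px < 2^n_scales || side_px %% 2^n_scales != 0) {
    stop("`side_px` must be a positive multiple of 2^n_scales", call. = FALSE)
  }
  k <- seq_len(n_scales)
  d <- side_px / 2^k
  tibble::tibble(
    k = as.integer(k),
    d_px = d,
    f_cpi = 4 * side_px / d,
    bandwidth_oct = 1,
    n_windows = as.integer(side_px / d),
    ring_width_px = d,
    margin_px = as.integer(d / 2),
    side_px = as.integer(side_px)
  )
}

# one-row scale sanity check used by the operator entry points
check_scale <- function(scale, side_px) {
  stopifnot(is.data.frame(scale), nrow(scale) == 1)
  if (scale$d_px < 4) {
    stop("scale too fine: center diameter below 4 px", call. = FALSE)
  }
  if (scale$side_px != side_px) {
    stop("scale was derived for a different canvas size", call. = FALSE)
  }
  if (scale$f_cpi >= side_px / 2) {
    stop("band-pass peak at or above Nyquist", call. = FALSE)
  }
  invisible(scale)
}
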