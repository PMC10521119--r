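#' The nonlocal-contrast operator
#'
#' Core of the package: a sliding center--surround operator in the
#' filter--rectify--filter tradition. At scale `k` the image is band-pass
#' filtered at `f_k` cycles/image (4 cycles per center diameter, 1-octave
#' bandwidth), squared (energy rectification), and averaged over a disk of
#' diameter `d_k` -- the center energy density. The surround takes an
#' octave-spaced bank over the full visible range, averages each band's energy
#' density over the annulus of inner radius `d_k/2` and outer radius
#' `3 d_k/2` (ring width equal to the center diameter), and averages across
#' bands -- power per octave on average. The amplitude map is their
#' difference; it is calibrated to be near zero on textures whose power per
#' octave is spatially homogeneous, and positive where local contrast at the
#' scale's band exceeds its surround.
#'
#' All maps are computed with reflective border padding; extremum search is
#' restricted to `margin_px` (default `d_k/2`, so the center disk stays inside
#' the original canvas).
#'
#' @name operator
NULL

# signed FFT frequencies in cycles per sample
fft_freq <- function(n) {
  f <- (0:(n - 1)) / n
  f[f > 0.5] <- f[f > 0.5] - 1
  f
}

# radial frequency grid in cycles per `ref_side`-pixel image, for an n x n fft
radial_freq_cpi <- function(n, ref_side) {
  fr <- fft_freq(n) * ref_side
  sqrt(outer(fr^2, fr^2, "+"))
}

# isotropic log-Gaussian amplitude transfer, unit peak, FWHM = bw octaves, no DC
log_gaussian_gain <- function(r, peak_cpi, bandwidth_oct = 1) {
  g <- array(0, dim(r))
  pos <- r > 0
  g[pos] <- exp(-4 * log(2) * (log2(r[pos] / peak_cpi))^2 / bandwidth_oct^2)
  g
}

#' Isotropic log-Gaussian band-pass filter
#'
#' Frequency-domain filtering with a radial log-Gaussian amplitude transfer:
#' unit gain at `peak_cpi`, full width at half maximum of `bandwidth_oct`
#' octaves, and zero DC (the output is exactly zero-mean).
#'
#' @param x a `lum_image` or a square numeric matrix.
#' @param peak_cpi peak frequency in cycles per image of `ref_side` pixels.
#' @param bandwidth_oct amplitude FWHM in octaves (default 1).
#' @param ref_side the side length the `peak_cpi` units refer to; defaults to
#'   the side of `x`. Pass the original side when filtering a padded raster.
#' @return A zero-mean numeric matrix of the same size as `x`.
#' @export
bandpass <- function(x, peak_cpi, bandwidth_oct = 1, ref_side = NULL) {
  m <- if (inherits(x, "lum_image")) x$pixels else x
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (is.null(ref_side)) ref_side <- nrow(m)
  if (bandwidth_oct <= 0) stop("`bandwidth_oct` must be positive", call. = FALSE)
  if (peak_cpi <= 0 || peak_cpi >= ref_side / 2) {
    stop("`peak_cpi` must lie strictly between 0 and Nyquist (ref_side/2)",
         call. = FALSE)
  }
  g <- log_gaussian_gain(radial_freq_cpi(nrow(m), ref_side), peak_cpi, bandwidth_oct)
  Re(stats::fft(stats::fft(m) * g, inverse = TRUE)) / length(m)
}

#' Reflect-pad a matrix
#'
#' Symmetric (half-sample) reflection padding on all four sides; `pad` must
#' not exceed the matrix side.
#'
#' @param m numeric matrix.
#' @param pad padding width in pixels.
#' @return The padded matrix.
#' @export
pad_reflect <- function(m, pad) {
  stopifnot(is.matrix(m), pad >= 0, pad <= nrow(m), pad <= ncol(m))
  if (pad == 0) return(m)
  ri <- c(pad:1, 1:nrow(m), nrow(m):(nrow(m) - pad + 1))
  ci <- c(pad:1, 1:ncol(m), ncol(m):(ncol(m) - pad + 1))
  m[ri, ci]
}

# squared wrapped distance grid for circular-convolution kernels
wrapped_r2 <- function(n) {
  d <- 0:(n - 1)
  d <- pmin(d, n - d)
  outer(d^2, d^2, "+")
}

disk_kernel <- function(n, diameter) {
  k <- wrapped_r2(n) <= (diameter / 2)^2
  k / sum(k)
}

annulus_kernel <- function(n, diameter) {
  r2 <- wrapped_r2(n)
  k <- r2 > (diameter / 2)^2 & r2 <= (1.5 * diameter)^2
  k / sum(k)
}

conv_circular <- function(a, kernel_fft) {
  Re(stats::fft(stats::fft(a) * kernel_fft, inverse = TRUE)) / length(a)
}

# octave-spaced surround band peaks covering [band_lo, band_hi), peaks < Nyquist
surround_band_peaks <- function(band_lo, band_hi) {
  if (band_lo <= 0 || band_lo >= band_hi) {
    stop("surround band limits must satisfy 0 < band_lo < band_hi", call. = FALSE)
  }
  band_lo * 2^(0:floor(log2(band_hi / band_lo) - 1e-9))
}

# shared machinery: one padded FFT feeds center and surround measures
operator_maps <- function(img, scale, band_lo = 2, band_hi = NULL,
                          margin = NULL) {
  stopifnot(inherits(img, "lum_image"))
  s <- img$side_px
  check_scale(scale, s)
  d <- scale$d_px
  if (is.null(band_hi)) band_hi <- s / 2
  if (is.null(margin)) margin <- scale$margin_px
  pad <- as.integer(ceiling(1.5 * d))
  P <- pad_reflect(img$pixels, pad)
  n <- nrow(P)
  Fp <- stats::fft(P)
  r <- radial_freq_cpi(n, s)
  band_energy <- function(peak) {
    b <- Re(stats::fft(Fp * log_gaussian_gain(r, peak, scale$bandwidth_oct),
                       inverse = TRUE)) / n^2
    b^2
  }
  kd <- stats::fft(disk_kernel(n, d))
  ka <- stats::fft(annulus_kernel(n, d))
  crop <- function(M) M[(pad + 1):(pad + s), (pad + 1):(pad + s)]
  center <- crop(conv_circular(band_energy(scale$f_cpi), kd))
  peaks <- surround_band_peaks(band_lo, band_hi)
  peaks <- peaks[peaks < s / 2]
  sur <- Reduce(`+`, lapply(peaks, function(p) {
    conv_circular(band_energy(p), ka)
  })) / length(peaks)
  list(center = center, surround = crop(sur), margin = as.integer(margin),
       band_peaks = peaks)
}

#' Center energy and surround power maps
#'
#' `center_energy_map()` returns, for every position, the mean squared value
#' of the band-pass filtered image (peak `f_cpi`, 1-octave FWHM) over the disk
#' of diameter `d_px` -- a per-pixel energy density. `surround_power_map()`
#' returns the across-band average of per-pixel band energy densities over the
#' surrounding annulus (inner radius `d_px/2`, outer radius `3 d_px/2`), for
#' an octave-spaced bank spanning `[band_lo, band_hi)` cycles/image.
#'
#' @param img a normalized `lum_image`.
#' @param scale one row of [operator_scales()].
#' @param band_lo,band_hi surround bank limits in cycles/image; defaults 2 to
#'   Nyquist.
#' @return A numeric matrix the size of the image.
#' @export
center_energy_map <- function(img, scale) {
  operator_maps(img, scale)$center
}

#' @rdname center_energy_map
#' @export
surround_power_map <- function(img, scale, band_lo = 2, band_hi = NULL) {
  operator_maps(img, scale, band_lo = band_lo, band_hi = band_hi)$surround
}

#' Nonlocal contrast modulation amplitude map
#'
#' The per-position difference between the center band energy density and the
#' octave-averaged surround power density (both per-pixel, so the 8-fold area
#' difference between annulus and disk does not bias the comparison).
#'
#' @inheritParams center_energy_map
#' @param band_lo,band_hi surround bank limits in cycles/image.
#' @param margin border width excluded from extremum search; defaults to the
#'   scale's `margin_px` (`d_px/2`).
#' @return An `amplitude_map` object: list with `values` (matrix), `scale`
#'   (one-row tibble), `valid_margin_px`, `band_peaks`.
#' @export
amplitude_map <- function(img, scale, band_lo = 2, band_hi = NULL, margin = NULL) {
  om <- operator_maps(img, scale, band_lo = band_lo, band_hi = band_hi,
                      margin = margin)
  structure(
    list(
      values = om$center - om$surround,
      scale = scale,
      valid_margin_px = om$margin,
      band_peaks = om$band_peaks
    ),
    class = "amplitude_map"
  )
}

#' Amplitude maps at every scale
#'
#' @inheritParams amplitude_map
#' @param scales tibble of scales as from [operator_scales()]; each row is
#'   processed independently.
#' @return A named list (`k1`, `k2`, ...) of `amplitude_map` objects.
#' @export
multiscale_maps <- function(img, scales = operator_scales(img$side_px),
                            band_lo = 2, band_hi = NULL) {
  maps <- purrr::map(seq_len(nrow(scales)), function(i) {
    amplitude_map(img, scales[i, ], band_lo = band_lo, band_hi = band_hi)
  })
  stats::setNames(maps, paste0("k", scales$k))
}

#' @export
print.amplitude_map <- function(x, ...) {
  cat(sprintf(
    "<amplitude_map> scale k=%d (d=%g px, f=%g cpi), %d x %d, margin %d px\n",
    x$scale$k, x$scale$d_px, x$scale$f_cpi,
    nrow(x$values), ncol(x$values), x$valid_margin_px
  ))
  invisible(x)
}

#' @export
as.matrix.amplitude_map <- function(x, ...) x$values

# logical mask of the valid (extremum-searchable) region
valid_mask <- function(map) {
  s <- nrow(map$values)
  mrg <- map$valid_margin_px
  ok <- matrix(FALSE, s, s)
  if (s - 2 * mrg > 0) {
    idx <- (mrg + 1):(s - mrg)
    ok[idx, idx] <- TRUE
  }
  ok
}

#' @export
tidy.amplitude_map <- function(x, ...) {
  s <- nrow(x$values)
  amp <- as.vector(x$values)
  ok <- as.vector(valid_mask(x))
  tibble::tibble(
    x = rep(seq_len(s), each = s),
    y = rep(seq_len(s), times = s),
    amplitude = amp,
    valid = ok
  )
}

#' @export
autoplot.amplitude_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$amplitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "amplitude") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("Contrast modulation amplitude, scale k=%d (f=%g cpi)",
                      object$scale$k, object$scale$f_cpi)
    ) +
    ggplot2::theme_minimal()
}

#' Export an amplitude map as 32-bit float TIFF plus JSON metadata
#'
#' @param map an `amplitude_map`.
#' @param path output TIFF path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_amplitude_map <- function(map, path) {
  stopifnot(inherits(map, "amplitude_map"))
  rng <- range(map$values)
  scaled <- if (diff(rng) > 0) (map$values - rng[1]) / diff(rng) else map$values * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(scale = as.list(map$scale), valid_margin_px = map$valid_margin_px,
         band_peaks = map$band_peaks, value_min = rng[1], value_max = rng[2]),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
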