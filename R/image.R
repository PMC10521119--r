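#' Luminance image objects
#'
#' A `lum_image` is a square raster of luminance values (cd/m^2 on an abstract
#' calibrated scale) together with its angular size. Mean luminance and RMS
#' contrast (population SD divided by mean) are always derived from the pixels,
#' so they cannot drift out of sync with the raster.
#'
#' @param pixels square numeric matrix of nonnegative luminance values.
#' @param angular_size_deg degrees of visual angle subtended by the canvas.
#' @param normalized logical flag set by [normalize_luminance()].
#' @return A `lum_image` object: a list with elements `pixels`, `side_px`,
#'   `angular_size_deg`, `mean_luminance`, `rms_contrast`, `normalized`.
#' @seealso [load_luminance()], [normalize_luminance()]
#' @export
new_lum_image <- function(pixels, angular_size_deg = 8, normalized = FALSE) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) != ncol(pixels) || nrow(pixels) < 1) {
    stop("`pixels` must be a non-empty square matrix", call. = FALSE)
  }
  if (angular_size_deg <= 0) stop("`angular_size_deg` must be positive", call. = FALSE)
  m <- mean(pixels)
  structure(
    list(
      pixels = pixels,
      side_px = nrow(pixels),
      angular_size_deg = angular_size_deg,
      mean_luminance = m,
      rms_contrast = if (m > 0) pop_sd(pixels) / m else NA_real_,
      normalized = isTRUE(normalized)
    ),
    class = "lum_image"
  )
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' @export
as.matrix.lum_image <- function(x, ...) x$pixels

#' @export
print.lum_image <- function(x, ...) {
  cat(sprintf(
    "<lum_image> %d x %d px, %.3g deg, mean %.4g cd/m2, RMS contrast %.4g%s\n",
    x$side_px, x$side_px, x$angular_size_deg, x$mean_luminance,
    x$rms_contrast, if (x$normalized) " (normalized)" else ""
  ))
  invisible(x)
}

#' Load a raster image as luminance
#'
#' Reads a PNG or TIFF file, reduces color to luminance with the Rec.709 luma
#' weights (0.2126 R + 0.7152 G + 0.0722 B), center-crops to a square, and
#' resamples to a `side_px` canvas. Pixel values are kept on the file's
#' nonnegative relative-luminance scale; calibrate with
#' [normalize_luminance()].
#'
#' @param path path to a readable PNG or TIFF file.
#' @param side_px side of the square working canvas in pixels (>= 64). The
#'   default 256 puts the highest operator frequency (64 cycles/image) a factor
#'   of two below Nyquist.
#' @param angular_size_deg angular size assigned to the canvas (default 8).
#' @return An unnormalized [new_lum_image()] object.
#' @export
load_luminance <- function(path, side_px = 256, angular_size_deg = 8) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    stop("`path` must name an existing image file", call. = FALSE)
  }
  if (side_px < 64) stop("`side_px` must be at least 64", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, " (PNG or TIFF expected)", call. = FALSE)
  )
  if (length(arr) == 0) stop("zero-size image: ", path, call. = FALSE)
  m <- if (length(dim(arr)) == 3) {
    if (dim(arr)[3] >= 3) {
      0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] + 0.0722 * arr[, , 3]
    } else {
      arr[, , 1]
    }
  } else {
    arr
  }
  # center-crop to square, then resample
  nr <- nrow(m); nc <- ncol(m); side0 <- min(nr, nc)
  r0 <- (nr - side0) %/% 2; c0 <- (nc - side0) %/% 2
  m <- m[(r0 + 1):(r0 + side0), (c0 + 1):(c0 + side0), drop = FALSE]
  if (side0 != side_px) {
    m <- EBImage::imageData(EBImage::resize(m, w = side_px, h = side_px))
  }
  m[m < 0] <- 0
  new_lum_image(m, angular_size_deg = angular_size_deg)
}

#' Normalize an image to target mean luminance and RMS contrast
#'
#' Applies the affine map `p -> a * (p - mean(p)) + mean_target` with
#' `a = rms_target * mean_target / sd(p)`, which sets the mean exactly to
#' `mean_target` and the RMS contrast (population SD / mean) exactly to
#' `rms_target`. If the map would drive pixels negative, they are clipped to 0;
#' when clipping touches at least 1% of pixels a warning is emitted and the
#' normalization is re-applied once to the clipped raster (so the calibration
#' targets are restored up to the residual second clip).
#'
#' @param img a [new_lum_image()] object with non-constant pixels.
#' @param mean_target target mean luminance in cd/m^2 (default 35).
#' @param rms_target target RMS contrast (default 0.45).
#' @return A normalized `lum_image`.
#' @export
normalize_luminance <- function(img, mean_target = 35, rms_target = 0.45) {
  stopifnot(inherits(img, "lum_image"))
  if (mean_target <= 0 || rms_target <= 0) {
    stop("normalization targets must be positive", call. = FALSE)
  }
  q <- norm_affine(img$pixels, mean_target, rms_target)
  frac <- mean(q < 0)
  if (frac >= 0.01) {
    warning(sprintf(
      "normalization clips %.1f%% of pixels; re-normalizing once after clipping",
      100 * frac
    ), call. = FALSE)
    q[q < 0] <- 0
    q <- norm_affine(q, mean_target, rms_target)
    q[q < 0] <- 0
  } else if (frac > 0) {
    q[q < 0] <- 0
  }
  out <- new_lum_image(q, angular_size_deg = img$angular_size_deg, normalized = TRUE)
  out
}

norm_affine <- function(p, mean_target, rms_target) {
  m <- mean(p)
  s <- pop_sd(p)
  if (s == 0) stop("cannot normalize a constant image (zero contrast)", call. = FALSE)
  rms_target * mean_target / s * (p - m) + mean_target
}

#' Write / read a luminance image with a JSON sidecar
#'
#' The raster is stored scaled to its peak value -- as grayscale PNG (8-bit
#' payload) or, for `.tif`/`.tiff` paths, as 16-bit TIFF when bit depth
#' matters. The sidecar `<path>.json` records the peak, mean luminance, RMS
#' contrast and angular size exactly, so the calibrated scale round-trips.
#'
#' @param img a `lum_image`.
#' @param path output PNG or TIFF path.
#' @return `write_luminance()` returns `path` invisibly; `read_luminance()`
#'   returns the reconstructed `lum_image`.
#' @export
write_luminance <- function(img, path) {
  stopifnot(inherits(img, "lum_image"))
  peak <- max(img$pixels)
  if (peak <= 0) peak <- 1
  scaled <- pmin(pmax(img$pixels / peak, 0), 1)
  if (tolower(tools::file_ext(path)) %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  } else {
    png::writePNG(scaled, target = path, dpi = NULL)
  }
  jsonlite::write_json(
    list(
      peak = peak,
      side_px = img$side_px,
      angular_size_deg = img$angular_size_deg,
      mean_luminance = img$mean_luminance,
      rms_contrast = img$rms_contrast,
      normalized = img$normalized
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_luminance
#' @export
read_luminance <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  raw <- if (tolower(tools::file_ext(path)) %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  m <- raw * meta$peak
  new_lum_image(m, angular_size_deg = meta$angular_size_deg,
                normalized = isTRUE(meta$normalized))
}

#' @export
tidy.lum_image <- function(x, ...) {
  s <- x$side_px
  lum <- as.vector(x$pixels)
  tibble::tibble(
    x = rep(seq_len(s), each = s),
    y = rep(seq_len(s), times = s),
    luminance = lum
  )
}

#' @export
autoplot.lum_image <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$luminance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", name = "cd/m²") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}
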