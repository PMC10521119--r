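#' Gaussian aperture windows
#'
#' The aperture ("window") that cuts a selected area out of the source image
#' is a radial Gaussian with full width at half maximum equal to the scale's
#' center diameter `d_px`, so the weight is 1 at the center, 0.5 at radius
#' `d_px/2` and `2^-4 = 0.0625` at radius `d_px`. Because the band-pass peak
#' is 4 cycles per center diameter, every window transmits four cycles of the
#' image regardless of scale. The profile is truncated to 0 where it falls
#' below 1% of its peak (radius ~1.29 `d_px`), so windows have compact
#' support and the synthesized stimulus has an exactly uniform background
#' outside all windows.
#'
#' @param r radial distance from the window center, px.
#' @param d_px window diameter (Gaussian FWHM), px.
#' @return Weights in `[0, 1]`.
#' @export
window_weight <- function(r, d_px) {
  w <- exp(-4 * log(2) * (r / d_px)^2)
  w[w < 0.01] <- 0
  w
}

#' @rdname window_weight
#' @param point length-2 numeric `(x, y)` center in px.
#' @param scale one row of [operator_scales()].
#' @return `make_window()` returns an `aperture_window`: a list with `center`,
#'   `diameter_px` and `weight` (a function of radius).
#' @export
make_window <- function(point, scale) {
  stopifnot(length(point) == 2, is.data.frame(scale), nrow(scale) == 1)
  d <- scale$d_px
  structure(
    list(
      center = c(x = as.numeric(point[1]), y = as.numeric(point[2])),
      diameter_px = d,
      weight = function(r) window_weight(r, d)
    ),
    class = "aperture_window"
  )
}

# combined weight raster: pointwise maximum over all windows of all sets
weight_raster <- function(side, sets) {
  W <- matrix(0, side, side)
  for (s in sets) {
    scale <- attr(s, "scale")
    d <- if (!is.null(scale)) scale$d_px else attr(s, "min_sep")
    if (is.null(d)) stop("extrema set carries no window diameter", call. = FALSE)
    for (i in seq_len(nrow(s))) {
      r <- sqrt(outer((seq_len(side) - s$y[i])^2, (seq_len(side) - s$x[i])^2, "+"))
      W <- pmax(W, window_weight(r, d))
    }
  }
  W
}

#' Synthesize an aperture stimulus from selected areas
#'
#' Blends the source image into a uniform background through the Gaussian
#' windows centered on the selected points:
#' `O(q) = B + W(q) * (I(q) - B)` with `W(q)` the pointwise maximum of all
#' window weights at `q` (maximum rather than sum, so overlapping windows do
#' not double contrast). Where no window reaches (`W = 0`), the output equals
#' the background exactly.
#'
#' @param img the source `lum_image`.
#' @param sets an `extrema_set` or a list of them (one or more scales); all
#'   must share one amplitude class.
#' @param background background luminance; defaults to the source mean.
#' @return A `stimulus_image` (a `lum_image` with extra fields
#'   `amplitude_class`, `scales_included`, `provenance`).
#' @export
synthesize <- function(img, sets, background = NULL) {
  stopifnot(inherits(img, "lum_image"))
  if (inherits(sets, "extrema_set")) sets <- list(sets)
  kinds <- unique(vapply(sets, function(s) attr(s, "kind"), character(1)))
  if (length(kinds) > 1) {
    stop("all extrema sets must share one amplitude class, got: ",
         paste(kinds, collapse = ", "), call. = FALSE)
  }
  B <- background %||% img$mean_luminance
  W <- weight_raster(img$side_px, sets)
  out <- new_lum_image(B + W * (img$pixels - B),
                       angular_size_deg = img$angular_size_deg,
                       normalized = FALSE)
  out$amplitude_class <- if (length(kinds)) kinds else NA_character_
  out$scales_included <- sort(unique(unlist(purrr::map(sets, function(s) {
    sc <- attr(s, "scale"); if (!is.null(sc)) sc$k
  }))))
  out$provenance <- sets
  class(out) <- c("stimulus_image", class(out))
  out
}

#' Per-frequency stimuli and their combination
#'
#' Builds one stimulus per scale from that scale's extrema set, plus the
#' aggregate stimulus combining the windows of all scales under the same
#' maximum-blend rule. Scales missing from `sets_by_scale` produce a warning
#' and are skipped.
#'
#' @inheritParams synthesize
#' @param sets_by_scale list of `extrema_set`s, one per scale, same class.
#' @return A list with `per_scale` (named list of `stimulus_image`s) and
#'   `combined`.
#' @export
per_frequency_variants <- function(img, sets_by_scale, background = NULL) {
  ks <- purrr::map(sets_by_scale, function(s) attr(s, "scale")$k)
  missing <- vapply(ks, is.null, logical(1))
  if (any(missing)) {
    warning("dropping extrema sets without scale information", call. = FALSE)
    sets_by_scale <- sets_by_scale[!missing]
    ks <- ks[!missing]
  }
  per_scale <- purrr::map(sets_by_scale, function(s) {
    synthesize(img, s, background = background)
  })
  names(per_scale) <- paste0("k", unlist(ks))
  list(
    per_scale = per_scale,
    combined = synthesize(img, sets_by_scale, background = background)
  )
}

#' Write a stimulus image plus its JSON manifest
#'
#' The raster goes through [write_luminance()] (PNG, or 16-bit TIFF by
#' extension); the manifest
#' `<path>.manifest.json` records the amplitude class, scales, and window
#' centers so the synthesis is reproducible.
#'
#' @param stim a `stimulus_image`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_stimulus <- function(stim, path) {
  stopifnot(inherits(stim, "stimulus_image"))
  write_luminance(stim, path)
  jsonlite::write_json(
    list(
      amplitude_class = stim$amplitude_class,
      scales_included = stim$scales_included,
      points = purrr::map(stim$provenance, function(s) {
        list(kind = attr(s, "kind"),
             d_px = if (!is.null(attr(s, "scale"))) attr(s, "scale")$d_px,
             points = as.data.frame(s))
      })
    ),
    paste0(path, ".manifest.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}
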