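#' Synthetic fixtures with known ground truth
#'
#' Deterministic generators used throughout the test suite: contrast-modulated
#' textures whose envelope is known by construction, schematic face-like
#' images with high-contrast patches at the eye and mouth positions, and
#' simulated between-subjects response logs. Every generator takes a `seed`
#' and is bit-reproducible.
#'
#' @name fixtures
NULL

# broadband noise with equal power per octave (1/f amplitude spectrum),
# the spectral profile of natural images; unit variance
octave_flat_noise <- function(side_px, f_lo = 2, f_hi = NULL) {
  if (is.null(f_hi)) f_hi <- side_px / 2
  w <- matrix(stats::rnorm(side_px^2), side_px)
  r <- radial_freq_cpi(side_px, side_px)
  A <- matrix(0, side_px, side_px)
  keep <- r >= f_lo & r <= f_hi
  A[keep] <- 1 / r[keep]
  x <- Re(stats::fft(stats::fft(w) * A, inverse = TRUE)) / side_px^2
  x / stats::sd(x)
}

# raised-cosine radial bump rescaled to [-1, 1]: +1 at the center, -1 outside
bump_envelope <- function(side_px, center, radius) {
  r <- sqrt(outer((seq_len(side_px) - center[2])^2,
                  (seq_len(side_px) - center[1])^2, "+"))
  e <- ifelse(r < radius, 0.5 * (1 + cos(pi * r / radius)), 0)
  2 * e - 1
}

#' Contrast-modulated texture with known envelope
#'
#' Builds `carrier * (1 + depth * envelope)`, normalizes it to the standard
#' mean luminance and RMS contrast, and returns the envelope raster as ground
#' truth. Carriers: `"noise"` (white noise band-passed at `carrier_cpi`,
#' 1-octave FWHM), `"grating"` (horizontal sinusoid at `carrier_cpi`), or
#' `"broadband"` (noise with equal power per octave from 2 cycles/image to
#' Nyquist, the natural-image spectral profile against which the operator is
#' calibrated). Envelopes: `"bump"` (raised cosine, +1 at `envelope_center`,
#' -1 outside `envelope_radius`, so full depth extinguishes the carrier away
#' from the bump) or `"sine"` (horizontal cosine at `envelope_cpi`).
#'
#' @param side_px canvas side in pixels.
#' @param carrier_cpi carrier frequency, cycles/image (ignored for
#'   `"broadband"`).
#' @param envelope_cpi envelope frequency for the `"sine"` envelope; must be
#'   below `carrier_cpi`.
#' @param modulation_depth depth in `[0, 1]`.
#' @param carrier_kind,envelope_kind see Details.
#' @param envelope_center,envelope_radius bump center `(x, y)` and radius in
#'   px; defaults: offset center at 40% of the canvas, radius `side_px / 3`.
#' @param seed RNG seed (required; fixtures are deterministic).
#' @param normalize normalize to (35 cd/m^2, RMS 0.45)? Default TRUE.
#' @return A list: `image` (a `lum_image`), `envelope` (matrix in `[-1, 1]`),
#'   `spec` (the generating parameters).
#' @export
make_modulated_texture <- function(side_px = 256, carrier_cpi = 16,
                                   envelope_cpi = 2, modulation_depth = 1,
                                   carrier_kind = c("noise", "grating", "broadband"),
                                   envelope_kind = c("bump", "sine"),
                                   envelope_center = NULL,
                                   envelope_radius = NULL,
                                   seed = 1, normalize = TRUE) {
  carrier_kind <- match.arg(carrier_kind)
  envelope_kind <- match.arg(envelope_kind)
  if (modulation_depth < 0 || modulation_depth > 1) {
    stop("`modulation_depth` must lie in [0, 1]", call. = FALSE)
  }
  if (envelope_kind == "sine" && envelope_cpi >= carrier_cpi &&
      carrier_kind != "broadband") {
    stop("`envelope_cpi` must be below `carrier_cpi`", call. = FALSE)
  }
  if (is.null(envelope_center)) envelope_center <- round(0.4 * side_px) * c(1, 1)
  if (is.null(envelope_radius)) envelope_radius <- side_px / 3
  withr::with_seed(seed, {
    carrier <- switch(carrier_kind,
      noise = {
        b <- bandpass(matrix(stats::rnorm(side_px^2), side_px), carrier_cpi,
                      bandwidth_oct = 1, ref_side = side_px)
        b / stats::sd(b)
      },
      grating = {
        x <- matrix(seq_len(side_px), side_px, side_px, byrow = TRUE)
        sqrt(2) * sin(2 * pi * carrier_cpi * (x - 1) / side_px)
      },
      broadband = octave_flat_noise(side_px)
    )
    env <- switch(envelope_kind,
      bump = bump_envelope(side_px, envelope_center, envelope_radius),
      sine = {
        x <- matrix(seq_len(side_px), side_px, side_px, byrow = TRUE)
        cos(2 * pi * envelope_cpi * (x - 1) / side_px)
      }
    )
    tex <- carrier * (1 + modulation_depth * env)
    # positive offset; exact calibration is an affine map, so the offset is
    # immaterial once normalized
    img <- new_lum_image(tex - min(tex) + 1)
    if (normalize) img <- normalize_luminance(img)
    list(
      image = img,
      envelope = env,
      spec = list(side_px = side_px, carrier_cpi = carrier_cpi,
                  envelope_cpi = envelope_cpi,
                  modulation_depth = modulation_depth,
                  carrier_kind = carrier_kind, envelope_kind = envelope_kind,
                  envelope_center = envelope_center,
                  envelope_radius = envelope_radius, seed = seed)
    )
  })
}

#' Schematic face image with known informative regions
#'
#' A low-contrast broadband background with a faint facial oval and three
#' high-contrast band-passed texture patches at the eye and mouth positions
#' -- the loci where contrast-modulation maxima of real faces concentrate.
#' Patch centers are returned as ground truth.
#'
#' @param side_px canvas side in pixels.
#' @param patch_gain contrast gain of the eye/mouth patches relative to the
#'   background texture (default 3).
#' @param background_gain background texture gain (default 0.3).
#' @param patch_cpi carrier frequency of the patches; default 16 cycles/image
#'   (the second operator scale's band, which is 16 cpi for any canvas).
#' @param seed RNG seed.
#' @param normalize normalize to (35, 0.45)? Default TRUE.
#' @param mirror mirror the layout left-right (truth mirrors with it).
#' @return A list: `image` (a `lum_image`), `truth` (tibble `part`, `x`, `y`),
#'   `spec`.
#' @export
make_schematic_face <- function(side_px = 256, patch_gain = 3,
                                background_gain = 0.3, patch_cpi = NULL,
                                seed = 1, normalize = TRUE, mirror = FALSE) {
  if (is.null(patch_cpi)) patch_cpi <- 16
  radius <- side_px / 8
  truth <- tibble::tibble(
    part = c("eye_left", "eye_right", "mouth"),
    x = side_px * c(0.35, 0.65, 0.50),
    y = side_px * c(0.38, 0.38, 0.70)
  )
  if (mirror) truth$x <- side_px + 1 - truth$x
  d <- as.matrix(stats::dist(truth[, c("x", "y")]))
  if (any(d[upper.tri(d)] < 2 * radius)) {
    warning("schematic face patches overlap", call. = FALSE)
  }
  withr::with_seed(seed, {
    base <- background_gain * octave_flat_noise(side_px)
    # faint facial oval (low-contrast luminance step)
    cx <- side_px / 2; cy <- side_px / 2
    ell <- outer((seq_len(side_px) - cy)^2 / (0.42 * side_px)^2,
                 (seq_len(side_px) - cx)^2 / (0.33 * side_px)^2, "+") <= 1
    base <- base + 0.15 * ell
    for (i in seq_len(nrow(truth))) {
      tex <- bandpass(matrix(stats::rnorm(side_px^2), side_px), patch_cpi,
                      bandwidth_oct = 1, ref_side = side_px)
      tex <- tex / stats::sd(tex)
      w <- (bump_envelope(side_px, c(truth$x[i], truth$y[i]), radius) + 1) / 2
      base <- base + patch_gain * background_gain * w * tex
    }
    img <- new_lum_image(base - min(base) + 1)
    if (normalize) img <- normalize_luminance(img)
    list(
      image = img,
      truth = truth,
      spec = list(side_px = side_px, patch_gain = patch_gain,
                  background_gain = background_gain, patch_cpi = patch_cpi,
                  patch_radius = radius, seed = seed, mirror = mirror)
    )
  })
}

#' Simulate between-subjects response logs
#'
#' Emulates the reference experiment's design: three observer groups, each
#' seeing face stimuli of one amplitude class (between-subjects), with a
#' per-observer true accuracy drawn from a Normal distribution clamped to
#' `[0, 100]` and trial outcomes drawn binomially. Incorrect trials respond
#' with a wrong label or "dont_know" with equal probability.
#'
#' The default `sigma = 18.6` was calibrated so that, together with the
#' binomial trial noise at 120 trials, the recovered partial eta squared has
#' median ~0.634 at the default group means -- see the methods vignette.
#'
#' @param group_means_pct named percent-correct means for the amplitude
#'   classes (default `c(min = 5, med = 35, max = 61)`).
#' @param sigma between-observer SD in percentage points.
#' @param n_per_group observers per class, same order as `group_means_pct`
#'   (default `c(13, 12, 13)`).
#' @param trials face trials per observer (default 120).
#' @param labels emotion label set (default neutral/happy).
#' @param seed RNG seed.
#' @return A tibble with one row per trial: `observer`, `class`, `kind`,
#'   `trial`, `truth`, `response`, plus the latent `true_accuracy_pct`.
#' @export
simulate_response_logs <- function(group_means_pct = c(min = 5, med = 35, max = 61),
                                   sigma = 18.6,
                                   n_per_group = c(13, 12, 13),
                                   trials = 120,
                                   labels = c("neutral", "happy"),
                                   seed = 1) {
  if (any(group_means_pct < 0 | group_means_pct > 100)) {
    stop("`group_means_pct` must lie in [0, 100]", call. = FALSE)
  }
  if (sigma < 0 || trials < 1 || any(n_per_group < 2)) {
    stop("invalid simulation parameters", call. = FALSE)
  }
  classes <- names(group_means_pct) %||% paste0("g", seq_along(group_means_pct))
  withr::with_seed(seed, {
    obs <- 0L
    logs <- purrr::map2(seq_along(classes), n_per_group, function(g, ng) {
      purrr::map(seq_len(ng), function(i) {
        obs <<- obs + 1L
        p <- min(max(stats::rnorm(1, group_means_pct[g], sigma), 0), 100) / 100
        truth <- sample(labels, trials, replace = TRUE)
        correct <- stats::rbinom(trials, 1, p) == 1
        response <- truth
        wrong <- which(!correct)
        response[wrong] <- vapply(truth[wrong], function(tr) {
          if (stats::runif(1) < 0.5) "dont_know" else sample(setdiff(labels, tr), 1)
        }, character(1))
        tibble::tibble(
          observer = sprintf("obs%02d", obs),
          class = classes[g], kind = "face",
          trial = seq_len(trials), truth = truth, response = response,
          true_accuracy_pct = 100 * p
        )
      })
    })
    dplyr::bind_rows(logs)
  })
}
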