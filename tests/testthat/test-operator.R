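# Most operator tests run on a 128-px canvas: the scale scheme is
# canvas-relative (f = 8, 16, 32, 64 cpi regardless of side), so nothing about
# the physics changes, only runtime.

test_that("the band-pass filter has unit peak gain, octave FWHM and no DC", {
  s <- 128
  x <- matrix(seq_len(s), s, s, byrow = TRUE)
  grating <- sin(2 * pi * 16 * (x - 1) / s)

  # constant image -> exactly zero
  expect_equal(max(abs(bandpass(matrix(7, s, s), 16))), 0)

  # on-peak sinusoid passes at gain 1 (integer cpi -> exact circular case)
  bp <- bandpass(grating, 16)
  expect_lt(abs(max(abs(bp)) / max(abs(grating)) - 1), 1e-9)

  # half an octave off-peak: half amplitude, quarter power (FWHM convention)
  bp_half <- bandpass(grating, 16 * sqrt(2))
  expect_lt(abs(mean(bp_half^2) / mean(grating^2) - 0.25), 0.025)

  # output is exactly zero-mean for arbitrary input
  arb <- random_image(s, seed = 8)$pixels
  expect_lt(abs(mean(bandpass(arb, 12.5))), 1e-9)

  expect_error(bandpass(grating, s / 2), "Nyquist")
  expect_error(bandpass(grating, 0), "Nyquist")
  expect_error(bandpass(grating, 16, bandwidth_oct = 0), "positive")
})

test_that("convolution maps equal direct disk/annulus sums at probe points", {
  s <- 128
  img <- quiet_texture(side_px = s, seed = 3)$image
  scale <- operator_scales(s)[2, ]
  d <- scale$d_px
  pad <- as.integer(ceiling(1.5 * d))
  P <- pad_reflect(as.matrix(img), pad)
  ctr <- center_energy_map(img, scale)
  sur <- surround_power_map(img, scale)
  e_center <- bandpass(P, scale$f_cpi, 1, ref_side = s)^2
  peaks <- 2 * 2^(0:(log2(s / 2 / 2) - 1))
  e_bands <- lapply(peaks, function(p) bandpass(P, p, 1, ref_side = s)^2)
  withr::with_seed(9, {
    probes <- cbind(sample(30:98, 10), sample(30:98, 10))
  })
  for (i in seq_len(nrow(probes))) {
    y <- probes[i, 1]; x <- probes[i, 2]
    r2 <- outer((seq_len(nrow(P)) - (y + pad))^2,
                (seq_len(ncol(P)) - (x + pad))^2, "+")
    disk <- r2 <= (d / 2)^2
    ann <- r2 > (d / 2)^2 & r2 <= (1.5 * d)^2
    expect_lt(abs(mean(e_center[disk]) - ctr[y, x]) / mean(e_center[disk]), 1e-6)
    direct_sur <- mean(vapply(e_bands, function(e) mean(e[ann]), numeric(1)))
    expect_lt(abs(direct_sur - sur[y, x]) / direct_sur, 1e-6)
  }
})

test_that("the amplitude map is energy-based and localizes planted envelopes", {
  s <- 128
  sc <- operator_scales(s)
  tex <- quiet_texture(side_px = s, carrier_cpi = 16, seed = 4,
                       envelope_center = c(51, 51), envelope_radius = s / 3)
  img <- tex$image
  m <- amplitude_map(img, sc[2, ])

  # contrast reversal leaves the map unchanged (energy is sign-blind)
  rev <- new_lum_image(2 * img$mean_luminance - img$pixels, normalized = TRUE)
  m_rev <- amplitude_map(rev, sc[2, ])
  expect_lt(max(abs(m$values - m_rev$values)), 1e-9 * max(abs(m$values)))

  # global maximum within d/4 of the planted envelope peak
  v <- m$values
  mrg <- m$valid_margin_px
  v[c(1:mrg, (s - mrg + 1):s), ] <- -Inf
  v[, c(1:mrg, (s - mrg + 1):s)] <- -Inf
  ij <- which(v == max(v), arr.ind = TRUE)[1, ]
  expect_lt(sqrt((ij[1] - 51)^2 + (ij[2] - 51)^2), sc$d_px[2] / 4)

  # peak response increases strictly with modulation depth (same carrier)
  peaks <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(dp) {
    im <- quiet_texture(side_px = s, carrier_cpi = 16, modulation_depth = dp,
                        seed = 4, envelope_center = c(51, 51),
                        envelope_radius = s / 3)$image
    mm <- amplitude_map(im, sc[2, ])
    idx <- (mrg + 1):(s - mrg)
    max(mm$values[idx, idx])
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("homogeneous octave-flat noise evokes near-zero response", {
  s <- 128
  sc <- operator_scales(s)[2, ]
  ratios <- vapply(1:4, function(seed) {
    un <- quiet_texture(side_px = s, carrier_kind = "broadband",
                        modulation_depth = 0, seed = seed)$image
    mo <- quiet_texture(side_px = s, carrier_kind = "broadband",
                        modulation_depth = 1, seed = seed)$image
    mu <- amplitude_map(un, sc); mm <- amplitude_map(mo, sc)
    idx <- (mu$valid_margin_px + 1):(s - mu$valid_margin_px)
    mean(abs(mu$values[idx, idx])) / max(mm$values[idx, idx])
  }, numeric(1))
  expect_lt(mean(ratios), 0.05)
})

test_that("maps are translation-equivariant away from borders", {
  s <- 128
  img <- quiet_texture(side_px = s, seed = 5)$image
  px <- as.matrix(img)
  shifted <- new_lum_image(px[c(9:s, 1:8), c(13:s, 1:12)], normalized = TRUE)
  sc <- operator_scales(s)[2, ]
  m1 <- amplitude_map(img, sc)$values
  m2 <- amplitude_map(shifted, sc)$values
  v <- 30:90
  expect_gt(stats::cor(as.vector(m1[v + 8, v + 12]), as.vector(m2[v, v])), 0.999)
})

test_that("multiscale maps are independent per scale and scale-invariant", {
  s <- 128
  img <- quiet_texture(side_px = s, seed = 3)$image
  # only three scales fit below Nyquist on a 128-px canvas
  sc <- operator_scales(s, 3)
  maps <- multiscale_maps(img, sc)
  expect_named(maps, paste0("k", 1:3))
  # permuting the scale order permutes the output
  perm <- multiscale_maps(img, sc[c(3, 1), ])
  expect_equal(perm$k3$values, maps$k3$values)
  expect_equal(perm$k1$values, maps$k1$values)

  # 2x downscaling with re-derived scales reproduces the per-scale maps
  small <- EBImage::imageData(EBImage::resize(as.matrix(img), w = s / 2, h = s / 2))
  img2 <- suppressWarnings(normalize_luminance(new_lum_image(small)))
  sc2 <- operator_scales(s / 2, 2)
  for (k in 2) {
    m1d <- EBImage::imageData(EBImage::resize(maps[[k]]$values, w = s / 2, h = s / 2))
    m2 <- amplitude_map(img2, sc2[k, ])$values
    mrg <- sc2$margin_px[k]
    idx <- (mrg + 1):(s / 2 - mrg)
    expect_gt(stats::cor(as.vector(m1d[idx, idx]), as.vector(m2[idx, idx])), 0.9)
  }
})

test_that("amplitude maps tidy to long tibbles and export to TIFF + JSON", {
  s <- 128
  img <- quiet_texture(side_px = s, seed = 3)$image
  m <- amplitude_map(img, operator_scales(s)[3, ])
  df <- tidy(m)
  expect_s3_class(df, "tbl_df")
  expect_equal(nrow(df), s^2)
  expect_equal(sum(df$valid), (s - 2 * m$valid_margin_px)^2)
  expect_equal(df$amplitude[df$x == 40 & df$y == 17], m$values[17, 40])
  td <- withr::local_tempdir()
  p <- file.path(td, "map.tif")
  write_amplitude_map(m, p)
  meta <- jsonlite::read_json(paste0(p, ".json"), simplifyVector = TRUE)
  expect_equal(meta$scale$d_px, 16)
  back <- tiff::readTIFF(p) * (meta$value_max - meta$value_min) + meta$value_min
  expect_lt(max(abs(back - m$values)), 1e-6 * diff(range(m$values)))
})
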