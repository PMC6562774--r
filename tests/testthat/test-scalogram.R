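fs <- 173.61

test_that("transform agrees with direct time-domain summation", {
  set.seed(21)
  x <- rnorm(96)
  scales <- morlet_scale_grid(6, c(4, 30))
  seg <- eeg_segment(x, fs = fs, segment_id = "oracle")
  res <- cwt(seg, scalogram_config(scales = scales))
  direct <- oracle_cwt_direct(x, fs, scales)
  expect_lt(max(Mod(res$coefficients - direct)), 1e-10)
})

test_that("transform is linear and zero maps to zero", {
  cfg <- scalogram_config(n_scales = 12)
  zero <- eeg_segment(numeric(128), fs = fs)
  expect_true(all(Mod(cwt(zero, cfg)$coefficients) == 0))

  set.seed(4)
  seg <- eeg_segment(rnorm(200), fs = fs)
  w1 <- cwt(seg, cfg)$coefficients
  w2 <- cwt(eeg_segment(2 * seg$samples, fs = fs), cfg)$coefficients
  expect_lt(max(Mod(w2 - 2 * w1)), 1e-10)
})

test_that("a pure sinusoid's ridge lands on the matching scale", {
  cfg <- scalogram_config()
  for (f0 in c(5, 10, 20)) {
    seg <- eeg_segment(sin(2 * pi * f0 * (0:1023) / fs), fs = fs)
    res <- cwt(seg, cfg)
    # average away from the borders to dodge edge effects
    mid <- 300:700
    ridge <- which.max(rowMeans(Mod(res$coefficients[, mid])))
    nearest <- which.min(abs(res$scales - morlet_scale(f0)))
    expect_lte(abs(ridge - nearest), 1)
  }
})

test_that("a shifted transient yields a correspondingly shifted ridge", {
  bump <- function(center) {
    tt <- (0:799) / fs
    exp(-((tt - center) / 0.05)^2) * sin(2 * pi * 10 * tt)
  }
  cfg <- scalogram_config(n_scales = 24)
  row <- function(center) {
    res <- cwt(eeg_segment(bump(center), fs = fs), cfg)
    k <- which.min(abs(res$scales - morlet_scale(10)))
    which.max(Mod(res$coefficients[k, ]))
  }
  shift_samples <- row(2.5) - row(1.5)
  expect_lt(abs(shift_samples - 1 * fs), 4)
})

test_that("edge-effect flag marks segments shorter than the widest wavelet", {
  short <- eeg_segment(rnorm(128), fs = fs)
  expect_true(cwt(short, scalogram_config())$edge_effect)
  long <- eeg_segment(rnorm(6000), fs = fs)
  expect_false(cwt(long, scalogram_config())$edge_effect)
})

test_that("scalogram modes compute energy and magnitude", {
  res <- structure(list(coefficients = matrix(c(3 + 4i, 0), 1)),
                   class = "cwt_result")
  expect_equal(to_scalogram(res, scalogram_config())[1, 1], 25)
  expect_equal(
    to_scalogram(res, scalogram_config(value_mode = "magnitude"))[1, 1], 5)
  expect_true(all(to_scalogram(res, scalogram_config()) >= 0))
})

test_that("rendering normalizes, resizes and stays within [0, 1]", {
  cfg <- scalogram_config()
  # identity case: already 32x32 -> min-max normalized input
  set.seed(11)
  m <- matrix(runif(32 * 32, 2, 7), 32, 32)
  img <- render_and_resize(m, cfg)
  expect_equal(img$pixels, (m - min(m)) / (max(m) - min(m)))
  expect_equal(min(img$pixels), 0)
  expect_equal(max(img$pixels), 1)

  # constant input maps to all-zeros by convention
  expect_true(all(render_and_resize(matrix(5, 40, 60), cfg)$pixels == 0))

  # full-size raster to 32x32
  big <- matrix(runif(662 * 536), 662, 536)
  out <- render_and_resize(big, cfg)
  expect_identical(dim(out$pixels), c(32L, 32L))
  expect_true(all(out$pixels >= 0 & out$pixels <= 1))

  expect_error(render_and_resize(matrix(c(1, NaN), 2, 2), cfg), "NaN")
})

test_that("the faithful render path matches direct resizing dimensions", {
  cfg <- scalogram_config(render_size = c(662, 536))
  m <- matrix(runif(64 * 200), 64, 200)
  out <- render_and_resize(m, cfg)
  expect_identical(dim(out$pixels), c(32L, 32L))
  expect_true(all(out$pixels >= 0 & out$pixels <= 1))
})

test_that("cubic resize interpolates exactly on constant and linear ramps", {
  # constant surface is reproduced exactly (kernel weights sum to 1)
  expect_equal(resize_matrix(matrix(3, 8, 8), c(5, 5)),
               matrix(3, 5, 5), tolerance = 1e-12)
  # the Keys kernel reproduces linear functions exactly away from edges
  ramp <- outer(seq(0, 1, length.out = 64), rep(1, 64))
  out <- resize_matrix(ramp, c(32, 32))
  inner <- out[4:29, 4:29]
  expected <- outer(( (4:29) - 0.5) * 2 + 0.5, rep(1, 26),
                    function(i, j) (i - 1) / 63)
  expect_equal(inner, expected, tolerance = 1e-10)
})

test_that("segment_to_input composes the pipeline deterministically", {
  seg <- generate_segment("A", synthesis_config(seed = 30), 1)
  img1 <- segment_to_input(seg)
  img2 <- segment_to_input(seg)
  expect_identical(img1$pixels, img2$pixels)
  expect_identical(dim(img1$pixels), c(32L, 32L))
  expect_identical(img1$class_label, "A")
  expect_identical(img1$source_id, seg$segment_id)
})

test_that("ictal images concentrate energy in the low-frequency rows", {
  ae <- fixture_ae_images(n_per_class = 20)
  labels <- vapply(ae$images, function(im) im$class_label, character(1))
  # rows run from high frequency (top) to low (bottom); find the image rows
  # whose pseudo-frequencies cover the 3-5 Hz discharge band
  freqs <- morlet_frequency(morlet_scale_grid(64))
  band_rows <- unique(pmax(1, pmin(32, round(which(freqs >= 3 & freqs <= 5) / 2))))
  band_energy <- function(im) mean(im$pixels[band_rows, ])
  e_energy <- mean(vapply(ae$images[labels == "E"], band_energy, numeric(1)))
  a_energy <- mean(vapply(ae$images[labels == "A"], band_energy, numeric(1)))
  expect_gt(e_energy, a_energy)
})

test_that("three-channel mode renders a colormapped 32x32x3 array", {
  m <- matrix(runif(64 * 80), 64, 80)
  img <- render_and_resize(m, scalogram_config(channels = 3))
  expect_identical(dim(img$pixels), c(32L, 32L, 3L))
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))
})

test_that("configuration validation rejects bad scales and sizes", {
  expect_error(scalogram_config(scales = c(2, 1, 3)), "increasing")
  expect_error(scalogram_config(scales = c(-1, 1)), "positive")
  expect_error(scalogram_config(input_size = c(4, 32)), ">= 8")
  expect_error(scalogram_config(channels = 2), "1 or 3")
})
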