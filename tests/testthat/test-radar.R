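test_that("frame duration follows chirp count and spacing", {
  expect_identical(round(frame_duration(radar_params())), 238)
  p1 <- radar_params(chirps_per_frame = 1L, T_i = 1e-3, T_d = 1e-9)
  expect_equal(frame_duration(p1), 1, tolerance = 1e-5)
  p2 <- radar_params(chirps_per_frame = 384L)
  expect_equal(frame_duration(p2), 2 * frame_duration(radar_params()))
})

test_that("range resolution identity res = c / (2 Bw)", {
  expect_equal(range_resolution(radar_params(bandwidth = 1e9)), 0.15,
               tolerance = 1e-3)
  expect_equal(range_resolution(radar_params()), 0.2998, tolerance = 1e-3)
  expect_equal(range_resolution(radar_params(bandwidth = 2e9)),
               range_resolution(radar_params(bandwidth = 1e9)) / 2)
})

test_that("ADC output is confined to the 10-bit range and is seeded", {
  fr <- synth_frames(gesture_profile("toward"), seed = 5)
  expect_true(all(fr$adc >= 0 & fr$adc <= 1023))
  expect_identical(dim(fr$adc), c(576L, 512L))
  fr2 <- synth_frames(gesture_profile("toward"), seed = 5)
  expect_identical(fr$adc, fr2$adc)
})

test_that("background scene has constant slow-time phase up to noise", {
  prof <- gesture_profile("background", noise_sd = 0)
  fr <- synth_frames(prof, seed = 1)
  x <- (fr$adc - 512) / 511
  rng <- t(apply(x, 1, stats::fft))[, 1:256]
  bin <- which.max(colSums(Mod(rng)^2))
  ph <- Arg(rng[, bin])
  expect_lt(stats::sd(ph), 1e-6)
})

test_that("constant radial velocity gives the closed-form Doppler phase step", {
  prof <- gesture_profile("toward", clutter_amplitude = 0, noise_sd = 0)
  prof$v <- function(t) rep(0.1, length(t))
  p <- radar_params()
  fr <- synth_frames(prof, p, seed = 1, n_frames = 1)
  x <- (fr$adc - 512) / 511
  rng <- t(apply(x, 1, stats::fft))[, 1:256]
  bin <- which.max(colSums(Mod(rng)^2))
  ph <- Arg(rng[, bin])
  dph <- diff(ph)
  dph <- atan2(sin(dph), cos(dph))  # wrap to (-pi, pi]
  # the range-FFT bin phase also drifts slightly with the moving beat
  # frequency, so allow 5% around the pure-Doppler closed form
  step <- 4 * pi * p$f0 * 0.1 * (p$T_i + p$T_d) / 299792458
  expect_equal(median(dph), step, tolerance = 0.05)
})

test_that("velocity beyond the unambiguous limit warns about aliasing", {
  prof <- gesture_profile("toward")
  prof$v <- function(t) rep(10, length(t))
  expect_warning(synth_frames(prof, seed = 1), "alias")
})

test_that("a pure slow-time tone peaks at the matching Doppler bin", {
  p <- radar_params()
  f_dopp <- 200
  pri <- p$T_i + p$T_d
  tau <- (0:511) / 512 * p$T_d
  f_b <- 2 * p$bandwidth * 2 / (299792458 * p$T_d)  # scatterer at 2 m
  t_k <- (0:575) * pri
  sig <- outer(2 * pi * f_dopp * t_k, 2 * pi * f_b * tau, `+`)
  adc <- matrix(as.integer(pmin(pmax(round(cos(sig) * 511) + 512, 0), 1023)),
                576, 512)
  md <- micro_doppler(adc, p)
  peak_freq <- apply(md$energy, 2, which.max)
  f_axis <- md$velocity * 2 * p$f0 / 299792458
  # oracle: full-length DFT of the analytic slow-time tone
  slow <- exp(2i * pi * f_dopp * t_k)
  dft_peak <- (which.max(Mod(stats::fft(slow))) - 1) / 576 / pri
  expect_lt(abs(median(f_axis[peak_freq]) - dft_peak), 1 / (64 * pri))
  expect_lt(abs(dft_peak - f_dopp), 1 / (576 * pri))
})

test_that("degenerate micro-Doppler inputs are rejected", {
  expect_error(micro_doppler(matrix(NaN, 64, 512), radar_params()),
               class = "eventsnn_config_error")
  expect_error(micro_doppler(matrix(512, 8, 512), radar_params()),
               class = "eventsnn_config_error")
})

test_that("binarization uses population moments and strict threshold", {
  # tile the 2x2 pattern [[0,10],[20,30]]: mu = 15, sigma = 11.18, Thr = 16.68
  m <- kronecker(matrix(c(0, 20, 10, 30), 2, 2), matrix(1, 8, 8))
  img <- binarize_and_downscale(m)
  expect_equal(attr(img, "mu"), 15)
  expect_equal(attr(img, "sigma"), sqrt(125), tolerance = 1e-9)
  expect_equal(attr(img, "threshold"), 15 + 0.15 * sqrt(125), tolerance = 1e-9)
  expect_identical(img[1:16, 1:16],
                   matrix(as.integer(kronecker(matrix(c(0, 1, 0, 1), 2, 2),
                                               matrix(1, 8, 8))), 16, 16))
})

test_that("constant maps binarize to all zero (nothing strictly above)", {
  expect_true(all(binarize_and_downscale(matrix(5, 32, 32)) == 0))
})

test_that("with s = 0 exactly the above-mean pixels survive", {
  m <- matrix(c(rep(0, 128), rep(10, 128)), 16, 16)
  img <- binarize_and_downscale(m, binarizer_params(s = 0))
  expect_identical(as.vector(img), as.integer(m > mean(m)))
})

test_that("adding a constant shifts the threshold, not the image", {
  set.seed(7)
  m <- matrix(rexp(64 * 33), 64, 33)
  a <- binarize_and_downscale(m)
  b <- binarize_and_downscale(m + 100)
  expect_identical(as.vector(a), as.vector(b))
  expect_equal(attr(b, "threshold") - attr(a, "threshold"), 100,
               tolerance = 1e-9)
})

test_that("gesture dataset is deterministic per seed with sane shapes", {
  ds1 <- synth_gesture_dataset(n_per_class = 2, seed = 11)
  ds2 <- synth_gesture_dataset(n_per_class = 2, seed = 11)
  expect_identical(ds1$images, ds2$images)
  expect_identical(dim(ds1$images), c(8L, 256L))
  expect_identical(ds1$labels, rep(0:3, each = 2))
  expect_true(all(ds1$images %in% 0:1))
  # different seeds draw different noise (the coarse binary images may
  # coincide; the raw frames cannot)
  f1 <- synth_frames(gesture_profile("hello"), seed = 11)
  f3 <- synth_frames(gesture_profile("hello"), seed = 12)
  expect_false(identical(f1$adc, f3$adc))
})
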