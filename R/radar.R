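# Synthetic FMCW radar front end: per-gesture beat signals of a moving point
# scatterer, micro-Doppler maps, dynamic-threshold binarization, 16x16 spike
# images.
#
# An FMCW radar emits linear chirps of duration T_d spaced T_i apart; after
# dechirping, a scatterer at range R produces a beat tone at
# f_b = 2 * B_w * R / (c * T_d), and its radial motion advances the
# phase between chirps by 4 * pi * f0 * v * (T_i + T_d) / c. The slow-time
# (chirp-to-chirp) phase history of the occupied range bin therefore carries
# the micro-Doppler signature of the motion.

C_LIGHT <- 299792458

#' FMCW radar acquisition parameters
#'
#' Defaults describe a low-resolution 8 GHz ultra-wideband sensor: 192
#' chirps per frame, 512 ADC samples per chirp, 10-bit ADC, inter-chirp
#' interval `T_i` = 1.2 ms, chirp duration `T_d` = 41 us (one frame = 238 ms
#' of recording), 500 MHz sweep bandwidth (range resolution
#' `c / (2 B_w)` = 30 cm).
#'
#' @param chirps_per_frame,samples_per_chirp,adc_bits acquisition geometry.
#' @param T_i inter-chirp interval (s). @param T_d chirp duration (s).
#' @param bandwidth sweep bandwidth `B_w` (Hz). @param f0 carrier (Hz).
#' @param n_frames_per_map frames combined into one micro-Doppler map.
#' @return A `radar_params` object.
#' @export
radar_params <- function(chirps_per_frame = 192L, samples_per_chirp = 512L,
                         adc_bits = 10L, T_i = 1.2e-3, T_d = 41e-6,
                         bandwidth = 500e6, f0 = 8e9, n_frames_per_map = 3L) {
  vals <- c(chirps_per_frame, samples_per_chirp, adc_bits, T_i, T_d,
            bandwidth, f0, n_frames_per_map)
  if (any(!is.finite(vals)) || any(vals <= 0))
    config_error("all radar parameters must be positive")
  structure(list(chirps_per_frame = as.integer(chirps_per_frame),
                 samples_per_chirp = as.integer(samples_per_chirp),
                 adc_bits = as.integer(adc_bits), T_i = T_i, T_d = T_d,
                 bandwidth = bandwidth, f0 = f0,
                 n_frames_per_map = as.integer(n_frames_per_map)),
            class = "radar_params")
}

#' Frame duration in milliseconds
#'
#' `chirps_per_frame * (T_i + T_d)`, in ms (238 ms at the defaults).
#'
#' @param params a [radar_params()].
#' @return duration in ms.
#' @export
frame_duration <- function(params = radar_params()) {
  params$chirps_per_frame * (params$T_i + params$T_d) * 1e3
}

#' Range resolution in meters: `c / (2 * B_w)`
#' @param params a [radar_params()].
#' @return resolution in m.
#' @export
range_resolution <- function(params = radar_params()) {
  C_LIGHT / (2 * params$bandwidth)
}

#' Largest unambiguous radial speed (m/s) at the chirp repetition interval
#' @param params a [radar_params()].
#' @return speed in m/s.
#' @export
unambiguous_velocity <- function(params = radar_params()) {
  prf <- 1 / (params$T_i + params$T_d)
  prf / 2 * C_LIGHT / (2 * params$f0)
}

#' Gesture motion profile
#'
#' A point scatterer with a class-specific radial-velocity trajectory:
#' `"hello"` — fast, small-amplitude oscillation of a waving hand;
#' `"toward"` — slow, large-amplitude approach/retreat of the hand;
#' `"horizontal"` — intermediate oscillation (arm swing, mostly tangential so
#' only a moderate radial component); `"background"` — no scatterer motion,
#' noise only.
#'
#' Every scene also contains a static clutter return at the resting range
#' (torso, walls): a strong zero-Doppler ridge that dominates the map's mean
#' and keeps the noise floor below the dynamic binarization threshold.
#'
#' @param class gesture label.
#' @param amplitude moving-scatterer echo amplitude relative to ADC full
#'   scale (0 disables the scatterer; forced to 0 for `"background"`).
#' @param clutter_amplitude static zero-Doppler return at `R0`.
#' @param noise_sd additive Gaussian noise, same scale.
#' @param R0 resting range of the subject (m).
#' @return A `gesture_profile` with a velocity function `v(t)` (m/s).
#' @export
gesture_profile <- function(class = c("hello", "toward", "horizontal",
                                      "background"),
                            amplitude = 0.5, clutter_amplitude = 0.3,
                            noise_sd = 0.02, R0 = 2) {
  class <- match.arg(class)
  v <- switch(class,
    hello = function(t) 0.6 * sin(2 * pi * 4 * t),
    toward = function(t) 2.0 * sin(2 * pi * 0.8 * t),
    horizontal = function(t) 1.1 * sin(2 * pi * 1.8 * t),
    background = function(t) rep(0, length(t)))
  if (class == "background") amplitude <- 0
  structure(list(class = class, v = v, amplitude = amplitude,
                 clutter_amplitude = clutter_amplitude,
                 noise_sd = noise_sd, R0 = R0),
            class = "gesture_profile")
}

#' Synthesize raw ADC frames for a gesture
#'
#' Generates the dechirped beat signal of the profile's point scatterer at
#' range `R(t) = R0 + integral of v`, with beat frequency
#' `2 * B_w * R / (c * T_d)` within each chirp and Doppler phase
#' `4 * pi * f0 * R / c` across chirps, adds Gaussian noise, and quantizes to
#' unsigned `adc_bits` integers. Deterministic per seed. A profile whose
#' velocity exceeds the unambiguous limit triggers an aliasing warning (not
#' an error).
#'
#' @param profile a [gesture_profile()].
#' @param params a [radar_params()].
#' @param seed RNG seed.
#' @param n_frames number of frames (defaults to `n_frames_per_map`).
#' @return A `radar_frames` object: integer matrix `adc` (chirps x samples,
#'   values in `[0, 2^adc_bits - 1]`) with the generation provenance.
#' @export
synth_frames <- function(profile, params = radar_params(), seed = 1L,
                         n_frames = params$n_frames_per_map) {
  stopifnot(inherits(profile, "gesture_profile"), inherits(params, "radar_params"))
  n_chirps <- n_frames * params$chirps_per_frame
  pri <- params$T_i + params$T_d
  t_chirp <- (seq_len(n_chirps) - 1L) * pri
  v <- profile$v(t_chirp)
  if (max(abs(v)) > unambiguous_velocity(params))
    warning("radial velocity exceeds the unambiguous Doppler limit; the signature will alias")
  R <- profile$R0 + cumsum(c(0, v[-length(v)])) * pri
  tau <- (seq_len(params$samples_per_chirp) - 1L) / params$samples_per_chirp *
    params$T_d
  f_b <- 2 * params$bandwidth * R / (C_LIGHT * params$T_d)
  phi <- 4 * pi * params$f0 * R / C_LIGHT
  f_b0 <- 2 * params$bandwidth * profile$R0 / (C_LIGHT * params$T_d)
  phi0 <- 4 * pi * params$f0 * profile$R0 / C_LIGHT
  with_preserved_seed(seed, {
    sig <- profile$amplitude *
      cos(outer(f_b, tau, function(f, x) 2 * pi * f * x) + phi)
    sig <- sig + profile$clutter_amplitude *
      matrix(cos(2 * pi * f_b0 * tau + phi0), nrow(sig), ncol(sig),
             byrow = TRUE)
    sig <- sig + matrix(stats::rnorm(length(sig), 0, profile$noise_sd),
                        nrow(sig), ncol(sig))
    half <- 2^(params$adc_bits - 1L)
    adc <- pmin(pmax(round(sig * (half - 1)) + half, 0), 2 * half - 1)
    structure(list(adc = matrix(as.integer(adc), n_chirps,
                                params$samples_per_chirp),
                   params = params, profile = profile, seed = as.integer(seed),
                   n_frames = as.integer(n_frames)),
              class = "radar_frames")
  })
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))

#' Compute a micro-Doppler map from raw frames
#'
#' Range FFT per chirp, selection of the range bin with maximal total
#' energy, then a short-time Fourier transform over the slow-time (complex)
#' sequence of that bin across the frame window: Hann window of
#' `window` chirps, 75% overlap at the default hop. The magnitude is linear
#' by default: the dynamic binarization threshold `mu + s*sigma` separates
#' signal from the noise bulk only when strong pixels dominate the map's
#' moments, which a dB compression destroys (`db = TRUE` is available for
#' visualization).
#'
#' @param frames a `radar_frames` object (or plain numeric chirps x samples
#'   matrix).
#' @param params a [radar_params()] (taken from `frames` when available).
#' @param window STFT window length in chirps.
#' @param hop hop between window starts in chirps.
#' @param db report `20*log10(|X| + eps)` instead of linear magnitude.
#' @return A `micro_doppler_map`: list with `energy` (velocity bins x
#'   slow-time bins, zero-Doppler centered), `velocity` axis (m/s), `time`
#'   axis (s), `range_bin`.
#' @export
micro_doppler <- function(frames, params = NULL, window = 64L, hop = 16L,
                          db = FALSE) {
  if (inherits(frames, "radar_frames")) {
    params <- frames$params
    adc <- frames$adc
  } else {
    adc <- frames
    if (is.null(params)) config_error("params required for a raw matrix")
  }
  if (!length(adc) || any(!is.finite(adc)))
    config_error("frames are empty or contain non-finite values")
  half <- 2^(params$adc_bits - 1L)
  x <- (adc - half) / (half - 1)
  rng <- t(apply(x, 1, stats::fft))[, seq_len(ncol(x) / 2), drop = FALSE]
  range_bin <- which.max(colSums(Mod(rng)^2))
  slow <- rng[, range_bin]
  n <- length(slow)
  if (n < window)
    config_error("need at least %d chirps for the STFT window", window)
  w <- hann_window(window)
  starts <- seq(1L, n - window + 1L, by = hop)
  spec <- vapply(starts, function(s) {
    X <- stats::fft(slow[s + seq_len(window) - 1L] * w)
    # center zero Doppler: negative frequencies first half up
    Mod(c(X[(window / 2 + 1L):window], X[seq_len(window / 2)]))
  }, numeric(window))
  if (db) spec <- 20 * log10(spec + 1e-12)
  prf <- 1 / (params$T_i + params$T_d)
  f_axis <- (seq_len(window) - 1L - window / 2) / window * prf
  structure(list(energy = spec,
                 velocity = f_axis * C_LIGHT / (2 * params$f0),
                 time = (starts - 1L + window / 2) / prf,
                 range_bin = range_bin, window = window, hop = hop, db = db,
                 params = params),
            class = "micro_doppler_map")
}

#' Binarization parameters for micro-Doppler maps
#'
#' The dynamic threshold is `Thr = mu + s * sigma`, with `mu` and `sigma`
#' the population mean and standard deviation (divide by n) over all map
#' pixels; `s` is a crude noise-filter hyper-parameter.
#'
#' @param s scale factor (>= 0).
#' @return A `binarizer_params` object.
#' @export
binarizer_params <- function(s = 0.15) {
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0)
    config_error("s must be a non-negative scalar")
  structure(list(s = s), class = "binarizer_params")
}

#' Threshold a micro-Doppler map and downscale to a 16x16 binary image
#'
#' Pixels strictly above `Thr = mu + s * sigma` are set to 1, the rest to 0;
#' the binary map is then partitioned into a 16x16 grid of blocks and an
#' output pixel is 1 iff any pixel of its block is 1 (OR pooling preserves
#' sparse spike semantics).
#'
#' @param map a `micro_doppler_map` or plain numeric matrix (at least
#'   16x16).
#' @param bin_params a [binarizer_params()].
#' @return 16x16 integer matrix of 0/1, with attributes `threshold`, `mu`,
#'   `sigma`.
#' @export
binarize_and_downscale <- function(map, bin_params = binarizer_params()) {
  m <- if (inherits(map, "micro_doppler_map")) map$energy else map
  if (!is.matrix(m) || !length(m)) config_error("map must be a nonempty matrix")
  if (nrow(m) < 16 || ncol(m) < 16)
    config_error("map must be at least 16x16 to downscale")
  mu <- mean(m)
  sigma <- sqrt(mean((m - mu)^2))
  thr <- mu + bin_params$s * sigma
  b <- m > thr
  rg <- split(seq_len(nrow(m)), cut(seq_len(nrow(m)), 16, labels = FALSE))
  cg <- split(seq_len(ncol(m)), cut(seq_len(ncol(m)), 16, labels = FALSE))
  out <- matrix(0L, 16, 16)
  for (i in 1:16) for (j in 1:16)
    out[i, j] <- as.integer(any(b[rg[[i]], cg[[j]]]))
  structure(out, threshold = thr, mu = mu, sigma = sigma)
}

#' Generate a synthetic 4-class gesture spike-image dataset
#'
#' Runs the full front end per sample — beat-signal synthesis, micro-Doppler
#' map, dynamic-threshold binarization, 16x16 OR-pooling — with a fresh
#' sub-seed per sample. Deterministic for a fixed seed.
#'
#' @param n_per_class samples per class.
#' @param params a [radar_params()].
#' @param seed master seed.
#' @param s binarization scale factor.
#' @param classes gesture classes to include.
#' @return List with `images` (n x 256 binary matrix, row-wise pixel order),
#'   `labels` (0-based, in the order of `classes`), `classes`.
#' @export
synth_gesture_dataset <- function(n_per_class = 40, params = radar_params(),
                                  seed = 1L, s = 0.15,
                                  classes = c("hello", "toward", "horizontal",
                                              "background")) {
  if (n_per_class < 1) config_error("n_per_class must be >= 1")
  n <- n_per_class * length(classes)
  images <- matrix(0L, n, 256)
  labels <- integer(n)
  k <- 0L
  bp <- binarizer_params(s)
  for (ci in seq_along(classes)) {
    prof <- gesture_profile(classes[ci])
    for (si in seq_len(n_per_class)) {
      k <- k + 1L
      sub_seed <- (seed * 10007L + ci * 1009L + si) %% .Machine$integer.max
      fr <- synth_frames(prof, params, seed = sub_seed)
      img <- binarize_and_downscale(micro_doppler(fr), bp)
      images[k, ] <- as.vector(t(img))
      labels[k] <- ci - 1L
    }
  }
  list(images = images, labels = labels, classes = classes)
}

#' End-to-end synthetic radar gesture classification demo
#'
#' Generates the synthetic gesture dataset, splits it per class into train
#' and test, trains the bias-free ReLU classifier, quantizes and converts it
#' to a spiking network, classifies the held-out samples on the event engine
#' with binary rate coding (0 Hz / 655 kHz) and ISI readout, and returns the
#' confusion matrix.
#'
#' @param seed master seed for data generation, training and conversion.
#' @param n_per_class samples per class.
#' @param train_frac per-class fraction used for training.
#' @param weight_bits quantization bit width.
#' @param epochs ANN training epochs.
#' @param duration_us presentation duration per sample.
#' @param params a [radar_params()].
#' @return List with `confusion` (rows = truth, cols = prediction, plus a
#'   `no_decision` column), `accuracy_pct`, `predicted`, `truth`, `model`,
#'   `network`.
#' @export
radar_demo <- function(seed = 1L, n_per_class = 40, train_frac = 0.75,
                       weight_bits = 4L, epochs = 300, duration_us = 5000,
                       params = radar_params()) {
  ds <- synth_gesture_dataset(n_per_class, params, seed = seed)
  split <- with_preserved_seed(seed, {
    test_idx <- integer(0)
    for (cl in unique(ds$labels)) {
      idx <- which(ds$labels == cl)
      n_test <- max(1L, round(length(idx) * (1 - train_frac)))
      test_idx <- c(test_idx, sample(idx, n_test))
    }
    test_idx
  })
  train <- list(images = ds$images[-split, , drop = FALSE] * 255,
                labels = ds$labels[-split])
  model <- train_toy_ann(train, epochs = epochs, seed = seed)
  qmodel <- quantize_weights(model, weight_bits)
  net <- network_from_ann(qmodel)
  res <- snn_classify(net, ds$images[split, , drop = FALSE],
                      binary_coder_params(duration_us = duration_us))
  truth <- ds$labels[split]
  cm <- confusion_matrix(truth, res$predicted, classes = ds$classes)
  list(confusion = cm, accuracy_pct = confusion_accuracy(cm),
       predicted = res$predicted, truth = truth, decisions = res$decisions,
       model = qmodel, network = net, test_idx = split)
}
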