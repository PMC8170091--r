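# Rate coding of images into spike trains and inter-spike-interval readout.

#' Rate coder parameters
#'
#' Pixel values are linearly mapped to firing frequencies:
#' `f = f_min + (f_max - f_min) * p / pixel_max`. The defaults are the
#' grayscale mapping `[0, 255] -> [100 kHz, 655 kHz]`; for binary images use
#' `binary_coder_params()`, which maps 0 -> 0 Hz and 1 -> 655 kHz.
#'
#' @param f_min,f_max frequency range in Hz (`0 <= f_min <= f_max`).
#' @param pixel_max largest pixel value (maps to `f_max`).
#' @param duration_us presentation duration in microseconds.
#' @param phase `"zero"` (spike k of a pixel at `k/f`, deterministic) or
#'   `"jitter"` (per-pixel uniform phase offset, seeded).
#' @param seed seed for `"jitter"` phases.
#' @return A `rate_coder_params` object.
#' @export
rate_coder_params <- function(f_min = 100e3, f_max = 655e3, pixel_max = 255,
                              duration_us = 5000, phase = c("zero", "jitter"),
                              seed = 1L) {
  phase <- match.arg(phase)
  if (f_min < 0 || f_max < f_min) config_error("need 0 <= f_min <= f_max")
  if (duration_us <= 0) config_error("duration_us must be positive")
  structure(list(f_min = f_min, f_max = f_max, pixel_max = pixel_max,
                 duration_us = duration_us, phase = phase,
                 seed = as.integer(seed)),
            class = "rate_coder_params")
}

#' @rdname rate_coder_params
#' @export
binary_coder_params <- function(f_max = 655e3, duration_us = 5000,
                                phase = "zero", seed = 1L) {
  rate_coder_params(f_min = 0, f_max = f_max, pixel_max = 1,
                    duration_us = duration_us, phase = phase, seed = seed)
}

#' Rate-encode an image into an AER spike stream
#'
#' Each pixel fires periodically at its mapped frequency. With zero phase,
#' spike k of a pixel falls at `t = k/f` (k = 1, 2, ...; no spike at t = 0,
#' so pixel value 0 / frequency 0 is the continuous no-spike limit). Each
#' spike time is rounded to integer nanoseconds independently, so the spike
#' count per pixel is exactly `floor(duration * f)`.
#'
#' @param image numeric vector (or matrix, flattened row-wise) of pixel
#'   values in `[0, pixel_max]`; entry i drives input address i - 1.
#' @param params a [rate_coder_params()].
#' @return Data frame `timestamp_ns`, `address`, sorted by time then address.
#' @examples
#' ev <- rate_encode(c(0, 255), rate_coder_params(duration_us = 100))
#' table(ev$address)  # pixel 0 at 100 kHz: 10 spikes; pixel 255: 65
#' @export
rate_encode <- function(image, params = rate_coder_params()) {
  stopifnot(inherits(params, "rate_coder_params"))
  if (is.matrix(image)) image <- as.vector(t(image))
  if (any(is.na(image)) || any(image < 0) || any(image > params$pixel_max))
    config_error("pixel values must lie in [0, %s]", params$pixel_max)
  f <- params$f_min + (params$f_max - params$f_min) * image / params$pixel_max
  dur_s <- params$duration_us * 1e-6
  n_k <- floor(dur_s * f + 1e-9)
  u <- rep(0, length(image))
  if (params$phase == "jitter")
    u <- with_preserved_seed(params$seed, stats::runif(length(image)))
  ts <- vector("list", length(image))
  for (i in seq_along(image)) {
    if (n_k[i] < 1) next
    k <- seq_len(n_k[i])
    ts[[i]] <- round((k - u[i]) / f[i] * 1e9)
  }
  ev <- data.frame(
    timestamp_ns = unlist(ts) %||% numeric(0),
    address = rep(seq_along(image) - 1L, vapply(ts, length, integer(1))))
  ev <- ev[order(ev$timestamp_ns, ev$address), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Decode output spike trains by shortest inter-spike interval
#'
#' The decision fires at the earliest instant any output neuron completes its
#' second spike; that neuron is the winner and its ISI (difference of its two
#' spike times) is reported. Ties at the identical nanosecond are broken by
#' the smaller neuron index. Spikes after the decision time cannot change the
#' outcome (the hardware protocol resets the network at that point).
#'
#' @param spikes AER data frame (`timestamp_ns`, `address`) of output-layer
#'   spikes, or an `snn_trace` (its last layer is used).
#' @param n_classes number of output neurons / classes.
#' @return An `isi_decision`: list with `winner` (0-based class index, or
#'   `NA` for no-decision), `isi_ns`, `decision_time_ns`, `reset` (logical:
#'   clear all accumulators now), `spike_times` (per class) and
#'   `n_spikes_total`.
#' @export
isi_decode <- function(spikes, n_classes) {
  if (inherits(spikes, "snn_trace")) spikes <- output_spikes(spikes)
  times <- lapply(seq_len(n_classes) - 1L, function(a)
    sort(spikes$timestamp_ns[spikes$address == a]))
  second <- vapply(times, function(tt) if (length(tt) >= 2) tt[2] else Inf,
                   numeric(1))
  out <- list(spike_times = times, n_spikes_total = nrow(spikes))
  if (all(is.infinite(second))) {
    out <- c(list(winner = NA_integer_, isi_ns = NA_real_,
                  decision_time_ns = NA_real_, reset = FALSE), out)
  } else {
    w <- which.min(second)  # which.min takes the first (smallest index) tie
    out <- c(list(winner = w - 1L,
                  isi_ns = times[[w]][2] - times[[w]][1],
                  decision_time_ns = second[w], reset = TRUE), out)
  }
  structure(out, class = "isi_decision")
}

#' @export
print.isi_decision <- function(x, ...) {
  if (is.na(x$winner))
    cat(sprintf("<isi_decision> no decision (%d output spikes)\n", x$n_spikes_total))
  else
    cat(sprintf("<isi_decision> class %d, ISI %.0f ns, decided at %.0f ns\n",
                x$winner, x$isi_ns, x$decision_time_ns))
  invisible(x)
}

#' Write classification decisions to CSV
#'
#' @param decisions list of `isi_decision` objects.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_decisions_csv <- function(decisions, path) {
  df <- data.frame(
    sample_id = seq_along(decisions) - 1L,
    winner = vapply(decisions, function(d) as.integer(d$winner), integer(1)),
    isi_ns = vapply(decisions, function(d) as.numeric(d$isi_ns), numeric(1)),
    decision_time_ns = vapply(decisions, function(d) as.numeric(d$decision_time_ns),
                              numeric(1)),
    n_spikes_total = vapply(decisions, function(d) d$n_spikes_total, numeric(1)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
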