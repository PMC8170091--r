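# Bit-exact integer integrate-and-fire neuron.
#
# The accumulator is a 7-bit register holding 0..63. Adding an incoming
# weight (times 8 when the layer's global scale is active) that reaches 64
# emits a spike and wraps the accumulator to the overflow residue rather than
# resetting it to zero; a negative sum clamps to zero without spiking. The
# wrap preserves sub-threshold charge exactly, which is what makes the mean
# firing rate a rectified-linear function of the mean input drive.

#' Neuron parameters
#'
#' @param scale_active if `TRUE` incoming weights are multiplied by
#'   `scale_factor` before accumulation (a per-layer hardware flag).
#' @param weight_bits weight bit width, used to validate incoming weights.
#' @param scale_factor weight multiplier when the scale is active (power of 2).
#' @return A `neuron_params` object with accumulator ceiling 63 and overflow
#'   threshold 64.
#' @export
neuron_params <- function(scale_active = FALSE, weight_bits = 4L,
                          scale_factor = 8L) {
  if (scale_factor < 1 || bitwAnd(as.integer(scale_factor),
                                  as.integer(scale_factor) - 1L) != 0L)
    config_error("scale_factor must be a power of two")
  structure(list(acc_max = 63L, threshold = 64L,
                 scale_factor = as.integer(scale_factor),
                 scale_active = isTRUE(scale_active),
                 w_max = weight_limit(weight_bits)),
            class = "neuron_params")
}

#' Fresh neuron state
#' @return A `neuron_state` with accumulator 0, no spikes recorded.
#' @export
neuron_state <- function() {
  structure(list(acc = 0L, spike_count = 0L, last_spike_times = numeric(0)),
            class = "neuron_state")
}

#' Deliver one weighted spike to a neuron
#'
#' Adds `weight` (times the scale factor if the scale is active) to the
#' accumulator. A sum `>= 64` fires and wraps (`acc <- sum - 64`); a negative
#' sum clamps to zero without firing. With effective contributions of
#' magnitude at most 56 the sum stays below 128, so a single subtraction
#' realizes the wrap.
#'
#' @param state a `neuron_state`.
#' @param weight integer synaptic weight within the representable range.
#' @param params a [neuron_params()].
#' @param t event timestamp (ns), recorded on firing.
#' @return List with `state` (updated) and `fired` (logical).
#' @examples
#' p <- neuron_params()
#' s <- neuron_state(); s$acc <- 60L
#' integrate_spike(s, 7L, p, t = 0)$state$acc  # wraps to 3
#' @export
integrate_spike <- function(state, weight, params, t = 0) {
  stopifnot(inherits(state, "neuron_state"), inherits(params, "neuron_params"))
  if (length(weight) != 1L || weight != round(weight) || abs(weight) > params$w_max)
    config_error("weight %s outside representable range [-%d, %d] (corrupt weight table?)",
                 weight, params$w_max, params$w_max)
  eff <- as.integer(weight) * (if (params$scale_active) params$scale_factor else 1L)
  s <- state$acc + eff
  fired <- FALSE
  if (s >= params$threshold) {
    fired <- TRUE
    state$acc <- s - params$threshold
    state$spike_count <- state$spike_count + 1L
    state$last_spike_times <- c(utils::tail(state$last_spike_times, 1L), t)
  } else if (s < 0L) {
    state$acc <- 0L
  } else {
    state$acc <- s
  }
  list(state = state, fired = fired)
}

#' Apply one leakage tick
#'
#' Leakage is an ordinary synapse with a negative weight driven by a clocked
#' input: a tick follows exactly the [integrate_spike()] contract. With no
#' ticks the neuron is a pure integrate-and-fire unit and holds its state
#' indefinitely.
#'
#' @param state a `neuron_state`.
#' @param leak_weight strictly negative integer weight.
#' @param params a [neuron_params()].
#' @param t tick timestamp.
#' @return The updated `neuron_state`.
#' @export
apply_leak_tick <- function(state, leak_weight, params = neuron_params(), t = 0) {
  if (length(leak_weight) != 1L || leak_weight >= 0)
    config_error("leak_weight must be strictly negative, got %s", leak_weight)
  integrate_spike(state, leak_weight, params, t)$state
}
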