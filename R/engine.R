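# Event-driven simulation: R surface over the compiled core.

#' Run an event-driven simulation
#'
#' Processes AER input events in timestamp order. Simultaneous spikes at a
#' layer are serialized by its arbiter; every granted spike fans out through
#' that layer's forward (and, for recurrent layers, lateral) weights, and
#' spikes emitted during delivery cascade — at the same timestamp but
#' strictly ordered after the triggering grant — into the next layer and back
#' into recurrent layers, until the network is quiescent. Arbitration and
#' propagation delays (ns scale, orders of magnitude below typical inter-spike
#' spacing) are modeled as zero-duration but strictly ordered.
#'
#' @param network a built `snn_network` with weights assigned.
#' @param events data frame with columns `timestamp_ns` (non-negative
#'   integers) and `address` (0-based input channel), or a path to an AER CSV
#'   (see [read_aer_csv()]). Presentation order of simultaneous events is
#'   irrelevant: the arbiter re-imposes order.
#' @param duration_ns simulate events with `timestamp_ns <= duration_ns`.
#' @param arbiter an [arbiter_spec()] shared by all layers.
#' @param max_cascade_events cap on spikes processed within one timestamp;
#'   exceeding it raises a runaway-recurrence error.
#' @return An `snn_trace`: list with `spikes` (data frame `timestamp_ns`,
#'   `layer` (1-based), `neuron` (0-based), in emission order), `acc` (list of
#'   final accumulator vectors), `lost` (per-layer arbiter capacity losses),
#'   `n_events_processed`, and the run configuration.
#' @examples
#' spec <- network_spec(1L, list(layer_spec(1L)), weight_bits = 4L)
#' net <- build_network(spec)
#' net <- set_layer_weights(net, 1, forward = matrix(7L, 1, 1))
#' net <- set_layer_scale(net, 1)
#' ev <- data.frame(timestamp_ns = (1:10) * 100000, address = 0L)
#' tr <- simulate_network(net, ev, duration_ns = 1e6)
#' nrow(tr$spikes)  # 8 spikes: 10 x 56 charge = 8 x 64 + 48
#' @export
simulate_network <- function(network, events, duration_ns,
                             arbiter = arbiter_spec(),
                             max_cascade_events = 1e6) {
  stopifnot(inherits(network, "snn_network"), inherits(arbiter, "arbiter_spec"))
  if (is.character(events)) events <- read_aer_csv(events)
  events <- validate_events(events, network$spec$n_inputs)
  check_overflow_headroom(network)
  layers <- lapply(network$layers, function(l) {
    list(n_in = l$n_in, n = l$n, scale = l$scale_active,
         forward = l$forward_w, lateral = l$lateral_w)
  })
  res <- cpp_run_sim(layers, as.numeric(events$timestamp_ns),
                     as.integer(events$address), as.numeric(duration_ns),
                     arbiter$H, arbiter$polling == "round_robin",
                     max_cascade_events)
  if (isTRUE(res$runaway))
    runtime_error("runaway recurrence: more than %g events in cascade at t = %g ns",
                  max_cascade_events, res$runaway_t)
  structure(list(
    spikes = data.frame(timestamp_ns = res$spike_t, layer = res$spike_layer,
                        neuron = res$spike_neuron),
    acc = res$acc, lost = res$lost,
    n_events_processed = res$n_processed,
    duration_ns = duration_ns, arbiter = arbiter,
    n_layers = length(network$layers)), class = "snn_trace")
}

validate_events <- function(events, n_inputs) {
  if (!all(c("timestamp_ns", "address") %in% names(events)))
    config_error("events need columns timestamp_ns and address")
  if (nrow(events)) {
    if (any(events$timestamp_ns < 0) ||
        any(events$timestamp_ns != round(events$timestamp_ns)))
      config_error("timestamps must be non-negative integer nanoseconds")
    if (any(events$address < 0) || any(events$address >= n_inputs))
      config_error("input addresses must lie in [0, %d)", n_inputs)
  }
  events
}

# A single delivery adds acc (<= 63) + effective weight; flag configurations
# whose sum could reach 128, where a single-subtraction wrap is no longer
# guaranteed by the hardware description.
check_overflow_headroom <- function(network) {
  for (l in network$layers) {
    mul <- if (l$scale_active) 8L else 1L
    wmax <- max(abs(l$forward_w), if (!is.null(l$lateral_w)) abs(l$lateral_w) else 0L)
    if (63L + wmax * mul >= 128L)
      warning(sprintf(
        "layer effective weight %d can push a full accumulator to >= 128; wrap behavior beyond one subtraction is undefined on hardware",
        wmax * mul))
  }
  invisible(network)
}

#' Output spikes of a trace as an AER event list
#'
#' @param trace an `snn_trace`.
#' @param layer layer index (defaults to the last layer).
#' @return Data frame `timestamp_ns`, `address` (0-based neuron index).
#' @export
output_spikes <- function(trace, layer = trace$n_layers) {
  sp <- trace$spikes[trace$spikes$layer == layer, , drop = FALSE]
  data.frame(timestamp_ns = sp$timestamp_ns, address = sp$neuron)
}

#' @export
print.snn_trace <- function(x, ...) {
  cat(sprintf("<snn_trace> %d spikes over %d layers, %.0f events processed\n",
              nrow(x$spikes), x$n_layers, x$n_events_processed))
  for (l in seq_len(x$n_layers))
    cat(sprintf("  layer %d: %d spikes, %d lost at arbiter\n", l,
                sum(x$spikes$layer == l), x$lost[l]))
  invisible(x)
}

#' Read / write AER event streams
#'
#' CSV with header `timestamp_ns,address`; timestamps are integer
#' nanoseconds, addresses 0-based.
#'
#' @param path file path.
#' @return `read_aer_csv`: data frame with those columns.
#' @export
read_aer_csv <- function(path) {
  ev <- utils::read.csv(path)
  if (!all(c("timestamp_ns", "address") %in% names(ev)))
    config_error("%s is not an AER CSV (need timestamp_ns,address header)", path)
  ev
}

#' @rdname read_aer_csv
#' @param events data frame with columns `timestamp_ns`, `address`.
#' @export
write_aer_csv <- function(events, path) {
  utils::write.csv(events[c("timestamp_ns", "address")], path, row.names = FALSE)
  invisible(path)
}

#' Export a trace: per-layer spike CSVs plus a JSON summary
#'
#' @param trace an `snn_trace`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_trace <- function(trace, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (l in seq_len(trace$n_layers)) {
    sp <- trace$spikes[trace$spikes$layer == l, c("timestamp_ns", "neuron")]
    utils::write.csv(sp, file.path(dir, sprintf("spikes_layer%d.csv", l)),
                     row.names = FALSE)
  }
  summary <- list(
    n_spikes_per_layer = as.integer(table(factor(trace$spikes$layer,
                                                 levels = seq_len(trace$n_layers)))),
    lost_per_layer = trace$lost,
    n_events_processed = trace$n_events_processed,
    duration_ns = trace$duration_ns,
    arbiter = unclass(trace$arbiter),
    final_acc = trace$acc)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
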