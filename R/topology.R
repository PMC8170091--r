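# Synthesis-time network structure: layers, connectivity masks, weight storage.
#
# Connectivity is fixed at build time (as it would be at hardware synthesis);
# only the weight values are mutable afterwards. A layer's fan-in address
# space is [0, n_in) for forward sources followed by [n_in, n_in + n) for
# lateral (recurrent) sources.

#' Describe one neuron layer
#'
#' @param n_neurons number of neurons in the layer (>= 1).
#' @param kind `"fc"` (feed-forward fully connectable) or `"recurrent_fc"`
#'   (additionally supports lateral synapses within the layer).
#' @param has_bias if `TRUE`, every neuron gets one extra bias synapse
#'   (a dedicated register, driven by a clocked bias/leak input).
#' @param forward_density fraction of forward candidate synapses kept when
#'   building in density mode, in `[0, 1]`.
#' @param lateral_density fraction of lateral candidate synapses kept
#'   (recurrent layers only; must be 0 for `"fc"`).
#' @return A `layer_spec` object.
#' @seealso [network_spec()], [build_network()]
#' @export
layer_spec <- function(n_neurons, kind = c("fc", "recurrent_fc"),
                       has_bias = FALSE, forward_density = 1,
                       lateral_density = 0) {
  kind <- match.arg(kind)
  if (!is_count(n_neurons) || n_neurons < 1)
    config_error("n_neurons must be a positive integer, got %s", n_neurons)
  for (d in c(forward_density, lateral_density))
    if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0 || d > 1)
      config_error("densities must lie in [0, 1]")
  if (kind == "fc" && lateral_density != 0)
    config_error("fc layers must have lateral_density = 0")
  structure(list(n_neurons = as.integer(n_neurons), kind = kind,
                 has_bias = isTRUE(has_bias),
                 forward_density = forward_density,
                 lateral_density = lateral_density),
            class = "layer_spec")
}

#' Describe a full network
#'
#' @param n_inputs number of external input channels (M).
#' @param layers list of [layer_spec()] objects, in order.
#' @param weight_bits synaptic weight bit width W (>= 2); weights are signed
#'   integers in `[-(2^(W-1)-1), 2^(W-1)-1]`.
#' @param seed integer seed controlling connectivity sampling.
#' @param exact_synapse_counts optional integer vector (one entry per layer,
#'   `NA` to fall back to density mode) giving the exact number of synapses
#'   to sample uniformly without replacement from the layer's candidate set
#'   (forward plus lateral); bias registers are not part of the candidate set.
#' @return A `network_spec` object.
#' @export
network_spec <- function(n_inputs, layers, weight_bits = 4L, seed = 1L,
                         exact_synapse_counts = NULL) {
  if (!is_count(n_inputs) || n_inputs < 1)
    config_error("n_inputs must be a positive integer")
  if (!length(layers) || !all(vapply(layers, inherits, TRUE, "layer_spec")))
    config_error("layers must be a non-empty list of layer_spec objects")
  if (!is_count(weight_bits) || weight_bits < 2)
    config_error("weight_bits must be an integer >= 2")
  if (!is.null(exact_synapse_counts) &&
      length(exact_synapse_counts) != length(layers))
    config_error("exact_synapse_counts must have one entry per layer")
  structure(list(n_inputs = as.integer(n_inputs), layers = layers,
                 weight_bits = as.integer(weight_bits),
                 seed = as.integer(seed),
                 exact_synapse_counts = exact_synapse_counts),
            class = "network_spec")
}

#' Maximum representable weight magnitude for a bit width
#' @param weight_bits bit width W.
#' @return `2^(W-1) - 1`.
#' @export
weight_limit <- function(weight_bits) as.integer(2^(weight_bits - 1) - 1)

#' Build a network: sample connectivity masks, zero-initialize weights
#'
#' Connectivity is sampled deterministically from `spec$seed`. In exact-count
#' mode (per-layer entry of `spec$exact_synapse_counts` not `NA`) exactly that
#' many synapses are drawn uniformly without replacement from the layer's
#' combined forward + lateral candidate pool; otherwise each candidate synapse
#' is kept independently with its layer's density.
#'
#' @param spec a [network_spec()].
#' @return An `snn_network` object holding per-layer masks and an all-zero
#'   weight table.
#' @examples
#' net <- build_network(prototype_spec())
#' count_weight_registers(net)$total
#' @export
build_network <- function(spec) {
  if (!inherits(spec, "network_spec")) config_error("spec must be a network_spec")
  with_preserved_seed(spec$seed, {
    n_in <- spec$n_inputs
    layers <- vector("list", length(spec$layers))
    for (i in seq_along(spec$layers)) {
      ls <- spec$layers[[i]]
      n <- ls$n_neurons
      recurrent <- ls$kind == "recurrent_fc"
      n_fwd <- n_in * n
      n_lat <- if (recurrent) n * n else 0L
      exact <- spec$exact_synapse_counts[[i]] %||% NA
      if (!is.na(exact)) {
        if (!is_count(exact) || exact > n_fwd + n_lat)
          config_error("layer %d: exact count %s exceeds %d candidate synapses",
                       i, exact, n_fwd + n_lat)
        keep <- logical(n_fwd + n_lat)
        keep[sample.int(n_fwd + n_lat, exact)] <- TRUE
      } else {
        keep <- c(stats::runif(n_fwd) < ls$forward_density,
                  if (n_lat) stats::runif(n_lat) < ls$lateral_density)
      }
      fwd_mask <- matrix(keep[seq_len(n_fwd)], n_in, n)
      lat_mask <- if (recurrent) matrix(keep[n_fwd + seq_len(n_lat)], n, n) else NULL
      layers[[i]] <- list(
        n_in = n_in, n = n, kind = ls$kind, has_bias = ls$has_bias,
        scale_active = FALSE,
        forward_mask = fwd_mask,
        lateral_mask = lat_mask,
        forward_w = matrix(0L, n_in, n),
        lateral_w = if (recurrent) matrix(0L, n, n) else NULL,
        bias_w = if (ls$has_bias) integer(n) else NULL)
      n_in <- n
    }
    structure(list(spec = spec, layers = layers,
                   weight_bits = spec$weight_bits,
                   w_max = weight_limit(spec$weight_bits)),
              class = "snn_network")
  })
}

#' Count weight registers (synapses) per layer and in total
#'
#' A weight register exists for every sampled synapse plus one bias register
#' per neuron in layers with bias, whether or not its value is zero.
#'
#' @param network a built `snn_network`.
#' @return List with `per_layer` (integer vector) and `total`.
#' @export
count_weight_registers <- function(network) {
  stopifnot(inherits(network, "snn_network"))
  per <- vapply(network$layers, function(l) {
    sum(l$forward_mask) + (if (is.null(l$lateral_mask)) 0L else sum(l$lateral_mask)) +
      (if (l$has_bias) l$n else 0L)
  }, numeric(1))
  list(per_layer = as.integer(per), total = as.integer(sum(per)))
}

#' Total distributed weight-memory bits
#'
#' @param network a built `snn_network`.
#' @return Synapse count times weight bit width.
#' @export
memory_bits <- function(network) {
  count_weight_registers(network)$total * network$weight_bits
}

#' Number of neurons in a built network
#' @param network a built `snn_network`.
#' @return total neuron count across layers.
#' @export
n_neurons <- function(network) {
  sum(vapply(network$layers, `[[`, integer(1), "n"))
}

#' The 336-neuron hardware prototype profile
#'
#' A recurrent layer of 256 neurons with exactly 19,878 synapses sampled from
#' its combined forward + lateral candidate pool, followed by fully connected
#' layers of 64 and 16 neurons with one bias register per FC neuron; 4-bit
#' weights (values -7..+7).
#'
#' @param seed connectivity sampling seed.
#' @return A `network_spec`.
#' @export
prototype_spec <- function(seed = 1L) {
  network_spec(
    n_inputs = 256L,
    layers = list(
      layer_spec(256L, "recurrent_fc"),
      layer_spec(64L, "fc", has_bias = TRUE),
      layer_spec(16L, "fc", has_bias = TRUE)),
    weight_bits = 4L, seed = seed,
    exact_synapse_counts = c(19878L, NA, NA))
}

#' Set weight values for one layer
#'
#' Weights may only be placed where the connectivity mask has a synapse and
#' must lie within the representable range for the network's bit width.
#'
#' @param network a built `snn_network`.
#' @param layer 1-based layer index.
#' @param forward,lateral integer matrices (source x target), or `NULL` to
#'   leave unchanged. Entries off the connectivity mask must be zero.
#' @param bias integer vector of per-neuron bias weights, or `NULL`.
#' @return The updated network.
#' @export
set_layer_weights <- function(network, layer, forward = NULL, lateral = NULL,
                              bias = NULL) {
  stopifnot(inherits(network, "snn_network"))
  l <- network$layers[[layer]]
  wmax <- network$w_max
  check <- function(w, mask, what) {
    if (any(w != round(w)) || any(abs(w) > wmax))
      config_error("%s weights must be integers in [-%d, %d]", what, wmax, wmax)
    if (!is.null(mask) && any(w[!mask] != 0))
      config_error("%s weights present where the %s mask has no synapse", what, what)
  }
  if (!is.null(forward)) {
    stopifnot(all(dim(forward) == dim(l$forward_w)))
    check(forward, l$forward_mask, "forward")
    l$forward_w <- matrix(as.integer(forward), nrow(forward), ncol(forward))
  }
  if (!is.null(lateral)) {
    if (is.null(l$lateral_w)) config_error("layer %d has no lateral synapses", layer)
    check(lateral, l$lateral_mask, "lateral")
    l$lateral_w <- matrix(as.integer(lateral), nrow(lateral), ncol(lateral))
  }
  if (!is.null(bias)) {
    if (is.null(l$bias_w)) config_error("layer %d has no bias registers", layer)
    check(bias, NULL, "bias")
    l$bias_w <- as.integer(bias)
  }
  network$layers[[layer]] <- l
  network
}

#' Activate or deactivate a layer's global weight scale
#'
#' When active, every synaptic weight of the layer is multiplied by 8 before
#' accumulation, which makes a fresh neuron fire after 8 rather than 64 units
#' of drive (an effective threshold of 8).
#'
#' @param network a built `snn_network`.
#' @param layer 1-based layer index (or vector of indices).
#' @param active logical flag.
#' @return The updated network.
#' @export
set_layer_scale <- function(network, layer, active = TRUE) {
  stopifnot(inherits(network, "snn_network"))
  for (i in layer) network$layers[[i]]$scale_active <- isTRUE(active)
  network
}

#' @export
print.snn_network <- function(x, ...) {
  cnt <- count_weight_registers(x)
  cat(sprintf("<snn_network> %d inputs, %d layers, %d neurons\n",
              x$spec$n_inputs, length(x$layers), n_neurons(x)))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    cat(sprintf("  layer %d: %s %d -> %d, %d registers%s%s\n", i, l$kind,
                l$n_in, l$n, cnt$per_layer[i],
                if (l$has_bias) ", bias" else "",
                if (l$scale_active) ", scale x8" else ""))
  }
  cat(sprintf("  weights: %d bit (range [-%d, %d]), %d registers, %d memory bits\n",
              x$weight_bits, x$w_max, x$w_max, cnt$total, memory_bits(x)))
  invisible(x)
}
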