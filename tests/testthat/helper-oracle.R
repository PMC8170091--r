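# Reference simulators used as independent oracles.
#
# oracle_simulate() is a clock-driven reference: it walks nanosecond ticks in
# increasing order (skipping ticks at which provably nothing can happen — the
# state only changes when an event exists) and, at each tick, serializes
# pending spikes layer by layer with the R-level arbiter and plain integer
# arithmetic. It shares no code with the compiled event engine.

oracle_simulate <- function(network, events, duration_ns,
                            arb = arbiter_spec()) {
  L <- length(network$layers)
  acc <- lapply(network$layers, function(l) integer(l$n))
  last_grant <- rep(-1L, L)
  spikes <- list()
  events <- events[events$timestamp_ns <= duration_ns, , drop = FALSE]
  ticks <- sort(unique(events$timestamp_ns))
  for (t in ticks) {
    pending <- rep(list(integer(0)), L)
    pending[[1]] <- events$address[events$timestamp_ns == t]
    repeat {
      busy <- which(vapply(pending, length, integer(1)) > 0)
      if (!length(busy)) break
      for (l in seq_len(L)) {
        if (!length(pending[[l]])) next
        batch <- pending[[l]]
        pending[[l]] <- integer(0)
        ar <- arbitrate(batch, arb, last_grant[l])
        last_grant[l] <- ar$last_grant %||% -1L
        ly <- network$layers[[l]]
        mul <- if (ly$scale_active) 8L else 1L
        for (src in ar$order) {
          w <- if (src < ly$n_in) ly$forward_w[src + 1L, ]
               else ly$lateral_w[src - ly$n_in + 1L, ]
          for (j in seq_len(ly$n)) {
            if (w[j] == 0L) next
            s <- acc[[l]][j] + w[j] * mul
            if (s >= 64L) {
              acc[[l]][j] <- s - 64L
              spikes[[length(spikes) + 1L]] <- c(t, l, j - 1L)
              if (!is.null(ly$lateral_w))
                pending[[l]] <- c(pending[[l]], ly$n_in + j - 1L)
              if (l < L) pending[[l + 1L]] <- c(pending[[l + 1L]], j - 1L)
            } else if (s < 0L) {
              acc[[l]][j] <- 0L
            } else {
              acc[[l]][j] <- s
            }
          }
        }
      }
    }
  }
  sp <- if (length(spikes)) as.data.frame(do.call(rbind, spikes))
        else data.frame(V1 = numeric(0), V2 = numeric(0), V3 = numeric(0))
  names(sp) <- c("timestamp_ns", "layer", "neuron")
  list(spikes = sp, acc = acc)
}

# Per-event brute-force single-neuron oracle: replays a weight sequence with
# the closed-form floor/mod bookkeeping.
oracle_neuron_counts <- function(acc0, effective_weights) {
  acc <- acc0
  fired <- 0L
  for (e in effective_weights) {
    s <- acc + e
    if (s >= 64) {
      fired <- fired + 1L
      acc <- s - 64
    } else if (s < 0) {
      acc <- 0
    } else {
      acc <- s
    }
  }
  list(fired = fired, acc = acc)
}

# Random small network + periodic input events for equivalence testing.
# Lateral weights are kept weak enough (per-source outgoing positive sum
# below the threshold 64) that recurrent cascades always terminate.
random_small_case <- function(seed) {
  set.seed(seed)
  n_in <- sample(1:6, 1)
  n_layers <- sample(1:3, 1)
  sizes <- sample(2:8, n_layers, replace = TRUE)
  recurrent <- c(runif(1) < 0.5, rep(FALSE, n_layers - 1))
  layers <- lapply(seq_len(n_layers), function(i)
    layer_spec(sizes[i], if (recurrent[i]) "recurrent_fc" else "fc",
               forward_density = runif(1, 0.4, 1),
               lateral_density = if (recurrent[i]) runif(1, 0.1, 0.3) else 0))
  net <- build_network(network_spec(n_in, layers, weight_bits = 4L,
                                    seed = seed))
  for (i in seq_len(n_layers)) {
    l <- net$layers[[i]]
    fw <- matrix(sample(-7:7, l$n_in * l$n, replace = TRUE), l$n_in, l$n)
    fw[!l$forward_mask] <- 0L
    lw <- NULL
    if (!is.null(l$lateral_mask)) {
      lw <- matrix(sample(-3:3, l$n * l$n, replace = TRUE), l$n, l$n)
      lw[!l$lateral_mask] <- 0L
      over <- rowSums(pmax(lw, 0)) >= 64
      lw[over, ] <- 0L
    }
    net <- set_layer_weights(net, i, forward = fw, lateral = lw)
  }
  n_ev <- sample(10:40, 1)
  ev <- data.frame(
    timestamp_ns = sample(seq(0, 5000, by = 250), n_ev, replace = TRUE),
    address = sample(seq_len(n_in) - 1L, n_ev, replace = TRUE))
  list(net = net, events = ev, duration_ns = 6000)
}

# Canonical form for comparing spike multisets.
spike_key <- function(sp) {
  sort(paste(sp$timestamp_ns, sp$layer, sp$neuron, sep = "/"))
}
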