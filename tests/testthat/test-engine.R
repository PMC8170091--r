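test_that("linear polling grants in ascending address order", {
  expect_identical(arbitrate(c(7L, 2L, 5L))$order, c(2L, 5L, 7L))
  expect_identical(arbitrate(3L)$order, 3L)
})

test_that("round-robin wraps past the last granted address", {
  r <- arbitrate(c(1L, 3L), arbiter_spec(polling = "round_robin"),
                 last_grant = 2L)
  expect_identical(r$order, c(3L, 1L))
  expect_identical(r$last_grant, 1L)
})

test_that("edge-detector capacity drops duplicates beyond H-1, counted", {
  r <- arbitrate(c(4L, 4L, 4L, 1L), arbiter_spec(H = 2L))
  expect_identical(r$order, c(1L, 4L))
  expect_identical(r$lost, 2L)
  r3 <- arbitrate(c(4L, 4L, 4L, 1L), arbiter_spec(H = 3L))
  expect_identical(r3$order, c(1L, 4L, 4L))
  expect_identical(r3$lost, 1L)
})

single_neuron_net <- function(weight, scale = FALSE) {
  net <- build_network(network_spec(1L, list(layer_spec(1L))))
  net <- set_layer_weights(net, 1, forward = matrix(as.integer(weight), 1, 1))
  if (scale) net <- set_layer_scale(net, 1) else net
}

test_that("periodic drive: 10 scaled +7 spikes give 8 outputs, residue 48", {
  net <- single_neuron_net(7L, scale = TRUE)
  ev <- data.frame(timestamp_ns = (1:10) * 100000, address = 0L)
  tr <- simulate_network(net, ev, duration_ns = 1e6)
  expect_identical(nrow(tr$spikes), 8L)
  expect_identical(tr$acc[[1]], 48L)  # 560 = 8*64 + 48
})

test_that("no input events: empty trace, accumulators untouched", {
  net <- single_neuron_net(7L)
  tr <- simulate_network(net, data.frame(timestamp_ns = numeric(0),
                                         address = integer(0)), 1e6)
  expect_identical(nrow(tr$spikes), 0L)
  expect_identical(tr$acc[[1]], 0L)
})

test_that("all-zero downstream weights keep the second layer silent", {
  net <- build_network(network_spec(1L, list(layer_spec(2L), layer_spec(2L))))
  net <- set_layer_weights(net, 1, forward = matrix(7L, 1, 2))
  ev <- data.frame(timestamp_ns = (1:50) * 1000, address = 0L)
  tr <- simulate_network(net, ev, 1e6)
  expect_gt(sum(tr$spikes$layer == 1), 0)
  expect_identical(sum(tr$spikes$layer == 2), 0L)
})

test_that("presentation order of simultaneous events does not alter the trace", {
  for (seed in 1:10) {
    case <- random_small_case(seed)
    tr1 <- simulate_network(case$net, case$events, case$duration_ns)
    set.seed(seed + 1000)
    shuffled <- case$events[sample(nrow(case$events)), ]
    tr2 <- simulate_network(case$net, shuffled, case$duration_ns)
    expect_identical(tr1$spikes, tr2$spikes)
    expect_identical(tr1$acc, tr2$acc)
  }
})

test_that("event-driven trace equals the clock-driven reference (spot check)", {
  for (seed in 1:40) {
    case <- random_small_case(seed)
    tr <- simulate_network(case$net, case$events, case$duration_ns)
    or <- oracle_simulate(case$net, case$events, case$duration_ns)
    expect_identical(spike_key(tr$spikes), spike_key(or$spikes))
    expect_identical(lapply(tr$acc, as.integer), or$acc)
  }
})

test_that("round-robin polling also matches the reference", {
  arb <- arbiter_spec(polling = "round_robin")
  for (seed in 101:115) {
    case <- random_small_case(seed)
    tr <- simulate_network(case$net, case$events, case$duration_ns, arbiter = arb)
    or <- oracle_simulate(case$net, case$events, case$duration_ns, arb = arb)
    expect_identical(spike_key(tr$spikes), spike_key(or$spikes))
    expect_identical(lapply(tr$acc, as.integer), or$acc)
  }
})

test_that("feed-forward charge conservation holds without underflow", {
  # positive weights only, so the clamp can never fire
  net <- build_network(network_spec(3L, list(layer_spec(4L))))
  set.seed(42)
  fw <- matrix(sample(0:7, 12, replace = TRUE), 3, 4)
  net <- set_layer_weights(net, 1, forward = fw)
  ev <- data.frame(timestamp_ns = rep((1:100) * 1000, each = 3),
                   address = rep(0:2, 100))
  tr <- simulate_network(net, ev, 2e5)
  for (j in 1:4) {
    emitted <- sum(tr$spikes$layer == 1 & tr$spikes$neuron == j - 1)
    charge <- sum(fw[, j]) * 100
    expect_identical(64 * emitted + tr$acc[[1]][j], charge)
  }
})

test_that("explosive recurrence triggers the runaway-cascade error", {
  net <- build_network(network_spec(
    8L, list(layer_spec(8L, "recurrent_fc", forward_density = 1,
                        lateral_density = 1))))
  net <- set_layer_weights(net, 1, forward = matrix(7L, 8, 8),
                           lateral = matrix(7L, 8, 8))
  net <- set_layer_scale(net, 1)
  ev <- data.frame(timestamp_ns = rep(1000, 8), address = 0:7)
  expect_error(
    suppressWarnings(simulate_network(net, ev, 1e6, max_cascade_events = 1e4)),
    class = "eventsnn_runtime_error")
})

test_that("event validation rejects bad addresses and timestamps", {
  net <- single_neuron_net(1L)
  expect_error(simulate_network(net, data.frame(timestamp_ns = 1, address = 5L),
                                1e6), class = "eventsnn_config_error")
  expect_error(simulate_network(net, data.frame(timestamp_ns = -1, address = 0L),
                                1e6), class = "eventsnn_config_error")
})

test_that("AER CSV and trace export round-trip", {
  ev <- data.frame(timestamp_ns = c(100, 200, 300), address = c(0L, 1L, 0L))
  tf <- tempfile(fileext = ".csv")
  write_aer_csv(ev, tf)
  expect_equal(read_aer_csv(tf), ev)

  net <- build_network(network_spec(2L, list(layer_spec(1L))))
  net <- set_layer_weights(net, 1, forward = matrix(c(7L, 7L), 2, 1))
  net <- set_layer_scale(net, 1)
  tr <- simulate_network(net, ev, 1e3)
  td <- tempfile()
  write_trace(tr, td)
  expect_true(file.exists(file.path(td, "spikes_layer1.csv")))
  summ <- jsonlite::read_json(file.path(td, "summary.json"),
                              simplifyVector = TRUE)
  expect_identical(as.integer(summ$n_spikes_per_layer), nrow(tr$spikes))
})
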