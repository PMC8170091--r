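test_that("pixel-to-frequency mapping and exact spike counts", {
  p <- rate_coder_params(duration_us = 100)
  ev <- rate_encode(c(0, 255, 51), p)
  counts <- table(factor(ev$address, levels = 0:2))
  # pixel 0 -> 100 kHz -> one spike every 10 us -> 10 spikes in 100 us
  expect_identical(as.integer(counts[["0"]]), 10L)
  # pixel 255 -> 655 kHz -> floor(0.0001 * 655000) = 65
  expect_identical(as.integer(counts[["1"]]), 65L)
  # pixel 51/255 -> 100 + 555 * 0.2 = 211 kHz -> 21 spikes
  expect_identical(as.integer(counts[["2"]]), 21L)
  # first spike at 1/f, none at t = 0
  expect_identical(min(ev$timestamp_ns[ev$address == 0]), 10000)
})

test_that("binary mapping: 0 -> silent, 1 -> 655 kHz", {
  ev <- rate_encode(c(0, 1), binary_coder_params(duration_us = 1000))
  expect_identical(sum(ev$address == 0), 0L)
  expect_identical(sum(ev$address == 1), 655L)
})

test_that("spike count is floor(duration * f) for random pixels and durations", {
  for (seed in 1:10) {
    set.seed(seed)
    px <- sample(0:255, 20, replace = TRUE)
    dur <- sample(500:5000, 1)
    p <- rate_coder_params(duration_us = dur)
    ev <- rate_encode(px, p)
    f <- 100e3 + 555e3 * px / 255
    expected <- floor(dur * 1e-6 * f + 1e-9)
    obs <- tabulate(ev$address + 1L, nbins = length(px))
    expect_identical(obs, as.integer(expected))
    # deterministic with zero phase
    expect_identical(rate_encode(px, p), ev)
  }
})

test_that("jittered phase keeps counts but changes times deterministically per seed", {
  px <- c(100, 200)
  pz <- rate_coder_params(duration_us = 1000)
  pj <- rate_coder_params(duration_us = 1000, phase = "jitter", seed = 3L)
  evz <- rate_encode(px, pz)
  evj <- rate_encode(px, pj)
  expect_identical(tabulate(evj$address + 1L, 2), tabulate(evz$address + 1L, 2))
  expect_false(identical(evj$timestamp_ns, evz$timestamp_ns))
  expect_identical(rate_encode(px, pj), evj)
})

test_that("pixel out of range is rejected", {
  expect_error(rate_encode(c(0, 300), rate_coder_params()),
               class = "eventsnn_config_error")
})

test_that("shortest-ISI readout picks the earliest second spike", {
  sp <- data.frame(timestamp_ns = c(100e3, 180e3, 90e3, 200e3) ,
                   address = c(2L, 2L, 5L, 5L))
  d <- isi_decode(sp, 6)
  expect_identical(d$winner, 2L)
  expect_identical(d$isi_ns, 80e3)
  expect_identical(d$decision_time_ns, 180e3)
  expect_true(d$reset)

  d1 <- isi_decode(data.frame(timestamp_ns = c(10, 11), address = c(3L, 3L)), 4)
  expect_identical(d1$winner, 3L)
  expect_identical(d1$isi_ns, 1)
})

test_that("ties at the same nanosecond go to the smaller neuron index", {
  sp <- data.frame(timestamp_ns = c(5, 9, 5, 9), address = c(3L, 3L, 1L, 1L))
  expect_identical(isi_decode(sp, 4)$winner, 1L)
})

test_that("silent outputs yield a no-decision record with spike totals", {
  d <- isi_decode(data.frame(timestamp_ns = c(5), address = c(0L)), 4)
  expect_true(is.na(d$winner))
  expect_false(d$reset)
  expect_identical(d$n_spikes_total, 1L)
})

test_that("spikes after the decision time cannot change the outcome", {
  sp <- data.frame(timestamp_ns = c(10, 20, 15, 40), address = c(0L, 0L, 1L, 1L))
  d <- isi_decode(sp, 2)
  extra <- rbind(sp, data.frame(timestamp_ns = c(21, 22, 23),
                                address = c(1L, 1L, 1L)))
  d2 <- isi_decode(extra, 2)
  expect_identical(d2$winner, d$winner)
  expect_identical(d2$decision_time_ns, d$decision_time_ns)
  expect_identical(d2$isi_ns, d$isi_ns)
})

test_that("raising a pixel value never delays the decision on a toy net", {
  # three input pixels, one neuron per class, positive diagonal weights
  net <- build_network(network_spec(3L, list(layer_spec(3L))))
  net <- set_layer_weights(net, 1, forward = diag(7L, 3))
  net <- set_layer_scale(net, 1)
  p <- rate_coder_params(duration_us = 2000)
  base <- c(120, 60, 30)
  d0 <- isi_decode(simulate_network(net, rate_encode(base, p), 2e6), 3)
  for (v in c(150, 200, 255)) {
    img <- base; img[1] <- v
    d <- isi_decode(simulate_network(net, rate_encode(img, p), 2e6), 3)
    expect_lte(d$decision_time_ns, d0$decision_time_ns)
    d0 <- d
  }
})

test_that("decision CSV export carries one row per sample", {
  ds <- list(isi_decode(data.frame(timestamp_ns = c(1, 2), address = c(0L, 0L)), 2),
             isi_decode(data.frame(timestamp_ns = numeric(0), address = integer(0)), 2))
  tf <- tempfile(fileext = ".csv")
  write_decisions_csv(ds, tf)
  df <- utils::read.csv(tf)
  expect_identical(nrow(df), 2L)
  expect_true(is.na(df$winner[2]))
})
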