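# Small ReLU networks and their conversion to quantized spiking weight
# tables.
#
# The conversion relies on the mean-rate equivalence of the wrap-around
# integrate-and-fire neuron: with constant input rates r_i, a neuron's
# long-run output rate is max(0, sum(w_i * r_i)) / 64, i.e. a rectified
# linear unit up to the fixed 1/64 gain. A bias-free ReLU network therefore
# maps onto the spiking fabric by quantizing its weights and rate-coding its
# inputs.

#' Synthetic 16x16 blob-stroke image dataset
#'
#' Each class is a fixed constellation of Gaussian blobs ("strokes"), drawn
#' with seeded jitter in position, width and amplitude. Images are grayscale
#' in `[0, 255]`. This is the no-download training/evaluation fixture for the
#' ANN-to-SNN path.
#'
#' @param n_per_class samples per class.
#' @param n_classes number of classes (2..4).
#' @param seed RNG seed.
#' @return List with `images` (matrix, one row per sample, 256 columns,
#'   row-wise pixel order), `labels` (0-based integer classes) and `side`.
#' @export
make_blob_dataset <- function(n_per_class = 125, n_classes = 4, seed = 1L) {
  if (n_classes < 2 || n_classes > 4) config_error("n_classes must be 2..4")
  anchors <- list(
    rbind(c(4, 4), c(8, 8), c(12, 12)),     # main diagonal stroke
    rbind(c(4, 12), c(8, 8), c(12, 4)),     # anti-diagonal stroke
    rbind(c(8, 3), c(8, 8), c(8, 13)),      # horizontal bar
    rbind(c(3, 8), c(8, 8), c(13, 8)))      # vertical bar
  side <- 16L
  with_preserved_seed(seed, {
    n <- n_per_class * n_classes
    images <- matrix(0, n, side * side)
    labels <- integer(n)
    gx <- matrix(rep(1:side, each = side), side, side)   # column index
    gy <- matrix(rep(1:side, times = side), side, side)  # row index
    k <- 0L
    for (cl in seq_len(n_classes)) {
      for (s in seq_len(n_per_class)) {
        k <- k + 1L
        img <- matrix(0, side, side)
        for (b in seq_len(nrow(anchors[[cl]]))) {
          cy <- anchors[[cl]][b, 1] + stats::rnorm(1, 0, 0.8)
          cx <- anchors[[cl]][b, 2] + stats::rnorm(1, 0, 0.8)
          sig <- stats::runif(1, 1.2, 1.8)
          amp <- stats::runif(1, 0.7, 1)
          img <- img + amp * exp(-((gy - cy)^2 + (gx - cx)^2) / (2 * sig^2))
        }
        img <- img / max(img) * 255
        images[k, ] <- as.vector(t(img))  # row-wise, matching rate_encode
        labels[k] <- cl - 1L
      }
    }
    list(images = images, labels = labels, side = side)
  })
}

new_ann_model <- function(W1, W2, quantized = FALSE, weight_bits = NULL,
                          norm_scale = 1) {
  structure(list(W1 = W1, W2 = W2, n_classes = ncol(W2),
                 quantized = quantized, weight_bits = weight_bits,
                 norm_scale = norm_scale),
            class = "ann_model")
}

#' Train a small bias-free ReLU classifier
#'
#' Architecture: `n_pixels -> n_hidden -> n_classes`, ReLU hidden layer,
#' linear outputs trained with softmax cross-entropy, no biases anywhere
#' (the spiking fabric this model is destined for uses none on this path).
#' Full-batch Adam; deterministic for a fixed seed. The returned weights are
#' max-abs normalized (one shared scale across the whole network) so they
#' lie in `[-1, 1]`; a shared scale preserves the relative magnitude of the
#' two layers, which keeps mean-rate proportionality end-to-end.
#'
#' @param dataset list with `images` (n x p matrix, pixel values 0..255) and
#'   `labels` (0-based integers).
#' @param epochs full-batch training steps; 0 returns the random
#'   initialization.
#' @param seed RNG seed for initialization.
#' @param n_hidden hidden layer width.
#' @param lr Adam step size.
#' @return An `ann_model`: list with `W1` (p x n_hidden), `W2`
#'   (n_hidden x n_classes), `n_classes`, `norm_scale`.
#' @export
train_toy_ann <- function(dataset, epochs = 300, seed = 1L, n_hidden = 64,
                          lr = 0.01) {
  x <- dataset$images / 255
  y <- as.integer(dataset$labels)
  if (length(unique(y)) < 2)
    config_error("dataset is degenerate: a single class")
  n_out <- max(y) + 1L
  n <- nrow(x); p <- ncol(x)
  Y <- matrix(0, n, n_out); Y[cbind(seq_len(n), y + 1L)] <- 1
  with_preserved_seed(seed, {
    W1 <- matrix(stats::rnorm(p * n_hidden, 0, sqrt(2 / p)), p, n_hidden)
    W2 <- matrix(stats::rnorm(n_hidden * n_out, 0, sqrt(2 / n_hidden)),
                 n_hidden, n_out)
    m1 <- v1 <- W1 * 0
    m2 <- v2 <- W2 * 0
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    if (epochs > 0) for (it in seq_len(epochs)) {
      H <- pmax(x %*% W1, 0)
      S <- H %*% W2
      P <- exp(S - apply(S, 1, max))
      P <- P / rowSums(P)
      dS <- (P - Y) / n
      g2 <- crossprod(H, dS)
      dH <- (dS %*% t(W2)) * (H > 0)
      g1 <- crossprod(x, dH)
      m1 <- b1 * m1 + (1 - b1) * g1; v1 <- b2 * v1 + (1 - b2) * g1^2
      m2 <- b1 * m2 + (1 - b1) * g2; v2 <- b2 * v2 + (1 - b2) * g2^2
      kc <- sqrt(1 - b2^it) / (1 - b1^it)
      W1 <- W1 - lr * kc * m1 / (sqrt(v1) + eps)
      W2 <- W2 - lr * kc * m2 / (sqrt(v2) + eps)
    }
    scale <- max(abs(W1), abs(W2))
    new_ann_model(W1 / scale, W2 / scale, norm_scale = scale)
  })
}

#' Forward pass / class prediction of an `ann_model`
#'
#' @param model an `ann_model`.
#' @param x matrix of samples (rows) or a single image vector, pixel values
#'   0..255.
#' @return `ann_forward`: list with `hidden` and `output` activation
#'   matrices; `predict_ann`: 0-based predicted class vector.
#' @export
ann_forward <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  H <- pmax((x / 255) %*% model$W1, 0)
  list(hidden = H, output = H %*% model$W2)
}

#' @rdname ann_forward
#' @export
predict_ann <- function(model, x) {
  max.col(ann_forward(model, x)$output, ties.method = "first") - 1L
}

#' Quantize ANN weights to a signed integer range
#'
#' Applies per-network max-abs normalization (so weights lie in `[-1, 1]`),
#' then maps linearly onto the representable integer range:
#' `w_q = round(w * (2^(W-1) - 1))` with ties rounded away from zero. For
#' W = 4 the range `[-1, 1]` maps to `[-7, +7]`.
#'
#' @param model an `ann_model` (real-valued or already quantized).
#' @param weight_bits bit width W (>= 2).
#' @return An `ann_model` with integer weight matrices, `quantized = TRUE`.
#' @export
quantize_weights <- function(model, weight_bits = 4L) {
  if (!is_count(weight_bits) || weight_bits < 2)
    config_error("weight_bits must be an integer >= 2")
  lim <- weight_limit(weight_bits)
  scale <- max(abs(model$W1), abs(model$W2))
  if (scale == 0) scale <- 1
  q <- function(w) round_half_away(w / scale * lim)
  new_ann_model(q(model$W1), q(model$W2), quantized = TRUE,
                weight_bits = as.integer(weight_bits),
                norm_scale = model$norm_scale * scale)
}

#' @rdname quantize_weights
#' @export
dequantize_weights <- function(model) {
  stopifnot(isTRUE(model$quantized))
  lim <- weight_limit(model$weight_bits)
  new_ann_model(model$W1 / lim, model$W2 / lim, norm_scale = model$norm_scale)
}

#' Build a spiking network from a quantized ANN
#'
#' Creates a fully connected feed-forward `snn_network` with the quantized
#' model's shape and weights (no biases, no recurrence, scale off).
#'
#' @param model a quantized `ann_model`.
#' @param seed connectivity seed (immaterial: density 1).
#' @return An `snn_network` ready to simulate.
#' @export
network_from_ann <- function(model, seed = 1L) {
  stopifnot(isTRUE(model$quantized))
  spec <- network_spec(
    n_inputs = nrow(model$W1),
    layers = list(layer_spec(ncol(model$W1), "fc"),
                  layer_spec(ncol(model$W2), "fc")),
    weight_bits = model$weight_bits, seed = seed)
  net <- build_network(spec)
  net <- set_layer_weights(net, 1, forward = model$W1)
  set_layer_weights(net, 2, forward = model$W2)
}

#' Predicted mean rates of a converted network under rate-coded input
#'
#' Propagates input frequencies through the quantized weights with the
#' rectified-linear mean-rate law `rate_out = max(0, W' rate_in) / 64` per
#' layer.
#'
#' @param model a quantized `ann_model`.
#' @param image pixel vector.
#' @param params a [rate_coder_params()].
#' @return List with per-layer expected rates in Hz (`hidden`, `output`).
#' @export
expected_rates <- function(model, image, params = rate_coder_params()) {
  if (is.matrix(image)) image <- as.vector(t(image))
  f <- params$f_min + (params$f_max - params$f_min) * image / params$pixel_max
  h <- pmax(crossprod(model$W1, f), 0) / 64
  o <- pmax(crossprod(model$W2, h), 0) / 64
  list(hidden = as.vector(h), output = as.vector(o))
}

#' Agreement between ANN mean-rate predictions and simulated spike rates
#'
#' Rate-encodes one image, simulates the converted network, and compares the
#' measured output spike rates against the mean-rate prediction on the same
#' quantized weights. Outputs whose predicted rate falls below `floor_frac`
#' of the largest prediction are excluded (their relative rate estimate is
#' dominated by discretization).
#'
#' @param model a quantized `ann_model`.
#' @param image pixel vector (0..`params$pixel_max`... scaled by coder).
#' @param duration_us presentation length; longer runs shrink the rate
#'   estimation error.
#' @param params a [rate_coder_params()] (duration is overridden).
#' @param floor_frac relative floor for including an output.
#' @return List with `max_rel_error`, and per-output `expected_hz`,
#'   `measured_hz`.
#' @export
ann_snn_rate_agreement <- function(model, image, duration_us = 10000,
                                   params = rate_coder_params(),
                                   floor_frac = 0.05) {
  params$duration_us <- duration_us
  net <- network_from_ann(model)
  ev <- rate_encode(image, params)
  tr <- simulate_network(net, ev, duration_ns = duration_us * 1e3)
  out <- output_spikes(tr)
  dur_s <- duration_us * 1e-6
  measured <- vapply(seq_len(model$n_classes) - 1L,
                     function(a) sum(out$address == a) / dur_s, numeric(1))
  exp_r <- expected_rates(model, image, params)$output
  if (all(exp_r == 0) && all(measured == 0))
    return(list(max_rel_error = 0, expected_hz = exp_r, measured_hz = measured))
  keep <- exp_r > max(exp_r) * floor_frac & exp_r > 0
  rel <- abs(measured[keep] - exp_r[keep]) / exp_r[keep]
  list(max_rel_error = if (any(keep)) max(rel) else 0,
       expected_hz = exp_r, measured_hz = measured)
}

#' Classify images with a spiking network and ISI readout
#'
#' @param network an `snn_network` whose last layer has one neuron per class.
#' @param images matrix (one image per row) or single vector.
#' @param params a [rate_coder_params()] controlling the input encoding.
#' @return List with `predicted` (0-based classes, `NA` for no-decision) and
#'   `decisions` (list of [isi_decode()] records).
#' @export
snn_classify <- function(network, images, params = binary_coder_params()) {
  if (is.null(dim(images))) images <- matrix(images, 1)
  n_classes <- network$layers[[length(network$layers)]]$n
  decisions <- vector("list", nrow(images))
  for (i in seq_len(nrow(images))) {
    ev <- rate_encode(images[i, ], params)
    tr <- simulate_network(network, ev, duration_ns = params$duration_us * 1e3)
    decisions[[i]] <- isi_decode(tr, n_classes)
  }
  list(predicted = vapply(decisions, function(d) as.integer(d$winner), integer(1)),
       decisions = decisions)
}

#' Read / write ANN layer weights as CSV
#'
#' One CSV per layer with a `src,dst,weight` header (0-based indices), plus
#' a JSON manifest recording the normalization scale and bit width for
#' quantized models.
#'
#' @param model an `ann_model`.
#' @param dir directory to write into.
#' @return `write_ann_csv`: the directory; `read_ann_csv`: an `ann_model`.
#' @export
write_ann_csv <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dump <- function(W, path) {
    idx <- which(!is.na(W), arr.ind = TRUE)
    utils::write.csv(data.frame(src = idx[, 1] - 1L, dst = idx[, 2] - 1L,
                                weight = W[idx]),
                     path, row.names = FALSE)
  }
  dump(model$W1, file.path(dir, "layer1.csv"))
  dump(model$W2, file.path(dir, "layer2.csv"))
  jsonlite::write_json(
    list(format = "eventsnn-ann/1", quantized = isTRUE(model$quantized),
         weight_bits = model$weight_bits, norm_scale = model$norm_scale,
         shape = c(nrow(model$W1), ncol(model$W1), ncol(model$W2))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_ann_csv
#' @export
read_ann_csv <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  load <- function(path, nr, nc) {
    df <- utils::read.csv(path)
    W <- matrix(0, nr, nc)
    W[cbind(df$src + 1L, df$dst + 1L)] <- df$weight
    W
  }
  new_ann_model(
    load(file.path(dir, "layer1.csv"), man$shape[1], man$shape[2]),
    load(file.path(dir, "layer2.csv"), man$shape[2], man$shape[3]),
    quantized = isTRUE(man$quantized),
    weight_bits = if (is.null(man$weight_bits)) NULL else as.integer(man$weight_bits),
    norm_scale = man$norm_scale)
}
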