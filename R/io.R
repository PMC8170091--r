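# Interchange formats: network specs as JSON, weight tables as CSV, plus an
# optional IDX image loader for external digit benchmarks.

#' Write / read a network spec as JSON
#'
#' Versioned document (`"format": "eventsnn-netspec/1"`) capturing layer
#' sizes, kinds, densities, bias flags, bit width, seed and exact synapse
#' counts.
#'
#' @param spec a [network_spec()].
#' @param path file path.
#' @return `read_network_spec_json`: a `network_spec`.
#' @export
write_network_spec_json <- function(spec, path) {
  stopifnot(inherits(spec, "network_spec"))
  doc <- list(
    format = "eventsnn-netspec/1",
    n_inputs = spec$n_inputs, weight_bits = spec$weight_bits,
    seed = spec$seed,
    exact_synapse_counts = if (is.null(spec$exact_synapse_counts)) NULL
      else lapply(spec$exact_synapse_counts,
                  function(x) if (is.na(x)) NULL else x),
    layers = lapply(spec$layers, unclass))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_network_spec_json
#' @export
read_network_spec_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "eventsnn-netspec/1"))
    config_error("%s: unsupported network spec format", path)
  layers <- lapply(doc$layers, function(l)
    layer_spec(l$n_neurons, l$kind, isTRUE(l$has_bias),
               l$forward_density, l$lateral_density))
  counts <- doc$exact_synapse_counts
  if (!is.null(counts))
    counts <- vapply(counts, function(x)
      if (is.null(x) || (is.character(x) && x == "NA")) NA_integer_
      else as.integer(x), integer(1))
  network_spec(doc$n_inputs, layers, doc$weight_bits, doc$seed, counts)
}

#' Write / read a weight table as CSV
#'
#' Columns `layer,src,dst,weight` (0-based indices). For recurrent layers,
#' lateral sources use the fan-in address `n_in + neuron`; bias rows use
#' `src = "B"`. All registers on the connectivity mask are written, zeros
#' included.
#'
#' @param network a built `snn_network`.
#' @param path file path.
#' @return `read_weights_csv`: the network with weights loaded.
#' @export
write_weights_csv <- function(network, path) {
  stopifnot(inherits(network, "snn_network"))
  rows <- list()
  for (li in seq_along(network$layers)) {
    l <- network$layers[[li]]
    idx <- which(l$forward_mask, arr.ind = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      layer = li, src = as.character(idx[, 1] - 1L), dst = idx[, 2] - 1L,
      weight = l$forward_w[idx])
    if (!is.null(l$lateral_mask)) {
      idx <- which(l$lateral_mask, arr.ind = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        layer = li, src = as.character(l$n_in + idx[, 1] - 1L),
        dst = idx[, 2] - 1L, weight = l$lateral_w[idx])
    }
    if (l$has_bias)
      rows[[length(rows) + 1L]] <- data.frame(
        layer = li, src = "B", dst = seq_len(l$n) - 1L, weight = l$bias_w)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights_csv
#' @export
read_weights_csv <- function(network, path) {
  stopifnot(inherits(network, "snn_network"))
  df <- utils::read.csv(path, colClasses = c(src = "character"))
  for (li in seq_along(network$layers)) {
    l <- network$layers[[li]]
    sub <- df[df$layer == li, , drop = FALSE]
    bias_rows <- sub$src == "B"
    fw <- l$forward_w * 0L
    lw <- if (!is.null(l$lateral_w)) l$lateral_w * 0L else NULL
    syn <- sub[!bias_rows, , drop = FALSE]
    src <- as.integer(syn$src)
    fwd_sel <- src < l$n_in
    fw[cbind(src[fwd_sel] + 1L, syn$dst[fwd_sel] + 1L)] <-
      as.integer(syn$weight[fwd_sel])
    network <- set_layer_weights(network, li, forward = fw)
    if (any(!fwd_sel)) {
      if (is.null(lw))
        config_error("layer %d: lateral weights in file but layer is fc", li)
      lw[cbind(src[!fwd_sel] - l$n_in + 1L, syn$dst[!fwd_sel] + 1L)] <-
        as.integer(syn$weight[!fwd_sel])
      network <- set_layer_weights(network, li, lateral = lw)
    }
    if (any(bias_rows)) {
      if (!l$has_bias) config_error("layer %d: bias rows but no bias registers", li)
      bw <- integer(l$n)
      bw[sub$dst[bias_rows] + 1L] <- as.integer(sub$weight[bias_rows])
      network <- set_layer_weights(network, li, bias = bw)
    }
  }
  network
}

#' Minimal IDX image/label reader (optional external-benchmark path)
#'
#' Reads the big-endian IDX format used by common handwritten-digit dumps.
#' Provided for users who want to run the full external benchmark; nothing
#' in the package requires it.
#'
#' @param path an IDX file (magic 0x0801 labels, 0x0803 images).
#' @return For labels an integer vector; for images a matrix with one row
#'   per image (pixels row-wise, 0..255).
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  n <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (magic == 2049L) {
    as.integer(readBin(con, "integer", n, size = 1, signed = FALSE))
  } else if (magic == 2051L) {
    nr <- readBin(con, "integer", 1, size = 4, endian = "big")
    nc <- readBin(con, "integer", 1, size = 4, endian = "big")
    px <- readBin(con, "integer", n * nr * nc, size = 1, signed = FALSE)
    matrix(as.integer(px), n, nr * nc, byrow = TRUE)
  } else {
    config_error("%s: not an IDX label/image file", path)
  }
}
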