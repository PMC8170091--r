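Package: eventsnn
Title: Event-Driven Simulation of Quantized Spiking Neural Network Hardware
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Bit-exact behavioral simulation of a tiny, fully parallel,
    event-driven digital spiking neural network architecture: quantized
    integer integrate-and-fire neurons with wrap-around overflow spiking
    and underflow clamping, deterministic per-layer spike arbitration,
    address-event representation (AER) spike streams, rate-coded input
    encoding, inter-spike-interval readout, and conversion of small ReLU
    networks to quantized spiking weight tables. Includes a synthetic
    FMCW radar front end that generates per-gesture micro-Doppler maps
    and binarized 16x16 spike images for end-to-end classification
    experiments without hardware, and a closed-form timing calculator
    for the CMOS thyristor delay cell that paces the asynchronous
    arbiter.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
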