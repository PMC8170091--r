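# Spike arbiter: serializes simultaneous spikes into a deterministic order.
#
# Each input line has an edge detector that can remember H-1 pending spikes;
# simultaneous repeats beyond that capacity are lost (counted, never
# reordered). The surviving multiset is granted in polling rounds: linear
# polling sweeps ascending addresses; round-robin sweeps ascending starting
# just after the last granted address, wrapping.

#' Arbiter configuration
#'
#' @param H edge-detector state count (>= 2); each input line can hold up to
#'   `H - 1` pending spikes.
#' @param polling `"linear"` (ascending address) or `"round_robin"`
#'   (ascending from just after the last grant, wrapping).
#' @return An `arbiter_spec` object.
#' @export
arbiter_spec <- function(H = 2L, polling = c("linear", "round_robin")) {
  polling <- match.arg(polling)
  if (!is_count(H) || H < 2) config_error("H must be an integer >= 2")
  structure(list(H = as.integer(H), polling = polling), class = "arbiter_spec")
}

#' Order a set of simultaneous spikes
#'
#' @param addresses integer vector of source addresses sharing one timestamp
#'   (repeats allowed).
#' @param spec an [arbiter_spec()].
#' @param last_grant address granted most recently (round-robin memory), or
#'   `NULL`/`-1` if none.
#' @return List with `order` (granted addresses, in grant order), `lost`
#'   (spikes dropped by edge-detector capacity) and `last_grant` (updated
#'   memory).
#' @examples
#' arbitrate(c(7L, 2L, 5L), arbiter_spec())$order            # 2 5 7
#' arbitrate(c(1L, 3L), arbiter_spec(polling = "round_robin"),
#'           last_grant = 2L)$order                          # 3 1
#' @export
arbitrate <- function(addresses, spec = arbiter_spec(), last_grant = NULL) {
  stopifnot(inherits(spec, "arbiter_spec"))
  addresses <- as.integer(addresses)
  if (!length(addresses))
    return(list(order = integer(0), lost = 0L, last_grant = last_grant))
  cnt <- table(addresses)
  cap <- spec$H - 1L
  lost <- sum(pmax(as.integer(cnt) - cap, 0L))
  pend <- pmin(as.integer(cnt), cap)
  addr <- as.integer(names(cnt))  # ascending
  ord <- integer(0)
  lg <- if (is.null(last_grant) || last_grant < 0) -1L else as.integer(last_grant)
  while (any(pend > 0L)) {
    live <- addr[pend > 0L]
    if (spec$polling == "round_robin") {
      after <- live[live > lg]
      round <- c(after, live[live <= lg])
    } else {
      round <- live
    }
    ord <- c(ord, round)
    pend[match(round, addr)] <- pend[match(round, addr)] - 1L
    lg <- round[length(round)]
  }
  list(order = ord, lost = as.integer(lost), last_grant = lg)
}
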