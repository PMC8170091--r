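# Closed-form delay-cell timing: two cross-coupled CMOS thyristors paced by
# a bias current generate the fixed ns-scale delay that clocks the arbiter's
# self-timed phases.
#
# Phase 1: the bias current I_c charges C_n linearly until the NMOS gate
# reaches V_tn, taking t_d1 = C_n * V_tn / I_c. Phase 2: the NMOS drain
# current (square law, transconductance beta_n) discharges C_p until the
# PMOS turns on, giving the cube-root expression
# t_d2 = (6 * C_n^2 * C_p / (beta_n * I_c^2))^(1/3). An alternative printed
# form expresses t_d2 through V_tp and the common load C_L = C_n = C_p; the
# two agree only under an implicit substitution (they coincide when
# V_tp = 1 V), so both are computed and compared rather than silently
# merged — see delay_consistency().

#' Delay-cell physical parameters
#'
#' @param C_n,C_p node capacitances (F). @param C_L common load capacitance
#'   (F), defaults to `C_n` (the symmetric case `C_L = C_p = C_n`).
#' @param V_tn,V_tp NMOS/PMOS threshold voltages (V), below `V_dd`.
#' @param V_dd supply voltage (V).
#' @param I_c bias current (A).
#' @param beta_n NMOS transconductance factor (A/V^2).
#' @return A `delay_cell_params` object.
#' @export
delay_cell_params <- function(C_n = 1e-13, C_p = C_n, C_L = C_n,
                              V_tn = 0.45, V_tp = 0.45, V_dd = 1.1,
                              I_c = 1e-6, beta_n = 2e-4) {
  vals <- c(C_n, C_p, C_L, V_tn, V_tp, V_dd, I_c, beta_n)
  if (any(!is.finite(vals)) || any(vals <= 0))
    config_error("all delay-cell parameters must be strictly positive")
  if (V_tn >= V_dd || V_tp >= V_dd)
    config_error("threshold voltages must be below V_dd")
  structure(list(C_n = C_n, C_p = C_p, C_L = C_L, V_tn = V_tn, V_tp = V_tp,
                 V_dd = V_dd, I_c = I_c, beta_n = beta_n),
            class = "delay_cell_params")
}

#' Delay-cell phase and total delays
#'
#' `delay_td1`: time for the bias current to charge `C_n` to the NMOS
#' threshold, `C_n * V_tn / I_c`. `delay_td2`: NMOS-conduction phase,
#' `(6 * C_n^2 * C_p / (beta_n * I_c^2))^(1/3)`. `delay_total`: their sum,
#' plus a check against a configured safe band (the fabricated cell targets
#' 100 ns with margin).
#'
#' @param p a [delay_cell_params()].
#' @return seconds (`delay_total`: list with `t_d`, `t_d1`, `t_d2`,
#'   `within_safe_band`, `safe_band`).
#' @export
delay_td1 <- function(p) {
  stopifnot(inherits(p, "delay_cell_params"))
  p$C_n * p$V_tn / p$I_c
}

#' @rdname delay_td1
#' @export
delay_td2 <- function(p) {
  stopifnot(inherits(p, "delay_cell_params"))
  (6 * p$C_n^2 * p$C_p / (p$beta_n * p$I_c^2))^(1 / 3)
}

#' @rdname delay_td1
#' @param safe_band two-element vector (s); the report flags whether the
#'   total delay lies inside it.
#' @export
delay_total <- function(p, safe_band = c(50e-9, 200e-9)) {
  td1 <- delay_td1(p)
  td2 <- delay_td2(p)
  td <- td1 + td2
  list(t_d = td, t_d1 = td1, t_d2 = td2,
       within_safe_band = td >= safe_band[1] && td <= safe_band[2],
       safe_band = safe_band)
}

#' Consistency report between the two printed forms of the second phase
#'
#' The capacitor form is `(6 C_n^2 C_p / (beta_n I_c^2))^(1/3)`; the
#' threshold form is `(6 V_tp / (beta_n I_c^2))^(1/3) * C_L` with
#' `C_L = C_p = C_n`. In the symmetric case their ratio is exactly
#' `V_tp^(1/3)`, so they coincide only at `V_tp` = 1 V; both are reported.
#'
#' @param p a [delay_cell_params()].
#' @return List with `td2_capacitor_form`, `td2_threshold_form`, `ratio`
#'   (threshold / capacitor), and `consistent` (ratio within 1% of 1).
#' @export
delay_consistency <- function(p) {
  cap <- delay_td2(p)
  thr <- (6 * p$V_tp / (p$beta_n * p$I_c^2))^(1 / 3) * p$C_L
  list(td2_capacitor_form = cap, td2_threshold_form = thr,
       ratio = thr / cap, consistent = abs(thr / cap - 1) < 0.01)
}

#' Solve for the bias current that yields a target total delay
#'
#' Bisection on `I_c` (the total delay is strictly decreasing in `I_c`).
#'
#' @param p a [delay_cell_params()] (its `I_c` is ignored).
#' @param target_s target total delay in seconds.
#' @param interval search interval for `I_c` (A).
#' @return The fitted `delay_cell_params`.
#' @export
solve_bias_current <- function(p, target_s = 100e-9,
                               interval = c(1e-12, 1e-1)) {
  f <- function(ic) {
    q <- p; q$I_c <- ic
    delay_total(q)$t_d - target_s
  }
  root <- stats::uniroot(f, interval, tol = 1e-18)$root
  p$I_c <- root
  p
}

#' Write a timing report as JSON
#'
#' @param p a [delay_cell_params()].
#' @param path output file.
#' @param safe_band passed to [delay_total()].
#' @return the report list, invisibly.
#' @export
write_timing_report <- function(p, path, safe_band = c(50e-9, 200e-9)) {
  rep <- c(delay_total(p, safe_band), list(consistency = delay_consistency(p)),
           list(params = unclass(p)))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(rep)
}
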