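#' Wave-to-pulse sigmoid
#'
#' Static sigmoid converting the total postsynaptic potential received by a
#' subpopulation into a mean firing rate,
#' \deqn{S(v) = 2 e_0 / (1 + \exp(r (v_0 - v))),}
#' bounded in \eqn{(0, 2 e_0)} and strictly increasing.
#'
#' @param v total postsynaptic potential (mV); vectorised.
#' @param p sigmoid parameter list with `e0` (half of the maximal rate,
#'   pulses/s), `v0` (PSP at half activation, mV), `r` (steepness, 1/mV).
#' @return firing rate (pulses/s), same length as `v`.
#' @export
#' @examples
#' wave_to_pulse(6, list(e0 = 2.5, v0 = 6, r = 0.56)) # midpoint: e0
wave_to_pulse <- function(v, p = default_params()$sigmoid) {
  if (!all(is.finite(v))) stop("non-finite membrane potential", call. = FALSE)
  stopifnot(p$e0 > 0, p$r > 0)
  2 * p$e0 / (1 + exp(p$r * (p$v0 - v)))
}

# derivative of the sigmoid, used by the analytic Jacobian
wave_to_pulse_deriv <- function(v, p = default_params()$sigmoid) {
  s <- wave_to_pulse(v, p)
  p$r * s * (1 - s / (2 * p$e0))
}

#' Pulse-to-wave second-order synaptic kinetics
#'
#' Time derivatives of the critically damped second-order filter that turns a
#' presynaptic firing rate into an average postsynaptic potential:
#' \deqn{\dot y = \dot y, \quad \ddot y = W w\, fr - 2 w \dot y - w^2 y.}
#' Its impulse response is \eqn{h(t) = W w t e^{-w t}} (peak \eqn{W/e} at
#' \eqn{t = 1/w}) and its steady state under constant rate \eqn{fr_0} is
#' \eqn{y^* = W fr_0 / w}.
#'
#' @param y PSP (mV); @param ydot PSP derivative (mV/s);
#' @param fr input firing rate (pulses/s);
#' @param k kinetics list with `W` (average synaptic gain, mV) and `w`
#'   (lumped rate constant, 1/s).
#' @return list with `dy` (mV/s) and `dydot` (mV/s^2).
#' @export
pulse_to_wave_derivatives <- function(y, ydot, fr, k) {
  if (!all(is.finite(c(y, ydot, fr)))) stop("non-finite input", call. = FALSE)
  stopifnot(k$w > 0, k$W >= 0)
  list(dy = ydot, dydot = k$W * k$w * fr - 2 * k$w * ydot - k$w^2 * y)
}

#' Closed-form responses of the pulse-to-wave filter
#'
#' Impulse response `W*w*t*exp(-w*t)` and step response
#' `(W*fr/w) * (1 - (1 + w*t) * exp(-w*t))` of the second-order kinetics, used
#' as analytic references.
#'
#' @param t time (s), vectorised; @param k kinetics list (`W`, `w`);
#' @param fr step amplitude (pulses/s) for the step response.
#' @return numeric vector of PSP values (mV).
#' @export
psp_impulse_response <- function(t, k) k$W * k$w * t * exp(-k$w * t)

#' @rdname psp_impulse_response
#' @export
psp_step_response <- function(t, k, fr = 1) {
  (k$W * fr / k$w) * (1 - (1 + k$w * t) * exp(-k$w * t))
}

#' Connectivity graph of the default model
#'
#' The directed edge list of the two-compartment model: source, target,
#' coupling constant, sign (+1 excitatory, -1 inhibitory), transmission delay
#' (s) and plasticity tag (`none`, `STD`, `STF`). Exactly three edges are
#' plastic: TC->PYR1 (STD, gain family ACd), RtN1->TC (STD, GTh) and
#' RtN2->TC (STF, BTh).
#'
#' @param p parameter list from [default_params()].
#' @return data.frame with columns `source`, `target`, `C`, `sign`, `delay`,
#'   `plasticity`.
#' @export
connectivity_graph <- function(p = default_params()) {
  cp <- p$couplings
  d_tc <- p$delays$tc_to_ncx
  d_ct <- p$delays$ncx_to_th
  e <- function(src, tgt, C, sign, delay = 0, plast = "none")
    data.frame(source = src, target = tgt, C = C, sign = sign,
               delay = delay, plasticity = plast, stringsAsFactors = FALSE)
  g <- rbind(
    e("PYR2", "PYR1", cp$PYR2_PYR1, +1),
    e("PYR1", "PYR2", cp$PYR1_PYR2, +1),
    e("PYR1", "PV",   cp$PYR1_PV,   +1),
    e("PYR1", "SSTa", cp$PYR1_SSTa, +1),
    e("PYR1", "SSTb", cp$PYR1_SSTb, +1),
    e("PYR1", "VIP",  cp$PYR1_VIP,  +1),
    e("PV",   "PYR1", cp$PV_PYR1,   -1),
    e("SSTa", "PYR1", cp$SSTa_PYR1, -1),
    e("SSTb", "PYR1", cp$SSTb_PYR1, -1),
    e("NGFC", "PYR1", cp$NGFC_PYR1, -1),
    e("VIP",  "SSTa", cp$VIP_SSTa,  -1),
    e("VIP",  "SSTb", cp$VIP_SSTb,  -1),
    e("SSTa", "VIP",  cp$SSTa_VIP,  -1),
    e("SSTa", "PV",   cp$SSTa_PV,   -1),
    e("NGFC", "VIP",  cp$NGFC_VIP,  -1),
    e("PV",   "PV",   cp$PV_PV,     -1),
    e("TC",   "PYR1", cp$TC_PYR1,   +1, d_tc, "STD"),
    e("TC",   "PV",   cp$TC_PV,     +1, d_tc),
    e("TC",   "SSTa", cp$TC_SSTa,   +1, d_tc),
    e("TC",   "SSTb", cp$TC_SSTb,   +1, d_tc),
    e("TC",   "NGFC", cp$TC_NGFC,   +1, d_tc),
    e("PYR1", "TC",   cp$PYR1_TC,   +1, d_ct),
    e("PYR1", "RtN1", cp$PYR1_RtN1, +1, d_ct),
    e("PYR1", "RtN2", cp$PYR1_RtN2, +1, d_ct),
    e("TC",   "TC",   cp$TC_TC,     +1),
    e("TC",   "RtN1", cp$TC_RtN1,   +1),
    e("TC",   "RtN2", cp$TC_RtN2,   +1),
    e("RtN1", "TC",   cp$RtN1_TC,   -1, 0, "STD"),
    e("RtN2", "TC",   cp$RtN2_TC,   -1, 0, "STF")
  )
  stopifnot(all(g$delay >= 0), sum(g$plasticity != "none") == 3L)
  g
}

#' Total synaptic input to one subpopulation
#'
#' Sums the signed, coupling-weighted, optionally delayed presynaptic PSP
#' contributions to a target subpopulation, plus any plastic gain scaling. The
#' result is linear in every contribution and independent of edge order.
#'
#' @param target name of the target subpopulation.
#' @param psps named numeric vector of current presynaptic PSP values (mV).
#' @param graph edge list as returned by [connectivity_graph()].
#' @param delayed named numeric vector of delayed PSP values for sources with
#'   delayed edges (defaults to `psps`, i.e. warm buffers holding the current
#'   value).
#' @param gains named numeric vector of plastic gain ratios keyed by
#'   plasticity family (`ACd`, `GTh`, `BTh`); defaults to 1.
#' @return total input (mV).
#' @export
total_input <- function(target, psps, graph, delayed = psps,
                        gains = c(ACd = 1, GTh = 1, BTh = 1)) {
  if (!target %in% c(graph$target, graph$source))
    stop("unknown target subpopulation: ", target, call. = FALSE)
  rows <- graph[graph$target == target, , drop = FALSE]
  if (nrow(rows) == 0) return(0)
  tot <- 0
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    y <- if (r$delay > 0) delayed[[r$source]] else psps[[r$source]]
    if (is.null(y)) stop("no PSP value for source ", r$source, call. = FALSE)
    gain <- 1
    if (r$plasticity != "none") {
      key <- if (r$source == "TC") "ACd" else if (r$source == "RtN1") "GTh" else "BTh"
      gain <- gains[[key]]
    }
    tot <- tot + r$sign * r$C * gain * y
  }
  tot
}
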