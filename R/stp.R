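#' Short-term plasticity state
#'
#' Tsodyks-Markram state of one plastic connection: `u`, the fraction of
#' synaptic resources used per presynaptic firing, and `k`, the fraction of
#' available resources, together with their constants.
#'
#' @param ue baseline of `u` (0 < ue <= 1).
#' @param tau_f facilitation time constant (s).
#' @param tau_d depression time constant (s).
#' @param x0 baseline gain (mV) scaled by the plastic ratio.
#' @param u,k initial values (default `ue` and 1: the resting fixed point).
#' @return list of class `stp_state`.
#' @export
stp_state <- function(ue, tau_f, tau_d, x0 = 1, u = ue, k = 1) {
  stopifnot(ue > 0, ue <= 1, tau_f > 0, tau_d > 0, u >= 0, k >= 0, k <= 1)
  structure(list(u = u, k = k, ue = ue, tau_f = tau_f, tau_d = tau_d, x0 = x0),
            class = "stp_state")
}

#' Short-term plasticity derivatives
#'
#' Facilitation/depression dynamics driven by the presynaptic firing rate
#' while stimulation is on:
#' \deqn{\dot u = (u_e - u)/\tau_f + (1 - u) u_e\, fr\, stim,}
#' \deqn{\dot k = (1 - k)/\tau_d - u\, k\, fr\, stim.}
#' With `stim = 0` the variables relax back to the resting values
#' `u = ue`, `k = 1`. Under constant drive the closed-form steady states are
#' \eqn{u^* = u_e (1 + \tau_f fr)/(1 + u_e \tau_f fr)} and
#' \eqn{k^* = 1/(1 + u^* fr \tau_d)}.
#'
#' @param s an [stp_state()]. @param fr presynaptic firing rate (pulses/s,
#'   >= 0). @param stim stimulation gate (0 or 1).
#' @return list with `du` and `dk` (1/s).
#' @export
stp_derivatives <- function(s, fr, stim) {
  if (fr < 0) stop("negative firing rate", call. = FALSE)
  list(du = (s$ue - s$u) / s$tau_f + (1 - s$u) * s$ue * fr * stim,
       dk = (1 - s$k) / s$tau_d - s$u * s$k * fr * stim)
}

#' Closed-form STP steady state under constant drive
#'
#' @param s an [stp_state()]. @param fr constant presynaptic rate (pulses/s).
#' @return list with `u_star` and `k_star`.
#' @export
stp_steady_state <- function(s, fr) {
  u_star <- s$ue * (1 + s$tau_f * fr) / (1 + s$ue * s$tau_f * fr)
  k_star <- 1 / (1 + u_star * fr * s$tau_d)
  list(u_star = u_star, k_star = k_star)
}

#' Effective plastic gain
#'
#' The modulated synaptic gain \eqn{x(t) = (u/u_e)\, k\, x_0}: at rest
#' (`u = ue`, `k = 1`) it equals the baseline `x0`; depression lowers it via
#' `k`, facilitation raises it via `u/ue`.
#'
#' @param s an [stp_state()].
#' @return gain (same units as `x0`).
#' @export
effective_gain <- function(s) (s$u / s$ue) * s$k * s$x0

#' Combined reticular firing rate
#'
#' The drive of extrasynaptic GABA accumulation: a weighted sum of the firing
#' rates of the fast- and slow-kinetics reticular subpopulations, the weights
#' tracking their plastic gain ratios,
#' \eqn{\phi_{RtN} = w_1 fr_1 + w_2 fr_2}.
#'
#' @param fr1,fr2 firing rates of RtN1 and RtN2 (pulses/s, >= 0).
#' @param w1,w2 weights (typically `c1 * GTh_ratio` and `c2 * BTh_ratio`).
#' @return phiRtN (A.U./s).
#' @export
rtn_combined_firing <- function(fr1, fr2, w1, w2) {
  if (any(c(fr1, fr2) < 0)) stop("negative firing rate", call. = FALSE)
  w1 * fr1 + w2 * fr2
}

#' Tonic inhibition state
#'
#' Extrasynaptic GABA accumulation `y26` (A.U.), the tonic IPSP `y11` (mV)
#' and its derivative `y24` (mV/s), with the tonic gain `ET`, rate `eT`
#' and GABA reuptake time constant `tau_IE`.
#'
#' @param y26,y11,y24 state values. @param ET gain (mV). @param eT rate
#'   (1/s). @param tau_IE reuptake time constant (s).
#' @return list of class `tonic_state`.
#' @export
tonic_state <- function(y26 = 0, y11 = 0, y24 = 0, ET = 0.125, eT = 0.5,
                        tau_IE = 10) {
  stopifnot(y26 >= 0, ET >= 0, eT > 0, tau_IE > 0)
  structure(list(y26 = y26, y11 = y11, y24 = y24, ET = ET, eT = eT,
                 tau_IE = tau_IE), class = "tonic_state")
}

#' GABA accumulation derivative
#'
#' \deqn{\dot y_{26} = -y_{26}/\tau_{IE} + \phi_{RtN}} while stimulation is
#' on, and \eqn{\dot y_{26} = -y_{26}/\tau_{IE}} otherwise: accumulation is
#' fed by the synchronous reticular firing elicited by the train and cleared
#' by reuptake.
#'
#' @param t a [tonic_state()]. @param phi combined reticular firing (A.U./s).
#' @param cms_on logical, stimulation on.
#' @return dy26 (A.U./s).
#' @export
gaba_accumulation_derivative <- function(t, phi, cms_on) {
  -t$y26 / t$tau_IE + if (isTRUE(cms_on)) phi else 0
}

#' Tonic IPSP derivatives
#'
#' Second-order critically damped transfer from GABA accumulation to the
#' tonic IPSP on the relay cells:
#' \deqn{\dot y_{11} = y_{24}, \quad
#'   \dot y_{24} = E_T e_T y_{26} - 2 e_T y_{24} - e_T^2 y_{11}.}
#' Constant accumulation `c` gives the steady IPSP \eqn{E_T c / e_T}.
#'
#' @param t a [tonic_state()].
#' @return list with `dy11` (mV/s) and `dy24` (mV/s^2).
#' @export
tonic_psp_derivatives <- function(t) {
  list(dy11 = t$y24,
       dy24 = t$ET * t$eT * t$y26 - 2 * t$eT * t$y24 - t$eT^2 * t$y11)
}

#' Presynaptic GABA-B gate
#'
#' Protocol-level switch modelling self-inhibition of the reticular
#' GABAergic terminals at high stimulation frequency: when enabled and GABA
#' accumulation exceeds the threshold while the train is on, the baseline
#' release fraction `ue` of both reticular STP states is multiplied by
#' `ue_multiplier` (clipped at 1, since `u` is a release fraction) and the
#' reuptake time constant is divided by `tau_reduction`. The gate latches:
#' once engaged it stays engaged for the rest of the run.
#'
#' @param threshold y26 level (A.U.) triggering engagement.
#' @param ue_multiplier multiplier on `ue` (default 50).
#' @param tau_reduction divisor on `tau_IE` (default 5).
#' @param enabled protocol-level switch.
#' @return list of class `gabab_gate`.
#' @export
gabab_gate <- function(threshold, ue_multiplier = 50, tau_reduction = 5,
                       enabled = TRUE) {
  if (ue_multiplier <= 0) stop("ue_multiplier must be positive", call. = FALSE)
  if (tau_reduction <= 0) stop("tau_reduction must be positive", call. = FALSE)
  structure(list(threshold = threshold, ue_multiplier = ue_multiplier,
                 tau_reduction = tau_reduction, enabled = isTRUE(enabled),
                 engaged = FALSE), class = "gabab_gate")
}

#' Update the GABA-B gate
#'
#' Applies the engagement rule; idempotent once engaged.
#'
#' @param g a [gabab_gate()]. @param y26 current GABA accumulation (A.U.).
#' @param stim_on logical, train currently on.
#' @param rtn1,rtn2 [stp_state()]s of the two reticular connections.
#' @param tonic a [tonic_state()].
#' @return list with updated `gate`, `rtn1`, `rtn2`, `tonic`.
#' @export
gabab_gate_update <- function(g, y26, stim_on, rtn1, rtn2, tonic) {
  if (g$enabled && isTRUE(stim_on) && !g$engaged && y26 > g$threshold) {
    g$engaged <- TRUE
    rtn1$ue <- min(1, rtn1$ue * g$ue_multiplier)
    rtn2$ue <- min(1, rtn2$ue * g$ue_multiplier)
    tonic$tau_IE <- tonic$tau_IE / g$tau_reduction
  }
  list(gate = g, rtn1 = rtn1, rtn2 = rtn2, tonic = tonic)
}
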