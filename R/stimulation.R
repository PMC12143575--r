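#' Stimulation protocol
#'
#' Describes one stimulation run: pulse frequency, train onset and duration,
#' per-subpopulation coupling coefficients (the lambda-E model: the membrane
#' polarisation induced by the extracellular field is proportional to the
#' local field magnitude, which decays with distance from the stimulated
#' nucleus, hence a larger coefficient for TC than for the reticular masses),
#' and whether the presynaptic GABA-B gate may engage.
#'
#' @param frequency pulse frequency (Hz); 0 means no stimulation.
#' @param onset train onset (s). @param duration train duration (s).
#' @param coupling named list of coupling coefficients for `TC`, `RtN1`,
#'   `RtN2` (A.U.).
#' @param gabab_enabled logical; engage the presynaptic GABA-B gate when GABA
#'   accumulation crosses its threshold (used at 150 Hz).
#' @return object of class `stim_protocol`.
#' @export
#' @examples
#' stim_protocol(100)
stim_protocol <- function(frequency, onset = 5, duration = 5,
                          coupling = default_params()$stim_coupling,
                          gabab_enabled = (frequency >= 150)) {
  stopifnot(is.numeric(frequency), length(frequency) == 1, frequency >= 0,
            onset >= 0, duration > 0)
  for (nm in c("TC", "RtN1", "RtN2"))
    if (is.null(coupling[[nm]]))
      stop("stimulation coupling map must cover ", nm, call. = FALSE)
  if (coupling$TC < coupling$RtN1 || coupling$TC < coupling$RtN2)
    stop("coupling[TC] must be >= coupling[RtN1] and coupling[RtN2]",
         call. = FALSE)
  structure(list(frequency = frequency, onset = onset, duration = duration,
                 coupling = coupling, gabab_enabled = isTRUE(gabab_enabled)),
            class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("<stim_protocol> %g Hz, train %g-%g s, coupling TC=%g RtN1=%g RtN2=%g, GABA-B gate %s\n",
              x$frequency, x$onset, x$onset + x$duration,
              x$coupling$TC, x$coupling$RtN1, x$coupling$RtN2,
              if (x$gabab_enabled) "enabled" else "disabled"))
  invisible(x)
}

# one RC-distorted biphasic cycle sampled at dt, normalised to peak `amplitude`.
# The square core is +A for pulse_width, a zero inter-phase plateau of
# updown_time, then -A for pulse_width; edges are shaped by a first-order
# filter that charges with rise_tau and relaxes with decay_tau (the
# electrode-tissue interface behaves as an RC circuit). The template is the
# periodic steady state (filtered over repeated cycles).
stim_cycle_template <- function(shape, period, dt) {
  n <- max(2L, round(period / dt))
  tt <- (seq_len(n) - 1) * dt
  core <- numeric(n)
  core[tt < shape$pulse_width] <- -1
  core[tt >= shape$pulse_width + shape$updown_time &
       tt < 2 * shape$pulse_width + shape$updown_time] <- 1
  y <- 0
  out <- numeric(n)
  for (rep in 1:4) { # iterate to periodic steady state
    for (i in seq_len(n)) {
      tau <- if (abs(core[i]) > abs(y)) shape$rise_tau else shape$decay_tau
      y <- y + dt * (core[i] - y) / tau
      out[i] <- y
    }
  }
  pk <- max(abs(out))
  if (pk <= 0) stop("degenerate stimulation pulse shape", call. = FALSE)
  out * shape$amplitude / pk
}

#' Stimulation waveform
#'
#' Value of the RC-distorted biphasic pulse train at times `t`: zero outside
#' the train, periodic at the protocol frequency inside it, with peak
#' magnitude equal to the configured amplitude. Deterministic.
#'
#' @param t time (s), vectorised.
#' @param shape pulse shape list (see `default_params()$stim_shape`).
#' @param proto a [stim_protocol()].
#' @param dt sampling resolution of the internal template (s).
#' @return waveform values (A.U.), same length as `t`.
#' @export
stim_waveform <- function(t, shape = default_params()$stim_shape, proto,
                          dt = 1e-5) {
  stopifnot(all(t >= 0))
  if (proto$frequency <= 0) return(numeric(length(t)))
  period <- 1 / proto$frequency
  if (2 * shape$pulse_width + shape$updown_time >= period)
    stop("stimulation period too short for the biphasic cycle", call. = FALSE)
  tpl <- stim_cycle_template(shape, period, dt)
  on <- stim_gate(t, proto) == 1
  out <- numeric(length(t))
  phase <- (t[on] - proto$onset) %% period
  idx <- pmin(length(tpl), floor(phase / dt) + 1L)
  out[on] <- tpl[idx]
  out
}

#' Stimulation gate
#'
#' 1 while the train is on (half-open interval `[onset, onset + duration)`),
#' 0 otherwise. This is the `stim` variable that gates the short-term
#' plasticity and GABA accumulation dynamics.
#'
#' @param t time (s), vectorised. @param proto a [stim_protocol()].
#' @return integer vector of 0/1.
#' @export
stim_gate <- function(t, proto) {
  if (proto$frequency <= 0) return(integer(length(t)))
  as.integer(t >= proto$onset & t < proto$onset + proto$duration)
}

#' Per-subpopulation stimulation inputs
#'
#' Applies the lambda-E coupling map to a waveform value: each thalamic
#' subpopulation receives `coupling * waveform`, added to its PSP sum before
#' the sigmoid.
#'
#' @param value waveform value(s) (A.U.). @param proto a [stim_protocol()].
#' @return named list of additive pre-sigmoid inputs for `TC`, `RtN1`, `RtN2`.
#' @export
apply_coupling <- function(value, proto) {
  for (nm in c("TC", "RtN1", "RtN2"))
    if (is.null(proto$coupling[[nm]]))
      stop("stimulation coupling map must cover ", nm, call. = FALSE)
  lapply(proto$coupling[c("TC", "RtN1", "RtN2")], function(co) co * value)
}
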