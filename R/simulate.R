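trace_names <- function() {
  c(paste0("y_", subpop_names()), paste0("fr_", subpop_names()),
    "lfp", "lfp_th", "ACd", "GTh", "BTh", "y26", "y11", "stim")
}

# assemble the flat parameter list consumed by the compiled core
core_pars <- function(p, gate_enabled, threshold) {
  sp <- p$subpopulations
  nm <- subpop_names()
  sig_of <- function(n, field) {
    ov <- sp[[n]]$sigmoid
    if (!is.null(ov) && !is.null(ov[[field]])) ov[[field]] else p$sigmoid[[field]]
  }
  list(
    W = vapply(nm, function(n) sp[[n]]$W, 0),
    w = vapply(nm, function(n) sp[[n]]$w, 0),
    e0 = vapply(nm, function(n) sig_of(n, "e0"), 0),
    v0 = vapply(nm, function(n) sig_of(n, "v0"), 0),
    r  = vapply(nm, function(n) sig_of(n, "r"), 0),
    sigmoid = p$sigmoid,
    couplings = p$couplings,
    stp = p$stp,
    tonic = p$tonic,
    gate = list(enabled = isTRUE(gate_enabled),
                threshold = as.numeric(threshold),
                ue_multiplier = p$gate$ue_multiplier,
                tau_reduction = p$gate$tau_reduction),
    lfp = p$lfp,
    stim_coupling = p$stim_coupling,
    noise_mean = c(p$noise$PYR1$mean, p$noise$PYR2$mean, p$noise$TC$mean),
    noise_sd = c(p$noise$PYR1$sd, p$noise$PYR2$sd, p$noise$TC$sd)
  )
}

# seeded standard-normal increments shared by every run of one experiment
noise_matrix <- function(n_total, seed) {
  set.seed(as.integer(seed))
  matrix(stats::rnorm(n_total * 3L), ncol = 3L)
}

#' Reference GABA-B engagement threshold
#'
#' The presynaptic GABA-B gate engages when extrasynaptic GABA accumulation
#' exceeds a threshold. The default threshold is the maximum accumulation
#' attained during a reference 100 Hz run with the gate disabled and the same
#' seed, so that at higher stimulation frequencies — where accumulation grows
#' faster — the threshold is crossed while the train is still on.
#'
#' @param params model parameters. @param seed integer RNG seed.
#' @return threshold (A.U.).
#' @export
gabab_threshold <- function(params = default_params(), seed = 1) {
  ref <- run_protocol(params, stim_protocol(100, gabab_enabled = FALSE),
                      seed = seed)
  max(ref$traces[, "y26"])
}

#' Run one stimulation protocol
#'
#' Integrates the full stochastic thalamocortical model with the fixed-step
#' Euler–Maruyama scheme (default dt = 1e-4 s, resolving the 0.5 ms pulse and
#' the fastest synaptic kinetics), after a discarded warm-up transient, and
#' records all traces at the output rate. The per-step update order is fixed:
#' stimulation waveform, total inputs and firing rates of both compartments
#' (delayed couplings read from ring buffers), PSP state update, short-term
#' plasticity, GABA accumulation and tonic IPSP, GABA-B gate check, delay
#' buffer push.
#'
#' Runs with the same parameters, protocol and seed are bit-identical;
#' changing only `fs_out` never changes the underlying trajectory.
#'
#' @param params parameter list (see [default_params()]); validated.
#' @param proto a [stim_protocol()]; use `stim_protocol(0)` for an
#'   unstimulated run.
#' @param seed integer seed for the noise stream.
#' @param duration,warmup recorded horizon and discarded warm-up (s);
#'   defaults from `params$integration`.
#' @param kappa scaling factor applied to the TC->PYR coupling (1 = intact).
#' @param clamp_drive if non-NULL, the neocortex sees this constant thalamic
#'   relay PSP (mV) instead of the simulated one (used for regime probing and
#'   cross-checks).
#' @param noise optional pre-generated standard-normal increment matrix
#'   (n_steps x 3); used by the battery to share one noise path.
#' @return object of class `tc_simulation`: `time` (s), `traces` (matrix with
#'   named columns: per-subpopulation PSPs `y_*` and firing rates `fr_*`,
#'   `lfp`, `lfp_th`, dynamic gain ratios `ACd`, `GTh`, `BTh`, GABA
#'   accumulation `y26`, tonic IPSP `y11`, normalised `ThGABA`, `stim`),
#'   `proto`, `seed`, `fs`, `dt`, `gate` (engagement info).
#' @export
#' @examples
#' \donttest{
#' p <- default_params()
#' p$integration$warmup <- 2; p$integration$duration <- 4
#' sim <- run_protocol(p, stim_protocol(0), seed = 1)
#' str(sim$time)
#' }
run_protocol <- function(params = default_params(), proto = stim_protocol(0),
                         seed = 1, duration = NULL, warmup = NULL, kappa = 1,
                         clamp_drive = NULL, noise = NULL) {
  validate_params(params)
  stopifnot(inherits(proto, "stim_protocol"))
  intg <- params$integration
  dt <- intg$dt
  if (is.null(duration)) duration <- intg$duration
  if (is.null(warmup)) warmup <- intg$warmup
  warm_steps <- round(warmup / dt)
  n_main <- round(duration / dt)
  n_total <- warm_steps + n_main
  stride <- max(1L, as.integer(round(1 / (dt * intg$fs_out))))

  threshold <- params$gate$threshold
  if (proto$gabab_enabled && !is.finite(threshold))
    threshold <- gabab_threshold(params, seed)
  if (!is.finite(threshold)) threshold <- Inf

  # stimulation sampled on the step grid; time origin at the end of warm-up
  tgrid <- (seq_len(n_total) - 1 - warm_steps) * dt
  gate01 <- integer(n_total)
  wave <- numeric(n_total)
  if (proto$frequency > 0) {
    main <- tgrid >= 0
    gate01[main] <- stim_gate(tgrid[main], proto)
    on <- gate01 == 1L
    if (any(on)) wave[on] <- stim_waveform(tgrid[on], params$stim_shape, proto,
                                           dt = min(dt, 1e-5))
  }

  if (is.null(noise)) noise <- noise_matrix(n_total, seed)
  if (nrow(noise) < n_total) stop("noise matrix shorter than the run", call. = FALSE)

  cp <- core_pars(params, proto$gabab_enabled, threshold)
  ctl <- list(dt = dt, n_total = as.integer(n_total),
              warm_steps = as.integer(warm_steps), stride = stride,
              delay_ct_steps = as.integer(round(params$delays$ncx_to_th / dt)),
              delay_tc_steps = as.integer(round(params$delays$tc_to_ncx / dt)),
              kappa = kappa,
              clamp_drive = !is.null(clamp_drive),
              clamp_value = if (is.null(clamp_drive)) 0 else clamp_drive)
  res <- simulate_core_cpp(cp, wave, gate01, noise, ctl)
  tr <- res$traces[seq_len(res$n_rec), , drop = FALSE]
  colnames(tr) <- trace_names()
  tr <- cbind(tr, ThGABA = pmin(1, tr[, "y26"] / params$tonic$norm))
  structure(list(
    time = (seq_len(nrow(tr)) - 1) * stride * dt,
    traces = tr,
    proto = proto, seed = seed, fs = 1 / (stride * dt), dt = dt,
    kappa = kappa, clamp_drive = clamp_drive,
    gate = list(enabled = proto$gabab_enabled, threshold = threshold,
                engaged = res$engaged, engage_time = res$engage_time)
  ), class = "tc_simulation")
}

#' @export
print.tc_simulation <- function(x, ...) {
  cat(sprintf("<tc_simulation> %.0f s at %g Hz output, %g Hz stimulation, seed %s\n",
              max(x$time), x$fs, x$proto$frequency, format(x$seed)))
  if (x$gate$enabled)
    cat(sprintf("  GABA-B gate: threshold %.4g, %s\n", x$gate$threshold,
                if (x$gate$engaged) sprintf("engaged at %.2f s", x$gate$engage_time)
                else "not engaged"))
  invisible(x)
}

#' Run the stimulation-frequency battery
#'
#' Runs one protocol per frequency with an identical noise path (same seed,
#' same pre-generated increments), so that runs differ only in the
#' stimulation, enabling paired comparison of suppression across frequencies.
#' The presynaptic GABA-B gate is enabled only at frequencies >= `gate_from`.
#'
#' @param params model parameters. @param freqs frequencies (Hz).
#' @param seed integer seed. @param gate_from lowest frequency (Hz) at which
#'   the GABA-B gate is enabled (default 150).
#' @param ... passed to [run_protocol()].
#' @return named list of `tc_simulation`, keyed by frequency.
#' @export
run_frequency_battery <- function(params = default_params(),
                                  freqs = c(50, 70, 100, 150), seed = 1,
                                  gate_from = 150, ...) {
  validate_params(params)
  intg <- params$integration
  n_total <- round((intg$warmup + intg$duration) / intg$dt)
  noise <- noise_matrix(n_total, seed)
  thr <- params$gate$threshold
  if (any(freqs >= gate_from) && !is.finite(thr)) {
    ref <- run_protocol(params, stim_protocol(100, gabab_enabled = FALSE),
                        seed = seed, noise = noise)
    thr <- max(ref$traces[, "y26"])
    params$gate$threshold <- thr
  }
  out <- lapply(freqs, function(f) {
    run_protocol(params,
                 stim_protocol(f, gabab_enabled = (f >= gate_from)),
                 seed = seed, noise = noise, ...)
  })
  names(out) <- as.character(freqs)
  out
}
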