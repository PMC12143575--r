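#' Default model parameter set
#'
#' Returns the full nested parameter list describing the thalamocortical
#' model: per-subpopulation synaptic kinetics and sigmoid constants,
#' connectivity coupling constants, short-term plasticity (STP) constants for
#' the three plastic connections, extrasynaptic tonic-inhibition constants,
#' the presynaptic GABA-B gate settings, stimulation waveform shape, noise,
#' transmission delays and integration settings.
#'
#' The neocortical compartment follows the classical neural-mass lineage:
#' excitatory kinetics \eqn{W \approx 3.25} mV, \eqn{w = 100} 1/s; slow
#' (dendritic, SST-like) inhibition \eqn{W = 22} mV, \eqn{w = 50} 1/s; fast
#' (somatic, PV-like) inhibition \eqn{W = 10} mV, \eqn{w = 500} 1/s, with the
#' recurrent pyramidal pair and coupling constants scaled from the classical
#' C = 135 set. Thalamic and stimulation constants were calibrated so that the
#' shipped defaults reproduce the target phenomenology: ~3-4 Hz interictal
#' spike-wave discharges driven by the thalamocortical relay PSP, and
#' frequency-dependent suppression of those discharges by 5 s stimulation
#' trains (see the package vignette for the calibration rationale).
#'
#' @return A nested list with sections `sigmoid`, `subpopulations`,
#'   `couplings`, `stp`, `tonic`, `gate`, `stim_shape`, `stim_coupling`,
#'   `noise`, `delays`, `lfp`, `integration`.
#' @export
#' @examples
#' p <- default_params()
#' names(p)
#' p$subpopulations$TC
default_params <- function() {
  list(
    sigmoid = list(e0 = 2.5, v0 = 6, r = 0.56),
    # per-subpopulation output synaptic kinetics: W (mV), w (1/s), role
    subpopulations = list(
      PYR1 = list(W = 3.6,   w = 110, role = "glutamatergic"),
      PYR2 = list(W = 3.6,   w = 110, role = "glutamatergic"),
      PV   = list(W = 11,    w = 550, role = "GABAergic"),
      SSTa = list(W = 24.2,  w = 55,  role = "GABAergic"),
      SSTb = list(W = 17.6,  w = 40,  role = "GABAergic"),
      VIP  = list(W = 22,    w = 55,  role = "GABAergic"),
      NGFC = list(W = 22,    w = 33,  role = "GABAergic"),
      # the relay population has a steeper activation curve (relay-mode
      # gating) and the reticular masses a raised activation threshold
      # (burst-like recruitment only by strong synchronous drive)
      TC   = list(W = 3.25,  w = 100, role = "glutamatergic",
                  sigmoid = list(e0 = 2.5, v0 = 0.7, r = 2.5)),
      RtN1 = list(W = 10,    w = 350, role = "GABAergic",
                  sigmoid = list(e0 = 2.5, v0 = 8, r = 0.56)),
      RtN2 = list(W = 15,    w = 30,  role = "GABAergic",
                  sigmoid = list(e0 = 2.5, v0 = 8, r = 0.56))
    ),
    # coupling constants, named <source>_<target>
    couplings = list(
      # neocortex: recurrent excitation (pyramidal pair)
      PYR2_PYR1 = 108, PYR1_PYR2 = 135,
      # pyramidal drive to interneurons
      PYR1_PV = 40.5, PYR1_SSTa = 33.75, PYR1_SSTb = 33.75, PYR1_VIP = 10,
      # inhibition onto pyramidal cells (apical: SSTa, NGFC; basal: PV, SSTb)
      PV_PYR1 = 70, SSTa_PYR1 = 16.875, SSTb_PYR1 = 16.875, NGFC_PYR1 = 1,
      # VIP-SST mutual inhibition and disinhibitory edges
      VIP_SSTa = 5, VIP_SSTb = 5, SSTa_VIP = 5, SSTa_PV = 13.5, NGFC_VIP = 2,
      # PV-PV present in the wiring but fixed to zero
      PV_PV = 0,
      # thalamocortical: relay drive to PYR (plastic, ACd) and FFI targets
      TC_PYR1 = 17.3, TC_PV = 3.5, TC_SSTa = 1.7, TC_SSTb = 1.7, TC_NGFC = 3.5,
      # corticothalamic feedback (delayed) and FFI onto reticular masses
      PYR1_TC = 2, PYR1_RtN1 = 2, PYR1_RtN2 = 2,
      # intrathalamic loop
      TC_TC = 6, TC_RtN1 = 1, TC_RtN2 = 1,
      RtN1_TC = 10, RtN2_TC = 0.8,
      # tonic IPSP pathway onto TC
      tonic_TC = 33
    ),
    # Tsodyks-Markram constants of the three plastic connections
    stp = list(
      ACd = list(ue = 0.5,  tau_f = 0.10, tau_d = 0.10, enabled = TRUE), # TC->PYR STD
      GTh = list(ue = 0.1,  tau_f = 0.02, tau_d = 0.02, enabled = TRUE), # RtN1->TC STD
      BTh = list(ue = 0.2,  tau_f = 4.00, tau_d = 0.40, enabled = TRUE)  # RtN2->TC STF
    ),
    # extrasynaptic GABA accumulation and tonic IPSP
    tonic = list(
      ET = 0.125,    # tonic gain (mV per A.U.), 100% level of the ablation study
      eT = 3,        # tonic rate constant (1/s)
      tau_IE = 12,   # GABA reuptake time constant (s)
      c1 = 0.02,     # weight of the fast-kinetics (RtN1) firing in phiRtN
      c2 = 0.22,     # weight of the slow-kinetics (RtN2) firing in phiRtN
      norm = 1.25    # normalisation for the exported ThGABA trace
    ),
    # presynaptic GABA-B self-inhibition gate (engaged at high frequency)
    gate = list(
      ue_multiplier = 50,
      tau_reduction = 3.5,
      threshold = NA_real_  # NA: computed from a reference 100 Hz run
    ),
    # biphasic pulse shape (RC-distorted at the electrode-tissue interface)
    stim_shape = list(
      rise_tau = 0.001, decay_tau = 0.0048, updown_time = 0.001,
      pulse_width = 0.0005, amplitude = 3.2
    ),
    # lambda-E coupling of the stimulation field to the thalamic masses
    stim_coupling = list(TC = 4, RtN1 = 4, RtN2 = 4),
    # firing-rate input noise to the excitatory masses:
    # mean (pulses/s) and diffusion sigma (pulses/s per sqrt(s))
    noise = list(
      PYR1 = list(mean = 0,    sd = 0),
      PYR2 = list(mean = 0.20, sd = 0.005),
      TC   = list(mean = 3.7,  sd = 0.015)
    ),
    delays = list(tc_to_ncx = 0.012, ncx_to_th = 0.012), # s
    lfp = list(apical_weight = 1, basal_weight = 1),
    integration = list(dt = 1e-4, warmup = 10, duration = 60, fs_out = 500)
  )
}

subpop_names <- function() {
  c("PYR1", "PYR2", "PV", "SSTa", "SSTb", "VIP", "NGFC", "TC", "RtN1", "RtN2")
}

#' Validate a model parameter list
#'
#' Checks structural completeness (every section and key of
#' [default_params()] present, no unknown keys) and the physical invariants:
#' positive rate constants and time constants, nonnegative gains and
#' couplings, `0 < ue <= 1`, fast reticular kinetics faster than slow
#' (`w_RtN1 > w_RtN2`), stimulation coupling on TC at least as large as on the
#' reticular masses, and a pulse shape compatible with a 150 Hz train.
#'
#' @param p parameter list shaped like [default_params()].
#' @return `p`, invisibly, if valid; otherwise an error naming the offending
#'   key.
#' @export
validate_params <- function(p) {
  ref <- default_params()
  chk_keys <- function(x, r, path) {
    if (!is.list(x)) stop("config section '", path, "' must be a list", call. = FALSE)
    unknown <- setdiff(names(x), names(r))
    # every subpopulation may carry an optional sigmoid override
    if (grepl("^params\\$subpopulations\\$", path))
      unknown <- setdiff(unknown, "sigmoid")
    if (length(unknown) > 0)
      stop("unknown config key: ", path, "$", unknown[1], call. = FALSE)
    missing <- setdiff(names(r), names(x))
    if (length(missing) > 0)
      stop("missing config key: ", path, "$", missing[1], call. = FALSE)
    for (nm in names(r)) {
      if (is.list(r[[nm]]) && !identical(nm, "threshold"))
        chk_keys(x[[nm]], r[[nm]], paste0(path, "$", nm))
    }
  }
  chk_keys(p, ref, "params")
  pos <- function(val, key) {
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val) || val <= 0)
      stop("parameter '", key, "' must be a positive finite number", call. = FALSE)
  }
  nonneg <- function(val, key) {
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val) || val < 0)
      stop("parameter '", key, "' must be a nonnegative finite number", call. = FALSE)
  }
  pos(p$sigmoid$e0, "sigmoid$e0"); pos(p$sigmoid$r, "sigmoid$r")
  for (nm in subpop_names()) {
    sp <- p$subpopulations[[nm]]
    nonneg(sp$W, paste0(nm, "$W")); pos(sp$w, paste0(nm, "$w"))
    if (!is.null(sp$sigmoid)) {
      pos(sp$sigmoid$e0, paste0(nm, "$sigmoid$e0"))
      pos(sp$sigmoid$r, paste0(nm, "$sigmoid$r"))
      if (!is.numeric(sp$sigmoid$v0))
        stop("subpopulation '", nm, "' sigmoid override needs v0", call. = FALSE)
    }
    if (!sp$role %in% c("glutamatergic", "GABAergic"))
      stop("subpopulation '", nm, "' has unknown role '", sp$role, "'", call. = FALSE)
  }
  for (nm in names(p$couplings)) nonneg(p$couplings[[nm]], paste0("couplings$", nm))
  if (p$couplings$PV_PV != 0)
    stop("couplings$PV_PV is fixed to zero in this model", call. = FALSE)
  for (nm in c("ACd", "GTh", "BTh")) {
    s <- p$stp[[nm]]
    pos(s$ue, paste0("stp$", nm, "$ue")); pos(s$tau_f, paste0("stp$", nm, "$tau_f"))
    pos(s$tau_d, paste0("stp$", nm, "$tau_d"))
    if (s$ue > 1) stop("stp$", nm, "$ue must be <= 1", call. = FALSE)
  }
  if (p$subpopulations$RtN1$w <= p$subpopulations$RtN2$w)
    stop("RtN1 kinetics must be faster than RtN2 (w_RtN1 > w_RtN2)", call. = FALSE)
  nonneg(p$tonic$ET, "tonic$ET"); pos(p$tonic$eT, "tonic$eT")
  pos(p$tonic$tau_IE, "tonic$tau_IE")
  nonneg(p$tonic$c1, "tonic$c1"); nonneg(p$tonic$c2, "tonic$c2")
  pos(p$tonic$norm, "tonic$norm")
  pos(p$gate$ue_multiplier, "gate$ue_multiplier")
  pos(p$gate$tau_reduction, "gate$tau_reduction")
  sh <- p$stim_shape
  for (nm in c("rise_tau", "decay_tau", "updown_time", "pulse_width", "amplitude"))
    pos(sh[[nm]], paste0("stim_shape$", nm))
  if (p$stim_coupling$TC < p$stim_coupling$RtN1 ||
      p$stim_coupling$TC < p$stim_coupling$RtN2)
    stop("stim_coupling$TC must be >= the reticular coupling coefficients",
         call. = FALSE)
  for (nm in names(p$noise)) {
    nonneg(p$noise[[nm]]$sd, paste0("noise$", nm, "$sd"))
    nonneg(p$noise[[nm]]$mean, paste0("noise$", nm, "$mean"))
  }
  nonneg(p$delays$tc_to_ncx, "delays$tc_to_ncx")
  nonneg(p$delays$ncx_to_th, "delays$ncx_to_th")
  pos(p$integration$dt, "integration$dt")
  nonneg(p$integration$warmup, "integration$warmup")
  pos(p$integration$duration, "integration$duration")
  pos(p$integration$fs_out, "integration$fs_out")
  invisible(p)
}

# deep-merge user overrides into defaults (unknown keys caught by validate)
merge_params <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- merge_params(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a run configuration from a YAML file
#'
#' Reads a (possibly partial) YAML configuration, fills unspecified values
#' from [default_params()], validates the result and attaches provenance (the
#' file's MD5 hash).
#'
#' @param path path to a YAML file whose top-level keys are a subset of the
#'   sections of [default_params()].
#' @return A validated parameter list with attribute `provenance`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  p <- merge_params(default_params(), user)
  validate_params(p)
  attr(p, "provenance") <- list(file = path, md5 = unname(tools::md5sum(path)))
  p
}
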