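#' Two-monopole LFP proxy
#'
#' Approximates the field potential at an SEEG contact from the synaptic
#' currents on the pyramidal population: synaptic activation at apical and at
#' basal dendrites creates current sinks/sources of opposite orientation, so
#' the proxy is the weighted difference of the two dendritic PSP sums,
#' `LFP = apical_weight * apical - basal_weight * basal`. Linear in both
#' arguments.
#'
#' @param apical,basal summed PSP contributions (mV) at the apical and basal
#'   compartments of the pyramidal population.
#' @param m list with `apical_weight` and `basal_weight`.
#' @return LFP (mV), vectorised.
#' @export
lfp_proxy <- function(apical, basal, m = default_params()$lfp) {
  m$apical_weight * apical - m$basal_weight * basal
}

# linear input matrix of the neocortical subsystem: row i = target mass,
# column j = source mass; entry = signed coupling of y_j into v_i. The
# TC->PYR entry is not here (the drive is a parameter of the subsystem).
ncx_input_matrix <- function(p, kappa = 1) {
  cp <- p$couplings
  M <- matrix(0, 7, 7,
              dimnames = list(subpop_names()[1:7], subpop_names()[1:7]))
  M["PYR1", "PYR2"] <- cp$PYR2_PYR1
  M["PYR1", "PV"]   <- -cp$PV_PYR1
  M["PYR1", "SSTa"] <- -cp$SSTa_PYR1
  M["PYR1", "SSTb"] <- -cp$SSTb_PYR1
  M["PYR1", "NGFC"] <- -cp$NGFC_PYR1
  M["PYR2", "PYR1"] <- cp$PYR1_PYR2
  M["PV", "PYR1"]   <- cp$PYR1_PV
  M["PV", "SSTa"]   <- -cp$SSTa_PV
  M["PV", "PV"]     <- -cp$PV_PV
  M["SSTa", "PYR1"] <- cp$PYR1_SSTa
  M["SSTa", "VIP"]  <- -cp$VIP_SSTa
  M["SSTb", "PYR1"] <- cp$PYR1_SSTb
  M["SSTb", "VIP"]  <- -cp$VIP_SSTb
  M["VIP", "PYR1"]  <- cp$PYR1_VIP
  M["VIP", "SSTa"]  <- -cp$SSTa_VIP
  M["VIP", "NGFC"]  <- -cp$NGFC_VIP
  M
}

# constant drive vector: contribution of the thalamic relay PSP `y6` to each
# neocortical mass (TC->PYR scaled by kappa)
ncx_drive_vector <- function(p, kappa = 1) {
  cp <- p$couplings
  c(PYR1 = kappa * cp$TC_PYR1, PYR2 = 0, PV = cp$TC_PV, SSTa = cp$TC_SSTa,
    SSTb = cp$TC_SSTb, VIP = 0, NGFC = cp$TC_NGFC)
}

#' Noise-free neocortical vector field
#'
#' Returns the 14-dimensional vector field of the isolated neocortical
#' compartment (PSP pairs of the seven masses) with the thalamic relay PSP
#' held constant at `y6` and the TC->PYR branch scaled by `kappa`. The slow
#' thalamic quantities change on a much longer timescale than the cortical
#' dynamics, which justifies freezing them as bifurcation parameters.
#'
#' @param params model parameters. @param y6 constant thalamic relay PSP
#'   (mV). @param kappa STD scaling factor on the TC->PYR connection.
#' @return function `f(x)` mapping a state vector `c(y[1:7], z[1:7])` to its
#'   time derivative.
#' @export
ncx_field <- function(params = default_params(), y6 = 0.26, kappa = 1) {
  cp <- core_pars(params, FALSE, Inf)
  force(y6); force(kappa)
  function(x) ncx_field_cpp(x, cp, y6, kappa)
}

# reduced equilibrium map F(y) = y - (W/w) * (S(M y + b) + mean_input);
# roots are the PSP components of neocortical equilibria
ncx_reduced <- function(params, y6, kappa) {
  sp <- params$subpopulations
  nm <- subpop_names()[1:7]
  W <- vapply(nm, function(n) sp[[n]]$W, 0)
  w <- vapply(nm, function(n) sp[[n]]$w, 0)
  M <- ncx_input_matrix(params, kappa)
  M["PYR1", ] <- M["PYR1", ] # kappa only scales the drive entry
  b <- ncx_drive_vector(params, kappa) * y6
  m_in <- c(params$noise$PYR1$mean, params$noise$PYR2$mean, 0, 0, 0, 0, 0)
  sig <- params$sigmoid
  list(
    F = function(y) {
      v <- drop(M %*% y) + b
      y - (W / w) * (wave_to_pulse(v, sig) + m_in)
    },
    J = function(y) {
      v <- drop(M %*% y) + b
      diag(7) - ((W / w) * wave_to_pulse_deriv(v, sig)) * M
    },
    full_jacobian = function(y) {
      v <- drop(M %*% y) + b
      D <- (W * w * wave_to_pulse_deriv(v, sig)) * M
      rbind(cbind(matrix(0, 7, 7), diag(7)),
            cbind(-diag(w^2) + D, diag(-2 * w)))
    },
    W = W, w = w, M = M, b = b, m_in = m_in, sig = sig
  )
}
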