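#' Parameters of the calcium-based plasticity model
#'
#' Constructs the full parameter set of the bistable synaptic-efficacy model
#' and its calcium dynamics. Defaults follow the published model: efficacy
#' time constant `tau_rho = 70` s, unstable fixed point `rho_star = 0.5`,
#' depression/potentiation rates `gamma_d = 101.5`, `gamma_p = 216.2`,
#' unbuffered-calcium fraction `eta = 0.04`, calcium clearance
#' `tau_ca = 12` ms, NMDA reversal `E_nmda = -3` mV, magnesium-block
#' parameters `theta = 2.552`, `kappa = 0.072` (cortical refit of the
#' Jahr-Stevens formalism), calcium-integrator time constant
#' `tau_star = 278.318` ms and conversion time constant `tau_change = 100` s.
#'
#' Calcium is tracked in uM. The resting value defaults to 0.07 uM; the
#' printed source value of 70 pM (1000x smaller) can be requested via
#' `ca_rest` but sits far below typical resting calcium, so the uM-scale
#' default is used. All values are plain numbers so any of them can be
#' overridden.
#'
#' The threshold matrices `theta_apical` and `theta_basal` map per-synapse
#' single-spike calcium peaks `(c_pre, c_post)` to the depression and
#' potentiation thresholds `(theta_d, theta_p)` on the integrated-calcium
#' variable. The fitted constants of the source model are not public;
#' shipped defaults were produced by [calibrate_threshold_matrix()] with the
#' default [driver_kernels()] so that a lone presynaptic spike crosses
#' neither threshold, a coincident pre+post pair crosses only the depression
#' threshold, and repeated coincident volleys cross the potentiation
#' threshold.
#'
#' @param tau_rho efficacy time constant, s.
#' @param rho_star unstable fixed point of the efficacy dynamics.
#' @param gamma_d,gamma_p depression and potentiation rates.
#' @param eta fraction of unbuffered calcium.
#' @param faraday Faraday constant, C/mol.
#' @param spine_volume spine volume, um^3.
#' @param ca_rest resting intracellular calcium, uM.
#' @param tau_ca free-calcium clearance time constant, ms.
#' @param E_nmda NMDA reversal potential, mV.
#' @param mg_theta,mg_kappa magnesium-block scaling and voltage slope.
#' @param mg_out extracellular magnesium, mM.
#' @param tau_star time constant of the leaky calcium integrator, ms.
#' @param tau_change conversion time constant for U_SE and g_AMPA, s.
#' @param theta_apical,theta_basal 2x2 threshold matrices (rows theta_d,
#'   theta_p; columns c_pre, c_post) for apical and basal synapses.
#' @param use_d,use_p fully depressed / potentiated release probability
#'   (`U_SE`) endpoints.
#' @param g_ampa_d,g_ampa_p fully depressed / potentiated peak AMPA
#'   conductance endpoints, nS.
#' @param use_ca_scale multiplicative scale applied to the `U_SE` endpoints
#'   (stand-in for extracellular-calcium modulation of release).
#' @return A `plasticity_params` list.
#' @export
plasticity_params <- function(tau_rho = 70, rho_star = 0.5,
                              gamma_d = 101.5, gamma_p = 216.2,
                              eta = 0.04, faraday = 96485,
                              spine_volume = 0.1, ca_rest = 0.07,
                              tau_ca = 12, E_nmda = -3,
                              mg_theta = 2.552, mg_kappa = 0.072,
                              mg_out = 1.0, tau_star = 278.318,
                              tau_change = 100,
                              theta_apical = NULL, theta_basal = NULL,
                              use_d = 0.2, use_p = 0.7,
                              g_ampa_d = 0.4, g_ampa_p = 1.2,
                              use_ca_scale = 1.0) {
  stopifnot(tau_rho > 0, tau_ca > 0, tau_star > 0, tau_change > 0,
            gamma_d > 0, gamma_p > 0, rho_star > 0, rho_star < 1,
            eta > 0, spine_volume > 0, use_d <= use_p, g_ampa_d <= g_ampa_p)
  if (is.null(theta_apical)) theta_apical <- .default_theta_matrix()
  if (is.null(theta_basal)) theta_basal <- .default_theta_matrix()
  for (m in list(theta_apical, theta_basal))
    if (!is.matrix(m) || any(dim(m) != 2L))
      stop("threshold matrices must be 2x2")
  p <- list(tau_rho = tau_rho, rho_star = rho_star, gamma_d = gamma_d,
            gamma_p = gamma_p, eta = eta, faraday = faraday,
            spine_volume = spine_volume, ca_rest = ca_rest, tau_ca = tau_ca,
            E_nmda = E_nmda, mg_theta = mg_theta, mg_kappa = mg_kappa,
            mg_out = mg_out, tau_star = tau_star, tau_change = tau_change,
            theta_apical = theta_apical, theta_basal = theta_basal,
            use_d = use_d * use_ca_scale, use_p = use_p * use_ca_scale,
            g_ampa_d = g_ampa_d, g_ampa_p = g_ampa_p)
  class(p) <- "plasticity_params"
  p
}

# Defaults frozen from calibrate_threshold_matrix() with default kernels
# (see the methods vignette). Rows: theta_d, theta_p; cols: c_pre, c_post.
.default_theta_matrix <- function() {
  matrix(c(61.9217, 169.4265,
           302.0243, 826.3813), nrow = 2, byrow = TRUE,
         dimnames = list(c("theta_d", "theta_p"), c("c_pre", "c_post")))
}

#' Reduced dendritic voltage / conductance driver kernels
#'
#' The morphologically detailed voltage of the source model is replaced by a
#' per-synapse kernel model: a presynaptic spike opens a double-exponential
#' NMDA conductance and deposits a local EPSP kernel; a postsynaptic spike
#' deposits a back-propagating-action-potential (BAP) kernel whose amplitude
#' attenuates as `exp(-path_offset / bap_attenuation_length)` along the
#' branch, and an instantaneous voltage-dependent-calcium-channel (VDCC)
#' calcium impulse attenuated the same way. All amplitudes and time
#' constants are explicit configuration.
#'
#' @param epsp_amplitude local EPSP peak, mV.
#' @param epsp_rise,epsp_decay EPSP kernel time constants, ms.
#' @param bap_amplitude BAP peak at the branch origin, mV.
#' @param bap_attenuation_length BAP space constant along the branch, um.
#' @param bap_rise,bap_decay BAP kernel time constants, ms.
#' @param nmda_rise,nmda_decay NMDA conductance time constants, ms.
#' @param synaptic_delay presynaptic axonal + synaptic delay, ms.
#' @param vdcc_impulse_gain calcium deposited per postsynaptic spike at the
#'   branch origin, uM.
#' @param v_rest resting local membrane potential, mV.
#' @return A `driver_kernels` list.
#' @export
driver_kernels <- function(epsp_amplitude = 8, epsp_rise = 1, epsp_decay = 20,
                           bap_amplitude = 45, bap_attenuation_length = 200,
                           bap_rise = 0.5, bap_decay = 5,
                           nmda_rise = 2, nmda_decay = 65,
                           synaptic_delay = 1, vdcc_impulse_gain = 0.1,
                           v_rest = -70) {
  stopifnot(epsp_decay > epsp_rise, bap_decay > bap_rise,
            nmda_decay > nmda_rise, epsp_amplitude >= 0, bap_amplitude >= 0,
            vdcc_impulse_gain >= 0, bap_attenuation_length > 0)
  k <- list(epsp_amplitude = epsp_amplitude, epsp_rise = epsp_rise,
            epsp_decay = epsp_decay, bap_amplitude = bap_amplitude,
            bap_attenuation_length = bap_attenuation_length,
            bap_rise = bap_rise, bap_decay = bap_decay,
            nmda_rise = nmda_rise, nmda_decay = nmda_decay,
            synaptic_delay = synaptic_delay,
            vdcc_impulse_gain = vdcc_impulse_gain, v_rest = v_rest)
  class(k) <- "driver_kernels"
  k
}

# pA -> uM/ms conversion: eta / (2 F X) with X in litres, charge in C.
.current_to_flux <- function(params) {
  vol_l <- params$spine_volume * 1e-15
  params$eta * 1e-15 / (2 * params$faraday * vol_l) * 1e6
}
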