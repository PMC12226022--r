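#' Magnesium block of the NMDA receptor
#'
#' Voltage dependence of the NMDA conductance under the Jahr-Stevens
#' formalism, `m(V) = 1 / (1 + ([Mg]_o / theta) * exp(-kappa * V))`,
#' strictly increasing in `V` with values in (0, 1).
#'
#' @param V local membrane potential, mV (vectorised).
#' @param params a [plasticity_params()] object.
#' @return Open fraction `m` in (0, 1).
#' @export
mg_block <- function(V, params = plasticity_params()) {
  if (any(!is.finite(V))) stop("V must be finite")
  1 / (1 + params$mg_out / params$mg_theta * exp(-params$mg_kappa * V))
}

#' Calcium current through NMDA receptors
#'
#' Returns the NMDA calcium current in the influx-positive convention used
#' by the calcium balance: `I* = g * m(V) * (E_nmda - V)`, which is
#' positive (calcium entering the spine) while `V < E_nmda` and the channel
#' is open. This is the printed `g m (V - E)` form with the sign flipped
#' once, so the calcium equation can add `I*` directly; the simulator
#' clamps negative values (no calcium extrusion above reversal).
#'
#' @param g_nmda instantaneous NMDA conductance, nS.
#' @param V local membrane potential, mV.
#' @param params a [plasticity_params()] object.
#' @return Current in pA (nS x mV), influx-positive.
#' @export
nmda_calcium_current <- function(g_nmda, V, params = plasticity_params()) {
  if (any(g_nmda < 0)) stop("conductance must be non-negative")
  g_nmda * mg_block(V, params) * (params$E_nmda - V)
}

#' One exponential-Euler step of spine calcium
#'
#' Advances `d[Ca]/dt = (I_nmda + I_vdcc) * eta/(2FX) - ([Ca] - rest)/tau_ca`
#' by `dt` with the currents held constant over the step (exact for the
#' linear equation).
#'
#' @param ca_i calcium concentration, uM.
#' @param i_nmda,i_vdcc influx-positive currents, pA.
#' @param dt step, ms.
#' @param params a [plasticity_params()] object.
#' @return Updated calcium concentration, uM.
#' @export
step_calcium <- function(ca_i, i_nmda, i_vdcc, dt, params = plasticity_params()) {
  if (dt <= 0) stop("dt must be positive")
  if (any(!is.finite(c(i_nmda, i_vdcc)))) stop("currents must be finite")
  flux <- (i_nmda + i_vdcc) * .current_to_flux(params)
  e <- exp(-dt / params$tau_ca)
  exc <- (ca_i - params$ca_rest) * e + flux * params$tau_ca * (1 - e)
  params$ca_rest + exc
}

#' One exponential-Euler step of the leaky calcium integrator
#'
#' Advances `dCa*/dt = -Ca*/tau_star + ([Ca] - rest)` by `dt` with the
#' calcium excess held constant over the step.
#'
#' @param ca_star integrator state, uM ms.
#' @param ca_i calcium concentration, uM.
#' @param dt step, ms.
#' @param params a [plasticity_params()] object.
#' @return Updated integrator state.
#' @export
step_ca_star <- function(ca_star, ca_i, dt, params = plasticity_params()) {
  if (dt <= 0) stop("dt must be positive")
  e <- exp(-dt / params$tau_star)
  ca_star * e + (ca_i - params$ca_rest) * params$tau_star * (1 - e)
}

#' One forward-Euler step of the bistable efficacy dynamics
#'
#' Advances `tau drho/dt = -rho(1-rho)(rho*-rho) + gamma_p (1-rho) H(Ca*-theta_p)
#' - gamma_d rho H(Ca*-theta_d)` by `dt` and clamps to \[0, 1\]. Negative
#' thresholds are the non-plastic sentinel: neither Heaviside term can fire.
#'
#' @param rho synaptic efficacy in \[0, 1\].
#' @param ca_star integrated calcium, uM ms.
#' @param theta_d,theta_p depression and potentiation thresholds; negative
#'   values mark a non-plastic synapse.
#' @param dt step, ms.
#' @param params a [plasticity_params()] object.
#' @return Updated efficacy.
#' @export
step_rho <- function(rho, ca_star, theta_d, theta_p, dt,
                     params = plasticity_params()) {
  if (dt <= 0) stop("dt must be positive")
  plastic <- theta_d >= 0 & theta_p >= 0
  hp <- plastic & ca_star >= theta_p
  hd <- plastic & ca_star >= theta_d
  drho <- -rho * (1 - rho) * (params$rho_star - rho) +
    params$gamma_p * (1 - rho) * hp - params$gamma_d * rho * hd
  pmin(1, pmax(0, rho + dt / (params$tau_rho * 1000) * drho))
}

#' Exponential conversion of efficacy into U_SE and peak AMPA conductance
#'
#' Both variables relax with time constant `tau_change` toward the
#' endpoint-interpolated targets `U_d + rho (U_p - U_d)` and
#' `g_d + rho (g_p - g_d)`; the update is the exact solution over `dt`
#' at fixed `rho`.
#'
#' @param rho synaptic efficacy.
#' @param use current `U_SE`.
#' @param g_ampa current peak AMPA conductance, nS.
#' @param dt step, ms.
#' @param params a [plasticity_params()] object.
#' @return List with updated `U_SE` and `g_AMPA`.
#' @export
update_use_gampa <- function(rho, use, g_ampa, dt, params = plasticity_params()) {
  if (dt <= 0) stop("dt must be positive")
  if (params$use_d > params$use_p || params$g_ampa_d > params$g_ampa_p)
    stop("depressed endpoints must not exceed potentiated endpoints")
  e <- exp(-dt / (params$tau_change * 1000))
  u_bar <- params$use_d + rho * (params$use_p - params$use_d)
  g_bar <- params$g_ampa_d + rho * (params$g_ampa_p - params$g_ampa_d)
  list(U_SE = u_bar + (use - u_bar) * e,
       g_AMPA = g_bar + (g_ampa - g_bar) * e)
}

#' Derive depression/potentiation thresholds from single-spike transients
#'
#' Applies the 2x2 threshold matrix of the synapse's neurite class to its
#' single-spike calcium peaks: `(theta_d, theta_p)' = A (c_pre, c_post)'`.
#' Non-plastic synapses receive the sentinel value -1 for both thresholds,
#' which no calcium trajectory can cross.
#'
#' @param c_pre,c_post peak single-spike calcium transients, uM (vectors).
#' @param neurite_kind `"apical"` or `"basal"` (recycled).
#' @param params a [plasticity_params()] object.
#' @param plastic logical vector; `FALSE` rows get sentinel thresholds.
#' @return Data frame with columns `theta_d`, `theta_p`.
#' @export
derive_thresholds <- function(c_pre, c_post, neurite_kind = "basal",
                              params = plasticity_params(), plastic = TRUE) {
  if (any(c_pre < 0) || any(c_post < 0)) stop("transients must be >= 0")
  n <- max(length(c_pre), length(c_post), length(neurite_kind),
           length(plastic))
  c_pre <- rep_len(c_pre, n); c_post <- rep_len(c_post, n)
  neurite_kind <- rep_len(neurite_kind, n); plastic <- rep_len(plastic, n)
  apical <- neurite_kind == "apical"
  A <- params$theta_apical; B <- params$theta_basal
  theta_d <- ifelse(apical, A[1, 1] * c_pre + A[1, 2] * c_post,
                            B[1, 1] * c_pre + B[1, 2] * c_post)
  theta_p <- ifelse(apical, A[2, 1] * c_pre + A[2, 2] * c_post,
                            B[2, 1] * c_pre + B[2, 2] * c_post)
  theta_d[!plastic] <- -1; theta_p[!plastic] <- -1
  data.frame(theta_d = theta_d, theta_p = theta_p)
}

# Assemble the flat parameter list consumed by the C++ integrator for one
# synapse. bap amplitude and vdcc gain are attenuated with the synapse's
# path offset here.
.syn_cpp_par <- function(params, kernels, g_nmda_hat, path_offset,
                         theta_d, theta_p, rho0, u0, g0) {
  att <- exp(-path_offset / kernels$bap_attenuation_length)
  list(tau_rho_s = params$tau_rho, rho_star = params$rho_star,
       gamma_d = params$gamma_d, gamma_p = params$gamma_p,
       theta_d = theta_d, theta_p = theta_p,
       ca_rest = params$ca_rest, tau_ca = params$tau_ca,
       tau_star = params$tau_star, k_flux = .current_to_flux(params),
       g_nmda_hat = g_nmda_hat, nmda_rise = kernels$nmda_rise,
       nmda_decay = kernels$nmda_decay, e_nmda = params$E_nmda,
       mg_out = params$mg_out, mg_theta = params$mg_theta,
       mg_kappa = params$mg_kappa, v_rest = kernels$v_rest,
       epsp_amp = kernels$epsp_amplitude, epsp_rise = kernels$epsp_rise,
       epsp_decay = kernels$epsp_decay,
       bap_amp = kernels$bap_amplitude * att,
       bap_rise = kernels$bap_rise, bap_decay = kernels$bap_decay,
       vdcc_gain = kernels$vdcc_impulse_gain * att,
       rho0 = rho0, u_d = params$use_d, u_p = params$use_p,
       g_d = params$g_ampa_d, g_p = params$g_ampa_p,
       u0 = u0, g0 = g0, tau_change_s = params$tau_change)
}

#' Measure single-spike calcium transients of a synapse
#'
#' Runs two isolated single-spike simulations from a quiescent state: one
#' with a lone presynaptic spike (NMDA calcium under the local EPSP) and
#' one with a lone postsynaptic spike (distance-attenuated VDCC impulse),
#' and returns the peak calcium excess over rest for each.
#'
#' @param g_nmda_hat peak NMDA conductance of the synapse, nS.
#' @param path_offset distance from the branch origin, um.
#' @param kernels a [driver_kernels()] object.
#' @param params a [plasticity_params()] object.
#' @param dt integration step, ms.
#' @return Named vector `c(c_pre, c_post)` in uM.
#' @export
measure_c_pre_c_post <- function(g_nmda_hat = 0.5, path_offset = 0,
                                 kernels = driver_kernels(),
                                 params = plasticity_params(), dt = 0.1) {
  par <- .syn_cpp_par(params, kernels, g_nmda_hat, path_offset,
                      theta_d = -1, theta_p = -1, rho0 = 0,
                      u0 = params$use_d, g0 = params$g_ampa_d)
  pre <- cpp_simulate_synapse(50, numeric(0), 500, dt, 500, par)
  post <- cpp_simulate_synapse(numeric(0), 50, 500, dt, 500, par)
  c(c_pre = pre$peak_ca_exc, c_post = post$peak_ca_exc)
}

#' Calibrate the threshold matrices against three induction protocols
#'
#' The fitted threshold constants of the source model are not public, so
#' defaults are produced by this helper: it measures the peak integrated
#' calcium of (i) a lone presynaptic spike, (ii) a single coincident
#' pre+post pair at `pair_lag` ms, and (iii) `n_volley` such pairs at
#' `volley_hz`, then places `theta_d` at the geometric midpoint of (i) and
#' (ii) and `theta_p` at the geometric midpoint of (ii) and (iii). The
#' thresholds are expressed as a 2x2 matrix acting on `(c_pre, c_post)`,
#' with `weight_post` of each threshold carried by the `c_post` column so
#' distal (attenuated) synapses scale both thresholds down.
#'
#' @param kernels a [driver_kernels()] object.
#' @param params a [plasticity_params()] object.
#' @param g_nmda_hat,path_offset reference synapse.
#' @param pair_lag post-after-pre lag, ms.
#' @param n_volley,volley_hz volley protocol.
#' @param weight_post fraction of each threshold attributed to `c_post`.
#' @param dt integration step, ms.
#' @return 2x2 matrix usable as `theta_apical` / `theta_basal`.
#' @export
calibrate_threshold_matrix <- function(kernels = driver_kernels(),
                                       params = plasticity_params(),
                                       g_nmda_hat = 0.5, path_offset = 0,
                                       pair_lag = 10, n_volley = 10,
                                       volley_hz = 50, weight_post = 0.02,
                                       dt = 0.1) {
  par <- .syn_cpp_par(params, kernels, g_nmda_hat, path_offset,
                      theta_d = -1, theta_p = -1, rho0 = 0,
                      u0 = params$use_d, g0 = params$g_ampa_d)
  peak_star <- function(pre, post, dur) {
    cpp_simulate_synapse(pre, post, dur, dt, dur, par)$peak_ca_star
  }
  p1 <- peak_star(50, numeric(0), 1500)
  p2 <- peak_star(50, 50 + pair_lag, 1500)
  t_pre <- 50 + seq(0, by = 1000 / volley_hz, length.out = n_volley)
  p3 <- peak_star(t_pre, t_pre + pair_lag, 1500 + max(t_pre))
  cc <- measure_c_pre_c_post(g_nmda_hat, path_offset, kernels, params, dt)
  theta_d <- sqrt(p1 * p2); theta_p <- sqrt(p2 * p3)
  m <- matrix(c((1 - weight_post) * theta_d / cc["c_pre"],
                weight_post * theta_d / cc["c_post"],
                (1 - weight_post) * theta_p / cc["c_pre"],
                weight_post * theta_p / cc["c_post"]),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("theta_d", "theta_p"), c("c_pre", "c_post")))
  attr(m, "protocol_peaks") <- c(pre_alone = p1, pair = p2, volley = p3)
  m
}

#' Simulate calcium-based plasticity for a table of synapses
#'
#' Event-driven integration of the full model per synapse: presynaptic
#' spikes (shifted by the synaptic delay) open the NMDA conductance and the
#' local EPSP kernel, postsynaptic spikes deposit distance-attenuated BAP
#' voltage kernels and VDCC calcium impulses; calcium and its leaky
#' integral are advanced with exponential Euler and the efficacy with
#' forward Euler (Heaviside terms evaluated on the post-step integral);
#' `U_SE` and `g_AMPA` relax continuously toward their rho-interpolated
#' targets. The state of every synapse is reported at `report_dt` (1 s by
#' default).
#'
#' @param syn_table a synapse table as produced by [gen_synapses()] +
#'   [init_synapse_states()]; must carry `theta_d`/`theta_p` (see
#'   [derive_thresholds()]) unless `auto_thresholds = TRUE`.
#' @param spike_trains named list: source id -> sorted spike times, ms.
#'   Presynaptic sources are matched by `pre_node`, postsynaptic by
#'   `post_node`; missing sources are treated as silent.
#' @param duration simulated time, ms.
#' @param kernels a [driver_kernels()] object.
#' @param params a [plasticity_params()] object.
#' @param report_dt reporting cadence, ms.
#' @param dt integration step, ms.
#' @param auto_thresholds derive thresholds from per-synapse
#'   [measure_c_pre_c_post()] before simulating.
#' @return A `plasticity_trace`: list with `time_s` and synapse-by-time
#'   matrices `rho`, `U_SE`, `g_AMPA`, plus the final state (including the
#'   proportionally rescaled peak NMDA conductance) in `$final`.
#' @export
simulate_plasticity <- function(syn_table, spike_trains, duration,
                                kernels = driver_kernels(),
                                params = plasticity_params(),
                                report_dt = 1000, dt = 0.1,
                                auto_thresholds = FALSE) {
  stopifnot(is.data.frame(syn_table), nrow(syn_table) > 0, duration > 0)
  if (auto_thresholds) syn_table <- add_thresholds(syn_table, kernels, params)
  if (is.null(syn_table$theta_d) || is.null(syn_table$theta_p) ||
      any(is.na(syn_table$theta_d)))
    stop("synapse table is missing thresholds; run add_thresholds() first")
  n <- nrow(syn_table)
  n_rep <- floor(duration / report_dt)
  rho <- use <- gam <- matrix(NA_real_, n, n_rep)
  final <- data.frame(syn_id = syn_table$syn_id, rho = NA_real_,
                      U_SE = NA_real_, g_AMPA = NA_real_, g_NMDA = NA_real_)
  times <- NULL
  g_nmda_hat <- if (!is.null(syn_table$g_NMDA_hat)) syn_table$g_NMDA_hat else
    rep(0.5, n)
  for (i in seq_len(n)) {
    pre <- spike_trains[[as.character(syn_table$pre_node[i])]]
    post <- spike_trains[[as.character(syn_table$post_node[i])]]
    if (is.null(pre)) pre <- numeric(0)
    if (is.null(post)) post <- numeric(0)
    if (length(pre) && any(pre < 0 | pre > duration))
      stop("spike outside [0, duration]")
    par <- .syn_cpp_par(params, kernels, g_nmda_hat[i],
                        syn_table$path_offset[i], syn_table$theta_d[i],
                        syn_table$theta_p[i], syn_table$rho[i],
                        syn_table$U_SE[i], syn_table$g_AMPA_hat[i])
    res <- cpp_simulate_synapse(pre + kernels$synaptic_delay, post,
                                duration + kernels$synaptic_delay + 1e-6,
                                dt, report_dt, par)
    if (is.null(times)) times <- res$report_times_ms[seq_len(n_rep)]
    rho[i, ] <- res$rho[seq_len(n_rep)]
    use[i, ] <- res$U_SE[seq_len(n_rep)]
    gam[i, ] <- res$g_AMPA[seq_len(n_rep)]
    final$rho[i] <- res$final[["rho"]]
    final$U_SE[i] <- res$final[["U_SE"]]
    final$g_AMPA[i] <- res$final[["g_AMPA"]]
  }
  # NMDA peaks rescaled in proportion to the rho-interpolated AMPA target
  tgt <- function(r) params$g_ampa_d + r * (params$g_ampa_p - params$g_ampa_d)
  final$g_NMDA <- g_nmda_hat * tgt(final$rho) / tgt(syn_table$rho)
  structure(list(time_s = times / 1000, rho = rho, U_SE = use, g_AMPA = gam,
                 syn_id = syn_table$syn_id, pre_node = syn_table$pre_node,
                 post_node = syn_table$post_node, final = final,
                 rho0 = syn_table$rho),
            class = "plasticity_trace")
}

#' Attach measured transients and derived thresholds to a synapse table
#'
#' Convenience wrapper: measures `c_pre`/`c_post` for the distinct
#' (conductance, offset) values in the table and applies
#' [derive_thresholds()] with the neurite kind of each synapse.
#'
#' @inheritParams simulate_plasticity
#' @return The synapse table with `c_pre`, `c_post`, `theta_d`, `theta_p`.
#' @export
add_thresholds <- function(syn_table, kernels = driver_kernels(),
                           params = plasticity_params()) {
  g <- if (!is.null(syn_table$g_NMDA_hat)) syn_table$g_NMDA_hat else
    rep(0.5, nrow(syn_table))
  key <- paste(signif(g, 6), signif(syn_table$path_offset, 6))
  uk <- !duplicated(key)
  cc <- vapply(which(uk), function(i)
    measure_c_pre_c_post(g[i], syn_table$path_offset[i], kernels, params),
    numeric(2))
  idx <- match(key, key[uk])
  syn_table$c_pre <- cc[1, idx]
  syn_table$c_post <- cc[2, idx]
  plastic <- if (!is.null(syn_table$plastic)) syn_table$plastic else TRUE
  th <- derive_thresholds(syn_table$c_pre, syn_table$c_post,
                          syn_table$neurite_kind, params, plastic)
  syn_table$theta_d <- th$theta_d
  syn_table$theta_p <- th$theta_p
  syn_table
}

#' Locate the separatrix of the efficacy dynamics by bisection
#'
#' Integrates the efficacy equation with the calcium drive held below both
#' thresholds from a bracketing pair of initial conditions and bisects the
#' boundary between convergence to 0 and to 1.
#'
#' @param params a [plasticity_params()] object.
#' @param duration_s simulated time per probe, s.
#' @param tol bisection tolerance on the initial value.
#' @param dt integration step, ms.
#' @return The separatrix initial value.
#' @export
rho_separatrix <- function(params = plasticity_params(), duration_s = 600,
                           tol = 1e-6, dt = 10) {
  goes_up <- function(r0) {
    f <- cpp_integrate_rho(r0, dt, duration_s * 1000, params$tau_rho,
                           params$rho_star, params$gamma_d, params$gamma_p,
                           1, 1, 0, 1L)
    tail(f, 1) > r0
  }
  lo <- 0.05; hi <- 0.95
  if (goes_up(lo) || !goes_up(hi)) stop("bracket does not straddle the separatrix")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (goes_up(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Integrate the bare efficacy dynamics at constant calcium drive
#'
#' @param rho0 initial efficacy.
#' @param duration_s simulated time, s.
#' @param ca_star constant value of the integrated-calcium variable.
#' @param theta_d,theta_p thresholds (negative = non-plastic sentinel).
#' @param params a [plasticity_params()] object.
#' @param dt step, ms.
#' @param n_report number of reported points.
#' @return Numeric vector of reported efficacies (last value = final).
#' @export
integrate_rho <- function(rho0, duration_s, ca_star = 0, theta_d = 1,
                          theta_p = 1, params = plasticity_params(),
                          dt = 1, n_report = 100) {
  cpp_integrate_rho(rho0, dt, duration_s * 1000, params$tau_rho,
                    params$rho_star, params$gamma_d, params$gamma_p,
                    theta_d, theta_p, ca_star, as.integer(n_report))
}
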