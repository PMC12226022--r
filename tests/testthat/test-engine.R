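p_def <- plasticity_params()

test_that("magnesium block follows the Jahr-Stevens form", {
  # algebraic midpoint: V = ln(Mg/theta) / kappa gives m = 0.5
  v_half <- log(p_def$mg_out / p_def$mg_theta) / p_def$mg_kappa
  expect_equal(mg_block(v_half), 0.5)
  expect_gt(mg_block(200), 0.999)                      # saturation
  # direct evaluation at V = -70 mV
  m70 <- 1 / (1 + (1 / 2.552) * exp(0.072 * 70))
  expect_equal(mg_block(-70), m70)
  v <- seq(-90, 40, 5)
  expect_true(all(diff(mg_block(v)) > 0))              # strictly increasing
  expect_true(all(mg_block(v) > 0 & mg_block(v) < 1))
  expect_error(mg_block(NaN), "finite")
})

test_that("NMDA calcium current: reversal, linearity, sign convention", {
  expect_equal(nmda_calcium_current(0, -50), 0)
  expect_equal(nmda_calcium_current(1, p_def$E_nmda), 0)   # reversal
  i1 <- nmda_calcium_current(0.5, -60)
  expect_equal(nmda_calcium_current(1, -60), 2 * i1)       # linear in g
  expect_gt(i1, 0)                        # influx-positive below reversal
  expect_error(nmda_calcium_current(-1, -60), "non-negative")
})

test_that("calcium and integrator steps match their closed forms", {
  # fixed point at rest
  expect_equal(step_calcium(p_def$ca_rest, 0, 0, 1), p_def$ca_rest)
  # linear decay of an excess: after tau_ca the excess is Delta/e
  ca <- p_def$ca_rest + 1
  t <- 0
  while (t < p_def$tau_ca) { ca <- step_calcium(ca, 0, 0, 0.01); t <- t + 0.01 }
  expect_equal(ca - p_def$ca_rest, exp(-1), tolerance = 1e-3)
  # constant-current steady state: rest + I * k * tau_ca
  k <- plastinet:::.current_to_flux(p_def)
  ca <- p_def$ca_rest
  for (i in 1:8000) ca <- step_calcium(ca, 2, 0, 0.1)
  expect_equal(ca, p_def$ca_rest + 2 * k * p_def$tau_ca, tolerance = 1e-9)
  # integrator: zero stays zero at rest, steady state tau_star * excess
  expect_equal(step_ca_star(0, p_def$ca_rest, 5), 0)
  cs <- 0
  for (i in 1:60000) cs <- step_ca_star(cs, p_def$ca_rest + 0.01, 0.1)
  expect_equal(cs, p_def$tau_star * 0.01, tolerance = 1e-6)
  expect_error(step_calcium(0.07, 0, 0, -1), "positive")
})

test_that("efficacy dynamics are bistable around rho* = 0.5", {
  # fixed points of the bare cubic
  expect_equal(step_rho(0, 0, 1, 1, 0.1), 0)
  expect_equal(step_rho(1, 0, 1, 1, 0.1), 1)
  # opposite limits from either side of the separatrix (growth near 0.5
  # has time constant tau / (rho*(1-rho*)) ~ 280 s, hence the long run)
  up <- integrate_rho(0.5 + 0.05, 1200)
  dn <- integrate_rho(0.5 - 0.05, 1200)
  expect_gt(tail(up, 1), 0.99)
  expect_lt(tail(dn, 1), 0.01)
  # convergence from 0.9 approaches 1 (exact solution reaches ~0.998 at
  # 600 s; see the vignette for the closed-form rate)
  expect_gt(tail(integrate_rho(0.9, 600), 1), 0.99)
  # non-plastic sentinel: calcium cannot move rho
  expect_equal(tail(integrate_rho(0.3, 10, ca_star = 1e9,
                                  theta_d = -1, theta_p = -1), 1), 0.3)
  # crossed thresholds pull rho toward gamma-determined equilibria:
  # above theta_p (both Heavisides on) gamma_p/(gamma_p+gamma_d) ~ 0.68,
  # above theta_d only, full depression
  expect_equal(tail(integrate_rho(0.1, 20, ca_star = 2, theta_d = 1,
                                  theta_p = 1.5), 1),
               p_def$gamma_p / (p_def$gamma_p + p_def$gamma_d),
               tolerance = 1e-2)
  expect_lt(tail(integrate_rho(0.9, 5, ca_star = 1.2, theta_d = 1,
                               theta_p = 1.5), 1), 0.1)
})

test_that("threshold derivation applies the 2x2 pathway matrices", {
  pid <- plasticity_params(theta_apical = diag(2), theta_basal = diag(2))
  th <- derive_thresholds(c(3, 0), c(5, 0), "apical", pid)
  expect_equal(th$theta_d, c(3, 0))
  expect_equal(th$theta_p, c(5, 0))
  # default shipped matrix equals the hand multiplication
  A <- p_def$theta_basal
  th2 <- derive_thresholds(1, 1, "basal", p_def)
  expect_equal(th2$theta_d, A[1, 1] + A[1, 2])
  expect_equal(th2$theta_p, A[2, 1] + A[2, 2])
  # non-plastic rows get negative sentinels
  th3 <- derive_thresholds(1, 1, "basal", p_def, plastic = c(TRUE, FALSE))
  expect_equal(th3$theta_d[2], -1)
  expect_error(derive_thresholds(-1, 1), ">= 0")
  expect_error(plasticity_params(theta_basal = diag(3)), "2x2")
})

test_that("single-spike transients: zero kernels, linearity, pre/post ratio", {
  k0 <- driver_kernels(epsp_amplitude = 0, vdcc_impulse_gain = 0)
  cc0 <- measure_c_pre_c_post(g_nmda_hat = 0, kernels = k0)
  expect_equal(unname(cc0), c(0, 0))
  cc <- measure_c_pre_c_post()
  expect_gte(cc["c_pre"] / cc["c_post"], 100)
  # doubling the VDCC gain doubles c_post
  k2 <- driver_kernels(vdcc_impulse_gain = 0.2)
  cc2 <- measure_c_pre_c_post(kernels = k2)
  expect_equal(unname(cc2["c_post"]), unname(2 * cc["c_post"]),
               tolerance = 1e-10)
})

test_that("U_SE / g_AMPA relax exponentially between their endpoints", {
  # fixed point at the potentiated endpoint
  r <- update_use_gampa(1, p_def$use_p, p_def$g_ampa_p, 1000)
  expect_equal(r$U_SE, p_def$use_p)
  # closed-form decay: after tau_change, 1/e of the gap remains
  u <- p_def$use_p
  for (i in seq_len(100)) u <- update_use_gampa(0, u, 1, 1000)$U_SE
  expect_equal(u, p_def$use_d + (p_def$use_p - p_def$use_d) * exp(-1),
               tolerance = 1e-12)
  # rho = 0.5 converges to the midpoint
  g <- p_def$g_ampa_d
  for (i in seq_len(1000)) g <- update_use_gampa(0.5, 0.3, g, 1e3)$g_AMPA
  expect_equal(g, (p_def$g_ampa_d + p_def$g_ampa_p) / 2, tolerance = 1e-4)
})

test_that("the assembled simulator honours its conservation invariants", {
  syn <- rbind(one_synapse(0), one_synapse(1))
  syn$syn_id <- 1:2
  # no spikes: exactly stationary at the fixed points
  tr <- simulate_plasticity(syn, list(), 5000)
  expect_equal(tr$rho, matrix(c(0, 1), 2, 5))
  expect_equal(tr$U_SE[1, ], rep(p_def$use_d, 5))
  # sparse pre-only drive below threshold: no changes
  s1 <- one_synapse(1)
  tr2 <- simulate_plasticity(s1, list("1" = seq(500, 59500, by = 10000)),
                             60000)
  expect_equal(tr2$final$rho, 1)
  # rho bounded and U_SE inside endpoint interval throughout
  pt <- pairing_trains(10)
  tr3 <- simulate_plasticity(one_synapse(0.5),
                             list("1" = pt$pre, "2" = pt$post), 15000)
  expect_true(all(tr3$rho >= 0 & tr3$rho <= 1))
  expect_true(all(tr3$U_SE >= p_def$use_d & tr3$U_SE <= p_def$use_p))
  # spikes outside the simulated window are rejected
  expect_error(simulate_plasticity(s1, list("1" = c(100, 99999)), 5000),
               "outside")
  # non-plastic sentinel thresholds freeze rho under strong drive
  snp <- one_synapse(0.5)
  snp$theta_d <- snp$theta_p <- -1
  trnp <- simulate_plasticity(snp, list("1" = pt$pre, "2" = pt$post), 15000)
  expect_equal(unique(as.vector(trnp$rho)), 0.5)
})

test_that("coincident volleys potentiate and the oracle integrator agrees", {
  syn <- one_synapse(0)
  vol <- sort(as.vector(outer(seq(0, 9) * 20, seq(500, 20000, 1000), "+")))
  tr <- simulate_plasticity(syn, list("1" = vol, "2" = vol + 10), 21000)
  expect_gt(tr$final$rho, 0.2)          # crossed theta_p, moved toward 1
  # brute-force reference at dt/10 (pure R, exponential Euler + forward
  # Euler on the same equations) over a short pairing episode
  kern <- driver_kernels()
  short_pre <- c(100, 120, 140); short_post <- short_pre + 10
  ref <- local({
    dt <- 0.01; par <- p_def
    dexp <- function(tr_, td) {
      tpk <- log(td / tr_) * tr_ * td / (td - tr_)
      exp(-tpk / td) - exp(-tpk / tr_)
    }
    att <- exp(-syn$path_offset / kern$bap_attenuation_length)
    nm_a <- nm_b <- ep_a <- ep_b <- bp_a <- bp_b <- 0
    ca <- 0; cs <- 0; rho <- 0
    kf <- plastinet:::.current_to_flux(par)
    pre_i <- round((short_pre + kern$synaptic_delay) / dt)
    post_i <- round(short_post / dt)
    for (i in 0:(400 / dt)) {
      if (i %in% pre_i) {
        nm_a <- nm_a + 1 / dexp(kern$nmda_rise, kern$nmda_decay)
        nm_b <- nm_b + 1 / dexp(kern$nmda_rise, kern$nmda_decay)
        ep_a <- ep_a + 1 / dexp(kern$epsp_rise, kern$epsp_decay)
        ep_b <- ep_b + 1 / dexp(kern$epsp_rise, kern$epsp_decay)
      }
      if (i %in% post_i) {
        bp_a <- bp_a + 1 / dexp(kern$bap_rise, kern$bap_decay)
        bp_b <- bp_b + 1 / dexp(kern$bap_rise, kern$bap_decay)
        ca <- ca + kern$vdcc_impulse_gain * att
      }
      v <- kern$v_rest + kern$epsp_amplitude * (ep_a - ep_b) +
        kern$bap_amplitude * att * (bp_a - bp_b)
      m <- 1 / (1 + par$mg_out / par$mg_theta * exp(-par$mg_kappa * v))
      g <- 0.5 * (nm_a - nm_b)
      i_star <- max(0, g * m * (par$E_nmda - v))
      e1 <- exp(-dt / par$tau_ca)
      ca <- ca * e1 + i_star * kf * par$tau_ca * (1 - e1)
      e2 <- exp(-dt / par$tau_star)
      cs <- cs * e2 + ca * par$tau_star * (1 - e2)
      hp <- cs >= syn$theta_p; hd <- cs >= syn$theta_d
      rho <- rho + dt / (par$tau_rho * 1000) *
        (-rho * (1 - rho) * (0.5 - rho) + par$gamma_p * (1 - rho) * hp -
           par$gamma_d * rho * hd)
      rho <- min(1, max(0, rho))
      nm_a <- nm_a * exp(-dt / kern$nmda_decay)
      nm_b <- nm_b * exp(-dt / kern$nmda_rise)
      ep_a <- ep_a * exp(-dt / kern$epsp_decay)
      ep_b <- ep_b * exp(-dt / kern$epsp_rise)
      bp_a <- bp_a * exp(-dt / kern$bap_decay)
      bp_b <- bp_b * exp(-dt / kern$bap_rise)
    }
    rho
  })
  fast <- simulate_plasticity(syn, list("1" = short_pre, "2" = short_post),
                              400, report_dt = 400, dt = 0.1)
  expect_equal(fast$final$rho, ref, tolerance = 5e-3)
})

test_that("timing asymmetry: causal pairing is never more depressing", {
  run <- function(lag) {
    pt <- pairing_trains(lag)
    simulate_plasticity(one_synapse(0.5),
                        list("1" = pt$pre, "2" = pt$post), 15000)$final$rho
  }
  expect_gte(run(10), run(-10))
})

test_that("halving dt leaves the pairing outcome unchanged to 1e-4", {
  pt <- pairing_trains(10)
  syn <- one_synapse(0.5)
  r1 <- simulate_plasticity(syn, list("1" = pt$pre, "2" = pt$post), 15000,
                            dt = 0.1)$final$rho
  r2 <- simulate_plasticity(syn, list("1" = pt$pre, "2" = pt$post), 15000,
                            dt = 0.05)$final$rho
  expect_lt(abs(r1 - r2), 1e-4)
})

test_that("calcium responses are additive for non-overlapping kernels", {
  syn <- one_synapse(0)
  one <- simulate_plasticity(syn, list("1" = 500), 3000,
                             report_dt = 3000)
  two <- simulate_plasticity(syn, list("1" = c(500, 1800)), 3000,
                             report_dt = 3000)
  cc1 <- measure_c_pre_c_post()
  # both spikes produce the same isolated peak (kernels decayed between)
  expect_equal(unname(cc1["c_pre"]),
               measure_c_pre_c_post(g_nmda_hat = 0.5)[["c_pre"]],
               tolerance = 1e-6)
  expect_equal(one$final$rho, two$final$rho) # neither crosses a threshold
})

test_that("threshold calibration separates the three induction protocols", {
  m <- calibrate_threshold_matrix()
  pk <- attr(m, "protocol_peaks")
  cc <- measure_c_pre_c_post()
  th <- derive_thresholds(cc["c_pre"], cc["c_post"], "basal",
                          plasticity_params(theta_basal = m))
  expect_lt(pk["pre_alone"], th$theta_d)   # lone pre spike crosses nothing
  expect_gt(pk["pair"], th$theta_d)        # pair crosses depression
  expect_lt(pk["pair"], th$theta_p)        # ... but not potentiation
  expect_gt(pk["volley"], th$theta_p)      # volleys cross potentiation
})
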