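# Desk-scale end-to-end scenarios shared by the direction-check tests.
# Sizes are chosen so each scenario simulates in seconds while leaving a
# clear planted signal (see the methods vignette for the rationale).

# Network with a dense co-firing subgroup ("assembly"): assembly members
# fire shared theta-burst volleys (the potentiation-inducing regime of the
# calcium model), the remaining neurons fire rate-matched independent
# Poisson trains. Returns the simulated trace plus metadata.
cofiring_scenario <- function(seed = 1, n_nodes = 100, n_assembly = 25,
                              duration_ms = 30000, volley_every = 1500,
                              p_within = 0.3, p_other = 0.08,
                              burst_len = 5, burst_isi = 15) {
  set.seed(seed)
  asm <- seq_len(n_assembly)
  net <- gen_network(n_nodes, conn_prob_fn = function(pre, post) {
    ifelse(pre$node_id <= n_assembly & post$node_id <= n_assembly,
           p_within, p_other)
  }, seed = seed)
  syn <- gen_synapses(net, mean_syn_per_conn = 1, sd_syn_per_conn = 0,
                      seed = seed + 1)
  syn <- init_synapse_states(syn, net, 0.5, seed = seed + 2)
  syn <- add_thresholds(syn)
  volleys <- seq(500, duration_ms - 500, by = volley_every)
  bg_rate <- 0.3
  member_rate <- burst_len * 0.9 * length(volleys) / (duration_ms / 1000) +
    bg_rate
  spikes <- stats::setNames(lapply(net$nodes$node_id, function(i) {
    bg <- runif(stats::rpois(1, bg_rate * duration_ms / 1000), 0,
                duration_ms)
    if (i <= n_assembly) {
      hit <- volleys[runif(length(volleys)) < 0.9]
      t <- c(bg, rep(hit, each = burst_len) +
               seq(0, by = burst_isi, length.out = burst_len) +
               rnorm(length(hit) * burst_len, 0, 2))
    } else {
      t <- c(bg, runif(stats::rpois(1, (member_rate - bg_rate) *
                                      duration_ms / 1000), 0, duration_ms))
    }
    t[t >= 0 & t < duration_ms]
  }), as.character(net$nodes$node_id))
  spikes <- lapply(spikes, plastinet:::.strictify)
  trace <- simulate_plasticity(syn, spikes, duration_ms)
  rates <- vapply(spikes, length, numeric(1)) / (duration_ms / 1000)
  list(net = net, syn = syn, spikes = spikes, trace = trace,
       assembly = asm, rates = rates)
}

# Thalamic-drive scenario: one stimulus pattern per condition drives a
# fixed fiber-to-neuron innervation; neurons respond in proportion to how
# many of their innervating fibers are active. Returns per-condition
# final efficacies over the shared connection index.
input_output_scenario <- function(seed = 1,
                                  labels = c("A", "B", "C", "E", "F", "H"),
                                  n_neurons = 40, fibers_per_neuron = 25,
                                  n_reps = 15, isi = 300, rate_max = 60) {
  sched <- gen_patterns(n_bundles = 40, n_fibers = 300, seed = seed)
  set.seed(seed + 1)
  innerv <- lapply(seq_len(n_neurons), function(i)
    sample(sched$fiber_id, fibers_per_neuron))
  syn <- data.frame(
    syn_id = seq_len(n_neurons * fibers_per_neuron),
    pre_node = paste0("f", unlist(innerv)),
    post_node = rep(seq_len(n_neurons), each = fibers_per_neuron),
    branch_id = rep(seq_len(n_neurons), each = fibers_per_neuron) * 10L +
      sample.int(5, n_neurons * fibers_per_neuron, replace = TRUE),
    path_offset = runif(n_neurons * fibers_per_neuron, 0, 150),
    neurite_kind = "basal", rho = rep_len(c(0, 1),
                                          n_neurons * fibers_per_neuron),
    U_SE = NA, g_AMPA_hat = NA, g_NMDA_hat = 0.5, plastic = TRUE)
  p <- plasticity_params()
  syn$U_SE <- ifelse(syn$rho == 1, p$use_p, p$use_d)
  syn$g_AMPA_hat <- ifelse(syn$rho == 1, p$g_ampa_p, p$g_ampa_d)
  syn <- add_thresholds(syn)
  duration <- n_reps * isi + 200
  out <- matrix(NA_real_, nrow(syn), length(labels),
                dimnames = list(NULL, labels))
  for (ci in seq_along(labels)) {
    sc <- add_presentations(sched, n_reps, isi, labels[ci],
                            seed = seed + 2)
    fib <- gen_stimulus_spikes(sc, rate_max = rate_max, seed = seed + 3 + ci)
    active <- sched$patterns[[labels[ci]]]
    post <- stats::setNames(lapply(seq_len(n_neurons), function(i) {
      k <- length(intersect(innerv[[i]], active))
      t <- unlist(lapply(sc$presentations$onset, function(on) {
        runif(stats::rpois(1, 0.06 * k), on + 5, on + 105)
      }))
      plastinet:::.strictify(c(t, runif(stats::rpois(
        1, 0.5 * duration / 1000), 0, duration)))
    }), as.character(seq_len(n_neurons)))
    trains <- c(fib, post)
    trains <- lapply(trains, function(x) x[x < duration])
    tr <- simulate_plasticity(syn, trains, duration)
    out[, ci] <- tr$final$rho
  }
  list(schedule = sched, syn = syn, rho_by_condition = out,
       labels = labels)
}
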