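#' Generate a layered directed network in a cortical-column-like cylinder
#'
#' Nodes receive a layer label (1-6), a position inside a cylinder whose
#' depth is stratified by layer, and directed edges drawn independently
#' with a pairwise connection probability. No self-loops, duplicate-free
#' edge list.
#'
#' @param n_nodes number of neurons (>= 2).
#' @param layer_fractions fractions of nodes per layer, summing to 1.
#' @param conn_prob_fn vectorised function `(pre_nodes, post_nodes) -> p`
#'   taking two aligned node data frames and returning connection
#'   probabilities in \[0, 1\]. Default: distance-decaying
#'   `p0 * exp(-d / d0)` with `p0 = 0.1`, `d0 = 150` um.
#' @param seed RNG seed.
#' @param radius cylinder radius, um.
#' @param layer_thickness depth of each of the six strata, um.
#' @return A `directed_network`: list with `nodes` (node_id, layer, x, y, z)
#'   and `edges` (pre, post).
#' @export
gen_network <- function(n_nodes, layer_fractions = rep(1 / 6, 6),
                        conn_prob_fn = NULL, seed = 1, radius = 230,
                        layer_thickness = 300) {
  stopifnot(n_nodes >= 2)
  if (abs(sum(layer_fractions) - 1) > 1e-8 || any(layer_fractions < 0))
    stop("layer_fractions must be non-negative and sum to 1")
  if (is.null(conn_prob_fn))
    conn_prob_fn <- function(pre, post) {
      d <- sqrt((pre$x - post$x)^2 + (pre$y - post$y)^2 + (pre$z - post$z)^2)
      0.1 * exp(-d / 150)
    }
  set.seed(seed)
  counts <- diff(round(cumsum(c(0, layer_fractions)) * n_nodes))
  layer <- rep(seq_along(layer_fractions), counts)
  r <- radius * sqrt(runif(n_nodes)); phi <- runif(n_nodes, 0, 2 * pi)
  depth <- (layer - runif(n_nodes)) * layer_thickness
  nodes <- data.frame(node_id = seq_len(n_nodes), layer = layer,
                      x = r * cos(phi), y = r * sin(phi), z = -depth)
  idx <- expand.grid(pre = seq_len(n_nodes), post = seq_len(n_nodes))
  idx <- idx[idx$pre != idx$post, ]
  p <- conn_prob_fn(nodes[idx$pre, ], nodes[idx$post, ])
  if (any(p < 0 | p > 1)) stop("connection probability outside [0, 1]")
  keep <- runif(nrow(idx)) < p
  edges <- data.frame(pre = idx$pre[keep], post = idx$post[keep])
  edges <- edges[order(edges$pre, edges$post), ]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 provenance = list(seed = seed, n_nodes = n_nodes)),
            class = "directed_network")
}

# truncated shifted negative-binomial pmf on 1..k_max, moment-matched
# numerically to the target mean and SD of synapses per connection
.syn_count_pmf <- function(mean_syn, sd_syn, k_max = 20) {
  if (sd_syn == 0) {
    stopifnot(mean_syn == round(mean_syn), mean_syn >= 1, mean_syn <= k_max)
    p <- numeric(k_max); p[mean_syn] <- 1
    return(p)
  }
  support <- 0:(k_max - 1)
  obj <- function(par) {
    pm <- stats::dnbinom(support, size = exp(par[1]), mu = exp(par[2]))
    pm <- pm / sum(pm)
    m <- sum((support + 1) * pm)
    s <- sqrt(sum((support + 1 - m)^2 * pm))
    (m - mean_syn)^2 + (s - sd_syn)^2
  }
  fit <- stats::optim(c(log(2), log(mean_syn - 1)), obj)
  pm <- stats::dnbinom(support, size = exp(fit$par[1]), mu = exp(fit$par[2]))
  pm / sum(pm)
}

#' Place multi-synapse connections on abstract dendritic branches
#'
#' Every edge of the network receives at least one synapse; per-connection
#' synapse counts follow a shifted, truncated negative-binomial law
#' moment-matched to the configured mean and SD (defaults 4.1 and 2.3).
#' Each synapse lands on one of the postsynaptic neuron's abstract
#' branches, uniformly along its length; branches are apical with a
#' per-post-layer probability and basal otherwise.
#'
#' @param network a [gen_network()] object.
#' @param mean_syn_per_conn,sd_syn_per_conn target moments of the
#'   synapses-per-connection law.
#' @param n_branches abstract dendritic branches per neuron.
#' @param branch_length branch length, um.
#' @param p_apical probability that a branch is apical; either a single
#'   number or a length-6 vector indexed by post-synaptic layer.
#' @param seed RNG seed.
#' @return A synapse table: one row per synapse with `syn_id`, `pre_node`,
#'   `post_node`, `branch_id`, `path_offset`, `neurite_kind`, and
#'   placeholder plasticity state (`rho`, `U_SE`, `g_AMPA_hat`,
#'   `g_NMDA_hat`, `plastic`).
#' @export
gen_synapses <- function(network, mean_syn_per_conn = 4.1,
                         sd_syn_per_conn = 2.3, n_branches = 20,
                         branch_length = 200, p_apical = 0.3, seed = 1) {
  stopifnot(mean_syn_per_conn >= 1)
  edges <- network$edges
  if (nrow(edges) == 0) stop("network has no edges")
  set.seed(seed)
  pmf <- .syn_count_pmf(mean_syn_per_conn, sd_syn_per_conn)
  counts <- sample.int(length(pmf), nrow(edges), replace = TRUE, prob = pmf)
  n_syn <- sum(counts)
  conn <- rep(seq_len(nrow(edges)), counts)
  post <- edges$post[conn]
  if (length(p_apical) == 1) p_apical <- rep(p_apical, 6)
  post_layer <- network$nodes$layer[match(post, network$nodes$node_id)]
  # branch-level apical/basal: branch k of a neuron is apical iff k <=
  # round(p_apical * n_branches) for its layer, so co-branch synapses agree
  n_apical <- round(p_apical * n_branches)
  branch_no <- sample.int(n_branches, n_syn, replace = TRUE)
  apical <- branch_no <= n_apical[post_layer]
  data.frame(syn_id = seq_len(n_syn), pre_node = edges$pre[conn],
             post_node = post, conn_id = conn,
             branch_id = post * 1000L + branch_no,
             path_offset = runif(n_syn, 0, branch_length),
             neurite_kind = ifelse(apical, "apical", "basal"),
             rho = 0, U_SE = NA_real_, g_AMPA_hat = NA_real_,
             g_NMDA_hat = 0.5, plastic = TRUE)
}

#' Build overlapping thalamic stimulus patterns over fiber bundles
#'
#' Generates 2-D fiber locations, clusters them into bundles with seeded
#' k-means, and forms the ten standard patterns: four disjoint base
#' patterns A-D each holding `floor(base_fraction * n_bundles)` bundles,
#' three pairwise unions E = A+B, F = B+C, G = C+D, two triple unions
#' H = A+B+C, I = B+C+D, and the full union J.
#'
#' @param n_bundles number of fiber bundles.
#' @param base_fraction fraction of bundles per base pattern.
#' @param n_fibers total number of pattern-carrying fibers.
#' @param n_nonspecific size of the always-active nonspecific fiber group.
#' @param extent side of the square flat-map region, um.
#' @param seed RNG seed.
#' @return A `stimulus_schedule`: fiber locations, bundle assignment,
#'   `patterns` (label -> fiber ids), `pattern_bundles` (label -> bundle
#'   ids), `nonspecific_fibers`, and an empty presentation list (see
#'   [add_presentations()]).
#' @export
gen_patterns <- function(n_bundles = 100, base_fraction = 0.12,
                         n_fibers = 1000, n_nonspecific = 100,
                         extent = 400, seed = 1) {
  per_base <- floor(base_fraction * n_bundles)
  if (4 * per_base > n_bundles) stop("base_fraction too large")
  if (per_base < 1) stop("base_fraction too small")
  set.seed(seed)
  loc <- matrix(runif(2 * n_fibers, 0, extent), ncol = 2,
                dimnames = list(NULL, c("u", "v")))
  bundle <- kmeans(loc, centers = n_bundles, nstart = 3,
                   iter.max = 50)$cluster
  base <- split(sample.int(n_bundles, 4 * per_base),
                rep(c("A", "B", "C", "D"), each = per_base))
  pb <- list(A = base$A, B = base$B, C = base$C, D = base$D,
             E = c(base$A, base$B), F = c(base$B, base$C),
             G = c(base$C, base$D), H = c(base$A, base$B, base$C),
             I = c(base$B, base$C, base$D),
             J = c(base$A, base$B, base$C, base$D))
  pb <- lapply(pb, sort)
  fibers <- lapply(pb, function(b) which(bundle %in% b))
  structure(list(fiber_id = seq_len(n_fibers), fiber_location = loc,
                 bundle_id = bundle, patterns = fibers, pattern_bundles = pb,
                 nonspecific_fibers = paste0("ns", seq_len(n_nonspecific)),
                 presentations = NULL, isi = 500,
                 provenance = list(seed = seed, n_bundles = n_bundles,
                                   base_fraction = base_fraction)),
            class = "stimulus_schedule")
}

#' Append a balanced random presentation order to a schedule
#'
#' Each pattern label is presented `n_repetitions` times in globally
#' shuffled order, one onset every `isi` ms.
#'
#' @param schedule a [gen_patterns()] object.
#' @param n_repetitions presentations per pattern.
#' @param isi onset-to-onset inter-stimulus interval, ms.
#' @param labels patterns to include (default all ten).
#' @param start_ms onset of the first presentation.
#' @param seed RNG seed.
#' @return The schedule with a `presentations` data frame (label, onset).
#' @export
add_presentations <- function(schedule, n_repetitions, isi = 500,
                              labels = names(schedule$patterns),
                              start_ms = 0, seed = 1) {
  set.seed(seed)
  lab <- sample(rep(labels, n_repetitions))
  schedule$presentations <- data.frame(
    label = lab, onset = start_ms + (seq_along(lab) - 1) * isi)
  schedule$isi <- isi
  schedule
}

#' Stimulus firing-rate profile
#'
#' Parametric stand-in for the adapting stimulus process: linear rise to
#' `rate_max` over `rise_ms`, then exponential adaptation with time
#' constant `tau_adapt` until `stim_duration`, zero outside.
#'
#' @param t time since stimulus onset, ms (vectorised).
#' @param rate_max peak rate, Hz.
#' @param rise_ms rise time, ms.
#' @param tau_adapt adaptation time constant, ms.
#' @param stim_duration stimulus length, ms.
#' @return Rate in Hz.
#' @export
stimulus_rate_profile <- function(t, rate_max = 17.5, rise_ms = 10,
                                  tau_adapt = 50, stim_duration = 100) {
  r <- ifelse(t < rise_ms, pmax(0, t) / rise_ms,
              exp(-(t - rise_ms) / tau_adapt))
  ifelse(t < 0 | t >= stim_duration, 0, rate_max * r)
}

# inhomogeneous Poisson thinning for one fiber over one stimulus window
.profile_spikes <- function(onset, rate_max, rise_ms, tau_adapt,
                            stim_duration) {
  n <- rpois(1, rate_max * stim_duration / 1000)
  if (n == 0) return(numeric(0))
  tt <- runif(n, 0, stim_duration)
  keep <- runif(n) * rate_max <
    stimulus_rate_profile(tt, rate_max, rise_ms, tau_adapt, stim_duration)
  sort(onset + tt[keep])
}

#' Generate stimulus-driven fiber spike trains
#'
#' For every presentation, the fibers of the active pattern emit spikes
#' from an inhomogeneous Poisson process with the [stimulus_rate_profile()]
#' peaking at `rate_max`; fibers not in the active pattern stay silent.
#' The nonspecific fiber group fires for every presentation with peak rate
#' `rate_max / 2`.
#'
#' @param schedule a schedule with presentations ([add_presentations()]).
#' @param rate_max peak pattern-fiber rate, Hz.
#' @param stim_duration stimulus length, ms.
#' @param rise_ms,tau_adapt profile parameters, ms.
#' @param seed RNG seed.
#' @return Named list of strictly increasing spike-time vectors (ms); fiber
#'   sources are named `"f<i>"`, nonspecific sources by their ids.
#' @export
gen_stimulus_spikes <- function(schedule, rate_max = 17.5,
                                stim_duration = 100, rise_ms = 10,
                                tau_adapt = 50, seed = 1) {
  if (is.null(schedule$presentations) || nrow(schedule$presentations) == 0)
    stop("schedule has no presentations")
  stopifnot(rate_max > 0)
  set.seed(seed)
  out <- c(stats::setNames(
    vector("list", length(schedule$fiber_id)),
    paste0("f", schedule$fiber_id)),
    stats::setNames(vector("list", length(schedule$nonspecific_fibers)),
                    schedule$nonspecific_fibers))
  out <- lapply(out, function(x) numeric(0))
  for (i in seq_len(nrow(schedule$presentations))) {
    lab <- schedule$presentations$label[i]
    onset <- schedule$presentations$onset[i]
    for (f in schedule$patterns[[lab]]) {
      key <- paste0("f", f)
      out[[key]] <- c(out[[key]],
                      .profile_spikes(onset, rate_max, rise_ms, tau_adapt,
                                      stim_duration))
    }
    for (key in schedule$nonspecific_fibers)
      out[[key]] <- c(out[[key]],
                      .profile_spikes(onset, rate_max / 2, rise_ms,
                                      tau_adapt, stim_duration))
  }
  lapply(out, .strictify)
}

# enforce sorted, strictly increasing, non-negative spike times
.strictify <- function(x) {
  x <- sort(x[x >= 0])
  while (any(d <- duplicated(x))) x[d] <- x[d] + 1e-3
  sort(x)
}

#' Construct a planted-assembly activity plan
#'
#' Assigns `n_groups` disjoint neuron groups per selected pattern to
#' consecutive latency windows, giving ground truth for assembly-detection
#' recovery scoring.
#'
#' @param network a [gen_network()] object.
#' @param patterns pattern labels to plant sequences for.
#' @param n_groups sequential groups per pattern.
#' @param group_size neurons per group.
#' @param seed RNG seed.
#' @return An `assembly_plan`: `groups` (name -> neuron ids) and `slots`
#'   (group, pattern, slot index).
#' @export
plant_assembly_plan <- function(network, patterns = c("A", "B", "C"),
                                n_groups = 3, group_size = 25, seed = 1) {
  set.seed(seed)
  need <- length(patterns) * n_groups * group_size
  stopifnot(need <= nrow(network$nodes))
  ids <- sample(network$nodes$node_id, need)
  groups <- split(ids, rep(seq_len(length(patterns) * n_groups),
                           each = group_size))
  names(groups) <- paste0("g", seq_along(groups))
  slots <- data.frame(
    group = names(groups),
    pattern = rep(patterns, each = n_groups),
    slot = rep(seq_len(n_groups) - 1L, length(patterns)))
  structure(list(groups = groups, slots = slots), class = "assembly_plan")
}

#' Generate spike trains with planted co-firing assemblies
#'
#' All neurons fire background Poisson spikes at `noise_rate`; at each
#' presentation of a pattern, the groups planted on it fire at
#' `in_window_rate` inside their consecutive `window_ms` latency windows.
#'
#' @param network a [gen_network()] object.
#' @param schedule schedule with presentations.
#' @param plan an [plant_assembly_plan()] object.
#' @param noise_rate background rate, Hz.
#' @param in_window_rate planted within-window rate, Hz.
#' @param window_ms latency window width, ms.
#' @param duration recording length, ms (default: end of last presentation
#'   window plus one inter-stimulus interval).
#' @param seed RNG seed.
#' @return Named list of spike-time vectors keyed by neuron id, with the
#'   plan attached as attribute `"plan"`.
#' @export
gen_planted_activity <- function(network, schedule, plan, noise_rate = 2,
                                 in_window_rate = 100, window_ms = 20,
                                 duration = NULL, seed = 1) {
  if (anyDuplicated(plan$slots[, c("group", "pattern", "slot")]))
    stop("overlapping latency windows for one group")
  pres <- schedule$presentations
  if (is.null(pres)) stop("schedule has no presentations")
  if (is.null(duration)) duration <- max(pres$onset) + schedule$isi
  set.seed(seed)
  ids <- network$nodes$node_id
  out <- stats::setNames(lapply(ids, function(i) {
    n <- rpois(1, noise_rate * duration / 1000)
    runif(n, 0, duration)
  }), as.character(ids))
  for (k in seq_len(nrow(plan$slots))) {
    g <- plan$slots$group[k]; pat <- plan$slots$pattern[k]
    w0 <- plan$slots$slot[k] * window_ms
    onsets <- pres$onset[pres$label == pat]
    for (on in onsets) {
      for (nid in plan$groups[[g]]) {
        key <- as.character(nid)
        n <- rpois(1, in_window_rate * window_ms / 1000)
        out[[key]] <- c(out[[key]], runif(n, on + w0, on + w0 + window_ms))
      }
    }
  }
  out <- lapply(out, .strictify)
  attr(out, "plan") <- plan
  out
}

#' Initialise synaptic states at the two fixed points
#'
#' Each synapse is placed at one of the two stable fixed points of the
#' efficacy dynamics: fully potentiated (`rho = 1`) with probability given
#' by its pathway, otherwise fully depressed (`rho = 0`); `U_SE` and
#' `g_AMPA_hat` are set to the corresponding endpoint values.
#'
#' @param syn_table a [gen_synapses()] table.
#' @param network the network (for layer lookup).
#' @param p_potentiated probability that a synapse starts potentiated:
#'   a single number or a 6x6 matrix indexed by (pre layer, post layer).
#' @param params a [plasticity_params()] object (endpoint values).
#' @param seed RNG seed.
#' @return The synapse table with `rho`, `U_SE`, `g_AMPA_hat` set.
#' @export
init_synapse_states <- function(syn_table, network, p_potentiated = 0.5,
                                params = plasticity_params(), seed = 1) {
  if (any(p_potentiated < 0 | p_potentiated > 1))
    stop("probability outside [0, 1]")
  set.seed(seed)
  if (is.matrix(p_potentiated)) {
    lay <- network$nodes$layer
    p <- p_potentiated[cbind(lay[match(syn_table$pre_node,
                                       network$nodes$node_id)],
                             lay[match(syn_table$post_node,
                                       network$nodes$node_id)])]
  } else p <- rep_len(p_potentiated, nrow(syn_table))
  pot <- runif(nrow(syn_table)) < p
  syn_table$rho <- as.numeric(pot)
  syn_table$U_SE <- ifelse(pot, params$use_p, params$use_d)
  syn_table$g_AMPA_hat <- ifelse(pot, params$g_ampa_p, params$g_ampa_d)
  syn_table
}
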