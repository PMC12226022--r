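#' Pair-based STDP control rule
#'
#' Evaluates the classic exponential pair-based STDP rule on one
#' pre/post spike-train pair: at every postsynaptic spike a potentiation
#' update `A_plus * exp(-dt / tau_plus)` is applied for contributing
#' presynaptic spikes (`dt = t_post - t_pre > 0`), and at every
#' presynaptic spike a depression update `-A_minus * exp(dt / tau_minus)`
#' for post-before-pre pairs (`dt < 0`). Under the `all_to_all` scheme all
#' earlier partner spikes contribute; under `nearest_neighbor` only the
#' most recent one. Weights accumulate without bounds (the rule is used
#' only as a change-magnitude control).
#'
#' @param pre_spikes,post_spikes sorted spike times, ms.
#' @param A_plus,A_minus update amplitudes.
#' @param tau_plus,tau_minus exponential decay windows, ms.
#' @param pairing_scheme `"all_to_all"` or `"nearest_neighbor"`.
#' @return Data frame of updates (`time`, `dw`) ordered in time, with the
#'   cumulative weight `w` after each event.
#' @export
stdp_weight_changes <- function(pre_spikes, post_spikes, A_plus = 0.05,
                                A_minus = 0.05, tau_plus = 20,
                                tau_minus = 20,
                                pairing_scheme = c("all_to_all",
                                                   "nearest_neighbor")) {
  pairing_scheme <- match.arg(pairing_scheme)
  if (is.unsorted(pre_spikes) || is.unsorted(post_spikes))
    stop("spike trains must be sorted")
  ev <- list()
  for (tp in post_spikes) {
    contrib <- pre_spikes[pre_spikes <= tp]
    if (!length(contrib)) next
    if (pairing_scheme == "nearest_neighbor") contrib <- max(contrib)
    ev[[length(ev) + 1]] <- data.frame(
      time = tp, dw = sum(A_plus * exp(-(tp - contrib) / tau_plus)))
  }
  for (tq in pre_spikes) {
    contrib <- post_spikes[post_spikes < tq]
    if (!length(contrib)) next
    if (pairing_scheme == "nearest_neighbor") contrib <- max(contrib)
    ev[[length(ev) + 1]] <- data.frame(
      time = tq, dw = -sum(A_minus * exp(-(tq - contrib) / tau_minus)))
  }
  if (!length(ev))
    return(data.frame(time = numeric(0), dw = numeric(0), w = numeric(0)))
  out <- do.call(rbind, ev)
  out <- out[order(out$time, -sign(out$dw)), ]
  out$w <- cumsum(out$dw)
  rownames(out) <- NULL
  out
}

#' L2 norm of efficacy changes over time
#'
#' Per report time, the Euclidean norm over synapses of the difference
#' between the trace and a reference: the previous report time
#' (`"previous"`), the initial state (`"t0"`), or the state at a fixed
#' time (`"fixed"`, e.g. the 5-minute mark).
#'
#' @param trace a `plasticity_trace` or a synapse-by-time matrix.
#' @param reference `"previous"`, `"t0"`, or `"fixed"`.
#' @param t_fixed_s reference time for `"fixed"`, s.
#' @return Data frame (`time_s`, `l2`).
#' @export
change_norm_series <- function(trace, reference = c("previous", "t0",
                                                    "fixed"),
                               t_fixed_s = 300) {
  reference <- match.arg(reference)
  m <- if (is.matrix(trace)) trace else trace$rho
  tt <- if (is.matrix(trace)) seq_len(ncol(trace)) else trace$time_s
  l2 <- switch(reference,
    previous = c(NA, sqrt(colSums((m[, -1, drop = FALSE] -
                                   m[, -ncol(m), drop = FALSE])^2))),
    t0 = sqrt(colSums((m - m[, 1])^2)),
    fixed = {
      j <- which.min(abs(tt - t_fixed_s))
      sqrt(colSums((m - m[, j])^2))
    })
  data.frame(time_s = tt, l2 = l2)
}

#' Mean per-step change norm after a settling period
#'
#' The step size of the matched random-walk control: the mean over report
#' steps beyond `t_min_s` of the L2 norm of consecutive-state differences.
#'
#' @param trace a `plasticity_trace` or synapse-by-time matrix.
#' @param t_min_s settling period to discard, s.
#' @return Scalar step size `l`.
#' @export
fit_step_size <- function(trace, t_min_s = 300) {
  m <- if (is.matrix(trace)) trace else trace$rho
  tt <- if (is.matrix(trace)) seq_len(ncol(m)) else trace$time_s
  keep <- which(tt > t_min_s)
  if (length(keep) < 2) stop("fewer than 2 report times after t_min")
  d <- m[, keep[-1], drop = FALSE] - m[, keep[-length(keep)], drop = FALSE]
  mean(sqrt(colSums(d^2)))
}

#' K-dimensional random-walk displacement control
#'
#' Each step moves all `K` coordinates by `+-epsilon` independently with
#' equal probability, so every step has norm exactly `epsilon * sqrt(K)`;
#' the displacement from the origin after `n` steps concentrates around
#' `l * sqrt(n)` with `l = epsilon * sqrt(K)`. `"analytic"` mode returns
#' that approximation directly.
#'
#' @param K number of changing connections (walk dimension).
#' @param N number of steps.
#' @param epsilon per-connection step.
#' @param seed RNG seed (simulate mode).
#' @param mode `"simulate"` or `"analytic"`.
#' @return Data frame (`step`, `displacement`) for steps 0..N.
#' @export
random_walk_displacement <- function(K, N, epsilon = 0.01, seed = 1,
                                     mode = c("simulate", "analytic")) {
  mode <- match.arg(mode)
  if (K < 1 || N < 0) stop("K must be >= 1 and N >= 0")
  l <- epsilon * sqrt(K)
  if (mode == "analytic")
    return(data.frame(step = 0:N, displacement = l * sqrt(0:N)))
  set.seed(seed)
  pos <- numeric(K)
  disp <- numeric(N + 1)
  for (n in seq_len(N)) {
    pos <- pos + epsilon * sample(c(-1, 1), K, replace = TRUE)
    disp[n + 1] <- sqrt(sum(pos^2))
  }
  data.frame(step = 0:N, displacement = disp)
}

#' Rate-matched control neuron set
#'
#' Samples, without replacement, a control set of the same size as the
#' assembly whose firing-rate distribution matches the assembly's by
#' stratified sampling over the assembly's rate deciles. Assembly members
#' are excluded from the candidate pool unless that makes matching
#' impossible, in which case the result is flagged.
#'
#' @param assembly_neurons neuron ids of the assembly.
#' @param population_rates named vector of firing rates for the whole
#'   population (names = neuron ids).
#' @param seed RNG seed.
#' @return Character vector of control ids; attribute `"flagged"` is TRUE
#'   when members could not be excluded.
#' @export
rate_matched_control <- function(assembly_neurons, population_rates,
                                 seed = 1) {
  if (!length(assembly_neurons)) stop("empty assembly")
  assembly_neurons <- as.character(assembly_neurons)
  set.seed(seed)
  rates <- population_rates[assembly_neurons]
  br <- unique(quantile(rates, seq(0, 1, 0.1), names = FALSE))
  bin <- findInterval(rates, br, rightmost.closed = TRUE, all.inside = TRUE)
  pool_ids <- setdiff(names(population_rates), assembly_neurons)
  flagged <- FALSE
  if (length(pool_ids) < length(assembly_neurons)) {
    pool_ids <- names(population_rates)
    flagged <- TRUE
  }
  pool_bin <- findInterval(population_rates[pool_ids], br,
                           rightmost.closed = TRUE, all.inside = TRUE)
  chosen <- character(0)
  for (b in sort(unique(bin))) {
    need <- sum(bin == b)
    cand <- setdiff(pool_ids[pool_bin == b], chosen)
    if (length(cand) < need) {        # borrow nearest-rate neurons
      extra <- setdiff(pool_ids, c(chosen, cand))
      ord <- extra[order(abs(population_rates[extra] -
                             stats::median(rates[bin == b])))]
      cand <- c(cand, ord)
      flagged <- flagged || length(cand) < need
    }
    chosen <- c(chosen, if (length(cand) > need)
      sample(cand, need) else cand[seq_len(min(need, length(cand)))])
  }
  structure(chosen, flagged = flagged)
}

#' Random changing-subgraph control
#'
#' Uniformly samples as many edges as the changing set from all network
#' edges whose endpoints both lie inside the changing subgraph's node set,
#' preserving the node set and edge count (hence the 0- and 1-simplex
#' counts) exactly.
#'
#' @param changing_edges data frame (`pre`, `post`), a subset of the
#'   network's edges.
#' @param network a [gen_network()] object.
#' @param seed RNG seed.
#' @return Data frame (`pre`, `post`) of control edges.
#' @export
random_changing_subgraph <- function(changing_edges, network, seed = 1) {
  ek <- function(e) paste(e$pre, e$post)
  if (!all(ek(changing_edges) %in% ek(network$edges)))
    stop("changing edges must be a subset of the network's edges")
  nodes <- unique(c(changing_edges$pre, changing_edges$post))
  cand <- network$edges[network$edges$pre %in% nodes &
                        network$edges$post %in% nodes, ]
  if (nrow(cand) < nrow(changing_edges))
    stop("not enough candidate edges inside the changing node set")
  set.seed(seed)
  out <- cand[sample.int(nrow(cand), nrow(changing_edges)), ]
  out <- out[order(out$pre, out$post), ]
  rownames(out) <- NULL
  out
}
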