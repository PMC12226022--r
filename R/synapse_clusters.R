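#' Detect spatial synapse clusters on a neuron's dendrites
#'
#' Seed rule: a synapse qualifies when at least `min_members - 1` other
#' synapses sit on the same branch within `radius` um along-branch
#' distance. Qualifying synapses within `radius` of each other on the same
#' branch are merged transitively, so clusters can span more than
#' `2 * radius` through chained windows; resulting clusters have at least
#' `min_members` members.
#'
#' @param syn_table synapse table with `post_node`, `branch_id`,
#'   `path_offset`.
#' @param neuron postsynaptic neuron id.
#' @param radius window radius, um.
#' @param min_members minimum cluster size (seed: "at least nine other
#'   synapses" for the default 10).
#' @return List of `synapse_cluster` lists: `post_neuron`, `branch_id`,
#'   `syn_ids`, `span`.
#' @export
detect_clusters <- function(syn_table, neuron, radius = 10,
                            min_members = 10) {
  st <- syn_table[syn_table$post_node == neuron, ]
  if (!nrow(st)) return(list())
  if (any(is.na(st$path_offset)) || is.null(st$branch_id))
    stop("missing branch/offset geometry")
  out <- list()
  for (b in unique(st$branch_id)) {
    sb <- st[st$branch_id == b, ]
    if (nrow(sb) < min_members) next
    off <- sb$path_offset
    within <- abs(outer(off, off, "-")) <= radius
    qualifies <- rowSums(within) >= min_members # self + (min-1) others
    if (!any(qualifies)) next
    q <- which(qualifies)
    g <- igraph::graph_from_adjacency_matrix(
      within[q, q, drop = FALSE], mode = "undirected", diag = FALSE)
    comp <- igraph::components(g)$membership
    for (cid in unique(comp)) {
      mem <- q[comp == cid]
      if (length(mem) < min_members) next
      out[[length(out) + 1]] <- structure(
        list(post_neuron = neuron, branch_id = b,
             syn_ids = sb$syn_id[mem],
             span = diff(range(off[mem]))),
        class = "synapse_cluster")
    }
  }
  out
}

# consecutive inter-synapse (gap) distances along a branch; iid Exp(lambda)
# under a homogeneous Poisson placement
.gap_distances <- function(offsets) {
  if (length(offsets) < 2) return(numeric(0))
  diff(sort(offsets))
}

# nearest-neighbour along-branch distances within a synapse subset
.nn_distances <- function(offsets) {
  if (length(offsets) < 2) return(numeric(0))
  o <- sort(offsets)
  gaps <- diff(o)
  vapply(seq_along(o), function(i) {
    lo <- if (i > 1) gaps[i - 1] else Inf
    hi <- if (i < length(o)) gaps[i] else Inf
    min(lo, hi)
  }, numeric(1))
}

#' Significance of a synapse cluster against an exponential distance null
#'
#' Under a homogeneous Poisson placement of synapses along branches, the
#' consecutive inter-synapse distances are iid exponential; the rate
#' `lambda` is fitted as `1 / mean` of all same-branch neighbour
#' distances on the neuron. The cluster's neighbour distances are tested
#' one-sided for being shorter than that null: their sum is compared with
#' the lower tail of a Gamma(n, lambda) distribution (n = number of
#' cluster neighbour distances). Exact zero distances are jittered by
#' machine epsilon (flagged via the `jittered` attribute).
#'
#' @param cluster a `synapse_cluster` from [detect_clusters()].
#' @param syn_table synapse table of the same neuron (null distances).
#' @return p-value (small = significantly clustered).
#' @export
cluster_significance <- function(cluster, syn_table) {
  st <- syn_table[syn_table$post_node == cluster$post_neuron, ]
  all_gap <- unlist(lapply(split(st$path_offset, st$branch_id),
                           .gap_distances))
  if (length(all_gap) < 2) stop("need >= 2 same-branch neighbour distances")
  jittered <- FALSE
  sb <- st[st$branch_id == cluster$branch_id, ]
  off <- sb$path_offset[sb$syn_id %in% cluster$syn_ids]
  d <- .gap_distances(off)
  if (any(d == 0)) { d[d == 0] <- .Machine$double.eps; jittered <- TRUE }
  all_gap <- all_gap[all_gap > 0]
  lambda <- 1 / mean(all_gap)
  structure(pgamma(sum(d), shape = length(d), rate = lambda),
            jittered = jittered)
}

#' Synaptic clustering coefficient (SCC) of assembly synapses on a neuron
#'
#' Quantifies co-localisation of the synapses a neuron receives from a
#' presynaptic assembly: the z-score, against `n_controls` random
#' same-size synapse subsets on the same neuron, of the mean
#' nearest-neighbour along-branch distance among the assembly synapses,
#' sign-flipped so larger means more clustered.
#'
#' @param syn_table synapse table.
#' @param neuron postsynaptic neuron id.
#' @param assembly presynaptic assembly neuron ids.
#' @param n_controls random subsets.
#' @param seed RNG seed.
#' @return z-score (NA when the neuron has < 2 assembly synapses).
#' @export
synaptic_clustering_coefficient <- function(syn_table, neuron, assembly,
                                            n_controls = 1000, seed = 1) {
  st <- syn_table[syn_table$post_node == neuron, ]
  sel <- st$pre_node %in% assembly
  if (sum(sel) < 2 || nrow(st) <= sum(sel)) return(NA_real_)
  mean_nn <- function(rows) {
    d <- unlist(lapply(split(rows$path_offset, rows$branch_id),
                       .nn_distances))
    if (!length(d)) return(NA_real_)
    mean(d)
  }
  obs <- mean_nn(st[sel, ])
  if (is.na(obs)) return(NA_real_)
  set.seed(seed)
  ctrl <- vapply(seq_len(n_controls), function(i)
    mean_nn(st[sample.int(nrow(st), sum(sel)), ]), numeric(1))
  ctrl <- ctrl[!is.na(ctrl)]
  if (length(ctrl) < 2 || sd(ctrl) == 0) return(NA_real_)
  -(obs - mean(ctrl)) / sd(ctrl)
}

#' Select target neurons by assembly indegree and synaptic clustering
#'
#' Assembly indegree is the number of presynaptic assembly members
#' connected to a neuron; the synaptic clustering coefficient scores
#' co-localisation of those synapses. Candidate neurons are ranked by the
#' product of their two ranks (larger = better on both) and the top
#' `n_select` are returned.
#'
#' @param assembly presynaptic assembly neuron ids.
#' @param syn_table synapse table.
#' @param network the network.
#' @param n_select neurons to select.
#' @param candidates candidate postsynaptic ids (default: all neurons with
#'   at least one assembly synapse, excluding assembly members).
#' @param n_controls,seed passed to [synaptic_clustering_coefficient()].
#' @return Data frame of selected neurons with `assembly_indegree` and
#'   `scc`, ordered best first.
#' @export
select_target_neurons <- function(assembly, syn_table, network,
                                  n_select = 10, candidates = NULL,
                                  n_controls = 200, seed = 1) {
  if (!length(assembly)) stop("empty assembly")
  ed <- network$edges
  from_asm <- ed[ed$pre %in% assembly, ]
  if (!nrow(from_asm)) stop("assembly has no efferent connections")
  if (is.null(candidates))
    candidates <- setdiff(unique(from_asm$post), assembly)
  indeg <- vapply(candidates, function(v)
    sum(from_asm$post == v), numeric(1))
  scc <- vapply(seq_along(candidates), function(i)
    synaptic_clustering_coefficient(syn_table, candidates[i], assembly,
                                    n_controls, seed + i), numeric(1))
  scc[is.na(scc)] <- -Inf
  score <- rank(indeg, ties.method = "average") *
    rank(scc, ties.method = "average")
  ord <- order(-score, -indeg, candidates)
  data.frame(neuron = candidates, assembly_indegree = indeg,
             scc = scc)[utils::head(ord, n_select), ]
}

#' Michelson contrast of an outcome within synapse categories
#'
#' `(P(outcome | category) - P(outcome)) / (P(outcome | category) +
#' P(outcome))`, bounded in \[-1, 1\]; 0 when both probabilities are 0.
#' Empty categories are reported as `NA`.
#'
#' @param category factor of category labels per synapse.
#' @param outcome_flag logical per synapse: did the outcome occur.
#' @return Named vector of contrasts per category level.
#' @export
michelson_contrast <- function(category, outcome_flag) {
  category <- as.factor(category)
  p_all <- mean(outcome_flag)
  vapply(levels(category), function(lv) {
    sel <- category == lv
    if (!any(sel)) return(NA_real_)
    p_cat <- mean(outcome_flag[sel])
    if (p_cat + p_all == 0) return(0)
    (p_cat - p_all) / (p_cat + p_all)
  }, numeric(1))
}

#' Classify synapses into assembly-by-cluster categories with outcomes
#'
#' Builds the four-way category table (assembly vs non-assembly crossed
#' with clustered vs non-clustered) plus the plasticity outcome of each
#' synapse from a trace.
#'
#' @param syn_table synapse table (rows analysed).
#' @param trace a `plasticity_trace` covering those synapses.
#' @param assembly presynaptic assembly neuron ids.
#' @param clustered_syn_ids synapse ids inside detected clusters.
#' @param tolerance change threshold on `|delta rho|`.
#' @return Data frame: `syn_id`, `category`, `outcome`, `rho0`,
#'   `delta_rho`.
#' @export
categorize_synapses <- function(syn_table, trace, assembly,
                                clustered_syn_ids, tolerance = 1e-3) {
  idx <- match(syn_table$syn_id, trace$syn_id)
  if (any(is.na(idx))) stop("trace does not cover the synapse table")
  delta <- trace$rho[idx, ncol(trace$rho)] - trace$rho0[idx]
  outcome <- ifelse(abs(delta) <= tolerance, "unchanged",
                    ifelse(delta > 0, "potentiated", "depressed"))
  cat4 <- paste0(ifelse(syn_table$pre_node %in% assembly, "assembly",
                        "non-assembly"), "_",
                 ifelse(syn_table$syn_id %in% clustered_syn_ids,
                        "clustered", "non-clustered"))
  data.frame(syn_id = syn_table$syn_id,
             category = factor(cat4, levels = c(
               "assembly_clustered", "assembly_non-clustered",
               "non-assembly_clustered", "non-assembly_non-clustered")),
             outcome = outcome, rho0 = trace$rho0[idx], delta_rho = delta)
}

#' Change amplitudes across categories with a two-way ANOVA
#'
#' Mean efficacy change per (assembly x clustered) cell, with main
#' effects and interaction from a two-way analysis of variance.
#'
#' @param delta_rho efficacy changes.
#' @param assembly logical: presynaptic assembly synapse.
#' @param clustered logical: synapse inside a spatial cluster.
#' @return List: `cell_means` (2x2), `anova` (the summary table).
#' @export
amplitude_by_category <- function(delta_rho, assembly, clustered) {
  df <- data.frame(y = delta_rho, a = factor(assembly),
                   c = factor(clustered))
  if (nlevels(df$a) < 2 || nlevels(df$c) < 2 ||
      any(table(df$a, df$c) < 2)) stop("empty or singleton category cell")
  fit <- aov(y ~ a * c, data = df)
  list(cell_means = tapply(df$y, list(assembly = df$a, clustered = df$c),
                           mean),
       anova = summary(fit)[[1]])
}
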