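#' @name topology
#' @title Directed simplex counts and k-edge indegree
#'
#' @description
#' A directed k-simplex is a set of k+1 nodes that are all-to-all
#' connected in a feedforward fashion: some ordering `v0, ..., vk` has an
#' edge `vi -> vj` for every `i < j`. 0-simplices are nodes, 1-simplices
#' edges, 2-simplices transitive triads. The k-edge indegree of an edge
#' `(u, v)` is the number of k-simplices whose every node innervates both
#' `u` and `v` — equivalently, the number of (k+2)-simplices in which
#' `(u, v)` is the edge from the next-to-last to the last node. Counts are
#' obtained by vertex-ordered depth-first search over successively
#' intersected out-neighbourhoods; reciprocal edges are two directed
#' edges, self-loops are rejected.
NULL

# sorted out-adjacency lists from an edge data frame over nodes 1..n
.adj_out <- function(edges, n) {
  a <- rep(list(integer(0)), n)
  if (nrow(edges)) {
    sp <- split(edges$post, edges$pre)
    a[as.integer(names(sp))] <- lapply(sp, function(v) sort(as.integer(v)))
  }
  a
}

.edges_of <- function(network) {
  if (inherits(network, "directed_network")) network$edges else network
}

# map arbitrary node ids to 1..n; returns list(edges, ids)
.canonical_edges <- function(edges, node_ids = NULL) {
  if (is.null(node_ids)) node_ids <- sort(unique(c(edges$pre, edges$post)))
  if (any(edges$pre == edges$post)) stop("self-loops present")
  if (anyDuplicated(paste(edges$pre, edges$post))) stop("duplicate edges")
  list(edges = data.frame(pre = match(edges$pre, node_ids),
                          post = match(edges$post, node_ids)),
       ids = node_ids)
}

#' Count directed simplices by dimension
#'
#' @param network a `directed_network` or an edge data frame (`pre`,
#'   `post`).
#' @param max_dim largest simplex dimension to count.
#' @param node_ids node universe (needed for the 0-simplex count when
#'   passing a bare edge list with isolated nodes).
#' @return Integer vector of counts for dimensions `0..max_dim` (named
#'   `dim0`, `dim1`, ...); zero beyond the top non-empty dimension, with
#'   early stop once a dimension is empty.
#' @export
simplex_counts <- function(network, max_dim = 6, node_ids = NULL) {
  edges <- .edges_of(network)
  if (is.null(node_ids) && inherits(network, "directed_network"))
    node_ids <- network$nodes$node_id
  cn <- .canonical_edges(edges, node_ids)
  n <- length(cn$ids)
  adj <- .adj_out(cn$edges, n)
  counts <- numeric(max_dim + 1)
  counts[1] <- n
  if (max_dim >= 1) {
    dfs <- function(cands, dim) {
      counts[dim + 1] <<- counts[dim + 1] + length(cands)
      if (dim == max_dim) return(invisible())
      for (u in cands) {
        nxt <- cands[match(cands, adj[[u]], nomatch = 0L) > 0L]
        if (length(nxt)) dfs(nxt, dim + 1)
      }
    }
    for (v in seq_len(n)) if (length(adj[[v]])) dfs(adj[[v]], 1)
  }
  stats::setNames(counts, paste0("dim", 0:max_dim))
}

#' Enumerate directed simplices of one dimension
#'
#' Memory-hungry companion of [simplex_counts()]; intended for small
#' graphs (cross-checks, last-edge counting).
#'
#' @inheritParams simplex_counts
#' @param dim simplex dimension to list.
#' @return Matrix with one simplex per row (node ids, feedforward order).
#' @export
simplex_list <- function(network, dim, node_ids = NULL) {
  edges <- .edges_of(network)
  if (is.null(node_ids) && inherits(network, "directed_network"))
    node_ids <- network$nodes$node_id
  cn <- .canonical_edges(edges, node_ids)
  n <- length(cn$ids)
  adj <- .adj_out(cn$edges, n)
  out <- list()
  dfs <- function(prefix, cands, d) {
    if (d == dim) {
      for (u in cands) out[[length(out) + 1]] <<- c(prefix, u)
      return(invisible())
    }
    for (u in cands) {
      nxt <- cands[match(cands, adj[[u]], nomatch = 0L) > 0L]
      if (length(nxt)) dfs(c(prefix, u), nxt, d + 1)
    }
  }
  if (dim == 0) return(matrix(cn$ids, ncol = 1))
  for (v in seq_len(n)) if (length(adj[[v]])) dfs(v, adj[[v]], 1)
  if (!length(out))
    return(matrix(integer(0), ncol = dim + 1))
  m <- do.call(rbind, out)
  matrix(cn$ids[m], ncol = dim + 1)
}

#' k-edge indegree of every edge
#'
#' For each edge `(u, v)`, the subgraph induced on the common
#' in-neighbours `{w : w -> u and w -> v}` is extracted and its k-simplex
#' counts give the k-edge indegrees; `k = 0` is the common in-neighbour
#' count.
#'
#' @param network a `directed_network` or edge data frame.
#' @param k_max largest k.
#' @return Data frame: `pre`, `post`, `k0` ... `k<k_max>`, edges sorted.
#' @export
k_edge_indegree <- function(network, k_max = 6) {
  edges <- .edges_of(network)
  cn <- .canonical_edges(edges)
  n <- length(cn$ids)
  e <- cn$edges[order(cn$edges$pre, cn$edges$post), ]
  adj_in <- rep(list(integer(0)), n)
  sp <- split(e$pre, e$post)
  adj_in[as.integer(names(sp))] <- lapply(sp, function(v) sort(as.integer(v)))
  res <- matrix(0, nrow(e), k_max + 1)
  for (i in seq_len(nrow(e))) {
    w <- adj_in[[e$pre[i]]]
    w <- w[match(w, adj_in[[e$post[i]]], nomatch = 0L) > 0L]
    if (!length(w)) next
    sub <- e[e$pre %in% w & e$post %in% w, ]
    res[i, ] <- simplex_counts(sub, k_max, node_ids = w)
  }
  out <- data.frame(pre = cn$ids[e$pre], post = cn$ids[e$post], res)
  names(out)[-(1:2)] <- paste0("k", 0:k_max)
  out
}

#' k-edge indegree within an induced node-subset subgraph
#'
#' @param network a `directed_network` or edge data frame.
#' @param node_subset node ids defining the induced subgraph.
#' @param k_max largest k.
#' @return As [k_edge_indegree()], restricted to subgraph edges.
#' @export
subgraph_edge_centrality <- function(network, node_subset, k_max = 6) {
  if (!length(node_subset)) stop("empty node subset")
  edges <- .edges_of(network)
  sub <- edges[edges$pre %in% node_subset & edges$post %in% node_subset, ]
  if (!nrow(sub))
    return(data.frame(pre = integer(0), post = integer(0)))
  k_edge_indegree(sub, k_max)
}

#' Pattern indegree of a neuron
#'
#' Number of a pattern's fibers with an innervation edge onto the node.
#'
#' @param innervation_map data frame (`fiber`, `neuron`) of fiber-to-neuron
#'   edges.
#' @param pattern_fibers fiber ids of the pattern.
#' @param node neuron id.
#' @param nodes optional node universe; when given, `node` must belong to
#'   it (a member without innervation then counts 0).
#' @return Integer count.
#' @export
pattern_indegree <- function(innervation_map, pattern_fibers, node,
                             nodes = unique(innervation_map$neuron)) {
  if (!node %in% nodes) stop("unknown node")
  sum(innervation_map$neuron == node &
        innervation_map$fiber %in% pattern_fibers)
}

#' Probability of plastic change binned by an edge metric
#'
#' Per metric bin: the probability that an edge changed, and the
#' probabilities of depression and potentiation conditioned on change.
#' Integer bins are used when the metric range is small (or
#' `binning = "integer"`), logarithmic bins otherwise; bins with fewer
#' than `min_count` edges are suppressed.
#'
#' @param edge_flags factor/character with levels `unchanged`,
#'   `depressed`, `potentiated`, aligned with `metric_values`.
#' @param metric_values numeric metric per edge (e.g. a k-edge indegree).
#' @param binning `"auto"`, `"integer"` or `"log"`.
#' @param min_count minimum edges per reported bin.
#' @param n_bins number of logarithmic bins.
#' @return Data frame: bin label, mid value, `n`, `p_changed`,
#'   `p_dep_given_changed`, `p_pot_given_changed`.
#' @export
prob_change_vs_metric <- function(edge_flags, metric_values,
                                  binning = c("auto", "integer", "log"),
                                  min_count = 50, n_bins = 8) {
  binning <- match.arg(binning)
  if (length(edge_flags) != length(metric_values))
    stop("flags and metric values are not aligned")
  edge_flags <- as.character(edge_flags)
  stopifnot(all(edge_flags %in% c("unchanged", "depressed", "potentiated")))
  if (binning == "auto")
    binning <- if (max(metric_values) <= 12) "integer" else "log"
  if (binning == "integer") {
    bin <- floor(metric_values)
    mids <- sort(unique(bin))
  } else {
    v <- log1p(metric_values)
    br <- seq(min(v), max(v) + 1e-9, length.out = n_bins + 1)
    bin <- findInterval(v, br, rightmost.closed = TRUE)
    mids <- expm1((br[-1] + br[-length(br)]) / 2)
  }
  out <- do.call(rbind, lapply(seq_along(sort(unique(bin))), function(j) {
    b <- sort(unique(bin))[j]
    sel <- bin == b
    n <- sum(sel)
    ch <- edge_flags[sel] != "unchanged"
    data.frame(bin = b,
               mid = if (binning == "integer") b else mids[b],
               n = n, p_changed = mean(ch),
               p_dep_given_changed =
                 if (any(ch)) mean(edge_flags[sel][ch] == "depressed")
                 else NA_real_,
               p_pot_given_changed =
                 if (any(ch)) mean(edge_flags[sel][ch] == "potentiated")
                 else NA_real_)
  }))
  out[out$n >= min_count, ]
}
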