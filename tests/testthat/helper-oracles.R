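# Independent brute-force oracles used to validate the efficient
# implementations. These deliberately avoid the package's ordered-DFS /
# assignment code paths.

# all permutations of a vector (recursive, no dependencies)
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

.perm_cache <- new.env()
perms_of_size <- function(s) {
  key <- as.character(s)
  if (is.null(.perm_cache[[key]])) .perm_cache[[key]] <- all_perms(seq_len(s))
  .perm_cache[[key]]
}

# brute-force directed simplex counts: for every node subset, count the
# orderings whose forward pairs are all edges
brute_simplex_counts <- function(edges, n, max_dim = 6) {
  A <- matrix(FALSE, n, n)
  if (nrow(edges)) A[cbind(edges$pre, edges$post)] <- TRUE
  counts <- numeric(max_dim + 1)
  counts[1] <- n
  for (d in seq_len(max_dim)) {
    s <- d + 1
    if (s > n) break
    cnt <- 0
    for (S in utils::combn(n, s, simplify = FALSE)) {
      if (sum(A[S, S]) < choose(s, 2)) next
      for (p in perms_of_size(s)) {
        v <- S[p]
        ok <- TRUE
        for (i in 1:(s - 1)) {
          if (!all(A[v[i], v[(i + 1):s]])) { ok <- FALSE; break }
        }
        if (ok) cnt <- cnt + 1
      }
    }
    counts[d + 1] <- cnt
    if (cnt == 0) break
  }
  counts
}

# brute-force simplex enumeration (same permutation scan, keeps the lists)
brute_simplex_list <- function(edges, n, dim) {
  A <- matrix(FALSE, n, n)
  if (nrow(edges)) A[cbind(edges$pre, edges$post)] <- TRUE
  s <- dim + 1
  out <- list()
  if (s > n) return(out)
  for (S in utils::combn(n, s, simplify = FALSE)) {
    if (sum(A[S, S]) < choose(s, 2)) next
    for (p in perms_of_size(s)) {
      v <- S[p]
      ok <- TRUE
      for (i in 1:(s - 1)) {
        if (!all(A[v[i], v[(i + 1):s]])) { ok <- FALSE; break }
      }
      if (ok) out[[length(out) + 1]] <- v
    }
  }
  out
}

# brute-force k-edge indegree by last-edge counting over (k+2)-simplices
brute_k_edge_indegree <- function(edges, n, k) {
  sims <- brute_simplex_list(edges, n, k + 2)
  key <- paste(edges$pre, edges$post)
  cnt <- stats::setNames(rep(0, length(key)), key)
  for (v in sims) {
    e <- paste(v[length(v) - 1], v[length(v)])
    cnt[e] <- cnt[e] + 1
  }
  cnt
}

# random simple digraph as an edge data frame
random_digraph <- function(n, p, seed) {
  set.seed(seed)
  idx <- expand.grid(pre = seq_len(n), post = seq_len(n))
  idx <- idx[idx$pre != idx$post, ]
  idx[runif(nrow(idx)) < p, ]
}

# brute-force EMD for equal-size uniform clouds: min over permutations
brute_emd_equal <- function(x, y) {
  n <- nrow(x)
  cost <- as.matrix(stats::dist(rbind(x, y)))[seq_len(n), n + seq_len(n),
                                              drop = FALSE]
  best <- Inf
  for (p in perms_of_size(n))
    best <- min(best, mean(cost[cbind(seq_len(n), p)]))
  best
}

# a one-synapse table with thresholds, for engine protocols
one_synapse <- function(rho0 = 0.5, path_offset = 20,
                        params = plasticity_params()) {
  s <- data.frame(syn_id = 1L, pre_node = 1L, post_node = 2L,
                  branch_id = 1L, path_offset = path_offset,
                  neurite_kind = "basal", rho = rho0, U_SE = params$use_d,
                  g_AMPA_hat = params$g_ampa_d, g_NMDA_hat = 0.5,
                  plastic = TRUE)
  add_thresholds(s, params = params)
}

# burst-pairing protocol spike trains (pre/post lag in ms)
pairing_trains <- function(lag, n_bursts = 3, pairs_per_burst = 20,
                           hz = 20, burst_gap = 5000) {
  pre <- as.vector(outer(seq_len(pairs_per_burst) * 1000 / hz,
                         seq_len(n_bursts) * burst_gap - burst_gap + 500,
                         "+"))
  list(pre = sort(pre), post = sort(pre + lag))
}
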