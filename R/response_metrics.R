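#' Summary of plastic changes in a trace
#'
#' Classifies every synapse (and every connection, via its mean efficacy)
#' as depressed, potentiated or unchanged by the sign of the last-minus-
#' first difference beyond `tolerance`; detects each synapse's first
#' crossing of the unstable fixed point with its direction; and breaks
#' fractions down by post-synaptic layer and neurite kind when the
#' synapse table is supplied.
#'
#' @param trace a `plasticity_trace`.
#' @param syn_table optional synapse table (layer / neurite breakdown).
#' @param network optional network (for layer lookup).
#' @param tolerance change threshold on `|delta rho|`.
#' @param rho_star unstable fixed point.
#' @return A `change_summary` list: per-level fractions, crossing counts,
#'   cumulative crossing-time curves, and `delta_g_ampa` moments.
#' @export
change_summary <- function(trace, syn_table = NULL, network = NULL,
                           tolerance = 1e-3, rho_star = 0.5) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  m <- trace$rho
  if (ncol(m) < 2) stop("trace needs >= 2 report times")
  first <- if (!is.null(trace$rho0)) trace$rho0 else m[, 1]
  delta <- m[, ncol(m)] - first
  cls <- ifelse(abs(delta) <= tolerance, "unchanged",
                ifelse(delta > 0, "potentiated", "depressed"))
  frac <- function(x) {
    t <- table(factor(x, c("depressed", "potentiated", "unchanged")))
    as.list(t / length(x))
  }
  # first rho* crossing per synapse
  above <- cbind(first, m) > rho_star
  crossed <- apply(above, 1, function(a) {
    j <- which(a[-1] != a[-length(a)])[1]
    if (is.na(j)) c(NA, NA) else c(j, ifelse(a[j + 1], 1, -1))
  })
  cross_t <- trace$time_s[crossed[1, ]]
  cross_dir <- crossed[2, ]
  curve <- function(tt) {
    tt <- sort(tt[!is.na(tt)])
    data.frame(time_s = tt, cum_count = seq_along(tt))
  }
  conn <- NULL
  if (!is.null(trace$pre_node)) {
    key <- paste(trace$pre_node, trace$post_node)
    cmean_first <- tapply(first, key, mean)
    cmean_last <- tapply(m[, ncol(m)], key, mean)
    cdelta <- cmean_last - cmean_first
    conn <- ifelse(abs(cdelta) <= tolerance, "unchanged",
                   ifelse(cdelta > 0, "potentiated", "depressed"))
  }
  by_layer <- by_kind <- NULL
  if (!is.null(syn_table)) {
    idx <- match(trace$syn_id, syn_table$syn_id)
    if (!is.null(network)) {
      lay <- network$nodes$layer[match(syn_table$post_node[idx],
                                       network$nodes$node_id)]
      by_layer <- tapply(cls, lay, function(x) unlist(frac(x)))
    }
    if (!is.null(syn_table$neurite_kind))
      by_kind <- tapply(cls, syn_table$neurite_kind[idx],
                        function(x) unlist(frac(x)))
  }
  dg <- trace$g_AMPA[, ncol(trace$g_AMPA)] - trace$g_AMPA[, 1]
  structure(list(
    synapse = c(frac(cls), n = length(cls)),
    connection = if (!is.null(conn)) c(frac(conn), n = length(conn)),
    class_by_synapse = cls,
    class_by_connection = conn,
    crossings = list(
      n_up = sum(cross_dir == 1, na.rm = TRUE),
      n_down = sum(cross_dir == -1, na.rm = TRUE),
      curve_up = curve(cross_t[cross_dir == 1]),
      curve_down = curve(cross_t[cross_dir == -1])),
    by_layer = by_layer, by_neurite = by_kind,
    delta_g_ampa = c(mean = mean(dg), sd = sd(dg))),
    class = "change_summary")
}

#' Pairwise Pearson correlations of binned spike counts
#'
#' @param binned a [bin_spikes()] object (optionally z-score the counts
#'   per session before pooling by passing `zscore = TRUE`).
#' @param pairs two-column matrix/data frame of source ids.
#' @param zscore z-score each neuron's counts first.
#' @return Data frame `a`, `b`, `r`; zero-variance members yield `NA`
#'   (reported, not dropped).
#' @export
pairwise_correlations <- function(binned, pairs, zscore = FALSE) {
  if (ncol(binned$counts) < 2) stop("need >= 2 bins")
  pairs <- as.matrix(pairs)
  bad <- !(pairs %in% binned$sources)
  if (any(bad)) stop("pair references unknown neuron")
  x <- binned$counts
  rownames(x) <- binned$sources
  if (zscore) x <- t(scale(t(x)))
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- x[pairs[i, 1], ]; b <- x[pairs[i, 2], ]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1))
  data.frame(a = pairs[, 1], b = pairs[, 2], r = r)
}

#' Spike-time reliability across stimulus repetitions
#'
#' Each repetition's spikes are binned at 1 ms, convolved with a Gaussian
#' kernel (sigma 10 ms by default) and mean-centred; reliability is the
#' mean cosine similarity over all repetition pairs. Pairs with an empty
#' repetition contribute 0 (counted, reported via attribute
#' `n_empty_pairs`).
#'
#' @param spikes_by_repetition list of spike-time vectors, one per
#'   repetition, each relative to its own window start, ms.
#' @param sigma_ms Gaussian kernel width.
#' @param window_ms analysis window (default: latest spike).
#' @return Scalar reliability in \[-1, 1\].
#' @export
spike_time_reliability <- function(spikes_by_repetition, sigma_ms = 10,
                                   window_ms = NULL) {
  n <- length(spikes_by_repetition)
  if (n < 2) stop("need >= 2 repetitions")
  if (all(lengths(spikes_by_repetition) == 0))
    stop("all repetitions empty")
  if (is.null(window_ms))
    window_ms <- ceiling(max(unlist(spikes_by_repetition))) + 1
  kern_t <- seq(-4 * sigma_ms, 4 * sigma_ms)
  kern <- dnorm(kern_t, sd = sigma_ms)
  smooth1 <- function(sp) {
    v <- tabulate(findInterval(sp[sp >= 0 & sp < window_ms],
                               seq(0, window_ms, 1)),
                  nbins = ceiling(window_ms))
    s <- convolve(v, rev(kern), type = "open")
    s <- s[(length(kern_t) - 1) / 2 + seq_along(v)]
    s - mean(s)
  }
  sm <- lapply(spikes_by_repetition, smooth1)
  empty <- lengths(spikes_by_repetition) == 0
  pairs <- utils::combn(n, 2)
  n_empty <- 0
  v <- apply(pairs, 2, function(ij) {
    if (empty[ij[1]] || empty[ij[2]]) { n_empty <<- n_empty + 1; return(0) }
    a <- sm[[ij[1]]]; b <- sm[[ij[2]]]
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    sum(a * b) / (na * nb)
  })
  structure(mean(v), n_empty_pairs = n_empty)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Earth mover's distance between two uniform-weight point clouds
#'
#' Exact optimal transport with a Euclidean ground metric: each cloud's
#' points carry equal mass; the clouds are replicated to a common mass
#' denominator and solved as an assignment problem (Hungarian algorithm).
#' Above `max_exact` replicated points, an entropically regularised
#' Sinkhorn approximation is used instead (flagged via attribute
#' `"exact"`).
#'
#' @param x,y numeric matrices (points in rows).
#' @param max_exact largest replicated problem solved exactly.
#' @param sinkhorn_reg,sinkhorn_iter regularisation and iterations of the
#'   approximate solver.
#' @return The distance; attribute `exact` records the solver used.
#' @export
emd_point_clouds <- function(x, y, max_exact = 600, sinkhorn_reg = 0.02,
                             sinkhorn_iter = 2000) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!nrow(x) || !nrow(y)) stop("empty pattern / point cloud")
  m <- nrow(x); n <- nrow(y)
  l <- m / .gcd(m, n) * n
  cost <- sqrt(pmax(outer(rowSums(x^2), rowSums(y^2), "+") -
                      2 * x %*% t(y), 0))
  if (l <= max_exact) {
    xi <- rep(seq_len(m), each = l / m)
    yi <- rep(seq_len(n), each = l / n)
    big <- cost[xi, yi, drop = FALSE]
    asg <- cpp_hungarian(big)
    structure(mean(big[cbind(seq_len(l), asg)]), exact = TRUE)
  } else {
    K <- exp(-cost / (sinkhorn_reg * max(cost)))
    u <- rep(1 / m, m); a <- rep(1 / m, m); b <- rep(1 / n, n)
    v <- rep(1 / n, n)
    for (i in seq_len(sinkhorn_iter)) {
      u <- a / (K %*% v)
      v <- b / (t(K) %*% u)
    }
    plan <- diag(as.vector(u)) %*% K %*% diag(as.vector(v))
    structure(sum(plan * cost), exact = FALSE)
  }
}

#' Exact 1-D earth mover's distance between two samples
#'
#' Quantile-function distance of the two empirical distributions.
#'
#' @param x,y numeric samples.
#' @return The distance.
#' @export
emd_1d <- function(x, y) {
  q <- seq(0, 1, length.out = 512 + 1)
  q <- (q[-1] + q[-length(q)]) / 2
  mean(abs(quantile(x, q, names = FALSE, type = 1) -
             quantile(y, q, names = FALSE, type = 1)))
}

#' Pairwise input distances between stimulus patterns
#'
#' Earth mover's distance between the patterns' 2-D fiber-location point
#' clouds (uniform weights, Euclidean ground metric), or the Hamming
#' distance between fiber-membership indicator vectors.
#'
#' @param schedule a [gen_patterns()] object.
#' @param metric `"emd"` or `"hamming"`.
#' @param labels patterns to include.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
input_distance_matrix <- function(schedule, metric = c("emd", "hamming"),
                                  labels = names(schedule$patterns)) {
  metric <- match.arg(metric)
  if (length(labels) < 2) stop("need >= 2 patterns")
  k <- length(labels)
  D <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    fi <- schedule$patterns[[labels[i]]]
    fj <- schedule$patterns[[labels[j]]]
    if (!length(fi) || !length(fj)) stop("empty pattern")
    D[i, j] <- D[j, i] <- if (metric == "emd") {
      as.numeric(emd_point_clouds(schedule$fiber_location[fi, , drop = FALSE],
                                  schedule$fiber_location[fj, , drop = FALSE]))
    } else {
      ind_i <- schedule$fiber_id %in% fi
      ind_j <- schedule$fiber_id %in% fj
      mean(ind_i != ind_j)
    }
  }
  D
}

#' Pairwise output distances between conditions
#'
#' Conditions are columns of a connection-by-condition matrix of mean
#' efficacies over a shared connection index. Metrics: Euclidean distance
#' of the vectors, Hamming distance of changed/unchanged flags (relative
#' to `baseline`), or 1-D earth mover's distance between the value
#' distributions.
#'
#' @param mean_rho_by_condition matrix (connections x conditions).
#' @param metric `"euclidean"`, `"hamming"` or `"emd"`.
#' @param baseline baseline vector for the Hamming changed-flags variant
#'   (default: the first condition).
#' @param tolerance changed/unchanged threshold.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
output_distance_matrix <- function(mean_rho_by_condition,
                                   metric = c("euclidean", "hamming",
                                              "emd"),
                                   baseline = NULL, tolerance = 1e-3) {
  metric <- match.arg(metric)
  m <- as.matrix(mean_rho_by_condition)
  if (any(is.na(m))) stop("conditions must share a complete connection index")
  k <- ncol(m)
  labs <- colnames(m)
  D <- matrix(0, k, k, dimnames = list(labs, labs))
  flags <- if (metric == "hamming") {
    if (is.null(baseline)) baseline <- m[, 1]
    abs(m - baseline) > tolerance
  }
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    D[i, j] <- D[j, i] <- switch(metric,
      euclidean = sqrt(sum((m[, i] - m[, j])^2)),
      hamming = mean(flags[, i] != flags[, j]),
      emd = emd_1d(m[, i], m[, j]))
  }
  D
}

#' Correlation between input and output distance matrices
#'
#' Pearson correlation of the condensed upper triangles, with a
#' Mantel-style permutation p-value (condition labels of the output
#' matrix permuted jointly over rows and columns).
#'
#' @param input_D,output_D square distance matrices over the same
#'   conditions.
#' @param n_perm permutations (>= 100).
#' @param seed RNG seed.
#' @return List `r`, `p`, `n_perm`. `r` is `NA` with `p = NA` when either
#'   condensed triangle is constant (degenerate).
#' @export
distance_correlation <- function(input_D, output_D, n_perm = 1e4,
                                 seed = 1) {
  stopifnot(nrow(input_D) == nrow(output_D))
  if (nrow(input_D) < 3) stop("need >= 3 conditions")
  if (n_perm < 100) stop("n_perm must be >= 100")
  ut <- upper.tri(input_D)
  a <- input_D[ut]
  b <- output_D[ut]
  if (sd(a) == 0 || sd(b) == 0)
    return(list(r = NA_real_, p = NA_real_, n_perm = n_perm,
                degenerate = TRUE))
  r <- cor(a, b)
  set.seed(seed)
  n <- nrow(input_D)
  cnt <- 0
  for (i in seq_len(n_perm)) {
    pm <- sample.int(n)
    rp <- cor(a, output_D[pm, pm][ut])
    if (!is.na(rp) && rp >= r) cnt <- cnt + 1
  }
  list(r = r, p = (cnt + 1) / (n_perm + 1), n_perm = n_perm,
       degenerate = FALSE)
}

#' Interspike-interval histogram
#'
#' Descriptive pooled ISI histogram over a set of spike trains.
#'
#' @param spikes named list of spike trains, ms.
#' @param breaks histogram breaks, ms.
#' @return Data frame `mid`, `count`.
#' @export
isi_histogram <- function(spikes, breaks = seq(0, 500, 10)) {
  isi <- unlist(lapply(spikes, diff))
  isi <- isi[isi <= max(breaks)]
  h <- hist(isi, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts)
}
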