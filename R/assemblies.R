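#' Bin spike trains into a neuron-by-bin count matrix
#'
#' Right-open bins `[t, t + bin_ms)`; spike counts are conserved.
#'
#' @param spikes named list of spike-time vectors, ms.
#' @param bin_ms bin width, ms.
#' @param t_start,t_end binning range; defaults to 0 and the latest spike.
#' @return A `binned_activity`: `counts` (neurons x bins), `bin_edges`,
#'   `sources`.
#' @export
bin_spikes <- function(spikes, bin_ms = 20, t_start = 0, t_end = NULL) {
  stopifnot(bin_ms > 0)
  if (is.null(t_end)) t_end <- max(c(unlist(spikes), t_start)) + 1e-9
  edges <- seq(t_start, t_end + bin_ms, by = bin_ms)
  counts <- t(vapply(spikes, function(x) {
    x <- x[x >= t_start & x < edges[length(edges)]]
    tabulate(findInterval(x, edges), nbins = length(edges) - 1)
  }, integer(length(edges) - 1)))
  structure(list(counts = counts, bin_edges = edges,
                 sources = names(spikes)),
            class = "binned_activity")
}

# circular shift of a vector by s (s >= 0)
.circ_shift <- function(x, s) {
  n <- length(x); s <- s %% n
  if (s == 0) x else c(x[(n - s + 1):n], x[1:(n - s)])
}

#' Detect time bins of significantly high population firing
#'
#' The per-bin population rate is compared with a threshold built from
#' shuffled controls: in each of `n_shuffles` controls every neuron's
#' binned train is circularly shifted by an independent uniform offset, and
#' the standard deviation of the shuffled population-rate trace is
#' recorded. The threshold is the mean of the original population rate
#' plus the 95th percentile of those standard deviations.
#'
#' @param binned a [bin_spikes()] object.
#' @param n_shuffles number of shuffled controls (>= 2).
#' @param seed RNG seed.
#' @param percentile percentile of the shuffled standard deviations.
#' @return Logical mask over bins with attributes `threshold`,
#'   `mean_rate`, `sd_percentile`.
#' @export
significant_bins <- function(binned, n_shuffles = 100, seed = 1,
                             percentile = 0.95) {
  stopifnot(n_shuffles >= 2)
  counts <- binned$counts
  pop <- colSums(counts)
  if (all(pop == 0)) stop("all-zero activity")
  set.seed(seed)
  n_bins <- ncol(counts)
  sds <- vapply(seq_len(n_shuffles), function(s) {
    shifted <- colSums(t(vapply(seq_len(nrow(counts)), function(i)
      .circ_shift(counts[i, ], sample.int(n_bins, 1) - 1),
      numeric(n_bins))))
    sd(shifted)
  }, numeric(1))
  thr <- mean(pop) + quantile(sds, percentile, names = FALSE)
  structure(pop > thr, threshold = thr, mean_rate = mean(pop),
            sd_percentile = quantile(sds, percentile, names = FALSE))
}

# Davies-Bouldin index; rows of x are observations
.davies_bouldin <- function(x, labels) {
  ks <- sort(unique(labels))
  cen <- t(vapply(ks, function(k)
    colMeans(x[labels == k, , drop = FALSE]), numeric(ncol(x))))
  s <- vapply(seq_along(ks), function(j) {
    d <- sweep(x[labels == ks[j], , drop = FALSE], 2, cen[j, ])
    mean(sqrt(rowSums(d^2)))
  }, numeric(1))
  db <- vapply(seq_along(ks), function(i) {
    r <- vapply(seq_along(ks), function(j) {
      if (i == j) return(NA_real_)
      m <- sqrt(sum((cen[i, ] - cen[j, ])^2))
      if (m == 0) Inf else (s[i] + s[j]) / m
    }, numeric(1))
    max(r, na.rm = TRUE)
  }, numeric(1))
  mean(db)
}

#' Cluster significant time bins into putative assembly activations
#'
#' Activation vectors (per-neuron spike counts of each significant bin)
#' are compared by cosine similarity; Ward's linkage is applied to the
#' distance `1 - cosine`, the candidate cluster numbers in `k_range` are
#' scored with the Davies-Bouldin index on the activation vectors
#' (Euclidean), and the labels at the index-minimising `k` are returned
#' (ties toward smaller `k`).
#'
#' @param binned a [bin_spikes()] object.
#' @param mask logical significant-bin mask from [significant_bins()].
#' @param k_range candidate numbers of clusters (default 5..20).
#' @return List: `labels` (per significant bin), `k`, `db_index_by_k`,
#'   `sig_bins` (bin indices), `hclust`.
#' @export
cluster_significant_bins <- function(binned, mask, k_range = 5:20) {
  sig <- which(mask)
  k_range <- k_range[k_range <= length(sig) - 1 & k_range >= 2]
  if (!length(k_range)) stop("fewer significant bins than requested clusters")
  x <- t(binned$counts[, sig, drop = FALSE]) # bins x neurons
  nrm <- sqrt(rowSums(x^2)); nrm[nrm == 0] <- 1
  cosine <- (x / nrm) %*% t(x / nrm)
  hc <- hclust(as.dist(pmax(1 - cosine, 0)), method = "ward.D2")
  db <- vapply(k_range, function(k)
    .davies_bouldin(x, cutree(hc, k)), numeric(1))
  k_best <- k_range[which.min(db)]
  list(labels = cutree(hc, k_best), k = k_best,
       db_index_by_k = stats::setNames(db, k_range), sig_bins = sig,
       hclust = hc)
}

# correlations of x with the cluster activation at every circular shift,
# via FFT cross-correlation (all offsets at once)
.circ_cor_all <- function(x, y) {
  n <- length(x)
  cc <- Re(stats::fft(stats::fft(x) * Conj(stats::fft(y)),
                      inverse = TRUE)) / n
  sx <- sd(x) * sqrt((n - 1) / n); sy <- sd(y) * sqrt((n - 1) / n)
  if (sx == 0 || sy == 0) return(rep(NA_real_, n))
  (cc / n - mean(x) * mean(y)) / (sx * sy)
}

#' Associate neurons with bin clusters to form functional assemblies
#'
#' Each neuron's binned spike counts are correlated with the binary
#' activation time series of every cluster; membership requires exceeding
#' the 95th percentile of the neuron's shuffle-control correlations
#' (circular shifts by uniform offsets, 1000 controls). A cluster is
#' accepted as a functional assembly only when the mean pairwise
#' correlation among its significant members exceeds the mean pairwise
#' correlation of the whole dataset. Zero-variance neurons are excluded
#' and reported via the `excluded` element.
#'
#' @param binned a [bin_spikes()] object.
#' @param clustering result of [cluster_significant_bins()].
#' @param n_shuffles shuffle controls per neuron (default 1000).
#' @param seed RNG seed.
#' @param percentile membership percentile.
#' @return List: `assemblies` (cluster label -> member source ids, accepted
#'   clusters only), `accepted`, `members_all`, `excluded`,
#'   `mean_pairwise`, `dataset_mean`.
#' @export
assign_neurons <- function(binned, clustering, n_shuffles = 1000, seed = 1,
                           percentile = 0.95) {
  counts <- binned$counts
  n_bins <- ncol(counts); n_neu <- nrow(counts)
  set.seed(seed)
  varz <- apply(counts, 1, var)
  excluded <- binned$sources[varz == 0]
  cors <- cor(t(counts[varz > 0, , drop = FALSE]))
  rownames(cors) <- colnames(cors) <- binned$sources[varz > 0]
  dataset_mean <- mean(cors[upper.tri(cors)], na.rm = TRUE)
  ks <- sort(unique(clustering$labels))
  members_all <- list(); mean_pair <- accepted <- stats::setNames(
    rep(NA, length(ks)), ks)
  for (k in ks) {
    act <- numeric(n_bins)
    act[clustering$sig_bins[clustering$labels == k]] <- 1
    obs <- thr <- rep(NA_real_, n_neu)
    for (i in which(varz > 0)) {
      allshift <- .circ_cor_all(counts[i, ], act)
      obs[i] <- allshift[1]
      thr[i] <- quantile(allshift[sample.int(n_bins, n_shuffles,
                                             replace = TRUE)],
                         percentile, names = FALSE, na.rm = TRUE)
    }
    mem <- which(!is.na(obs) & obs > thr)
    members_all[[as.character(k)]] <- binned$sources[mem]
    keep <- intersect(mem, which(varz > 0))
    mp <- if (length(keep) >= 2) {
      sub <- cors[binned$sources[keep], binned$sources[keep]]
      mean(sub[upper.tri(sub)], na.rm = TRUE)
    } else NA_real_
    mean_pair[as.character(k)] <- mp
    accepted[as.character(k)] <- !is.na(mp) && mp > dataset_mean
  }
  list(assemblies = members_all[accepted %in% TRUE], accepted = accepted,
       members_all = members_all, excluded = excluded,
       mean_pairwise = mean_pair, dataset_mean = dataset_mean)
}

#' Run the full assembly-detection pipeline
#'
#' Bin, find significant bins, cluster them, and assign neurons.
#'
#' @param spikes named list of spike trains, ms.
#' @param bin_ms bin width, ms.
#' @param k_range candidate cluster numbers.
#' @param n_shuffles_bins,n_shuffles_neurons shuffle-control counts.
#' @param seed RNG seed.
#' @param t_end end of the analysed recording, ms.
#' @return An `assembly_result` combining the stage outputs.
#' @export
detect_assemblies <- function(spikes, bin_ms = 20, k_range = 5:20,
                              n_shuffles_bins = 100,
                              n_shuffles_neurons = 1000, seed = 1,
                              t_end = NULL) {
  binned <- bin_spikes(spikes, bin_ms, t_end = t_end)
  mask <- significant_bins(binned, n_shuffles_bins, seed = seed)
  cl <- cluster_significant_bins(binned, mask, k_range)
  asg <- assign_neurons(binned, cl, n_shuffles_neurons, seed = seed + 1)
  structure(list(binned = binned, mask = mask, clustering = cl,
                 assignment = asg, assemblies = asg$assemblies),
            class = "assembly_result")
}

#' Assembly label sequences per stimulus repetition
#'
#' For each presentation, the cluster label of every significant bin in
#' the response window `[onset, onset + window_ms)`, with `NA` as the null
#' symbol for non-significant bins.
#'
#' @param result an [detect_assemblies()] object.
#' @param schedule a schedule with presentations.
#' @param window_ms response window, ms.
#' @return Named list: pattern label -> matrix (repetitions x bins) of
#'   cluster labels / `NA`.
#' @export
assembly_sequences <- function(result, schedule, window_ms = 200) {
  pres <- schedule$presentations
  if (is.null(pres)) stop("schedule has no presentations")
  edges <- result$binned$bin_edges
  bin_ms <- edges[2] - edges[1]
  n_bins <- floor(window_ms / bin_ms)
  lab_full <- rep(NA_integer_, length(edges) - 1)
  lab_full[result$clustering$sig_bins] <- result$clustering$labels
  out <- list()
  for (p in unique(pres$label)) {
    ons <- pres$onset[pres$label == p]
    m <- matrix(NA_integer_, length(ons), n_bins)
    for (r in seq_along(ons)) {
      first <- findInterval(ons[r], edges)
      idx <- first + seq_len(n_bins) - 1
      if (max(idx) > length(lab_full)) stop("window overruns the recording")
      m[r, ] <- lab_full[idx]
    }
    out[[p]] <- m
  }
  out
}

#' Jaccard similarity of two sets
#'
#' `|intersection| / |union|`; 1 iff the sets are equal, 0 iff disjoint.
#'
#' @param set_a,set_b vectors treated as sets.
#' @return Scalar in \[0, 1\].
#' @export
jaccard_similarity <- function(set_a, set_b) {
  if (!length(set_a) && !length(set_b)) stop("both sets empty")
  length(intersect(set_a, set_b)) / length(union(set_a, set_b))
}

#' Hamming similarity of two equal-length symbol sequences
#'
#' Fraction of positions with equal symbols; two null symbols (`NA`)
#' count as equal.
#'
#' @param a,b sequences of equal length.
#' @return Scalar in \[0, 1\]; 1 iff identical.
#' @export
hamming_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("sequences differ in length")
  eq <- (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
  mean(eq)
}

#' Reliability of assembly sequences over repetitions
#'
#' Mean Hamming similarity over all pairs of repetitions of one pattern;
#' differences between groups of pairwise similarities can be assessed
#' with [reliability_test()].
#'
#' @param seq_matrix repetitions-by-bins label matrix (one pattern), as
#'   produced by [assembly_sequences()].
#' @return List: `reliability` (scalar) and `pair_values`.
#' @export
hamming_reliability <- function(seq_matrix) {
  n <- nrow(seq_matrix)
  if (n < 2) stop("need at least 2 repetitions")
  pairs <- utils::combn(n, 2)
  v <- apply(pairs, 2, function(ij)
    hamming_similarity(seq_matrix[ij[1], ], seq_matrix[ij[2], ]))
  list(reliability = mean(v), pair_values = v)
}

#' Kruskal-Wallis test of reliability differences between groups
#'
#' @param pair_values_by_group named list of pairwise-similarity vectors.
#' @return The `htest` object of [stats::kruskal.test()].
#' @export
reliability_test <- function(pair_values_by_group) {
  kruskal.test(pair_values_by_group)
}
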