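test_that("change summaries classify synapses and count crossings", {
  tr <- list(rho = cbind(c(0.5, 0.6, 0.2, 0.9, 0.5, 0.4),
                         c(0.5, 0.4, 0.2, 0.95, 0.51, 0.8)),
             rho0 = c(0.5, 0.6, 0.2, 0.9, 0.5, 0.4),
             g_AMPA = cbind(rep(1, 6), rep(1, 6)),
             time_s = c(1, 2), syn_id = 1:6,
             pre_node = c(1, 1, 2, 2, 3, 3), post_node = rep(9, 6))
  class(tr) <- "plasticity_trace"
  cs <- change_summary(tr, tolerance = 1e-3)
  expect_equal(cs$class_by_synapse,
               c("unchanged", "depressed", "unchanged", "potentiated",
                 "potentiated", "potentiated"))
  expect_equal(sum(unlist(cs$synapse[1:3])), 1)
  # crossings: syn 2 crossed down, syn 5 and 6 crossed up
  expect_equal(cs$crossings$n_down, 1)
  expect_equal(cs$crossings$n_up, 2)
  expect_true(!is.unsorted(cs$crossings$curve_up$cum_count))
  expect_lte(cs$crossings$n_up + cs$crossings$n_down,
             sum(cs$class_by_synapse != "unchanged"))
  # constant trace: all unchanged, no crossings
  tr0 <- tr; tr0$rho <- cbind(tr$rho[, 1], tr$rho[, 1])
  cs0 <- change_summary(tr0)
  expect_equal(unname(unlist(cs0$synapse["unchanged"])), 1)
  expect_equal(cs0$crossings$n_up + cs0$crossings$n_down, 0)
  expect_error(change_summary(tr, tolerance = -1), "tolerance")
})

test_that("pairwise correlations behave on canonical trains", {
  x <- rbind(a = c(1, 0, 2, 0, 1, 0), b = c(1, 0, 2, 0, 1, 0),
             c = c(0, 1, 0, 2, 0, 1), d = rep(1, 6))
  b <- structure(list(counts = x, bin_edges = seq(0, 120, 20),
                      sources = rownames(x)), class = "binned_activity")
  pc <- pairwise_correlations(b, rbind(c("a", "b"), c("a", "c"),
                                       c("a", "d")))
  expect_equal(pc$r[1], 1)
  expect_lt(pc$r[2], 0)
  expect_true(is.na(pc$r[3]))            # zero-variance partner reported NA
  expect_error(pairwise_correlations(b, rbind(c("a", "zz"))), "unknown")
  # independent Poisson trains decorrelate at long T
  set.seed(17)
  y <- matrix(rpois(2 * 5000, 1), 2, 5000)
  b2 <- structure(list(counts = y, bin_edges = seq(0, 1e5, 20),
                       sources = c("p", "q")), class = "binned_activity")
  expect_lt(abs(pairwise_correlations(b2, rbind(c("p", "q")))$r),
            3 / sqrt(5000))
})

test_that("spike-time reliability: identity, translation, jitter decay", {
  sp <- list(c(10, 50, 90), c(10, 50, 90), c(10, 50, 90))
  expect_equal(as.numeric(spike_time_reliability(sp)), 1)
  # invariance to a global offset applied to all repetitions
  sp_off <- lapply(sp, function(x) x + 37)
  expect_equal(as.numeric(spike_time_reliability(sp_off, window_ms = 200)),
               as.numeric(spike_time_reliability(sp, window_ms = 200)),
               tolerance = 1e-6)
  # far-apart responses: near zero (slightly negative from mean-centering)
  far <- list(10, 500, 990)
  r_far <- as.numeric(spike_time_reliability(far, window_ms = 1000))
  expect_lt(r_far, 0.05)
  expect_gt(r_far, -0.1)
  # reliability decreases with independent jitter
  set.seed(18)
  base <- sort(runif(20, 0, 500))
  rel_at <- function(sd_j) {
    mean(replicate(5, as.numeric(spike_time_reliability(
      lapply(1:6, function(i) sort(base + rnorm(20, 0, sd_j))),
      window_ms = 600))))
  }
  r0 <- rel_at(1); r1 <- rel_at(8); r2 <- rel_at(40)
  expect_gt(r0, r1); expect_gt(r1, r2)
  expect_true(all(c(r0, r1, r2) >= -1 & c(r0, r1, r2) <= 1))
  # empty repetitions contribute zero pairs
  some <- list(c(10, 20), numeric(0), c(10, 20))
  r <- spike_time_reliability(some, window_ms = 100)
  expect_equal(attr(r, "n_empty_pairs"), 2)
  expect_error(spike_time_reliability(list(numeric(0), numeric(0))),
               "empty")
  expect_error(spike_time_reliability(list(1)), "repetitions")
})

test_that("earth mover's distance is exact on solvable cases", {
  # identical clouds and singletons
  x <- matrix(runif(10), 5)
  expect_equal(as.numeric(emd_point_clouds(x, x)), 0, tolerance = 1e-12)
  expect_equal(as.numeric(emd_point_clouds(matrix(c(0, 0), 1),
                                           matrix(c(3, 4), 1))), 5)
  # split-mass example against the brute-force transport oracle
  set.seed(19)
  for (r in 1:10) {
    a <- matrix(runif(8), 4); b <- matrix(runif(8), 4)
    expect_equal(as.numeric(emd_point_clouds(a, b)), brute_emd_equal(a, b),
                 tolerance = 1e-10)
  }
  # unequal sizes: exact replication solution vs assignment library
  a <- matrix(runif(6), 3); b <- matrix(runif(10), 5)
  v <- emd_point_clouds(a, b)
  expect_true(attr(v, "exact"))
  if (requireNamespace("clue", quietly = TRUE)) {
    cost <- as.matrix(stats::dist(rbind(a, b)))[1:3, 4:8]
    big <- cost[rep(1:3, each = 5), rep(1:5, each = 3)]
    ref <- mean(big[cbind(1:15, as.integer(clue::solve_LSAP(big)))])
    expect_equal(as.numeric(v), ref, tolerance = 1e-10)
  }
  # triangle inequality on random triples
  for (r in 1:5) {
    a <- matrix(runif(8), 4); b <- matrix(runif(8), 4)
    cc <- matrix(runif(8), 4)
    expect_lte(as.numeric(emd_point_clouds(a, cc)),
               as.numeric(emd_point_clouds(a, b)) +
                 as.numeric(emd_point_clouds(b, cc)) + 1e-12)
  }
  # the approximate path stays close to the exact one
  a <- matrix(runif(40), 20); b <- matrix(runif(40), 20)
  ex <- emd_point_clouds(a, b)
  ap <- emd_point_clouds(a, b, max_exact = 1)
  expect_false(attr(ap, "exact"))
  expect_lt(abs(as.numeric(ap) - as.numeric(ex)) / as.numeric(ex), 0.15)
  # 1-D distance: shifted samples move by the shift
  z <- runif(200)
  expect_equal(emd_1d(z, z + 0.25), 0.25, tolerance = 1e-9)
})

test_that("input and output distance matrices are proper distances", {
  sched <- gen_patterns(30, n_fibers = 240, seed = 20)
  labs <- c("A", "B", "E", "H")
  D <- input_distance_matrix(sched, "emd", labs)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 4))
  expect_true(all(D[upper.tri(D)] > 0))
  # A is closer to E = A+B than to the disjoint B
  expect_lt(D["A", "E"], D["A", "B"])
  Dh <- input_distance_matrix(sched, "hamming", labs)
  expect_equal(Dh, t(Dh))
  expect_equal(Dh["A", "B"] * length(sched$fiber_id),
               length(sched$patterns$A) + length(sched$patterns$B))
  # output distances
  m <- cbind(c1 = c(0.2, 0.5, 0.9), c2 = c(0.2, 0.5, 0.9),
             c3 = c(0.2, 0.5, 0.4))
  Do <- output_distance_matrix(m, "euclidean")
  expect_equal(Do["c1", "c2"], 0)
  expect_equal(Do["c1", "c3"], 0.5)
  Dhm <- output_distance_matrix(m, "hamming", baseline = m[, 1])
  expect_equal(Dhm["c1", "c3"], 1 / 3)
  De <- output_distance_matrix(m, "emd")
  expect_equal(De["c1", "c2"], 0)
  expect_gt(De["c1", "c3"], 0)
})

test_that("distance correlation: affine exactness and permutation null", {
  set.seed(21)
  A <- as.matrix(stats::dist(matrix(runif(12), 6)))
  r <- distance_correlation(A, 2 * A, n_perm = 200, seed = 1)
  expect_equal(r$r, 1)
  expect_lt(r$p, 0.05)
  # constant output: degenerate, reported as NA
  r0 <- distance_correlation(A, A * 0, n_perm = 200)
  expect_true(is.na(r0$r))
  # independent matrices: p roughly uniform over repeats
  ps <- replicate(40, {
    B <- as.matrix(stats::dist(matrix(runif(12), 6)))
    C <- as.matrix(stats::dist(matrix(runif(12), 6)))
    distance_correlation(B, C, n_perm = 200, seed = 2)$p
  })
  expect_gt(mean(ps > 0.2), 0.5)
  expect_error(distance_correlation(A[1:2, 1:2], A[1:2, 1:2],
                                    n_perm = 200), "conditions")
  # agreement with an established Mantel implementation
  if (requireNamespace("vegan", quietly = TRUE)) {
    B <- as.matrix(stats::dist(matrix(runif(14), 7)))
    C <- B + as.matrix(stats::dist(matrix(runif(14), 7)))
    expect_equal(distance_correlation(B, C, n_perm = 200)$r,
                 unname(vegan::mantel(B, C, permutations = 10)$statistic))
  }
})
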