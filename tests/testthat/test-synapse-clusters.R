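# synapse table on one neuron from explicit offsets
branch_table <- function(offsets, branch = 1, neuron = 7) {
  data.frame(syn_id = seq_along(offsets), pre_node = 99,
             post_node = neuron, branch_id = branch,
             path_offset = offsets)
}

test_that("cluster detection applies the seed-and-merge rule", {
  # 10 synapses at 1 um spacing: one 10-member cluster
  cl <- detect_clusters(branch_table(seq(0, 9)), 7)
  expect_length(cl, 1)
  expect_length(cl[[1]]$syn_ids, 10)
  # 9 synapses only: no cluster ("at least nine other" fails)
  expect_length(detect_clusters(branch_table(seq(0, 8)), 7), 0)
  # chained windows: three dense groups bridge transitively into one
  # cluster of more than 10 synapses spanning more than 20 um
  off <- c(seq(0, 2, length.out = 10), seq(9.5, 11.5, length.out = 10),
           seq(19, 21, length.out = 10))
  cl3 <- detect_clusters(branch_table(off), 7)
  expect_length(cl3, 1)
  expect_length(cl3[[1]]$syn_ids, 30)
  expect_gt(cl3[[1]]$span, 20)
  # synapses on different branches never co-cluster
  two <- rbind(branch_table(seq(0, 9), branch = 1),
               branch_table(seq(0, 9), branch = 2))
  two$syn_id <- seq_len(nrow(two))
  cl4 <- detect_clusters(two, 7)
  expect_length(cl4, 2)
  expect_error(detect_clusters(branch_table(c(1, NA)), 7), "geometry")
})

test_that("cluster detection equals a brute-force window scan", {
  brute <- function(off, radius = 10, min_members = 10) {
    q <- which(vapply(seq_along(off), function(i)
      sum(abs(off - off[i]) <= radius) - 1 >= min_members - 1, logical(1)))
    if (!length(q)) return(list())
    # transitive closure over the radius relation among qualifying synapses
    comp <- seq_along(q)
    repeat {
      changed <- FALSE
      for (i in seq_along(q)) for (j in seq_along(q)) {
        if (abs(off[q[i]] - off[q[j]]) <= radius &&
            comp[i] != comp[j]) {
          comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    out <- split(q, comp)
    out[lengths(out) >= min_members]
  }
  set.seed(13)
  for (r in 1:10) {
    off <- sort(runif(40, 0, 120))
    got <- detect_clusters(branch_table(off), 7)
    want <- brute(off)
    expect_length(got, length(want))
    got_sets <- lapply(got, function(cl) sort(cl$syn_ids))
    want_sets <- lapply(unname(want), sort)
    expect_setequal(vapply(got_sets, paste, "", collapse = ","),
                    vapply(want_sets, paste, "", collapse = ","))
  }
})

test_that("cluster detection ignores branch labels and row order", {
  off <- c(seq(0, 9), 50, 60)
  t1 <- branch_table(off, branch = 1)
  t2 <- branch_table(off, branch = 42)       # relabelled branch
  t3 <- t1[sample(nrow(t1)), ]               # permuted rows
  ids <- function(tb) sort(detect_clusters(tb, 7)[[1]]$syn_ids)
  expect_equal(ids(t1), ids(t2))
  expect_equal(ids(t1), ids(t3))
})

test_that("cluster significance is calibrated and hits its limits", {
  # p-values uniform when the cluster is just Poisson-placed synapses
  set.seed(14)
  ps <- replicate(400, {
    st <- branch_table(cumsum(rexp(250, 0.4)))
    i <- sample(5:235, 1)
    cl <- structure(list(post_neuron = 7, branch_id = 1,
                         syn_ids = st$syn_id[i:(i + 9)]),
                    class = "synapse_cluster")
    as.numeric(cluster_significance(cl, st))
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  # all-zero distances: p -> 0
  st0 <- branch_table(c(rep(5, 10), cumsum(rexp(90, 0.5)) + 10))
  cl0 <- structure(list(post_neuron = 7, branch_id = 1, syn_ids = 1:10),
                   class = "synapse_cluster")
  expect_lt(as.numeric(cluster_significance(cl0, st0)), 1e-10)
  expect_true(attr(cluster_significance(cl0, st0), "jittered"))
  # distances 10x the neuron mean: p near 1
  sta <- branch_table(c(seq(0, 180, by = 20), cumsum(rexp(200, 0.5)) + 200))
  cla <- structure(list(post_neuron = 7, branch_id = 1, syn_ids = 1:10),
                   class = "synapse_cluster")
  expect_gt(as.numeric(cluster_significance(cla, sta)), 0.95)
})

test_that("target-neuron selection maximises indegree and clustering", {
  set.seed(15)
  # toy: candidates differ in assembly indegree and synapse concentration
  asm <- 1:5
  edges <- rbind(
    expand.grid(pre = asm, post = 11),          # indegree 5
    expand.grid(pre = asm[1:2], post = 12),     # indegree 2
    expand.grid(pre = asm, post = 13),          # indegree 5, scattered
    data.frame(pre = 6, post = 14))             # no assembly input
  net <- structure(list(nodes = data.frame(node_id = 1:20, layer = 5,
                                           x = 0, y = 0, z = 0),
                        edges = edges), class = "directed_network")
  syn <- data.frame(
    syn_id = 1:13,
    pre_node = c(asm, asm[1:2], asm, 6),
    post_node = c(rep(11, 5), rep(12, 2), rep(13, 5), 14),
    branch_id = c(rep(1, 5), 1, 1, 1:5, 1),
    path_offset = c(1, 2, 3, 4, 5, 10, 80, 10, 40, 80, 120, 160, 5))
  # pad each neuron with non-assembly synapses so the SCC null exists
  pad <- data.frame(syn_id = 100 + 1:40, pre_node = 50,
                    post_node = rep(c(11, 12, 13, 14), each = 10),
                    branch_id = rep(c(2, 2, 6, 2), each = 10),
                    path_offset = runif(40, 0, 180))
  syn <- rbind(syn, pad)
  sel <- select_target_neurons(asm, syn, net, n_select = 2,
                               n_controls = 200, seed = 1)
  expect_equal(sel$neuron[1], 11)  # equal indegree, concentrated synapses
  expect_false(14 %in% sel$neuron) # zero assembly indegree never selected
  expect_error(select_target_neurons(integer(0), syn, net), "empty")
})

test_that("Michelson contrast matches hand arithmetic and its limits", {
  # 20 synapses, 4 categories of 5; potentiation counts 4/2/1/1
  category <- rep(c("a_cl", "a_nc", "n_cl", "n_nc"), each = 5)
  pot <- c(rep(TRUE, 4), FALSE,
           rep(TRUE, 2), rep(FALSE, 3),
           TRUE, rep(FALSE, 4),
           TRUE, rep(FALSE, 4))
  ct <- michelson_contrast(category, pot)
  # P(pot) = 8/20 = 0.4; by hand: (0.8-0.4)/1.2, 0, (0.2-0.4)/0.6 twice
  expect_equal(unname(ct), c(1 / 3, 0, -1 / 3, -1 / 3))
  # lower bound: category with zero probability of a nonzero outcome
  ct2 <- michelson_contrast(rep(c("x", "y"), each = 5),
                            c(rep(FALSE, 5), rep(TRUE, 5)))
  expect_equal(unname(ct2["x"]), -1)
  # both probabilities zero: defined 0
  ct3 <- michelson_contrast(c("x", "x"), c(FALSE, FALSE))
  expect_equal(unname(ct3), 0)
  # sign compensation: non-empty categories cannot all share one sign
  set.seed(16)
  for (r in 1:20) {
    cat4 <- sample(letters[1:4], 200, TRUE)
    out <- runif(200) < 0.3
    ct4 <- michelson_contrast(cat4, out)
    ct4 <- ct4[!is.na(ct4) & ct4 != 0]
    if (length(ct4) > 1) expect_true(min(ct4) < 0 && max(ct4) > 0)
  }
  expect_true(all(abs(ct) <= 1))
})

test_that("category table and two-way ANOVA agree with direct computation", {
  tr <- list(rho = cbind(c(0, 1, 0.5, 0.2), c(0.4, 1, 0.5, 0)),
             rho0 = c(0, 1, 0.5, 0.2), syn_id = 1:4, time_s = 1:2)
  class(tr) <- "plasticity_trace"
  st <- data.frame(syn_id = 1:4, pre_node = c(1, 1, 9, 9),
                   post_node = 5, branch_id = 1, path_offset = 1:4)
  ctab <- categorize_synapses(st, tr, assembly = 1,
                              clustered_syn_ids = c(1, 3))
  expect_equal(as.character(ctab$category),
               c("assembly_clustered", "assembly_non-clustered",
                 "non-assembly_clustered", "non-assembly_non-clustered"))
  expect_equal(ctab$outcome, c("potentiated", "unchanged", "unchanged",
                               "depressed"))
  # balanced toy two-way ANOVA against textbook arithmetic
  y <- c(1, 2, 3, 4, 2, 3, 4, 5, 5, 6, 7, 8, 9, 10, 11, 12)
  a <- rep(c(TRUE, FALSE), each = 8)
  cl <- rep(rep(c(TRUE, FALSE), each = 4), 2)
  res <- amplitude_by_category(y, a, cl)
  fit <- stats::aov(y ~ factor(a) * factor(cl))
  expect_equal(unname(res$anova[["F value"]][1:3]),
               unname(summary(fit)[[1]][["F value"]][1:3]))
  expect_equal(res$cell_means["TRUE", "TRUE"], mean(y[a & cl]))
  # identical groups: F ~ 0 for the group factors
  y0 <- rep(c(1, 2), 8)
  res0 <- amplitude_by_category(y0, a, cl)
  expect_lt(res0$anova[["F value"]][1], 1e-10)
  expect_error(amplitude_by_category(y[1:4], a[1:4], c(TRUE, TRUE, FALSE,
                                                       FALSE)),
               "cell")
})
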