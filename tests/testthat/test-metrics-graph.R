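test_that("density thresholding keeps exactly the strongest edges", {
  set.seed(20)
  n <- 8
  fc <- matrix(runif(n * n, -1, 1), n)
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  M <- n * (n - 1) / 2

  full <- threshold_graph(fc, 1)
  expect_equal(full$n_edges, M)
  expect_true(all(full$adjacency[upper.tri(fc)] == 1))

  tiny <- threshold_graph(fc, 0.4 / M)      # below one edge after rounding
  expect_equal(sum(tiny$adjacency), 0)

  one <- threshold_graph(fc, 1.2 / M)       # rounds to a single edge
  expect_equal(sum(one$adjacency) / 2, 1)
  strongest <- which(unclass(fc) == max(fc[upper.tri(fc)]), arr.ind = TRUE)
  expect_equal(one$adjacency[strongest[1, 1], strongest[1, 2]], 1L)

  for (d in c(0.1, 0.25, 0.5, 0.8)) {
    g <- threshold_graph(fc, d)
    expect_equal(sum(g$adjacency) / 2, round(d * M))
    expect_equal(g$adjacency, t(g$adjacency))
    expect_equal(diag(g$adjacency), rep(0L, n), ignore_attr = TRUE)
  }
})

test_that("modularity reproduces hand-computed clique partitions", {
  # two 4-cliques, no inter-edges
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1
  diag(A) <- 0
  mod2 <- rep(1:2, each = 4)
  expect_equal(modularity_q(A, mod2), 0.5)
  expect_equal(modularity_q(A, rep(1, 8)), 0)
  # splitting each clique in half scores lower
  mod4 <- rep(1:4, each = 2)
  expect_lt(modularity_q(A, mod4), 0.5)
  expect_error(modularity_q(matrix(0, 4, 4), rep(1, 4)), "edgeless")
})

test_that("modularity agrees with brute-force and igraph on random graphs", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(5:12, 1)
    A <- matrix(rbinom(n * n, 1, 0.4), n)
    A <- 1 * ((A + t(A)) > 0)
    diag(A) <- 0
    if (sum(A) == 0) next
    mod <- sample(1:3, n, replace = TRUE)
    q <- modularity_q(A, mod)
    expect_equal(q, brute_modularity(A, mod), tolerance = 1e-12)
    ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(q, igraph::modularity(ig, mod), tolerance = 1e-12)
    expect_gte(q, -1); expect_lte(q, 1)
  }
})

test_that("clustering and path length match brute-force on small graphs", {
  set.seed(22)
  reps <- 0
  while (reps < 15) {
    n <- sample(5:12, 1)
    g <- igraph::sample_gnp(n, 0.5)
    if (!igraph::is_connected(g)) next
    reps <- reps + 1
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    C_pkg <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
    L_pkg <- igraph::mean_distance(g)
    expect_equal(C_pkg, brute_clustering(A), tolerance = 1e-12)
    expect_equal(L_pkg, brute_path_length(A), tolerance = 1e-12)
  }
})

test_that("small-world coefficient behaves on canonical graphs", {
  n <- 10
  complete <- matrix(1, n, n); diag(complete) <- 0
  expect_equal(small_world(complete, n_random = 5, seed = 1), 1)

  # Watts-Strogatz regime: ring lattice with a few shortcuts
  ws <- igraph::sample_smallworld(1, 30, 3, 0.05)
  A <- as.matrix(igraph::as_adjacency_matrix(ws))
  if (igraph::is_connected(ws))
    expect_gt(small_world(A, n_random = 30, seed = 2), 1)

  # ER graphs are their own null model: SW ~ 1 on average (a single sparse
  # instance fluctuates through its clustering coefficient)
  set.seed(3)
  sws <- replicate(8, {
    repeat {
      er <- igraph::sample_gnm(20, 60)
      if (igraph::is_connected(er)) break
    }
    small_world(as.matrix(igraph::as_adjacency_matrix(er)),
                n_random = 30, seed = sample.int(1e6, 1))
  })
  expect_equal(mean(sws), 1, tolerance = 0.15)

  disc <- matrix(0, 6, 6)
  disc[1, 2] <- disc[2, 1] <- 1
  disc[3, 4] <- disc[4, 3] <- 1
  expect_error(small_world(disc), "disconnected")
})

test_that("consensus modules are deterministic and resolve degenerate k", {
  ref <- synth_reference_signals(18, 500, n_communities = 3,
                                 within_cor = 0.75, seed = 6)
  fc <- static_fc(ref)
  p1 <- consensus_modules(fc, k = 3, runs = 50, seed = 10)
  p2 <- consensus_modules(fc, k = 3, runs = 50, seed = 10)
  expect_identical(p1$assignment, p2$assignment)

  # k = N: every region its own module
  small <- static_fc(synth_reference_signals(6, 300, n_communities = 6,
                                             within_cor = 0, seed = 7))
  pN <- consensus_modules(small, k = 6, runs = 10, seed = 2)
  expect_equal(sort(pN$assignment), 1:6)
})

test_that("lesion graph metrics drop the lesioned node and track module damage", {
  ref <- synth_reference_signals(20, 1000, n_communities = 4,
                                 within_cor = 0.75, seed = 8)
  fc <- static_fc(ref)
  comm <- attr(ref, "communities")
  gm <- lesion_graph_metrics(fc, comm, lesioned_node = NULL,
                             q_densities = c(0.2, 0.3), sw_densities = 0.4,
                             n_random = 10, seed = 1)
  expect_equal(nrow(gm$q), 2)
  expect_true(all(is.finite(gm$q$Q)))

  # decorrelating one block's regions lowers modularity vs the intact FC
  fc_damaged <- unclass(fc)
  hub <- which(comm == 1)
  set.seed(30)
  fc_damaged[hub, ] <- fc_damaged[hub, ] * 0.1 +
    matrix(rnorm(length(hub) * 20, sd = 0.05), length(hub))
  fc_damaged[, hub] <- t(fc_damaged[hub, ])
  diag(fc_damaged) <- 1
  gm_d <- lesion_graph_metrics(fc_damaged, comm,
                               q_densities = c(0.2, 0.3), sw_densities = 0.4,
                               n_random = 10, seed = 1)
  expect_lt(gm_d$mean_q, gm$mean_q)

  # removing a lesioned node shrinks the matrix it works on
  gm_l <- lesion_graph_metrics(fc, comm, lesioned_node = 3,
                               q_densities = 0.3, sw_densities = 0.4,
                               n_random = 5, seed = 1)
  expect_true(is.finite(gm_l$mean_q))
})
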