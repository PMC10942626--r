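test_that("monolayer modularity matches hand values and a brute-force
           double-loop oracle", {
  tri2 <- two_triangles()
  expect_equal(modularity_mono(tri2, rep(1, 6)), 0, tolerance = 1e-12)
  expect_equal(modularity_mono(tri2, c(1, 1, 1, 2, 2, 2)), 0.5)
  # brute force on random weighted graphs up to 12 nodes
  for (s in 1:6) {
    n <- sample(4:12, 1)
    A <- rand_sym(n, density = 0.6, seed = 200 + s)
    if (sum(A) == 0) next
    mb <- sample(1:3, n, replace = TRUE)
    two_m <- sum(A)
    k <- rowSums(A)
    q <- 0
    for (i in 1:n) {
      for (j in 1:n) {
        if (mb[i] == mb[j]) q <- q + A[i, j] - k[i] * k[j] / two_m
      }
    }
    expect_equal(modularity_mono(A, mb), q / two_m, tolerance = 1e-12)
    # igraph as an independent implementation of the same statistic
    g <- igraph::graph_from_adjacency_matrix(A, "undirected",
                                             weighted = TRUE)
    expect_equal(modularity_mono(A, mb),
                 igraph::modularity(g, mb, weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
  expect_error(modularity_mono(matrix(0, 3, 3), c(1, 1, 2)), "edgeless")
})

test_that("multilayer modularity reduces to the monolayer form and responds
           to the coupling term", {
  A <- rand_sym(5, density = 0.9, seed = 21)
  mb <- c(1, 1, 2, 2, 2)
  expect_equal(modularity_multi(list(A), mb, gamma = 1, omega = 1),
               modularity_mono(A, mb), tolerance = 1e-12)
  # identical layers, omega = 0: mean of per-layer modularity
  expect_equal(modularity_multi(list(A, A, A), mb, gamma = 1, omega = 0),
               modularity_mono(A, mb), tolerance = 1e-12)
  # with identical partitions across layers Q increases monotonically in omega
  B <- rand_sym(5, density = 0.9, seed = 22)
  qs <- sapply(c(0, 0.5, 1, 2, 5), function(om) {
    modularity_multi(list(A, B), mb, gamma = 1, omega = om)
  })
  expect_true(all(diff(qs) > 0))
})

test_that("hand-expanded multilayer modularity matches on 4-node layers", {
  A <- rand_sym(4, density = 1, seed = 23)
  B <- rand_sym(4, density = 1, seed = 24)
  mb <- matrix(c(1, 1, 2, 2, 1, 2, 2, 1), 4, 2)
  gamma <- 1; omega <- 0.7
  # explicit expansion of the supra sum
  intra <- 0; total <- 0
  for (L in list(list(A, 1), list(B, 2))) {
    Al <- L[[1]]; l <- L[[2]]
    kl <- rowSums(Al); two_m <- sum(Al)
    for (i in 1:4) {
      for (j in 1:4) {
        if (mb[i, l] == mb[j, l]) {
          intra <- intra + Al[i, j] - gamma * kl[i] * kl[j] / two_m
        }
      }
    }
    total <- total + two_m
  }
  inter <- 2 * omega * sum(mb[, 1] == mb[, 2])
  oracle <- (intra + inter) / (total + 4 * 2 * 1 * omega)
  expect_equal(modularity_multi(list(A, B), mb, gamma, omega), oracle,
               tolerance = 1e-12)
})

test_that("community detection recovers planted structure", {
  tri2 <- two_triangles()
  p <- detect_communities(tri2, n_repeats = 10, seed = 1)
  expect_equal(p$n_communities, 2)
  expect_equal(p$Q, 0.5)
  expect_true(all(table(p$membership, c(1, 1, 1, 2, 2, 2)) %in% c(0, 3)))
  # complete graph: one community
  K6 <- matrix(1, 6, 6); diag(K6) <- 0
  expect_equal(detect_communities(K6, n_repeats = 5, seed = 2)$n_communities,
               1)
  # two-block SBM recovered in >= 95% of seeds
  ok <- 0
  for (s in 1:20) {
    set.seed(s)
    b <- rep(1:2, each = 10)
    A <- matrix(0, 20, 20)
    for (i in 1:19) {
      for (j in (i + 1):20) {
        A[i, j] <- A[j, i] <- rbinom(1, 1, if (b[i] == b[j]) 0.9 else 0.05)
      }
    }
    pt <- detect_communities(A, n_repeats = 10, seed = s)
    ok <- ok + (pt$n_communities == 2 &&
                  all(table(pt$membership, b) %in% c(0, 10)))
  }
  expect_gte(ok, 19)
})

test_that("detected partitions never fall below the trivial partition's Q", {
  for (s in 1:5) {
    A <- rand_sym(8, density = 0.5, seed = 300 + s)
    if (sum(A) == 0) next
    p <- detect_communities(A, n_repeats = 3, seed = s)
    expect_gte(p$Q, modularity_mono(A, rep(1, 8)) - 1e-12)
  }
  expect_error(detect_communities(matrix(0, 3, 3)), "empty")
})

test_that("consensus model rank is a fixed point on identical partitions and
           robust to label noise", {
  parts <- replicate(4, c(1, 1, 2, 2, 3, 3), simplify = FALSE)
  cr <- consensus_model_rank(parts, seed = 5)
  expect_equal(cr$rank, 3)
  expect_true(cr$agreement)
  # idempotence: feeding the consensus back returns itself
  cr2 <- consensus_model_rank(list(cr$membership, cr$membership), seed = 6)
  expect_equal(cr2$rank, cr$rank)
  # 3 blocks of 9 nodes with 10% label noise: rank 3 in >= 90% of seeds
  ok <- 0
  for (s in 1:10) {
    set.seed(s)
    base <- rep(1:3, each = 3)
    parts <- lapply(1:6, function(i) {
      p <- base
      flip <- runif(9) < 0.1
      p[flip] <- sample(1:3, sum(flip), replace = TRUE)
      p
    })
    ok <- ok + (consensus_model_rank(parts, seed = s)$rank == 3)
  }
  expect_gte(ok, 9)
  expect_error(consensus_model_rank(list(c(1, 2))), ">= 2 partitions")
  expect_error(consensus_model_rank(list(c(1, 2), c(1, 2, 3))), "common node")
})

test_that("consensus on orthogonal partitions attains the exhaustive-oracle
           modularity", {
  p1 <- c(1, 1, 2, 2)
  p2 <- c(1, 2, 1, 2)
  cr <- consensus_model_rank(list(p1, p2), seed = 7)
  binaries <- lapply(list(p1, p2), function(mb) outer(mb, mb, `==`) * 1)
  # enumerate all partitions of 4 nodes, evaluate multilayer Q with the
  # consensus membership replicated across layers
  parts4 <- list(c(1,1,1,1), c(1,1,1,2), c(1,1,2,1), c(1,2,1,1), c(2,1,1,1),
                 c(1,1,2,2), c(1,2,1,2), c(1,2,2,1), c(1,1,2,3), c(1,2,1,3),
                 c(1,2,3,1), c(2,1,1,3), c(2,1,3,1), c(2,3,1,1), c(1,2,3,4))
  qs <- vapply(parts4, function(mb) {
    modularity_multi(binaries, matrix(mb, 4, 2), gamma = 1, omega = 1)
  }, 0)
  achieved <- modularity_multi(binaries,
                               matrix(cr$membership, 4, 2), 1, 1)
  expect_gte(achieved, max(qs) - 1e-9)
})

test_that("consensus ranks of a planted coupling tensor match the planted
           spatial and temporal structure", {
  g <- rank32_dataset(n_participants = 3, n_trials = 400, seed = 77)
  sp <- sparsify_dual_domain(build_tensor(g$dataset, "redundant"),
                             n_random = 100, seed = 7)
  rk <- select_ranks(sp, n_repeats = 20, seed = 8)
  expect_equal(rk$spatial$rank, 3)
  expect_equal(rk$temporal$rank, 2)
  expect_equal(unname(rk$spatial$membership), rep(1:3, each = 3))
  expect_equal(length(unique(rk$temporal$membership[1:5])), 1)
  expect_equal(length(unique(rk$temporal$membership[6:10])), 1)
})
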