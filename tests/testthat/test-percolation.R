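test_that("giant-component fraction matches explicit component analysis", {
  K5 <- matrix(1, 5, 5); diag(K5) <- 0
  expect_equal(giant_component_fraction(K5), 1)
  expect_equal(giant_component_fraction(matrix(0, 4, 4)), 0.25)
  expect_equal(giant_component_fraction(two_triangles()), 0.5)
  # igraph as independent oracle on random graphs
  for (s in 1:5) {
    A <- rand_sym(8, density = 0.35, seed = s)
    g <- igraph::graph_from_adjacency_matrix(A > 0, "undirected")
    expect_equal(giant_component_fraction(A),
                 max(igraph::components(g)$csize) / 8)
  }
  expect_error(giant_component_fraction(matrix(1, 2, 3)), "square")
})

test_that("a path graph stops at the first removal: Pc is the minimum weight
           and no removals survive", {
  for (weights in list(c(0.5, 0.1, 0.9, 0.7), c(0.1, 0.5, 0.7, 0.9))) {
    A <- matrix(0, 5, 5)
    for (k in 1:4) {
      A[k, k + 1] <- weights[k]
      A[k + 1, k] <- weights[k]
    }
    rep_ <- percolation_threshold(A, n_random = 100, seed = 1)
    expect_equal(rep_$Pc, min(weights))
    expect_equal(nrow(rep_$removed_edges), 0)
    expect_equal(rep_$retained, A)
  }
})

test_that("a weak bridge to a pendant node bounds Pc from above", {
  A <- matrix(0, 5, 5)
  cl <- combn(4, 2)
  w <- seq(0.5, 0.75, length.out = ncol(cl))
  for (k in seq_len(ncol(cl))) {
    A[cl[1, k], cl[2, k]] <- w[k]
    A[cl[2, k], cl[1, k]] <- w[k]
  }
  A[4, 5] <- A[5, 4] <- 0.1 # bridge
  rep_ <- percolation_threshold(A, n_random = 100, seed = 2)
  expect_lte(rep_$Pc, 0.1)
})

test_that("percolation agrees with an exhaustive-enumeration oracle on small
           graphs", {
  mk <- function(n, edges, weights) {
    A <- matrix(0, n, n)
    for (k in seq_along(weights)) {
      A[edges[k, 1], edges[k, 2]] <- weights[k]
      A[edges[k, 2], edges[k, 1]] <- weights[k]
    }
    A
  }
  cases <- list(
    # star plus weak chord
    list(A = mk(5, rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(2, 3)),
                c(0.9, 0.8, 0.7, 0.6, 0.1)), n = 5),
    # path with shuffled weights
    list(A = mk(5, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)),
                c(0.4, 0.9, 0.2, 0.7)), n = 5),
    # two triangles sharing no nodes, distinct weights
    list(A = mk(6, rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5)),
                c(0.9, 0.7, 0.5, 0.3)), n = 6))
  for (cs in cases) {
    A <- cs$A
    n <- cs$n
    pairs <- enumerate_pairs(n, include_diagonal = FALSE)
    w <- A[pairs]
    present <- which(w > 0)
    E <- length(present)
    # oracle: exact ER reference by enumerating all edge placements, then
    # ascending removal while the remaining giant component >= reference
    ref <- exact_er_reference(pairs, n, E)
    edges <- pairs[present, , drop = FALSE]
    wts <- w[present]
    ord <- order(wts, seq_len(E))
    gc_after <- sapply(seq_len(E), function(s) {
      keep <- ord[-seq_len(s)]
      gc_frac_r(edges[keep, , drop = FALSE], n)
    })
    stop_at <- which(gc_after < ref)
    s_stop <- if (length(stop_at)) stop_at[1] else E + 1
    oracle_removed <- if (s_stop > 1) ord[seq_len(s_stop - 1)] else integer(0)
    oracle_pc <- if (s_stop <= E) wts[ord[s_stop]] else max(wts)
    rep_ <- percolation_threshold(A, n_random = 400, seed = 5)
    expect_equal(rep_$Pc, oracle_pc)
    expect_equal(nrow(rep_$removed_edges), length(oracle_removed))
  }
})

test_that("percolation reports are deterministic given the seed and the
           component curve never increases", {
  A <- rand_sym(7, density = 0.7, seed = 6)
  r1 <- percolation_threshold(A, n_random = 50, seed = 9)
  r2 <- percolation_threshold(A, n_random = 50, seed = 9)
  expect_identical(r1, r2)
  r3 <- percolation_threshold(A, n_random = 200, seed = 10)
  expect_equal(r3$Pc, r1$Pc)
  expect_true(all(diff(r1$component_curve) <= 1e-12))
})

test_that("uniform weight scaling scales Pc and preserves the retained set", {
  A <- rand_sym(6, density = 0.7, seed = 7)
  r1 <- percolation_threshold(A, n_random = 100, seed = 11)
  r2 <- percolation_threshold(7 * A, n_random = 100, seed = 11)
  expect_equal(r2$Pc, 7 * r1$Pc)
  expect_equal(r2$retained > 0, r1$retained > 0)
})

test_that("empty layers pass through with a degenerate warning", {
  expect_warning(r <- percolation_threshold(matrix(0, 4, 4), seed = 1),
                 "degenerate")
  expect_equal(r$Pc, 0)
})

test_that("dual-domain sparsification only zeroes entries and keeps the
           mask consistent", {
  g <- rank32_dataset(n_participants = 1, n_trials = 150, seed = 18)
  tens <- build_tensor(g$dataset, "redundant")
  sp <- sparsify_dual_domain(tens, n_random = 50, seed = 3)
  expect_true(all(sp$values[!sp$mask] == 0))
  expect_true(all(sp$values[sp$mask] == tens$values[sp$mask]))
  expect_true(all(sp$values <= tens$values + 1e-15))
  expect_true(all(sp$values[sp$mask] > 0))
  # masked values all clear the per-layer noise floor
  for (l in seq_len(nrow(sp$layers))) {
    vals_l <- sp$values[, , l]
    expect_true(all(vals_l[vals_l > 0] >= sp$noise_floor[l]))
  }
})

test_that("entries significant in only one domain are masked out", {
  g <- rank32_dataset(n_participants = 1, n_trials = 150, seed = 19)
  tens <- build_tensor(g$dataset, "redundant")
  # recompute the single-domain masks by sparsifying each orientation and
  # verify the conjunction
  sp <- sparsify_dual_domain(tens, n_random = 50, seed = 4)
  one_sided <- sp$values > 0
  expect_true(all(one_sided == sp$mask))
  # an entry failing the floor cannot be retained however strong its rank
  floor_fail <- tens$values < min(sp$noise_floor)
  expect_true(all(!sp$mask[floor_fail]))
})
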