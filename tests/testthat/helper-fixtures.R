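# Shared fixture builders. Everything is generated in code at test time.

# planted rank-(3,2) redundant structure: three muscle triples driven by
# independent task contrasts, two temporal windows
rank32_planted <- function() {
  data.frame(i = 1:9, j = 1:9, class = "redundant",
             t_from = rep(c(1L, 1L, 6L), each = 3),
             t_to = rep(c(5L, 5L, 10L), each = 3),
             strength = rep(c(1, 1.2, 1), 3),
             group = rep(1:3, each = 3))
}

rank32_dataset <- function(n_participants = 3, n_trials = 400, seed = 77) {
  generate(synthetic_spec(n_participants = n_participants,
                          n_trials = n_trials, n_muscles = 9,
                          n_timepoints = 10, n_classes = 4,
                          planted = rank32_planted(), seed = seed))
}

# a spanning path of task-irrelevant couplings (independent latent per pair)
path_planted <- function(t_from = 1L, t_to = 4L) {
  data.frame(i = c(1L, 2L, 3L, 4L), j = c(2L, 3L, 4L, 5L),
             class = "irrelevant", t_from = t_from, t_to = t_to,
             strength = 1)
}

# identifiable non-negative factors: disjoint spatial support, compact
# temporal bumps (synergy-like structure; identifiability makes the
# factorisation unique up to permutation and scale)
structured_factors <- function(K = 15, TT = 10) {
  V0 <- rbind(c(rep(1, 5), rep(0, K - 5)),
              c(rep(0, 5), rep(1, 5), rep(0, K - 10)),
              c(rep(0, K - 5), rep(1, 5)))
  w1 <- pmax(0, dnorm(seq_len(TT), TT * 0.25, TT * 0.1) - 0.02)
  w2 <- pmax(0, dnorm(seq_len(TT), TT * 0.8, TT * 0.1) - 0.02)
  list(V = V0, W = rbind(w1, w2) * 10)
}

# planted rank-(3,2) tensor A = V' S' W (+ optional noise), layer-specific
# S. The first two layers carry near-pure factor combinations (separability)
# so the non-negative factorisation is unique up to permutation and scale;
# the remaining layers mix all combinations at random.
planted_tensor <- function(L = 4, K = 15, TT = 10, noise_sd = 0, seed = 1) {
  set.seed(seed)
  f <- structured_factors(K, TT)
  pure <- list(rbind(c(1, 0, 0), c(0, 0, 1)),
               rbind(c(0, 1, 0), c(1, 0, 0)))
  A <- lapply(seq_len(L), function(l) {
    S <- if (l <= 2L) pure[[l]] else matrix(runif(6, 0.2, 1), 2, 3)
    X <- t(f$V) %*% t(S) %*% f$W
    if (noise_sd > 0) X <- X + matrix(abs(rnorm(K * TT, sd = noise_sd)), K, TT)
    X
  })
  list(layers = A, V = f$V, W = f$W)
}

# tensor with layer-specific one-to-one factor pairing (all-to-all across
# layers), the regime where CP's fixed pairing is misspecified
paired_layers_tensor <- function(L = 6, K = 15, TT = 12, noise_sd = 0.5,
                                 seed = 11) {
  set.seed(seed)
  f <- structured_factors(K, TT)
  combos <- expand.grid(i = 1:2, j = 1:3)
  lapply(seq_len(L), function(l) {
    S <- matrix(0, 2, 3)
    cb <- combos[(l - 1) %% 6 + 1, ]
    S[cb$i, cb$j] <- 1
    t(f$V) %*% t(S) %*% f$W +
      matrix(abs(rnorm(K * TT, sd = noise_sd)), K, TT)
  })
}

# symmetric adjacency of two disjoint triangles on 6 nodes
two_triangles <- function() {
  A <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))) {
    A[e[1], e[2]] <- 1
    A[e[2], e[1]] <- 1
  }
  A
}

rand_sym <- function(n, density = 1, seed = 1, weights = TRUE) {
  set.seed(seed)
  A <- matrix(0, n, n)
  idx <- which(upper.tri(A), arr.ind = TRUE)
  keep <- runif(nrow(idx)) < density
  w <- if (weights) runif(sum(keep)) else 1
  A[idx[keep, , drop = FALSE]] <- w
  A + t(A)
}

# plain-R union-find giant-component fraction (independent of the package's
# compiled path)
gc_frac_r <- function(edges, n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      a <- find(edges[e, 1]); b <- find(edges[e, 2])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  max(table(roots)) / n
}

# exact expected giant-component fraction of a random network with n nodes
# and E edges drawn from the given pair universe (exhaustive enumeration)
exact_er_reference <- function(pairs, n, E) {
  combos <- utils::combn(nrow(pairs), E)
  mean(apply(combos, 2L, function(ix) {
    gc_frac_r(pairs[ix, , drop = FALSE], n)
  }))
}
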