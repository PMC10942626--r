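# Model-rank selection: modularity-based community detection on mono- and
# multilayer coupling networks, with consensus over participants/tasks.

#' Newman-Girvan modularity of a partition
#'
#' `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) * delta(g_i, g_j)` with
#' `m = sum(A)/2`; the degree-preserving random network is the null model.
#'
#' @param adj symmetric non-negative adjacency matrix.
#' @param membership integer community id per node.
#' @return modularity Q (typically in `[0, 1]`; 0 for the trivial
#'   all-in-one partition).
#' @export
modularity_mono <- function(adj, membership) {
  adj <- as.matrix(adj)
  n <- nrow(adj)
  stopifnot(length(membership) == n)
  two_m <- sum(adj)
  if (two_m <= 0) stop("modularity undefined for an edgeless network",
                       call. = FALSE)
  k <- rowSums(adj)
  B <- adj - outer(k, k) / two_m
  same <- outer(membership, membership, `==`)
  sum(B[same]) / two_m
}

#' Multilayer (multiplex) modularity
#'
#' Generalises the Q-statistic with an inter-layer coupling term:
#' `Q = (1/2mu) * sum_ijlr [ (A_ijl - gamma * P_ijl) delta_lr +
#' delta_ij * omega ] * delta(g_il, g_jr)` where `P_ijl` is the
#' Newman-Girvan null of layer `l`, coupling is all-to-all across layers for
#' the same node, and `2mu` is the total edge weight including coupling.
#' Reduces to [modularity_mono()] for a single layer with `gamma = 1`.
#'
#' @param layers list of symmetric adjacency matrices over a common node set.
#' @param membership `n x L` integer matrix (or vector, recycled across
#'   layers): community of node i in layer l.
#' @param gamma intra-layer resolution (default 1, classical modularity).
#' @param omega inter-layer coupling (default 1).
#' @return multilayer modularity Q.
#' @export
modularity_multi <- function(layers, membership, gamma = 1, omega = 1) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  n <- nrow(layers[[1L]])
  L <- length(layers)
  if (is.vector(membership)) membership <- matrix(membership, n, L)
  stopifnot(nrow(membership) == n, ncol(membership) == L)
  total <- 0
  intra <- 0
  for (l in seq_len(L)) {
    A <- as.matrix(layers[[l]])
    two_m <- sum(A)
    if (two_m <= 0) stop("modularity undefined: edgeless layer", call. = FALSE)
    k <- rowSums(A)
    B <- A - gamma * outer(k, k) / two_m
    same <- outer(membership[, l], membership[, l], `==`)
    intra <- intra + sum(B[same])
    total <- total + two_m
  }
  inter <- 0
  if (L > 1L && omega > 0) {
    for (l in seq_len(L - 1L)) {
      for (r in (l + 1L):L) {
        inter <- inter + 2 * omega * sum(membership[, l] == membership[, r])
      }
    }
  }
  two_mu <- total + n * L * (L - 1L) * omega
  (intra + inter) / two_mu
}

# ---- generalised Louvain on a (supra-)modularity matrix ----------------------

# one greedy pass to a local optimum of sum_ij B_ij delta(g_i, g_j)
.louvain_local <- function(B, membership) {
  n <- nrow(B)
  repeat {
    moved <- FALSE
    for (i in sample.int(n)) {
      s <- rowsum(B[i, ], membership)
      comms <- as.integer(rownames(s))
      cur <- membership[i]
      s_i <- s[, 1L] - ifelse(comms == cur, B[i, i], 0)
      best <- comms[which.max(s_i)] # which.max takes the lowest index on ties
      if (best != cur && s_i[match(best, comms)] >
            s_i[match(cur, comms)] + 1e-12) {
        membership[i] <- best
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  membership
}

# full generalised Louvain: local moves + aggregation, single restart
.genlouvain_once <- function(B) {
  n <- nrow(B)
  map <- seq_len(n) # original node -> current super-node
  Bcur <- B
  repeat {
    mb <- .louvain_local(Bcur, seq_len(nrow(Bcur)))
    mb <- match(mb, sort(unique(mb)))
    if (max(mb) == nrow(Bcur)) break # no merges in this phase
    map <- mb[map]
    Bcur <- as.matrix(rowsum(t(rowsum(Bcur, mb)), mb))
    if (nrow(Bcur) == 1L) break
  }
  match(map, sort(unique(map)))
}

#' Detect communities by modularity maximisation
#'
#' Greedy Louvain-style optimisation of the (multilayer) Q-statistic:
#' repeated local node moves with aggregation, best of `n_repeats` random
#' restarts. For a list of layers the supra-modularity matrix couples copies
#' of each node across layers with weight `omega`.
#'
#' @param x symmetric adjacency matrix, or list of such matrices (multiplex).
#' @param gamma,omega resolution and inter-layer coupling (defaults 1, 1).
#' @param n_repeats random restarts; the partition with the best Q is kept.
#' @param seed RNG seed for reproducibility.
#' @return a `partition`: `membership` (vector, or `n x L` matrix for
#'   multiplex input), `n_communities`, `Q`, and bookkeeping.
#' @export
detect_communities <- function(x, gamma = 1, omega = 1, n_repeats = 50,
                               seed = NULL) {
  multilayer <- is.list(x) && !is.matrix(x)
  if (multilayer && length(x) == 1L) {
    x <- x[[1L]]
    multilayer <- FALSE
  }
  if (multilayer) {
    layers <- lapply(x, as.matrix)
    n <- nrow(layers[[1L]])
    L <- length(layers)
    if (sum(vapply(layers, sum, 0)) <= 0) stop("empty network", call. = FALSE)
    N <- n * L
    B <- matrix(0, N, N)
    for (l in seq_len(L)) {
      A <- layers[[l]]
      two_m <- sum(A)
      k <- rowSums(A)
      P <- if (two_m > 0) gamma * outer(k, k) / two_m else 0
      idx <- (l - 1L) * n + seq_len(n)
      B[idx, idx] <- A - P
    }
    if (omega > 0 && L > 1L) {
      for (l in seq_len(L - 1L)) {
        for (r in (l + 1L):L) {
          il <- (l - 1L) * n + seq_len(n)
          ir <- (r - 1L) * n + seq_len(n)
          B[cbind(il, ir)] <- B[cbind(il, ir)] + omega
          B[cbind(ir, il)] <- B[cbind(ir, il)] + omega
        }
      }
    }
  } else {
    A <- as.matrix(x)
    if (sum(A) <= 0) stop("empty network", call. = FALSE)
    n <- nrow(A)
    L <- 1L
    k <- rowSums(A)
    B <- A - gamma * outer(k, k) / sum(A)
  }
  score <- function(mb) sum(B[outer(mb, mb, `==`)])
  best <- .with_seed(seed, function() {
    best_mb <- NULL
    best_s <- -Inf
    for (r in seq_len(max(1L, n_repeats))) {
      mb <- .genlouvain_once(B)
      s <- score(mb)
      if (s > best_s + 1e-12) {
        best_s <- s
        best_mb <- mb
      }
    }
    # never return a partition worse than the trivial all-in-one
    if (score(rep(1L, nrow(B))) > best_s + 1e-12) {
      best_mb <- rep(1L, nrow(B))
    }
    best_mb
  })
  if (multilayer) {
    membership <- matrix(best, n, L)
    Q <- modularity_multi(layers, membership, gamma, omega)
  } else {
    membership <- best
    Q <- modularity_mono(A, membership)
  }
  structure(list(membership = membership,
                 n_communities = length(unique(as.vector(best))),
                 Q = Q, gamma = gamma, omega = if (multilayer) omega else NA,
                 multilayer = multilayer),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition: %d communities, Q = %.4f%s>\n", x$n_communities,
              x$Q, if (x$multilayer) " (multilayer)" else ""))
  invisible(x)
}

#' Consensus model rank from a set of partitions
#'
#' Each input partition over a common node set is converted to a binary
#' co-classification matrix (1 where two nodes share a community); the
#' matrices are stacked as layers of a new multiplex network and community
#' detection is re-applied. The number of consensus communities is the model
#' rank. Both detection variants are run: the multilayer form (default
#' result) and the monolayer form on the mean co-classification matrix.
#'
#' @param partitions list of membership vectors (or `partition` objects)
#'   over the same nodes.
#' @param gamma,omega,n_repeats,seed passed to [detect_communities()].
#' @return a `model_rank`: `rank` (multilayer consensus), `rank_monolayer`,
#'   `membership`, `agreement` flag and the consensus trace.
#' @export
consensus_model_rank <- function(partitions, gamma = 1, omega = 1,
                                 n_repeats = 50, seed = NULL) {
  mbs <- lapply(partitions, function(p) {
    if (inherits(p, "partition")) p$membership else p
  })
  if (length(mbs) < 2L) stop("need >= 2 partitions for consensus",
                             call. = FALSE)
  n <- length(mbs[[1L]])
  if (any(vapply(mbs, length, 0L) != n)) {
    stop("partitions must cover a common node set", call. = FALSE)
  }
  binaries <- lapply(mbs, function(mb) {
    (outer(mb, mb, `==`)) * 1
  })
  multi <- detect_communities(binaries, gamma, omega, n_repeats,
                              seed = .child_seed(seed, 1L))
  mean_mat <- Reduce(`+`, binaries) / length(binaries)
  mono <- detect_communities(mean_mat, gamma, omega = 0, n_repeats,
                             seed = .child_seed(seed, 2L))
  # node-level consensus membership: first layer of the multilayer partition
  membership <- multi$membership[, 1L]
  membership <- match(membership, sort(unique(membership)))
  structure(list(rank = length(unique(membership)),
                 rank_multilayer = length(unique(membership)),
                 rank_monolayer = mono$n_communities,
                 agreement = length(unique(membership)) ==
                   mono$n_communities,
                 membership = membership,
                 trace = list(multilayer = multi, monolayer = mono)),
            class = "model_rank")
}

#' @export
print.model_rank <- function(x, ...) {
  cat(sprintf("<model_rank: %d (multilayer) / %d (monolayer)%s>\n",
              x$rank_multilayer, x$rank_monolayer,
              if (x$agreement) "" else " [disagreement]"))
  invisible(x)
}

#' Consensus spatial and temporal model ranks of a coupling tensor
#'
#' For each layer (participant x task variable) the spatial slices (muscle
#' networks across timepoint pairs) and temporal slices (timepoint networks
#' across muscle pairs) are treated as multiplex networks; community
#' detection gives one spatial and one temporal partition per layer, and the
#' consensus over layers fixes the model ranks.
#'
#' @param tensor a `coupling_tensor` or `sparse_coupling`.
#' @param gamma,omega,n_repeats passed to [detect_communities()].
#' @param seed RNG seed.
#' @return list with `spatial` and `temporal` `model_rank` objects.
#' @export
select_ranks <- function(tensor, gamma = 1, omega = 1, n_repeats = 50,
                         seed = NULL) {
  stopifnot(inherits(tensor, "coupling_tensor"))
  nL <- nrow(tensor$layers)
  sv <- as_layers(tensor, "spatial")
  tv <- as_layers(tensor, "temporal")
  part_for <- function(view, l, k) {
    sl <- which(view$slice_index$layer == l)
    mats <- lapply(sl, function(s) {
      m <- view$matrices[, , s]
      diag(m) <- 0 # same-node self-couplings carry no community information
      m
    })
    mats <- Filter(function(m) sum(m) > 0, mats)
    if (!length(mats)) return(NULL)
    detect_communities(mats, gamma, omega, n_repeats,
                       seed = .child_seed(seed, k))$membership[, 1L]
  }
  sp_parts <- Filter(Negate(is.null),
                     lapply(seq_len(nL), function(l) part_for(sv, l, l)))
  tm_parts <- Filter(Negate(is.null),
                     lapply(seq_len(nL), function(l) part_for(tv, l, nL + l)))
  if (length(sp_parts) < 2L || length(tm_parts) < 2L) {
    stop("too few non-empty layers for consensus rank selection",
         call. = FALSE)
  }
  list(spatial = consensus_model_rank(sp_parts, gamma, omega, n_repeats,
                                      seed = .child_seed(seed, 900001L)),
       temporal = consensus_model_rank(tm_parts, gamma, omega, n_repeats,
                                       seed = .child_seed(seed, 900002L)))
}
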