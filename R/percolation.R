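# Percolation-based sparsification: each network layer is pruned at its
# percolation threshold relative to weight-shuffled null networks, and an
# entry must survive in both the spatial and the temporal domain.

#' Giant-component fraction of a weighted network
#'
#' Size of the largest connected component divided by the number of nodes,
#' treating strictly positive entries as edges.
#'
#' @param adj square symmetric non-negative matrix.
#' @return fraction in `[1/n, 1]`.
#' @export
giant_component_fraction <- function(adj) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj)) stop("adjacency matrix must be square",
                                   call. = FALSE)
  if (!isTRUE(all.equal(adj, t(adj)))) stop("adjacency must be symmetric",
                                            call. = FALSE)
  n <- nrow(adj)
  idx <- which(upper.tri(adj, diag = TRUE) & adj > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(1 / n)
  curve <- .gc_curve_cpp(idx, n, seq_len(nrow(idx)))
  curve[1L]
}

# Core percolation on an edge list. pairs: the universe of possible edges
# (k x 2 matrix; may include self-pairs, which never affect connectivity);
# w: weights over that universe (0 = absent). Null networks are
# equivalently sized random networks: the same number of nodes and edges,
# edges placed uniformly at random in the universe, removed in random
# order. Edges are removed in ascending weight order while the empirical
# giant component stays at or above the random-network reference (the mean
# null giant-component fraction at full density); the first removal that
# would push it below is not committed. Returns retained logical, Pc,
# curves, and the layer-significance statistic.
.percolate_edges <- function(pairs, w, n, n_random = 100, seed = NULL) {
  present <- which(w > 0)
  retained <- w > 0
  if (length(present) == 0L) {
    return(list(retained = retained, Pc = 0, empirical = numeric(0),
                null_mean = numeric(0), removed = integer(0),
                deviation_exceeded = 0, degenerate = TRUE))
  }
  E <- length(present)
  edges <- pairs[present, , drop = FALSE]
  wts <- w[present]
  ord <- order(wts, seq_len(E)) # ascending weight, ties by index
  emp <- .gc_curve_cpp(edges, n, ord)
  nulls <- .with_seed(seed, function() {
    curves <- matrix(0, n_random, E + 1L)
    for (r in seq_len(n_random)) {
      eidx <- sample.int(nrow(pairs), E)
      curves[r, ] <- .gc_curve_cpp(pairs[eidx, , drop = FALSE], n,
                                   sample.int(E))
    }
    curves
  })
  null_mean <- colMeans(nulls)
  reference <- null_mean[1L] # random-network giant component at full density
  # KS-style layer statistic: largest deviation of a giant-component curve
  # from the null mean curve
  d_emp <- max(abs(emp - null_mean))
  d_null <- apply(abs(nulls - rep(null_mean, each = n_random)), 1L, max)
  drop_at <- which(emp[-1L] < reference)
  s_stop <- if (length(drop_at)) drop_at[1L] else E + 1L
  removed_local <- if (s_stop > 1L) ord[seq_len(s_stop - 1L)] else integer(0)
  Pc <- if (s_stop <= E) wts[ord[s_stop]] else max(wts)
  retained[present[removed_local]] <- FALSE
  list(retained = retained, Pc = Pc,
       empirical = emp, null_mean = null_mean, reference = reference,
       # fraction of null curves deviating strictly less from the null mean
       # than the observed curve does (ties count against significance, so a
       # layer indistinguishable from its nulls is never flagged)
       deviation_exceeded = mean(d_emp > d_null),
       removed = present[removed_local], degenerate = FALSE)
}

#' Percolation threshold of one network layer
#'
#' Edges are removed in ascending weight order while the giant-component
#' fraction of the remaining network stays at or above the reference level
#' of equivalently sized random networks (same node and edge count, edges
#' placed at random); the threshold `Pc` is the weight of the edge whose
#' removal would first make the giant component smaller than that
#' reference. Edges removed before that point are the sub-significant ones.
#'
#' @param adj square symmetric non-negative matrix.
#' @param n_random number of weight-shuffled null networks (>= 20).
#' @param seed RNG seed for the null ensemble (recorded in the report).
#' @return a `percolation_report`: `Pc`, `component_curve` (empirical giant
#'   fraction vs removal step, step 0 first), `null_curve`, `removed_edges`
#'   (two-column index matrix), `retained` adjacency, `n_random`, `seed`.
#' @export
percolation_threshold <- function(adj, n_random = 100, seed = NULL) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj) || !isTRUE(all.equal(adj, t(adj)))) {
    stop("adjacency must be square and symmetric", call. = FALSE)
  }
  if (n_random < 20) stop("n_random must be >= 20", call. = FALSE)
  n <- nrow(adj)
  # self-couplings join the edge universe only when the data contains them
  pairs <- enumerate_pairs(n, include_diagonal = any(diag(adj) > 0))
  w <- adj[pairs]
  res <- .percolate_edges(pairs, w, n, n_random, seed)
  if (res$degenerate) warning("degenerate layer without edges; Pc = 0")
  keep <- matrix(0, n, n)
  kp <- pairs[res$retained, , drop = FALSE]
  keep[kp] <- w[res$retained]
  keep[kp[, c(2L, 1L), drop = FALSE]] <- w[res$retained]
  structure(list(Pc = res$Pc, component_curve = res$empirical,
                 null_curve = res$null_mean,
                 removed_edges = pairs[res$removed, , drop = FALSE],
                 retained = keep, n_random = n_random, seed = seed),
            class = "percolation_report")
}

#' @export
print.percolation_report <- function(x, ...) {
  cat(sprintf("<percolation_report: Pc = %.4g, %d edge(s) removed>\n",
              x$Pc, nrow(x$removed_edges)))
  invisible(x)
}

#' Dual-domain percolation sparsification of a coupling tensor
#'
#' Every spatial layer (muscle network per timepoint pair and layer) and
#' every temporal layer (timepoint network per muscle pair and layer) is
#' sparsified at its percolation threshold; a tensor entry is retained only
#' if it survives in both domains.
#'
#' The percolation step is rank-based within each layer, so it is blind to
#' the absolute magnitude of the couplings. A retained entry must therefore
#' also clear the estimator's noise floor: under independence the
#' bias-corrected information estimate behaves asymptotically like a
#' chi-squared variable over `2 n ln 2` (in bits), and the floor is the
#' Bonferroni-corrected upper quantile of that null across all tensor
#' entries. Entries at genuinely coupled (muscle pair, timepoint pair)
#' combinations exceed it by orders of magnitude at realistic trial counts.
#'
#' @param tensor a `coupling_tensor` (with per-layer trial counts).
#' @param n_random null networks per layer.
#' @param alpha significance level for the noise floor (Bonferroni-corrected
#'   across all tensor entries; default 0.05).
#' @param df effective degrees of freedom of the chi-squared noise null
#'   (default 5, conservative for pairwise estimates and class mixtures).
#' @param seed seed for the null ensembles (per-layer seeds derived from it).
#' @return a `sparse_coupling`: the masked tensor (`values`), logical `mask`,
#'   per-domain threshold matrices, and the parent tensor bookkeeping.
#' @export
sparsify_dual_domain <- function(tensor, n_random = 100, alpha = 0.05,
                                 df = 5, seed = NULL) {
  stopifnot(inherits(tensor, "coupling_tensor"))
  vals <- tensor$values
  n_mp <- nrow(tensor$muscle_pairs)
  n_tp <- nrow(tensor$time_pairs)
  nL <- nrow(tensor$layers)
  mask_sp <- array(FALSE, dim = dim(vals))
  mask_tm <- array(FALSE, dim = dim(vals))
  Pc_sp <- matrix(0, n_tp, nL)
  Pc_tm <- matrix(0, n_mp, nL)
  n_entries <- n_mp * n_tp * nL
  floor_bits <- rep(0, nL)
  if (!is.null(tensor$layers$n_trials)) {
    floor_bits <- stats::qchisq(1 - alpha / n_entries, df) /
      (2 * tensor$layers$n_trials * log(2))
  }
  mask_floor <- array(FALSE, dim = dim(vals))
  k <- 0L
  for (l in seq_len(nL)) {
    mask_floor[, , l] <- vals[, , l] >= floor_bits[l]
    for (ti in seq_len(n_tp)) {
      k <- k + 1L
      res <- .percolate_edges(tensor$muscle_pairs, vals[, ti, l],
                              tensor$n_muscles, n_random,
                              .child_seed(seed, k))
      mask_sp[, ti, l] <- res$retained
      Pc_sp[ti, l] <- res$Pc
    }
    for (mi in seq_len(n_mp)) {
      k <- k + 1L
      res <- .percolate_edges(tensor$time_pairs, vals[mi, , l],
                              tensor$n_timepoints, n_random,
                              .child_seed(seed, k))
      mask_tm[mi, , l] <- res$retained
      Pc_tm[mi, l] <- res$Pc
    }
  }
  mask <- mask_sp & mask_tm & mask_floor
  out <- vals
  out[!mask] <- 0
  structure(list(values = out, mask = mask,
                 Pc_spatial = Pc_sp, Pc_temporal = Pc_tm,
                 muscle_pairs = tensor$muscle_pairs,
                 time_pairs = tensor$time_pairs, layers = tensor$layers,
                 interaction = tensor$interaction,
                 n_muscles = tensor$n_muscles,
                 n_timepoints = tensor$n_timepoints,
                 muscle_names = tensor$muscle_names,
                 n_random = n_random, alpha = alpha, df = df,
                 noise_floor = floor_bits, seed = seed),
            class = c("sparse_coupling", "coupling_tensor"))
}

#' @export
print.sparse_coupling <- function(x, ...) {
  cat(sprintf(paste0("<sparse_coupling (%s): %.1f%% of entries retained ",
                     "(%d x %d x %d)>\n"), x$interaction,
              100 * mean(x$mask), dim(x$values)[1L], dim(x$values)[2L],
              dim(x$values)[3L]))
  invisible(x)
}
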