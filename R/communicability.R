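# Subnetwork analysis of extracted spatial networks: communicability,
# below-average pruning, and submodule detection.

#' Network communicability profile
#'
#' Total communicability of node i is the row sum of the matrix exponential
#' of the adjacency matrix, `C(i) = sum_j [e^A]_ij`, counting weighted walks
#' of all lengths between node pairs.
#'
#' @param adj symmetric square adjacency matrix.
#' @return a `communicability_profile`: `node_total` (per node),
#'   `edge_matrix` (`e^A`), and the input adjacency.
#' @export
communicability <- function(adj) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj) || !isTRUE(all.equal(adj, t(adj)))) {
    stop("adjacency must be square and symmetric", call. = FALSE)
  }
  eA <- as.matrix(Matrix::expm(Matrix::Matrix(adj)))
  structure(list(node_total = rowSums(eA), edge_matrix = eA, adj = adj),
            class = "communicability_profile")
}

#' @export
print.communicability_profile <- function(x, ...) {
  cat("<communicability_profile>\n")
  print(round(x$node_total, 4))
  invisible(x)
}

#' Prune edges with below-average communicability
#'
#' Retains an existing edge (i, j) only if its communicability
#' `[e^A]_ij` is at least the mean communicability over all existing edges.
#' A single pass; re-application may prune further.
#'
#' @param adj symmetric adjacency matrix.
#' @param profile optional [communicability()] profile of `adj` (computed if
#'   missing).
#' @return pruned symmetric adjacency matrix.
#' @export
prune_below_average <- function(adj, profile = NULL) {
  adj <- as.matrix(adj)
  if (is.null(profile)) profile <- communicability(adj)
  if (!isTRUE(all.equal(profile$adj, adj))) {
    stop("profile was not computed from this adjacency matrix", call. = FALSE)
  }
  edges <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  if (nrow(edges) == 0L) {
    warning("edgeless network; returned unchanged")
    return(adj)
  }
  comm <- profile$edge_matrix[edges]
  keep <- comm >= mean(comm) - 1e-12 # ties at the mean are retained
  out <- matrix(0, nrow(adj), ncol(adj))
  ke <- edges[keep, , drop = FALSE]
  out[ke] <- adj[ke]
  out[ke[, c(2L, 1L), drop = FALSE]] <- adj[ke]
  diag(out) <- diag(adj)
  out
}

#' Submodules of a spatial network
#'
#' Monolayer modularity-based community detection applied to an extracted
#' spatial network.
#'
#' @param adj symmetric adjacency matrix.
#' @param n_repeats,seed passed to [detect_communities()].
#' @return a `partition`.
#' @export
submodules <- function(adj, n_repeats = 50, seed = NULL) {
  detect_communities(as.matrix(adj), gamma = 1, n_repeats = n_repeats,
                     seed = seed)
}

#' Spatial factor as a muscle network
#'
#' Maps a spatial factor vector (one value per muscle pair) back to a
#' symmetric muscle-by-muscle adjacency matrix, for communicability and
#' submodule analysis.
#'
#' @param v factor vector over muscle pairs.
#' @param muscle_pairs two-column pair index matching `v`.
#' @param n_muscles number of muscles.
#' @return symmetric `n_muscles x n_muscles` matrix.
#' @export
factor_to_network <- function(v, muscle_pairs, n_muscles) {
  stopifnot(length(v) == nrow(muscle_pairs))
  A <- matrix(0, n_muscles, n_muscles)
  A[muscle_pairs] <- v
  A[muscle_pairs[, c(2L, 1L), drop = FALSE]] <- v
  A
}
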