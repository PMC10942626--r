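# Sample-based non-negative matrix tri-factorisation (sNM3F): shared
# temporal factors W and spatial factors V across layers, layer-specific
# coefficient matrices S, A_l ~ V' S_l' W. Multiplicative updates; each
# block update is a Lee-Seung step on a linear non-negative subproblem, so
# the objective is non-increasing.

.as_layer_list <- function(A) {
  if (inherits(A, "coupling_tensor")) A <- A$values
  if (is.array(A) && length(dim(A)) == 3L) {
    lapply(seq_len(dim(A)[3L]), function(l) A[, , l])
  } else if (is.list(A)) {
    lapply(A, as.matrix)
  } else {
    list(as.matrix(A))
  }
}

.offdiag <- function(G) {
  diag(G) <- 0
  G
}

#' Fit a space-time tri-factorisation to a coupling tensor
#'
#' Minimises `sum_l || A_l - V' S_l' W ||_F^2` over non-negative spatial
#' factors `V` (`spatial_rank x muscle_pairs`), temporal factors `W`
#' (`temporal_rank x timepoint_pairs`) shared across layers, and
#' layer-specific non-negative coefficients `S` (all-to-all pairing: any
#' spatial factor can combine with any temporal factor), optionally with an
#' orthogonality-encouraging penalty on the factor Gram matrices. The
#' coefficients `S` scale the information overlap carried by each
#' spatial-temporal factor combination for each participant and task; they
#' are not variance accounted for.
#'
#' @param A a `sparse_coupling`/`coupling_tensor`, 3-d array
#'   (`muscle_pairs x timepoint_pairs x layers`), or list of layer matrices.
#' @param spatial_rank,temporal_rank numbers of spatial / temporal factors.
#' @param max_iter maximum multiplicative-update iterations (default 500).
#' @param tol relative objective-change convergence tolerance (default 1e-6).
#' @param n_restarts random restarts; the fit with the lowest residual wins.
#' @param seed RNG seed (restart seeds derived from it).
#' @param ortho_v,ortho_w orthogonality penalty weights on the rows of `V`
#'   and `W` (defaults 0: plain tri-factorisation).
#' @return an `snm3f` object: `V`, `W`, `S` (`layers x temporal_rank x
#'   spatial_rank`), `residual` (Frobenius), `rel_residual`, `objective`
#'   trace of the winning restart, `converged`.
#' @export
snm3f_fit <- function(A, spatial_rank, temporal_rank, max_iter = 500,
                      tol = 1e-6, n_restarts = 10, seed = NULL,
                      ortho_v = 0, ortho_w = 0) {
  layers <- .as_layer_list(A)
  K <- nrow(layers[[1L]]); TT <- ncol(layers[[1L]]); L <- length(layers)
  J <- as.integer(spatial_rank); I <- as.integer(temporal_rank)
  if (J < 1L || I < 1L) stop("ranks must be >= 1", call. = FALSE)
  if (J > K || I > TT) stop("rank exceeds tensor dimension", call. = FALSE)
  for (Al in layers) {
    if (any(Al < 0)) stop("input tensor must be non-negative", call. = FALSE)
  }
  normA2 <- sum(vapply(layers, function(Al) sum(Al^2), 0))
  if (normA2 == 0) {
    return(structure(list(
      V = matrix(0, J, K), W = matrix(0, I, TT), S = array(0, c(L, I, J)),
      residual = 0, rel_residual = 0, objective = 0, converged = TRUE,
      spatial_rank = J, temporal_rank = I, dims = c(K = K, T = TT, L = L)),
      class = "snm3f"))
  }
  eps <- 1e-12
  run_once <- function() {
    Vt <- matrix(runif(K * J), K, J) # K x J, t(V)
    W <- matrix(runif(I * TT), I, TT)
    St <- lapply(seq_len(L), function(l) matrix(runif(J * I), J, I)) # t(S_l)
    objective <- numeric(0)
    obj <- function() {
      fit <- sum(vapply(seq_len(L), function(l) {
        sum((layers[[l]] - Vt %*% St[[l]] %*% W)^2)
      }, 0))
      pen <- 0
      if (ortho_v > 0) pen <- pen + ortho_v * sum(.offdiag(t(Vt) %*% Vt)^2)
      if (ortho_w > 0) pen <- pen + ortho_w * sum(.offdiag(W %*% t(W))^2)
      fit + pen
    }
    prev <- obj()
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      WWt <- W %*% t(W) # I x I
      VtV <- t(Vt) %*% Vt # J x J
      for (l in seq_len(L)) {
        num <- t(Vt) %*% layers[[l]] %*% t(W) # J x I
        den <- VtV %*% St[[l]] %*% WWt
        St[[l]] <- St[[l]] * num / (den + eps)
      }
      numV <- matrix(0, K, J); denG <- matrix(0, J, J)
      for (l in seq_len(L)) {
        SW <- St[[l]] %*% W # J x TT
        numV <- numV + layers[[l]] %*% t(SW)
        denG <- denG + SW %*% t(SW)
      }
      denV <- Vt %*% denG
      if (ortho_v > 0) denV <- denV + 2 * ortho_v * Vt %*%
          .offdiag(t(Vt) %*% Vt)
      Vt <- Vt * numV / (denV + eps)
      numW <- matrix(0, I, TT); denH <- matrix(0, I, I)
      for (l in seq_len(L)) {
        VS <- t(St[[l]]) %*% t(Vt) # I x K
        numW <- numW + VS %*% layers[[l]]
        denH <- denH + VS %*% t(VS)
      }
      denW <- denH %*% W
      if (ortho_w > 0) denW <- denW + 2 * ortho_w *
          .offdiag(W %*% t(W)) %*% W
      W <- W * numW / (denW + eps)
      cur <- obj()
      objective <- c(objective, cur)
      if (prev > 0 && abs(prev - cur) / prev < tol) {
        converged <- TRUE
        break
      }
      prev <- cur
    }
    resid2 <- sum(vapply(seq_len(L), function(l) {
      sum((layers[[l]] - Vt %*% St[[l]] %*% W)^2)
    }, 0))
    list(Vt = Vt, W = W, St = St, resid2 = resid2, objective = objective,
         converged = converged)
  }
  fits <- lapply(seq_len(max(1L, n_restarts)), function(r) {
    .with_seed(.child_seed(if (is.null(seed)) NULL else seed, r), run_once)
  })
  best <- fits[[which.min(vapply(fits, `[[`, 0, "resid2"))]]
  if (!best$converged) {
    warning(sprintf("sNM3F did not converge in %d iterations (residual %.3g)",
                    max_iter, sqrt(best$resid2)))
  }
  S <- array(0, c(L, I, J))
  for (l in seq_len(L)) S[l, , ] <- t(best$St[[l]])
  structure(list(V = t(best$Vt), W = best$W, S = S,
                 residual = sqrt(best$resid2),
                 rel_residual = sqrt(best$resid2 / normA2),
                 objective = best$objective, converged = best$converged,
                 spatial_rank = J, temporal_rank = I,
                 dims = c(K = K, T = TT, L = L)),
            class = "snm3f")
}

#' @export
print.snm3f <- function(x, ...) {
  cat(sprintf(paste0("<snm3f: %d spatial x %d temporal factors, %d layer(s),",
                     " relative residual %.4g>\n"),
              x$spatial_rank, x$temporal_rank, x$dims[["L"]],
              x$rel_residual))
  invisible(x)
}

#' Reconstruct a coupling tensor from its tri-factorisation
#'
#' Per layer, `sum_{i,j} S[l,i,j] * outer(V[j,], W[i,])`.
#'
#' @param dec an `snm3f` object.
#' @return array `muscle_pairs x timepoint_pairs x layers`.
#' @export
reconstruct <- function(dec) {
  stopifnot(inherits(dec, "snm3f"))
  K <- dec$dims[["K"]]; TT <- dec$dims[["T"]]; L <- dec$dims[["L"]]
  out <- array(0, c(K, TT, L))
  for (l in seq_len(L)) {
    Sl <- matrix(dec$S[l, , ], dec$temporal_rank, dec$spatial_rank)
    out[, , l] <- t(dec$V) %*% t(Sl) %*% dec$W
  }
  out
}

#' Non-negative canonical polyadic (CP) decomposition
#'
#' Comparator for the tri-factorisation: CP assumes a one-to-one pairing of
#' spatial, temporal and layer factors (component r couples `V[r,]`, `W[r,]`
#' and `C[,r]` exclusively). Fitted by multiplicative alternating updates.
#'
#' @param A tensor input as in [snm3f_fit()].
#' @param rank number of CP components.
#' @param max_iter,tol,n_restarts,seed as in [snm3f_fit()].
#' @return a `cp_decomp`: `V` (`rank x muscle_pairs`), `W`
#'   (`rank x timepoint_pairs`), layer loadings `C` (`layers x rank`),
#'   `residual`, `rel_residual`, `objective` trace.
#' @export
cp_fit <- function(A, rank, max_iter = 500, tol = 1e-6, n_restarts = 10,
                   seed = NULL) {
  layers <- .as_layer_list(A)
  K <- nrow(layers[[1L]]); TT <- ncol(layers[[1L]]); L <- length(layers)
  R <- as.integer(rank)
  if (R < 1L) stop("rank must be >= 1", call. = FALSE)
  if (R > K * TT) stop("rank exceeds tensor dimension", call. = FALSE)
  X <- array(0, c(K, TT, L))
  for (l in seq_len(L)) X[, , l] <- layers[[l]]
  if (any(X < 0)) stop("input tensor must be non-negative", call. = FALSE)
  normA2 <- sum(X^2)
  X1 <- matrix(X, nrow = K)                      # K x (TT*L)
  X2 <- matrix(aperm(X, c(2L, 1L, 3L)), nrow = TT) # TT x (K*L)
  X3 <- matrix(aperm(X, c(3L, 1L, 2L)), nrow = L)  # L x (K*TT)
  kr <- function(Y, Z) { # Khatri-Rao: column r = kron(Y[,r], Z[,r])
    out <- matrix(0, nrow(Y) * nrow(Z), ncol(Y))
    for (r in seq_len(ncol(Y))) out[, r] <- kronecker(Y[, r], Z[, r])
    out
  }
  eps <- 1e-12
  run_once <- function() {
    U1 <- matrix(runif(K * R), K, R)
    U2 <- matrix(runif(TT * R), TT, R)
    U3 <- matrix(runif(L * R), L, R)
    objective <- numeric(0)
    prev <- Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      Z <- kr(U3, U2)
      U1 <- U1 * (X1 %*% Z) / (U1 %*% ((t(U2) %*% U2) * (t(U3) %*% U3)) + eps)
      Z <- kr(U3, U1)
      U2 <- U2 * (X2 %*% Z) / (U2 %*% ((t(U1) %*% U1) * (t(U3) %*% U3)) + eps)
      Z <- kr(U2, U1)
      U3 <- U3 * (X3 %*% Z) / (U3 %*% ((t(U1) %*% U1) * (t(U2) %*% U2)) + eps)
      cur <- normA2 - 2 * sum(X3 * (U3 %*% t(Z))) +
        sum((t(U1) %*% U1) * (t(U2) %*% U2) * (t(U3) %*% U3))
      objective <- c(objective, cur)
      if (is.finite(prev) && prev > 0 && abs(prev - cur) / prev < tol) {
        converged <- TRUE
        break
      }
      prev <- cur
    }
    list(U1 = U1, U2 = U2, U3 = U3, resid2 = max(0, cur),
         objective = objective, converged = converged)
  }
  fits <- lapply(seq_len(max(1L, n_restarts)), function(r) {
    .with_seed(.child_seed(if (is.null(seed)) NULL else seed, 7000L + r),
               run_once)
  })
  best <- fits[[which.min(vapply(fits, `[[`, 0, "resid2"))]]
  structure(list(V = t(best$U1), W = t(best$U2), C = best$U3,
                 residual = sqrt(best$resid2),
                 rel_residual = sqrt(best$resid2 / normA2),
                 objective = best$objective, converged = best$converged,
                 rank = R, dims = c(K = K, T = TT, L = L)),
            class = "cp_decomp")
}

#' @export
print.cp_decomp <- function(x, ...) {
  cat(sprintf("<cp_decomp: rank %d, relative residual %.4g>\n",
              x$rank, x$rel_residual))
  invisible(x)
}
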