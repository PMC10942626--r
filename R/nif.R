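# The central model object: the full task-space pipeline from envelopes to
# space-time muscle networks, as one fitting function returning a classed
# object.

#' Fit space-time muscle networks in the task space
#'
#' Runs the full network-information pipeline on an EMG dataset: (i) build
#' multiplex coupling tensors over muscle pairs, timepoint pairs and
#' (task x participant) layers for the task-irrelevant (conditional MI),
#' task-redundant and task-synergistic (rectified co-information) classes;
#' (ii) sparsify each class at its percolation threshold jointly in space
#' and time; (iii) select spatial and temporal model ranks by consensus
#' multilayer community detection (unless given); (iv) extract shared
#' spatial and temporal factors with layer-specific coefficients by
#' non-negative tri-factorisation; (v) analyse the spatial factors as
#' muscle networks (communicability, below-average pruning, submodules).
#'
#' @param dataset an [emg_dataset()].
#' @param spatial_rank,temporal_rank model ranks; `NULL` selects them by
#'   consensus community detection per interaction class.
#' @param interactions coupling classes to model.
#' @param sparsify apply dual-domain percolation sparsification.
#' @param n_random null networks per percolation layer.
#' @param rank_repeats Louvain restarts during rank selection.
#' @param n_restarts tri-factorisation restarts.
#' @param seed global seed; all stage seeds are derived from it.
#' @param ... further arguments to [snm3f_fit()].
#' @return an object of class `"nif"`; see [summary.nif()], [coef.nif()],
#'   [plot.nif()], [residuals.nif()], [fitted.nif()].
#' @export
nif <- function(dataset, spatial_rank = NULL, temporal_rank = NULL,
                interactions = c("irrelevant", "redundant", "synergistic"),
                sparsify = TRUE, n_random = 100, rank_repeats = 20,
                n_restarts = 10, seed = NULL, ...) {
  stopifnot(inherits(dataset, "emg_dataset"))
  interactions <- match.arg(interactions, several.ok = TRUE)
  tensors <- build_tensor(dataset, "all")[interactions]
  fits <- list()
  for (ci in seq_along(interactions)) {
    cls <- interactions[ci]
    tens <- tensors[[cls]]
    sp <- if (sparsify) {
      sparsify_dual_domain(tens, n_random, seed = .child_seed(seed, 10L * ci))
    } else tens
    if (all(sp$values == 0)) {
      fits[[cls]] <- list(tensor = tens, sparse = sp, ranks = NULL,
                          decomposition = NULL, networks = NULL,
                          empty = TRUE)
      next
    }
    if (is.null(spatial_rank) || is.null(temporal_rank)) {
      rk <- select_ranks(sp, n_repeats = rank_repeats,
                         seed = .child_seed(seed, 10L * ci + 1L))
      sr <- if (is.null(spatial_rank)) rk$spatial$rank else spatial_rank
      tr <- if (is.null(temporal_rank)) rk$temporal$rank else temporal_rank
    } else {
      rk <- NULL
      sr <- spatial_rank
      tr <- temporal_rank
    }
    sr <- min(sr, nrow(tens$muscle_pairs))
    tr <- min(tr, nrow(tens$time_pairs))
    dec <- snm3f_fit(sp, sr, tr, n_restarts = n_restarts,
                     seed = .child_seed(seed, 10L * ci + 2L), ...)
    nets <- lapply(seq_len(sr), function(j) {
      A <- factor_to_network(dec$V[j, ], tens$muscle_pairs, tens$n_muscles)
      if (sum(A) == 0) return(list(adj = A, profile = NULL, pruned = A,
                                   submodules = NULL))
      prof <- communicability(A)
      list(adj = A, profile = prof,
           pruned = prune_below_average(A, prof),
           submodules = submodules(A, n_repeats = rank_repeats,
                                   seed = .child_seed(seed,
                                                      10L * ci + 3L + j)))
    })
    fits[[cls]] <- list(tensor = tens, sparse = sp, ranks = rk,
                        spatial_rank = sr, temporal_rank = tr,
                        decomposition = dec, networks = nets, empty = FALSE)
  }
  structure(list(fits = fits, interactions = interactions,
                 muscle_names = dataset$muscle_names,
                 n_muscles = dataset$n_muscles,
                 n_timepoints = dataset$n_timepoints,
                 n_participants = dataset$n_participants,
                 tasks = vapply(dataset$tasks, `[[`, "", "name"),
                 sparsify = sparsify, seed = seed,
                 call = match.call()),
            class = "nif")
}

#' @export
print.nif <- function(x, ...) {
  cat("Space-time muscle networks in the task space\n")
  cat(sprintf("  %d participant(s), %d muscles, %d timepoints, task(s): %s\n",
              x$n_participants, x$n_muscles, x$n_timepoints,
              paste(x$tasks, collapse = ", ")))
  for (cls in x$interactions) {
    f <- x$fits[[cls]]
    if (isTRUE(f$empty)) {
      cat(sprintf("  %-12s: no couplings survived sparsification\n", cls))
    } else {
      cat(sprintf(
        "  %-12s: %d spatial x %d temporal factors, rel. residual %.3f\n",
        cls, f$spatial_rank, f$temporal_rank,
        f$decomposition$rel_residual))
    }
  }
  invisible(x)
}

#' Summarise a fitted task-space model
#'
#' @param object a `nif` object.
#' @param ... unused.
#' @return a `summary.nif` with per-class ranks, residuals, retained
#'   densities and communicability summaries.
#' @export
summary.nif <- function(object, ...) {
  rows <- lapply(object$interactions, function(cls) {
    f <- object$fits[[cls]]
    data.frame(
      interaction = cls,
      spatial_rank = if (isTRUE(f$empty)) NA_integer_ else f$spatial_rank,
      temporal_rank = if (isTRUE(f$empty)) NA_integer_ else f$temporal_rank,
      rel_residual = if (isTRUE(f$empty)) NA_real_
                     else f$decomposition$rel_residual,
      retained = if (inherits(f$sparse, "sparse_coupling"))
        mean(f$sparse$mask) else 1,
      total_coupling = sum(f$tensor$values))
  })
  structure(list(table = do.call(rbind, rows), object = object),
            class = "summary.nif")
}

#' @export
print.summary.nif <- function(x, ...) {
  print(x$object)
  cat("\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Extract participant/task coefficients
#'
#' The coefficient arrays `S` (layers x temporal x spatial) scale the
#' information overlap carried by each spatial-temporal factor combination
#' per participant and task; they are not variance accounted for.
#'
#' @param object a `nif` object.
#' @param ... unused.
#' @return named list of coefficient arrays, one per interaction class.
#' @export
coef.nif <- function(object, ...) {
  out <- lapply(object$fits, function(f) {
    if (isTRUE(f$empty)) NULL else f$decomposition$S
  })
  out[!vapply(out, is.null, TRUE)]
}

#' Reconstruction residuals per interaction class
#'
#' @param object a `nif` object.
#' @param ... unused.
#' @return named numeric vector of Frobenius residuals.
#' @export
residuals.nif <- function(object, ...) {
  vapply(object$fits, function(f) {
    if (isTRUE(f$empty)) 0 else f$decomposition$residual
  }, 0)
}

#' Reconstructed coupling tensors from the fitted factors
#'
#' @param object a `nif` object.
#' @param ... unused.
#' @return named list of arrays, one per interaction class.
#' @export
fitted.nif <- function(object, ...) {
  out <- lapply(object$fits, function(f) {
    if (isTRUE(f$empty)) NULL else reconstruct(f$decomposition)
  })
  out[!vapply(out, is.null, TRUE)]
}

#' Plot temporal factors and spatial factor networks
#'
#' One row per interaction class: temporal factor time courses (left) and a
#' heat map of the spatial factor loadings over muscle pairs (right).
#'
#' @param x a `nif` object.
#' @param ... unused.
#' @return invisibly, `x`.
#' @export
plot.nif <- function(x, ...) {
  live <- Filter(function(f) !isTRUE(f$empty), x$fits)
  if (!length(live)) {
    warning("nothing to plot: all classes empty")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(length(live), 2L), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (cls in names(live)) {
    dec <- live[[cls]]$decomposition
    graphics::matplot(t(dec$W), type = "l", lty = 1, lwd = 2,
                      xlab = "timepoint pair", ylab = "temporal factor",
                      main = paste(cls, "temporal"))
    graphics::image(t(dec$V), axes = FALSE, col = grDevices::hcl.colors(32),
                    xlab = "muscle pair", ylab = "spatial factor",
                    main = paste(cls, "spatial"))
  }
  invisible(x)
}
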