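# Generalisability of extracted space-time networks: leave-one-out and
# random-ablation similarity protocols with Fisher-Z aggregation.

.safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b)
}

# greedy maximum-correlation assignment of test factor rows to ref rows
.match_corr <- function(ref, test) {
  stopifnot(nrow(ref) == nrow(test))
  R <- nrow(ref)
  cm <- matrix(0, R, R)
  for (a in seq_len(R)) {
    for (b in seq_len(R)) cm[a, b] <- .safe_cor(ref[a, ], test[b, ])
  }
  out <- numeric(R)
  pairing <- integer(R)
  avail_r <- rep(TRUE, R); avail_t <- rep(TRUE, R)
  for (k in seq_len(R)) {
    sub <- cm
    sub[!avail_r, ] <- -Inf
    sub[, !avail_t] <- -Inf
    ij <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
    out[ij[1L]] <- cm[ij[1L], ij[2L]]
    pairing[ij[1L]] <- ij[2L]
    avail_r[ij[1L]] <- FALSE
    avail_t[ij[2L]] <- FALSE
  }
  list(r = out, pairing = pairing)
}

#' Match factors between two decompositions and correlate them
#'
#' Factors are matched by greedy maximum-correlation assignment (each
#' reference factor to its best unmatched test factor) before computing the
#' per-pair Pearson correlation; invariant to factor permutation and
#' positive rescaling.
#'
#' @param ref,test `snm3f` or `cp_decomp` objects with equal ranks and
#'   dimensions (or plain factor matrices, factors in rows).
#' @param orientation `"spatial"`, `"temporal"`, or `"both"` (objects only).
#' @return for matrices, a list with `r` and `pairing`; for decompositions,
#'   a data.frame with columns `orientation`, `factor`, `r`.
#' @export
match_and_correlate <- function(ref, test,
                                orientation = c("both", "spatial",
                                                "temporal")) {
  orientation <- match.arg(orientation)
  if (is.matrix(ref)) {
    if (!is.matrix(test) || !all(dim(ref) == dim(test))) {
      stop("factor matrices must have identical dimensions", call. = FALSE)
    }
    return(.match_corr(ref, test))
  }
  get_fac <- function(obj, what) {
    m <- obj[[what]]
    if (is.null(m)) stop("object lacks ", what, " factors", call. = FALSE)
    m
  }
  rows <- list()
  for (ori in if (orientation == "both") c("spatial", "temporal")
       else orientation) {
    what <- if (ori == "spatial") "V" else "W"
    rm_ <- get_fac(ref, what); tm_ <- get_fac(test, what)
    if (nrow(rm_) != nrow(tm_)) stop("rank mismatch between decompositions",
                                     call. = FALSE)
    if (ncol(rm_) != ncol(tm_)) stop("dimension mismatch between ",
                                     "decompositions", call. = FALSE)
    mc <- .match_corr(rm_, tm_)
    rows[[ori]] <- data.frame(orientation = ori,
                              factor = seq_along(mc$r), r = mc$r)
  }
  do.call(rbind, rows)
}

#' Fisher-Z summary of correlation coefficients
#'
#' Correlations are transformed with `atanh`, averaged (and their standard
#' deviation taken) on the Z scale, and transformed back with `tanh`.
#' Values at exactly +/-1 are clipped with a warning. The Z-scale summaries
#' are reported alongside, since a back-transformed sd is not itself a
#' correlation bound.
#'
#' @param rs numeric vector of correlations in `[-1, 1]`.
#' @return list with `mean_r`, `sd_r`, `z_mean`, `z_sd`, `n`.
#' @export
fisher_summary <- function(rs) {
  if (length(rs) == 0L) stop("empty correlation list", call. = FALSE)
  if (any(abs(rs) > 1)) stop("correlations must lie in [-1, 1]",
                             call. = FALSE)
  if (any(abs(rs) == 1)) {
    warning("correlations at +/-1 clipped for the Z transform")
    rs <- pmin(pmax(rs, -(1 - 1e-10)), 1 - 1e-10)
  }
  z <- atanh(rs)
  zsd <- if (length(z) > 1L) sd(z) else 0
  list(mean_r = tanh(mean(z)), sd_r = tanh(zsd),
       z_mean = mean(z), z_sd = zsd, n = length(rs))
}

.similarity_report <- function(rows, protocol, seed = NULL) {
  summ <- lapply(split(rows$r, rows$orientation), fisher_summary)
  structure(list(comparisons = rows, protocol = protocol,
                 summary = summ, n_iterations = length(unique(rows$unit)),
                 seed = seed),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("<similarity_report (%s): %d comparison unit(s)>\n",
              x$protocol, x$n_iterations))
  for (ori in names(x$summary)) {
    s <- x$summary[[ori]]
    cat(sprintf("  %s: mean r = %.3f (sd %.3f, n = %d)\n", ori, s$mean_r,
                s$sd_r, s$n))
  }
  invisible(x)
}

#' Leave-one-out generalisability of the space-time decomposition
#'
#' Removes one participant (or one task variable) at a time, re-runs the
#' coupling + decomposition pipeline on the reduced dataset, and correlates
#' the matched spatial and temporal factors with those from the full
#' dataset.
#'
#' @param dataset an [emg_dataset()] with at least 2 units along `axis`.
#' @param axis `"participant"` or `"task"`.
#' @param spatial_rank,temporal_rank model ranks for the decomposition.
#' @param interaction coupling class to analyse.
#' @param sparsify apply dual-domain percolation before decomposition.
#' @param n_random null networks per percolation layer.
#' @param seed RNG seed.
#' @param ... further arguments to [snm3f_fit()].
#' @return a `similarity_report` with one comparison per held-out unit.
#' @export
leave_n_out <- function(dataset, axis = c("participant", "task"),
                        spatial_rank, temporal_rank,
                        interaction = "redundant", sparsify = FALSE,
                        n_random = 100, seed = NULL, ...) {
  axis <- match.arg(axis)
  stopifnot(inherits(dataset, "emg_dataset"))
  n_units <- if (axis == "participant") dataset$n_participants
             else length(dataset$tasks)
  if (n_units < 2L) stop("need >= 2 units along '", axis, "' to hold out",
                         call. = FALSE)
  fit_one <- function(ds, k) {
    tens <- build_tensor(ds, interaction)
    if (sparsify) tens <- sparsify_dual_domain(tens, n_random,
                                               seed = .child_seed(seed,
                                                                  100L + k))
    # common fitting seed: a held-out unit that leaves the coupling values
    # unchanged (e.g. a duplicated participant) reproduces the reference
    snm3f_fit(tens, spatial_rank, temporal_rank,
              seed = .child_seed(seed, 200L), ...)
  }
  full <- fit_one(dataset, 0L)
  rows <- list()
  for (u in seq_len(n_units)) {
    ds <- if (axis == "participant") {
      emg_dataset(dataset$emg[-u],
                  lapply(dataset$tasks, function(tv) {
                    tv$values <- tv$values[-u]
                    tv
                  }),
                  dataset$muscle_names)
    } else {
      emg_dataset(dataset$emg, dataset$tasks[-u], dataset$muscle_names)
    }
    cmp <- match_and_correlate(full, fit_one(ds, u))
    cmp$unit <- u
    rows[[u]] <- cmp
  }
  .similarity_report(do.call(rbind, rows),
                     paste0("leave_one_", axis), seed)
}

#' Random-ablation generalisability protocol
#'
#' Per iteration, a uniformly sized random subset (1 to `T - 1`) of
#' timepoint-pair columns is removed from every layer of the input tensor,
#' the decomposition is re-extracted on the reduced tensor, factors are
#' matched to the reference fit on the full tensor, and Pearson
#' correlations are recorded (temporal factors compared on the surviving
#' columns). Summaries use the Fisher-Z transform.
#'
#' @param A input tensor (array, list of layer matrices, or
#'   `coupling_tensor`).
#' @param spatial_rank,temporal_rank model ranks.
#' @param method `"snm3f"` or `"cp"` (CP uses `spatial_rank` components).
#' @param n_iterations number of ablation iterations (default 50).
#' @param ablate_fraction optional fixed fraction of columns to remove
#'   (0 reproduces the reference exactly); default random sizes.
#' @param seed RNG seed; same seed reproduces the report.
#' @param ... further arguments to the fitter.
#' @return a `similarity_report` with one unit per iteration.
#' @export
random_ablation <- function(A, spatial_rank, temporal_rank,
                            method = c("snm3f", "cp"), n_iterations = 50,
                            ablate_fraction = NULL, seed = NULL, ...) {
  method <- match.arg(method)
  layers <- .as_layer_list(A)
  TT <- ncol(layers[[1L]])
  if (n_iterations < 1L) stop("n_iterations must be >= 1", call. = FALSE)
  fit <- function(ls, sd_) {
    if (method == "snm3f") {
      f <- snm3f_fit(ls, spatial_rank, temporal_rank, seed = sd_, ...)
      list(V = f$V, W = f$W)
    } else {
      f <- cp_fit(ls, spatial_rank, seed = sd_, ...)
      list(V = f$V, W = f$W)
    }
  }
  full <- fit(layers, .child_seed(seed, 1L))
  # the reduced tensor must keep at least temporal_rank columns so the
  # re-extraction stays defined
  kmax <- max(1L, TT - max(1L, temporal_rank))
  drops <- .with_seed(seed, function() {
    lapply(seq_len(n_iterations), function(i) {
      k <- if (!is.null(ablate_fraction)) round(ablate_fraction * TT)
           else sample.int(kmax, 1L)
      k <- min(k, kmax)
      if (k == 0L) integer(0) else sort(sample.int(TT, k))
    })
  })
  rows <- list()
  for (i in seq_len(n_iterations)) {
    drop <- drops[[i]]
    keep <- setdiff(seq_len(TT), drop)
    red <- lapply(layers, function(Al) Al[, keep, drop = FALSE])
    # same fitting seed as the reference: an empty ablation reproduces the
    # reference decomposition exactly
    f <- fit(red, .child_seed(seed, 1L))
    r_sp <- .match_corr(full$V, f$V)$r
    r_tm <- .match_corr(full$W[, keep, drop = FALSE], f$W)$r
    rows[[i]] <- data.frame(
      orientation = rep(c("spatial", "temporal"),
                        c(length(r_sp), length(r_tm))),
      factor = c(seq_along(r_sp), seq_along(r_tm)),
      r = c(r_sp, r_tm), unit = i)
  }
  rep_ <- .similarity_report(do.call(rbind, rows), "random_ablation", seed)
  rep_$n_iterations <- n_iterations
  rep_
}
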