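# Assembly of the multiplex coupling tensor: all muscle pairs x timepoint
# pairs x (task variable x participant) layers, for each interaction class.

#' Construct a task variable
#'
#' @param name identifier, e.g. `"direction"` or `"heel_y"`.
#' @param values for a discrete variable, a per-trial factor (or list of
#'   factors, one per participant); for a continuous variable, a
#'   `trials x timepoints` matrix (or list of matrices) aligned with the
#'   envelope time base.
#' @param kind `"discrete"` or `"continuous"`; inferred from `values` when
#'   missing.
#' @return a `task_variable` object whose `$values` is a per-participant list.
#' @export
task_variable <- function(name, values, kind = NULL) {
  if (!is.list(values)) values <- list(values)
  first <- values[[1L]]
  if (is.null(kind)) {
    kind <- if (is.factor(first) || is.character(first) ||
                is.logical(first)) "discrete" else "continuous"
  }
  kind <- match.arg(kind, c("discrete", "continuous"))
  values <- lapply(values, function(v) {
    if (kind == "discrete") {
      v <- as.factor(v)
      if (nlevels(droplevels(v)) < 2L || min(table(droplevels(v))) < 2L) {
        stop("discrete task variable '", name,
             "' needs >= 2 classes with >= 2 trials each", call. = FALSE)
      }
      droplevels(v)
    } else {
      as.matrix(v)
    }
  })
  structure(list(name = name, kind = kind, values = values),
            class = "task_variable")
}

#' @export
print.task_variable <- function(x, ...) {
  cat(sprintf("<task_variable '%s' (%s), %d participant(s)>\n",
              x$name, x$kind, length(x$values)))
  invisible(x)
}

#' Bundle EMG envelopes and task variables into an analysis dataset
#'
#' @param emg list of envelope arrays (`trials x muscles x timepoints`), one
#'   per participant, or a single array / `processed_emg`.
#' @param tasks a `task_variable` or list of task variables, each with one
#'   entry per participant.
#' @param muscle_names optional muscle labels.
#' @return an `emg_dataset` object.
#' @export
emg_dataset <- function(emg, tasks, muscle_names = NULL) {
  if (!is.list(emg) || is.array(emg)) emg <- list(emg)
  emg <- lapply(emg, function(e) {
    e <- unclass(e)
    stopifnot(is.array(e), length(dim(e)) == 3L)
    e
  })
  if (inherits(tasks, "task_variable")) tasks <- list(tasks)
  M <- dim(emg[[1L]])[2L]; TT <- dim(emg[[1L]])[3L]
  for (e in emg) stopifnot(dim(e)[2L] == M, dim(e)[3L] == TT)
  for (tv in tasks) {
    if (length(tv$values) != length(emg)) {
      stop("task variable '", tv$name, "' must have one entry per participant",
           call. = FALSE)
    }
    for (p in seq_along(emg)) {
      nt <- dim(emg[[p]])[1L]
      len <- if (tv$kind == "discrete") length(tv$values[[p]])
             else nrow(tv$values[[p]])
      if (len != nt) stop("task variable '", tv$name,
                          "' not aligned with trials of participant ", p,
                          call. = FALSE)
      if (tv$kind == "continuous" && ncol(tv$values[[p]]) != TT) {
        stop("continuous task variable '", tv$name,
             "' not aligned with the envelope time base", call. = FALSE)
      }
    }
  }
  if (is.null(muscle_names)) {
    muscle_names <- dimnames(emg[[1L]])[[2L]]
    if (is.null(muscle_names)) muscle_names <- paste0("m", seq_len(M))
  }
  structure(list(emg = emg, tasks = tasks, muscle_names = muscle_names,
                 n_participants = length(emg), n_muscles = M,
                 n_timepoints = TT),
            class = "emg_dataset")
}

#' @export
print.emg_dataset <- function(x, ...) {
  cat(sprintf(paste0("<emg_dataset: %d participant(s), %d muscles, ",
                     "%d timepoints, %d task variable(s)>\n"),
              x$n_participants, x$n_muscles, x$n_timepoints, length(x$tasks)))
  invisible(x)
}

#' Enumerate unordered index pairs
#'
#' Muscle pairs exclude self-pairs; timepoint pairs include the diagonal
#' (temporally proximal dependencies live there).
#'
#' @param n number of items (>= 2).
#' @param include_diagonal include `(i, i)` pairs.
#' @return two-column integer matrix of pairs `(i, j)` with `i <= j`.
#' @export
enumerate_pairs <- function(n, include_diagonal = FALSE) {
  if (n < 2L) stop("need at least 2 items to form pairs", call. = FALSE)
  idx <- which(upper.tri(matrix(0, n, n), diag = include_diagonal),
               arr.ind = TRUE)
  out <- cbind(i = idx[, 1L], j = idx[, 2L])[order(idx[, 1L], idx[, 2L]), ,
                                             drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- vectorised pairwise information on copula-normalised columns -----------

# corrected pairwise bivariate Gaussian entropies (nats) from covariance
.h2_mat_nats <- function(C, n) {
  v <- diag(C)
  d2 <- outer(v, v) - C^2
  d2[d2 < .Machine$double.eps] <- NA
  0.5 * log(d2) + log(2 * pi * exp(1)) - .ent_bias_nats(n, 2L)
}

.h1_vec_nats <- function(C, n) {
  0.5 * log(diag(C)) + 0.5 * log(2 * pi * exp(1)) - .ent_bias_nats(n, 1L)
}

# corrected pairwise MI matrix (nats) from covariance of copnormed columns
.pair_mi_mat_nats <- function(C, n) {
  h1 <- .h1_vec_nats(C, n)
  outer(h1, h1, `+`) - .h2_mat_nats(C, n)
}

# per-layer pairwise information for one participant x one task variable.
# Z: trials x (M*T) envelope matrix, column (m, t) at index (t-1)*M + m.
# Returns column-pair matrices (nats): cmi, coi (plus components).
.layer_info <- function(Z, tau, kind, M, TT, tau_pairing = "own") {
  n <- nrow(Z)
  const <- apply(Z, 2L, function(col) max(col) == min(col))
  Zs <- Z
  # deterministic inert placeholder for degenerate columns; entries touching
  # them are zeroed below
  Zs[, const] <- seq_len(n)
  Zc <- .copnorm_mat(Zs)
  P <- ncol(Zc)
  C <- cov(Zc)
  if (kind == "discrete") {
    tau <- as.factor(tau)
    lev <- levels(tau)
    pk <- as.numeric(table(tau)) / n
    cmi_m <- matrix(0, P, P)
    h1_mix <- .h1_vec_nats(C, n)
    h2_mix <- .h2_mat_nats(C, n)
    for (ki in seq_along(lev)) {
      idx <- tau == lev[ki]
      nk <- sum(idx)
      Zk_cw <- .copnorm_mat(Zs[idx, , drop = FALSE]) # class-wise ranks
      cmi_m <- cmi_m + pk[ki] * .pair_mi_mat_nats(cov(Zk_cw), nk)
      Ck <- cov(Zc[idx, , drop = FALSE])             # mixture components
      h1_mix <- h1_mix - pk[ki] * .h1_vec_nats(Ck, nk)
      h2_mix <- h2_mix - pk[ki] * .h2_mat_nats(Ck, nk)
    }
    coi_m <- h2_mix - outer(h1_mix, h1_mix, `+`)
    mi_tau <- h1_mix
  } else {
    # continuous tau: trials x T matrix, copnormed per timepoint
    Tc <- .copnorm_mat(tau)
    col_t <- rep(seq_len(TT), each = M)
    A <- cbind(Zc, Tc)
    CA <- cov(A)
    ld <- function(cols) determinant(CA[cols, cols, drop = FALSE],
                                     logarithm = TRUE)$modulus[1L]
    hg <- function(cols) 0.5 * ld(cols) +
      0.5 * length(cols) * log(2 * pi * exp(1)) -
      .ent_bias_nats(n, length(cols))
    mi_tau <- vapply(seq_len(P), function(a) {
      z <- P + col_t[a]
      hg(a) + hg(z) - hg(c(a, z))
    }, numeric(1))
    cmi_m <- matrix(NA_real_, P, P)
    coi_m <- matrix(NA_real_, P, P)
    for (a in seq_len(P - 1L)) {
      for (b in (a + 1L):P) {
        if (tau_pairing == "mean" && col_t[a] != col_t[b]) {
          # condition on the task series averaged over the two timepoints
          zc <- .copnorm_mat((tau[, col_t[a]] + tau[, col_t[b]]) / 2)
          xa <- Zc[, a]; xb <- Zc[, b]
          cmi_m[a, b] <- .cmi_ggg_nats(xa, xb, zc)
          joint <- .mi_gg_nats(cbind(xa, xb), zc)
          coi_m[a, b] <- joint - .mi_gg_nats(xa, zc) - .mi_gg_nats(xb, zc)
        } else {
          z <- P + unique(c(col_t[a], col_t[b]))
          # near-collinear task columns (smooth trajectories) make the
          # conditional entropies numerically unstable; fall back to one
          if (length(z) == 2L &&
                abs(CA[z[1L], z[2L]] /
                      sqrt(CA[z[1L], z[1L]] * CA[z[2L], z[2L]])) > 0.95) {
            z <- z[1L]
          }
          cmi_m[a, b] <- hg(c(a, z)) + hg(c(b, z)) - hg(z) - hg(c(a, b, z))
          joint <- hg(c(a, b)) + hg(z) - hg(c(a, b, z))
          # marginal MIs against the same task target as the joint term
          ix <- hg(a) + hg(z) - hg(c(a, z))
          iy <- hg(b) + hg(z) - hg(c(b, z))
          coi_m[a, b] <- joint - ix - iy
        }
        cmi_m[b, a] <- cmi_m[a, b]
        coi_m[b, a] <- coi_m[a, b]
      }
    }
  }
  # couplings with a degenerate (constant) column carry no information
  if (any(const)) {
    cmi_m[const, ] <- 0; cmi_m[, const] <- 0
    coi_m[const, ] <- 0; coi_m[, const] <- 0
  }
  list(cmi = cmi_m, coi = coi_m)
}

#' Build multiplex coupling tensors over muscle pairs and timepoint pairs
#'
#' For every unordered muscle pair, timepoint pair and layer (task variable
#' x participant), estimates the task-irrelevant coupling (conditional MI
#' given the task variable) and the signed co-information, and rectifies the
#' latter into task-redundant and task-synergistic halves. For a timepoint
#' pair (t1, t2), t1 != t2, the two orderings of the muscles over the
#' timepoints are averaged into one cell.
#'
#' @param dataset an [emg_dataset()].
#' @param interaction which tensors to return: one class, or `"all"`.
#' @param tau_pairing for a continuous task variable and a timepoint pair
#'   (t1, t2): `"own"` conditions on the task values at both members' own
#'   timepoints jointly; `"mean"` on the series averaged over the two.
#' @return for `"all"`, a list with `coupling_tensor` objects `irrelevant`,
#'   `redundant`, `synergistic` and the signed `coi`; otherwise the single
#'   requested `coupling_tensor`.
#' @export
build_tensor <- function(dataset,
                         interaction = c("all", "irrelevant", "redundant",
                                         "synergistic"),
                         tau_pairing = c("own", "mean")) {
  interaction <- match.arg(interaction)
  tau_pairing <- match.arg(tau_pairing)
  stopifnot(inherits(dataset, "emg_dataset"))
  M <- dataset$n_muscles; TT <- dataset$n_timepoints
  if (M < 2L || TT < 2L) stop("need >= 2 muscles and >= 2 timepoints",
                              call. = FALSE)
  mp <- enumerate_pairs(M, include_diagonal = FALSE)
  tp <- enumerate_pairs(TT, include_diagonal = TRUE)
  layers <- expand.grid(participant = seq_len(dataset$n_participants),
                        task = vapply(dataset$tasks, `[[`, "", "name"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # row-major in (task, participant): task varies slowest
  layers <- layers[, c("task", "participant")]
  layers$n_trials <- vapply(dataset$emg, function(e) dim(e)[1L],
                            0L)[layers$participant]
  rownames(layers) <- NULL
  nL <- nrow(layers)
  cmi_t <- array(0, dim = c(nrow(mp), nrow(tp), nL))
  coi_t <- array(0, dim = c(nrow(mp), nrow(tp), nL))
  col_of <- function(m, t) (t - 1L) * M + m
  li <- 0L
  for (tv in dataset$tasks) {
    for (p in seq_len(dataset$n_participants)) {
      li <- li + 1L
      e <- dataset$emg[[p]]
      Z <- matrix(e, nrow = dim(e)[1L]) # column (m, t) at (t-1)*M + m
      info <- .layer_info(Z, tv$values[[p]], tv$kind, M, TT, tau_pairing)
      for (ti in seq_len(nrow(tp))) {
        t1 <- tp[ti, 1L]; t2 <- tp[ti, 2L]
        a1 <- col_of(mp[, 1L], t1); b1 <- col_of(mp[, 2L], t2)
        v_cmi <- info$cmi[cbind(a1, b1)]
        v_coi <- info$coi[cbind(a1, b1)]
        if (t1 != t2) {
          a2 <- col_of(mp[, 1L], t2); b2 <- col_of(mp[, 2L], t1)
          v_cmi <- (v_cmi + info$cmi[cbind(a2, b2)]) / 2
          v_coi <- (v_coi + info$coi[cbind(a2, b2)]) / 2
        }
        cmi_t[, ti, li] <- v_cmi
        coi_t[, ti, li] <- v_coi
      }
    }
  }
  cmi_t <- cmi_t / log(2) # bits
  coi_t <- coi_t / log(2) # bits, signed
  cmi_t[cmi_t < 0] <- 0   # MI/CMI clipped at zero
  red_t <- -coi_t; red_t[red_t < 0] <- 0
  syn_t <- coi_t; syn_t[syn_t < 0] <- 0
  mk <- function(values, class) {
    structure(list(values = values, muscle_pairs = mp, time_pairs = tp,
                   layers = layers, interaction = class,
                   n_muscles = M, n_timepoints = TT,
                   muscle_names = dataset$muscle_names),
              class = "coupling_tensor")
  }
  out <- list(irrelevant = mk(cmi_t, "irrelevant"),
              redundant = mk(red_t, "redundant"),
              synergistic = mk(syn_t, "synergistic"),
              coi = mk(coi_t, "coi"))
  if (interaction == "all") out else out[[interaction]]
}

#' @export
print.coupling_tensor <- function(x, ...) {
  cat(sprintf(paste0("<coupling_tensor (%s): %d muscle pairs x %d timepoint",
                     " pairs x %d layers>\n"), x$interaction,
              nrow(x$muscle_pairs), nrow(x$time_pairs), nrow(x$layers)))
  invisible(x)
}

# ---- layer views ------------------------------------------------------------

#' View a coupling tensor as stacks of symmetric adjacency matrices
#'
#' `"spatial"` returns muscle-by-muscle matrices, one per (timepoint pair,
#' layer); `"temporal"` returns timepoint-by-timepoint matrices, one per
#' (muscle pair, layer). The view round-trips losslessly to the parent
#' tensor via [layers_to_tensor()].
#'
#' @param tensor a `coupling_tensor`.
#' @param orientation `"spatial"` or `"temporal"`.
#' @return a `layer_view`: array `n x n x n_slices` plus slice bookkeeping.
#' @export
as_layers <- function(tensor, orientation = c("spatial", "temporal")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(tensor, "coupling_tensor"))
  nL <- nrow(tensor$layers)
  if (orientation == "spatial") {
    n <- tensor$n_muscles
    pairs <- tensor$muscle_pairs
    n_slices <- nrow(tensor$time_pairs) * nL
    slice_index <- expand.grid(unit = seq_len(nrow(tensor$time_pairs)),
                               layer = seq_len(nL))
    get_vals <- function(u, l) tensor$values[, u, l]
  } else {
    n <- tensor$n_timepoints
    pairs <- tensor$time_pairs
    n_slices <- nrow(tensor$muscle_pairs) * nL
    slice_index <- expand.grid(unit = seq_len(nrow(tensor$muscle_pairs)),
                               layer = seq_len(nL))
    get_vals <- function(u, l) tensor$values[u, , l]
  }
  mats <- array(0, dim = c(n, n, n_slices))
  for (s in seq_len(n_slices)) {
    v <- get_vals(slice_index$unit[s], slice_index$layer[s])
    A <- matrix(0, n, n)
    A[cbind(pairs[, 1L], pairs[, 2L])] <- v
    A[cbind(pairs[, 2L], pairs[, 1L])] <- v
    mats[, , s] <- A
  }
  structure(list(matrices = mats, orientation = orientation,
                 slice_index = slice_index, pairs = pairs,
                 parent_dims = dim(tensor$values)),
            class = "layer_view")
}

#' Reassemble a coupling-tensor value array from a layer view
#'
#' @param view a `layer_view` from [as_layers()].
#' @return numeric array with the parent tensor's dimensions.
#' @export
layers_to_tensor <- function(view) {
  stopifnot(inherits(view, "layer_view"))
  vals <- array(0, dim = view$parent_dims)
  pairs <- view$pairs
  for (s in seq_len(dim(view$matrices)[3L])) {
    v <- view$matrices[, , s][cbind(pairs[, 1L], pairs[, 2L])]
    u <- view$slice_index$unit[s]; l <- view$slice_index$layer[s]
    if (view$orientation == "spatial") vals[, u, l] <- v else vals[u, , l] <- v
  }
  vals
}
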