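# Synthetic trial-structured EMG-like data with planted task-redundant,
# task-synergistic and task-irrelevant couplings, plus the canonical
# four-observation redundancy/synergy truth tables.

.default_planted <- function() {
  data.frame(
    i = c(1L, 4L, 3L, 7L),
    j = c(2L, 5L, 6L, 8L),
    class = c("redundant", "redundant", "synergistic", "irrelevant"),
    t_from = c(1L, 6L, 1L, 1L),
    t_to = c(5L, 10L, 5L, 10L),
    strength = 1,
    stringsAsFactors = FALSE)
}

#' Specify a synthetic planted-coupling dataset
#'
#' The defaults emulate a desk-scale reaching-style study: 5 participants,
#' 100 trials each, 9 muscles, a 10-point envelope, a binary discrete task
#' variable, and four planted couplings (two redundant pairs in
#' complementary time windows, one synergistic and one task-irrelevant
#' pair).
#'
#' @param n_participants,n_trials,n_muscles,n_timepoints dataset dimensions.
#' @param planted data.frame with columns `i`, `j` (muscle pair), `class`
#'   (`"redundant"`, `"synergistic"`, `"irrelevant"`), `t_from`, `t_to`
#'   (timepoint window) and `strength`; `NULL` plants nothing. A row with
#'   `i == j` drives that single muscle with the class latent (redundant:
#'   the task latent; irrelevant: a shared task-independent latent), so a
#'   set of such rows plants a graded all-to-all coupling among the driven
#'   muscles; not available for the synergistic class.
#' @param task `"discrete"` or `"continuous"`.
#' @param n_classes classes of a discrete task variable.
#' @param noise_sd standard deviation of the independent envelope noise.
#' @param seed mandatory RNG seed; the same spec is byte-identical.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_participants = 5, n_trials = 100,
                           n_muscles = 9, n_timepoints = 10,
                           planted = .default_planted(),
                           task = c("discrete", "continuous"),
                           n_classes = 2, noise_sd = 0.25, seed) {
  task <- match.arg(task)
  if (missing(seed)) stop("a seed is mandatory for synthetic data",
                          call. = FALSE)
  if (is.null(planted)) {
    planted <- .default_planted()[0, ]
  }
  if (nrow(planted) && is.null(planted$group)) planted$group <- 1L
  if (nrow(planted)) {
    key <- paste(pmin(planted$i, planted$j), pmax(planted$i, planted$j))
    if (anyDuplicated(key)) {
      stop("contradictory class assignment: a muscle pair is planted twice",
           call. = FALSE)
    }
    if (any(planted$i == planted$j & planted$class == "synergistic")) {
      stop("synergistic couplings are pairwise: i == j is not allowed",
           call. = FALSE)
    }
    if (task == "discrete" &&
          any(planted$group > n_classes - 1L & planted$class == "redundant")) {
      stop("redundant groups need independent task contrasts: ",
           "group id must be < n_classes", call. = FALSE)
    }
    if (task == "continuous" && any(planted$group != 1L)) {
      stop("latent groups are only available with a discrete task variable",
           call. = FALSE)
    }
    if (any(planted$i > n_muscles | planted$j > n_muscles |
              planted$t_to > n_timepoints | planted$t_from < 1L)) {
      stop("planted couplings out of bounds", call. = FALSE)
    }
    if (any(planted$strength < 0)) stop("strength must be >= 0",
                                        call. = FALSE)
  }
  structure(list(n_participants = n_participants, n_trials = n_trials,
                 n_muscles = n_muscles, n_timepoints = n_timepoints,
                 planted = planted, task = task, n_classes = n_classes,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

.softplus <- function(x) log1p(exp(x))

#' Generate a synthetic planted-coupling dataset
#'
#' Redundant pairs: both muscles are driven by the same task-determined
#' latent, so each carries the same task information. Synergistic pairs:
#' with a discrete task the two muscles take random signs whose product
#' encodes the (binary-reduced) class, and with a continuous task the task
#' series tracks the product of two independent latents, so the task is
#' decodable only jointly. Irrelevant pairs share a task-independent trial
#' latent. Envelope non-negativity is enforced with a softplus, which is
#' monotone and therefore invisible to the rank-based estimators.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `dataset` (an [emg_dataset()]), `emg` (per-participant
#'   envelope arrays), `tasks` (list of [task_variable()]), and
#'   `ground_truth` (the planted table).
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  M <- spec$n_muscles; TT <- spec$n_timepoints
  n <- spec$n_trials; k <- spec$n_classes
  out <- .with_seed(spec$seed, function() {
    emg <- vector("list", spec$n_participants)
    tau_vals <- vector("list", spec$n_participants)
    for (p in seq_len(spec$n_participants)) {
      x <- array(rnorm(n * M * TT, sd = spec$noise_sd), dim = c(n, M, TT))
      if (spec$task == "discrete") {
        cls <- sample(rep_len(seq_len(k), n))
        # orthogonal class contrasts give (near-)independent task latents,
        # one per planted group; group 1 is the graded class score
        ctr <- if (k > 2L) stats::contr.helmert(k) else
          matrix(seq(-1, 1, length.out = k), k, 1)
        ctr <- scale(ctr)
        mu_groups <- ctr[cls, , drop = FALSE]
        mu <- mu_groups[, 1L]
        tau_vals[[p]] <- factor(paste0("c", cls))
      } else {
        z <- rnorm(n)
        shape <- sin(pi * seq_len(TT) / (TT + 1))
        tau <- outer(z, shape) + matrix(rnorm(n * TT, sd = 0.1), n, TT)
        mu <- z
        tau_vals[[p]] <- tau
      }
      planted <- spec$planted
      if (nrow(planted) && is.null(planted$group)) planted$group <- 1L
      n_groups <- if (nrow(planted)) max(planted$group) else 1L
      zl_groups <- matrix(rnorm(n * n_groups), n, n_groups) # irrelevant latents
      if (nrow(planted)) {
        for (q in seq_len(nrow(planted))) {
          pl <- planted[q, ]
          tw <- pl$t_from:pl$t_to
          s <- pl$strength
          grp <- pl$group
          mu_g <- if (spec$task == "discrete") mu_groups[, min(grp, ncol(mu_groups))]
                  else mu
          if (pl$i == pl$j) {
            # per-muscle drive: couples the muscle to the group latent, so
            # all driven muscles become pairwise coupled with graded weights
            drv <- if (pl$class == "redundant") mu_g else zl_groups[, grp]
            for (t in tw) x[, pl$i, t] <- x[, pl$i, t] + s * drv
            next
          }
          if (pl$class == "redundant") {
            for (t in tw) {
              x[, pl$i, t] <- x[, pl$i, t] + s * mu_g
              x[, pl$j, t] <- x[, pl$j, t] + s * mu_g
            }
          } else if (pl$class == "synergistic") {
            if (spec$task == "discrete") {
              # sign-product (parity) coding: each muscle's sign is random,
              # their agreement encodes the binary-reduced class
              sa <- sample(c(-1, 1), n, replace = TRUE)
              cls_bin <- (as.integer(tau_vals[[p]]) - 1L) %% 2L
              sb <- sa * (2 * cls_bin - 1)
            } else {
              # differential coding: the task tracks the difference of the
              # two muscles, masked marginally by a strong shared latent
              u <- rnorm(n, sd = 1.5)
              d <- rnorm(n)
              sa <- u + d / 2
              sb <- u - d / 2
              shape2 <- cos(pi * seq_len(TT) / (TT + 1))
              tau_vals[[p]] <- tau_vals[[p]] + outer(d, shape2)
            }
            for (t in tw) {
              x[, pl$i, t] <- x[, pl$i, t] + s * sa
              x[, pl$j, t] <- x[, pl$j, t] + s * sb
            }
          } else { # irrelevant: shared latent independent of the task
            zl <- rnorm(n)
            for (t in tw) {
              x[, pl$i, t] <- x[, pl$i, t] + s * zl
              x[, pl$j, t] <- x[, pl$j, t] + s * zl
            }
          }
        }
      }
      emg[[p]] <- .softplus(x)
    }
    list(emg = emg, tau_vals = tau_vals)
  })
  tv <- task_variable(if (spec$task == "discrete") "condition" else "trajectory",
                      out$tau_vals, kind = spec$task)
  ds <- emg_dataset(out$emg, list(tv))
  gt <- spec$planted
  if (nrow(gt) && is.null(gt$group)) gt$group <- 1L
  list(dataset = ds, emg = out$emg, tasks = list(tv), ground_truth = gt)
}

#' Four-observation redundancy and synergy truth tables
#'
#' The canonical worked examples of informational redundancy and synergy
#' for a muscle pair with equiprobable on/off states and a left/right task
#' variable. In the redundancy table the task is L exactly when `mx` is on
#' (and `my` off), so either muscle alone yields the full bit; in the
#' synergy table the task is L exactly when `mx` and `my` agree, so neither
#' muscle alone is predictive but the pair yields the full bit.
#'
#' @return list of two data.frames, `redundancy` and `synergy`, with
#'   columns `mx`, `my` (0/1) and `tau` (`"L"`/`"R"`).
#' @export
figure2_tables <- function() {
  list(
    redundancy = data.frame(mx = c(1, 1, 0, 0), my = c(0, 0, 1, 1),
                            tau = c("L", "L", "R", "R"),
                            stringsAsFactors = FALSE),
    synergy = data.frame(mx = c(1, 1, 0, 0), my = c(1, 0, 1, 0),
                         tau = c("L", "R", "R", "L"),
                         stringsAsFactors = FALSE))
}

#' Score recovery of planted couplings
#'
#' Precision and recall of the retained tensor entries against the planted
#' set: a tensor entry (muscle pair, timepoint pair, layer) is a planted
#' positive when its muscle pair is planted with the matching interaction
#' class and both timepoints fall inside the planted window.
#'
#' @param ground_truth planted table from [generate()].
#' @param sparse a `sparse_coupling` (or named list of them per class).
#' @return data.frame with `class`, `precision`, `recall`, counts.
#' @export
score_recovery <- function(ground_truth, sparse) {
  if (inherits(sparse, "sparse_coupling")) {
    sparse <- setNames(list(sparse), sparse$interaction)
  }
  rows <- lapply(names(sparse), function(cls) {
    sp <- sparse[[cls]]
    mp <- sp$muscle_pairs; tp <- sp$time_pairs
    gt <- ground_truth[ground_truth$class == cls, , drop = FALSE]
    # per-muscle drives (i == j) imply pairwise couplings between all driven
    # muscles over their overlapping windows
    if (is.null(gt$group)) gt$group <- 1L
    drv <- gt[gt$i == gt$j, , drop = FALSE]
    gt <- gt[gt$i != gt$j, , drop = FALSE]
    if (nrow(drv) > 1L) {
      for (a in seq_len(nrow(drv) - 1L)) {
        for (b in (a + 1L):nrow(drv)) {
          t0 <- max(drv$t_from[a], drv$t_from[b])
          t1 <- min(drv$t_to[a], drv$t_to[b])
          if (t0 <= t1 && drv$i[a] != drv$i[b] &&
                drv$group[a] == drv$group[b]) {
            gt <- rbind(gt, data.frame(
              i = min(drv$i[a], drv$i[b]), j = max(drv$i[a], drv$i[b]),
              class = cls, t_from = t0, t_to = t1,
              strength = min(drv$strength[a], drv$strength[b]),
              group = drv$group[a]))
          }
        }
      }
    }
    planted <- array(FALSE, dim = dim(sp$mask))
    if (nrow(gt)) {
      for (q in seq_len(nrow(gt))) {
        mi <- which(mp[, 1L] == min(gt$i[q], gt$j[q]) &
                      mp[, 2L] == max(gt$i[q], gt$j[q]))
        ti <- which(tp[, 1L] >= gt$t_from[q] & tp[, 2L] <= gt$t_to[q])
        planted[mi, ti, ] <- TRUE
      }
    }
    n_ret <- sum(sp$mask)
    n_pl <- sum(planted)
    tp_ <- sum(sp$mask & planted)
    data.frame(class = cls,
               precision = if (n_ret > 0) tp_ / n_ret else NA_real_,
               recall = if (n_pl > 0) tp_ / n_pl else NA_real_,
               retained = n_ret, planted = n_pl)
  })
  do.call(rbind, rows)
}
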