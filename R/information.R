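#' @useDynLib taskspace, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cov qnorm rank sd var cor quantile rnorm runif setNames
NULL

# ---- validation helpers -----------------------------------------------------

.check_finite <- function(x, what = "input") {
  if (!is.numeric(x)) stop(what, " must be numeric", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) {
    stop(what, " contains NA or non-finite values", call. = FALSE)
  }
  invisible(x)
}

.min_trials_mi <- 8L # estimator guard for copula-based MI

# ---- copula normalisation ---------------------------------------------------

#' Copula-normalise a sample vector
#'
#' Maps a sample to standard-normal ranks \eqn{\Phi^{-1}(r_i/(n+1))}, the
#' empirical-copula transform underlying Gaussian-copula mutual information.
#' The output depends on the input only through its ranks, so it is invariant
#' under any strictly monotone transformation of the data.
#'
#' @param x numeric vector, length at least 2, finite values.
#' @param tie_policy how tied values are ranked; `"average"` (default) is
#'   deterministic and permutation-invariant.
#' @return numeric vector of standard-normal scores, same length as `x`.
#' @examples
#' copula_normalize(c(1, 2, 3)) # middle element is exactly 0
#' @export
copula_normalize <- function(x, tie_policy = c("average", "min", "max")) {
  tie_policy <- match.arg(tie_policy)
  .check_finite(x, "copula_normalize() input")
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (max(x) == min(x)) {
    stop("degenerate input: all samples identical", call. = FALSE)
  }
  qnorm(rank(x, ties.method = tie_policy) / (n + 1))
}

# column-wise copula normalisation of a matrix
.copnorm_mat <- function(X, tie_policy = "average") {
  X <- as.matrix(X)
  apply(X, 2L, function(col) qnorm(rank(col, ties.method = tie_policy) /
                                     (length(col) + 1)))
}

# ---- Gaussian entropy -------------------------------------------------------

# small-sample bias of a d-dimensional Gaussian entropy estimate (nats);
# subtracting it gives the psi-corrected estimator.
.ent_bias_nats <- function(n, d) {
  d * (log(2) - log(n - 1)) / 2 + sum(digamma((n - seq_len(d)) / 2)) / 2
}

# bias-corrected Gaussian entropy in nats from an n x d data matrix
.ent_g_nats <- function(X, bias_correct = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- ncol(X)
  if (n <= d + 1L) stop("need n > d + 1 samples for entropy estimation",
                        call. = FALSE)
  C <- cov(X)
  ch <- tryCatch(chol(C), error = function(e) {
    stop("degenerate input: singular covariance", call. = FALSE)
  })
  h <- sum(log(diag(ch))) + 0.5 * d * log(2 * pi * exp(1))
  if (bias_correct) h <- h - .ent_bias_nats(n, d)
  h
}

#' Bias-corrected Gaussian entropy in bits
#'
#' Entropy of a multivariate Gaussian fitted to the data, with the standard
#' psi-function small-sample correction. Translation invariant; scaling a
#' univariate input by `a` adds `log2(|a|)` bits.
#'
#' @param x numeric vector or `n x d` matrix (rows are samples).
#' @param bias_correct apply the psi-function small-sample correction.
#' @return entropy in bits.
#' @export
gaussian_entropy_bits <- function(x, bias_correct = TRUE) {
  x <- as.matrix(x)
  .check_finite(x, "gaussian_entropy_bits() input")
  .ent_g_nats(x, bias_correct) / log(2)
}

# ---- information estimate container ----------------------------------------

#' @export
print.info_estimate <- function(x, ...) {
  cat(sprintf("<%s estimate (%s): %.4f bits>\n", x$kind, x$estimator, x$value))
  invisible(x)
}

#' @export
as.double.info_estimate <- function(x, ...) x$value

.info_estimate <- function(value, estimator, kind, components = NULL) {
  structure(list(value = value, estimator = estimator, kind = kind,
                 components = components),
            class = "info_estimate")
}

# ---- GCMI between continuous vectors ---------------------------------------

# MI in nats between copula-normalised column blocks; x, y matrices n x dx/dy
.mi_gg_nats <- function(x, y, bias_correct = TRUE) {
  x <- as.matrix(x); y <- as.matrix(y)
  .ent_g_nats(x, bias_correct) + .ent_g_nats(y, bias_correct) -
    .ent_g_nats(cbind(x, y), bias_correct)
}

#' Gaussian-copula mutual information between muscle trial vectors
#'
#' Estimates MI in bits between two continuous variables (or variable blocks)
#' as the negative entropy of the empirical Gaussian copula: margins are
#' rank-normalised to standard normal and MI is computed from bias-corrected
#' Gaussian entropies. Negative bias-corrected estimates are clipped to zero.
#'
#' @param x,y numeric vectors (or matrices with trials in rows) of equal
#'   length; at least 8 trials.
#' @param clip clip negative bias-corrected estimates at 0 (default).
#' @return an `info_estimate` with the MI in bits.
#' @examples
#' set.seed(1)
#' z <- rnorm(200)
#' mi_gc(z + rnorm(200, sd = 0.5), z + rnorm(200, sd = 0.5))
#' @export
mi_gc <- function(x, y, clip = TRUE) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y must have the same number of trials",
                               call. = FALSE)
  if (nrow(x) < .min_trials_mi) {
    stop("need at least ", .min_trials_mi, " trials for copula estimation",
         call. = FALSE)
  }
  cx <- .copnorm_mat(x)
  cy <- .copnorm_mat(y)
  v <- .mi_gg_nats(cx, cy) / log(2)
  .info_estimate(if (clip) max(0, v) else v, "gcmi", "MI")
}

# ---- Gaussian-mixture MI with a discrete task variable ----------------------

.check_classes <- function(tau, d, n_min_extra = 2L) {
  tau <- as.factor(tau)
  cnt <- table(tau)
  if (length(cnt) < 2L) stop("discrete task variable needs >= 2 classes",
                             call. = FALSE)
  bad <- names(cnt)[cnt < d + n_min_extra]
  if (length(bad)) {
    stop("degenerate class(es) with too few trials: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tau
}

# model-based MI (nats) between continuous block x and discrete tau:
# overall Gaussian entropy minus class-weighted conditional entropies,
# on copula-normalised data.
.mi_model_gd_nats <- function(cx, tau, bias_correct = TRUE) {
  n <- nrow(cx)
  h_unc <- .ent_g_nats(cx, bias_correct)
  h_cond <- 0
  for (k in levels(tau)) {
    idx <- tau == k
    h_cond <- h_cond + (sum(idx) / n) * .ent_g_nats(cx[idx, , drop = FALSE],
                                                    bias_correct)
  }
  h_unc - h_cond
}

#' Mutual information between muscle activity and a discrete task variable
#'
#' Gaussian-mixture estimator: the muscle vector is copula-normalised across
#' all trials, then MI is the overall Gaussian entropy minus the
#' class-weighted conditional Gaussian entropies. Clipped at zero.
#'
#' @param x numeric vector or matrix (trials in rows).
#' @param tau per-trial discrete labels (factor or coercible).
#' @param clip clip negative estimates at 0.
#' @return an `info_estimate` with the MI in bits.
#' @export
mi_mixed <- function(x, tau, clip = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) != length(tau)) stop("tau must have one label per trial",
                                   call. = FALSE)
  if (nrow(x) < .min_trials_mi) {
    stop("need at least ", .min_trials_mi, " trials", call. = FALSE)
  }
  tau <- .check_classes(tau, ncol(x))
  cx <- .copnorm_mat(x)
  v <- .mi_model_gd_nats(cx, tau) / log(2)
  .info_estimate(if (clip) max(0, v) else v, "gaussian_mixture", "MI")
}

# ---- conditional MI ---------------------------------------------------------

# Gaussian conditional MI (nats) of copnormed blocks given copnormed z:
# I(x;y|z) = H(xz) + H(yz) - H(z) - H(xyz)
.cmi_ggg_nats <- function(cx, cy, cz, bias_correct = TRUE) {
  .ent_g_nats(cbind(cx, cz), bias_correct) +
    .ent_g_nats(cbind(cy, cz), bias_correct) -
    .ent_g_nats(cz, bias_correct) -
    .ent_g_nats(cbind(cx, cy, cz), bias_correct)
}

#' Conditional mutual information between muscles given a task variable
#'
#' Quantifies the task-irrelevant part of a muscle coupling. For a discrete
#' task variable the estimate is the class-weighted sum of within-class
#' Gaussian-copula MI, with ranks recomputed within each class (conditioning
#' changes the marginals). For a continuous task variable the conditional MI
#' is computed in closed form on the copula-normalised triple. Clipped at
#' zero; symmetric in `x` and `y`.
#'
#' @param x,y numeric vectors/matrices of muscle amplitudes (trials in rows).
#' @param tau a factor (discrete) or numeric vector/matrix (continuous,
#'   per-trial values; a matrix conditions on all its columns jointly).
#' @param clip clip negative estimates at 0.
#' @return an `info_estimate` with the conditional MI in bits.
#' @export
cmi <- function(x, y, tau, clip = TRUE) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y must have the same number of trials",
                               call. = FALSE)
  n <- nrow(x)
  if (is.factor(tau) || is.character(tau) || is.logical(tau)) {
    tau <- .check_classes(as.factor(tau), ncol(x) + ncol(y))
    if (length(tau) != n) stop("tau must have one label per trial",
                               call. = FALSE)
    v <- 0
    for (k in levels(tau)) {
      idx <- tau == k
      cxk <- .copnorm_mat(x[idx, , drop = FALSE])
      cyk <- .copnorm_mat(y[idx, , drop = FALSE])
      v <- v + (sum(idx) / n) * .mi_gg_nats(cxk, cyk)
    }
    est <- "gaussian_mixture"
  } else {
    tau <- as.matrix(tau)
    if (nrow(tau) != n) stop("tau must be aligned with trials", call. = FALSE)
    v <- .cmi_ggg_nats(.copnorm_mat(x), .copnorm_mat(y), .copnorm_mat(tau))
    est <- "gcmi"
  }
  v <- v / log(2)
  .info_estimate(if (clip) max(0, v) else v, est, "CMI")
}

# ---- plugin discrete MI -----------------------------------------------------

.joint_symbols <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) == 1L) factor(x[, 1L]) else factor(do.call(paste, c(
    lapply(seq_len(ncol(x)), function(j) x[, j]), sep = "\r")))
}

#' Plugin mutual information between discrete variables
#'
#' Exact empirical MI in bits from joint frequencies; used for worked
#' examples with binary on/off muscle states where copula estimators are
#' undefined.
#'
#' @param x vector (or matrix whose columns are jointly observed variables).
#' @param y vector or matrix, same number of observations.
#' @return an `info_estimate` with the MI in bits.
#' @examples
#' tabs <- figure2_tables()
#' mi_plugin_discrete(tabs$redundancy$mx, tabs$redundancy$tau) # 1 bit
#' @export
mi_plugin_discrete <- function(x, y) {
  fx <- .joint_symbols(x)
  fy <- .joint_symbols(y)
  if (length(fx) == 0L) stop("empty input", call. = FALSE)
  if (length(fx) != length(fy)) stop("x and y must have equal length",
                                     call. = FALSE)
  p <- table(fx, fy) / length(fx)
  px <- rowSums(p); py <- colSums(p)
  terms <- p * log2(p / outer(px, py))
  .info_estimate(sum(terms[p > 0]), "plugin_discrete", "MI")
}

# ---- co-information ---------------------------------------------------------

#' Co-information of a muscle pair about a task variable
#'
#' Signed three-way information `I(x; y; tau) = I([x,y]; tau) - I(x; tau) -
#' I(y; tau)`. Negative values indicate net redundancy (both muscles carry
#' the same task information), positive values net synergy (task information
#' available only from the joint observation). Components are used unclipped
#' so that the additive identity holds exactly; they are returned in
#' `$components`.
#'
#' @param x,y muscle trial vectors (numeric, or discrete for the plugin
#'   estimator).
#' @param tau task variable: factor (discrete), numeric (continuous), or
#'   discrete vector with `estimator = "plugin_discrete"`.
#' @param estimator `"auto"` picks `gaussian_mixture` for discrete tau and
#'   `gcmi` for continuous tau; `"plugin_discrete"` treats all three
#'   variables as finite-alphabet symbols.
#' @return an `info_estimate` of kind `"coI"` (signed, bits) with components
#'   `mi_x`, `mi_y`, `mi_joint`.
#' @export
co_information <- function(x, y, tau,
                           estimator = c("auto", "gcmi", "gaussian_mixture",
                                         "plugin_discrete")) {
  estimator <- match.arg(estimator)
  if (estimator == "plugin_discrete") {
    ix <- mi_plugin_discrete(x, tau)$value
    iy <- mi_plugin_discrete(y, tau)$value
    ixy <- mi_plugin_discrete(cbind(x, y), tau)$value
    est <- "plugin_discrete"
  } else {
    x <- as.matrix(x); y <- as.matrix(y)
    discrete <- is.factor(tau) || is.character(tau) || is.logical(tau)
    if (estimator == "gaussian_mixture") discrete <- TRUE
    if (discrete) {
      tau <- as.factor(tau)
      ix <- mi_mixed(x, tau, clip = FALSE)$value
      iy <- mi_mixed(y, tau, clip = FALSE)$value
      ixy <- mi_mixed(cbind(x, y), tau, clip = FALSE)$value
      est <- "gaussian_mixture"
    } else {
      tau <- as.matrix(tau)
      ix <- mi_gc(x, tau, clip = FALSE)$value
      iy <- mi_gc(y, tau, clip = FALSE)$value
      ixy <- mi_gc(cbind(x, y), tau, clip = FALSE)$value
      est <- "gcmi"
    }
  }
  .info_estimate(ixy - ix - iy, est, "coI",
                 components = c(mi_x = ix, mi_y = iy, mi_joint = ixy))
}

#' Split a signed co-information matrix into redundant and synergistic parts
#'
#' Parses a symmetric matrix of co-information values into two equally sized
#' non-negative matrices: the rectified negative part (task redundancy) and
#' the positive part (task synergy). `synergistic - redundant` reconstructs
#' the input exactly.
#'
#' @param coi symmetric numeric matrix of signed co-information values.
#' @return list with non-negative matrices `redundant` and `synergistic`.
#' @export
split_signed <- function(coi) {
  coi <- as.matrix(coi)
  if (nrow(coi) != ncol(coi) || !isTRUE(all.equal(coi, t(coi)))) {
    stop("co-information matrix must be symmetric", call. = FALSE)
  }
  red <- -coi
  red[red < 0] <- 0
  syn <- coi
  syn[syn < 0] <- 0
  list(redundant = red, synergistic = syn)
}
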