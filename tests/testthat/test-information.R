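test_that("copula normalisation maps ranks to standard-normal scores", {
  expect_equal(copula_normalize(c(1, 2, 3)),
               qnorm(c(0.25, 0.5, 0.75)))
  expect_identical(copula_normalize(c(5, 1, 9))[order(c(5, 1, 9))][2], 0)
  # invariance under strictly monotone transforms
  set.seed(1)
  x <- rnorm(50)
  expect_equal(copula_normalize(exp(x)), copula_normalize(x))
  expect_equal(copula_normalize(x^3), copula_normalize(x))
})

test_that("tied samples are ranked by explicit average-rank oracle", {
  x <- c(2, 1, 2, 3, 1)
  # brute-force average ranks by sort-and-group
  sorted <- sort(x)
  avg_rank <- vapply(x, function(v) mean(which(sorted == v)), 0)
  expect_equal(copula_normalize(x), qnorm(avg_rank / (length(x) + 1)))
})

test_that("degenerate copula inputs are rejected", {
  expect_error(copula_normalize(rep(1, 10)), "degenerate")
  expect_error(copula_normalize(c(1, NA, 3)), "NA")
  expect_error(copula_normalize(c(1, Inf, 3)), "finite")
})

test_that("Gaussian entropy matches closed forms", {
  set.seed(2)
  x <- rnorm(1e5)
  expect_equal(gaussian_entropy_bits(x), 0.5 * log2(2 * pi * exp(1)),
               tolerance = 0.01)
  # scaling law H(aX) - H(X) = log2|a|, exact for the plug-in estimator
  expect_equal(gaussian_entropy_bits(3 * x) - gaussian_entropy_bits(x),
               log2(3), tolerance = 1e-9)
  expect_equal(gaussian_entropy_bits(x + 100), gaussian_entropy_bits(x),
               tolerance = 1e-9)
})

test_that("bivariate Gaussian entropy agrees with the analytic value within
           Monte-Carlo tolerance", {
  rho <- 0.5
  closed <- 0.5 * log2((2 * pi * exp(1))^2 * (1 - rho^2))
  est <- sapply(1:100, function(s) {
    set.seed(s)
    z <- rnorm(1000)
    x <- cbind(z, rho * z + sqrt(1 - rho^2) * rnorm(1000))
    gaussian_entropy_bits(x)
  })
  # the estimate from one seed must sit inside the spread established by
  # the repeated-draw oracle
  expect_lt(abs(est[1] - closed), 5 * sd(est))
  expect_lt(abs(mean(est) - closed), 3 * sd(est) / sqrt(100))
})

test_that("singular covariance is a degenerate-input error", {
  x <- rnorm(50)
  expect_error(gaussian_entropy_bits(cbind(x, x)), "singular|degenerate")
})

test_that("Gaussian-copula MI matches the closed-form Gaussian oracle", {
  for (rho in c(0.3, 0.6, 0.9)) {
    set.seed(100 + round(100 * rho))
    n <- 1e4
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    expect_equal(mi_gc(x, y)$value, -0.5 * log2(1 - rho^2),
                 tolerance = 0.05)
  }
})

test_that("Gaussian-copula MI is symmetric, non-negative and near zero under
           independence", {
  set.seed(3)
  x <- rnorm(5000)
  y <- rnorm(5000)
  expect_lte(mi_gc(x, y)$value, 0.02)
  expect_gte(mi_gc(x, y)$value, 0)
  expect_identical(mi_gc(x, y)$value, mi_gc(y, x)$value)
  # rank invariance
  z <- 0.7 * x + rnorm(5000)
  expect_equal(mi_gc(exp(x), z)$value, mi_gc(x, z)$value, tolerance = 1e-12)
  expect_error(mi_gc(x, y[1:10]), "same number of trials")
})

test_that("mixture MI vanishes for shuffled labels and saturates at the
           half-normal limit for separated classes", {
  set.seed(4)
  n <- 2000
  cl <- factor(rep(c("a", "b"), n / 2))
  x <- rnorm(n)
  expect_lte(mi_mixed(x, sample(cl))$value, 0.02)
  # perfectly separated classes: the copula transform maps them to the two
  # halves of a normal, whose class-conditional Gaussian fit caps the
  # estimate at -log2(1 - 2/pi)/2
  xs <- ifelse(cl == "a", -10, 10) + rnorm(n)
  expect_equal(mi_mixed(xs, cl)$value, -0.5 * log2(1 - 2 / pi),
               tolerance = 0.05)
  expect_equal(mi_mixed(exp(xs / 20), cl)$value, mi_mixed(xs, cl)$value,
               tolerance = 1e-12)
  expect_error(mi_mixed(x[1:20], factor(c(rep("a", 18), "b", "b"))),
               "degenerate class")
})

test_that("conditional MI removes task-driven coupling and matches the
           analytic Gaussian value for a shared latent", {
  set.seed(5)
  n <- 5000
  tau <- rnorm(n)
  x <- tau + rnorm(n)
  y <- 2 * tau + rnorm(n)
  expect_lte(cmi(x, y, tau)$value, 0.05)
  expect_identical(cmi(x, y, tau)$value, cmi(y, x, tau)$value)
  # x, y share a tau-independent latent: I(x;y|tau) = I(x;y) with
  # correlation 1/2 for unit-variance components
  z <- rnorm(n)
  x2 <- z + rnorm(n)
  y2 <- z + rnorm(n)
  closed <- -0.5 * log2(1 - 0.25)
  expect_equal(cmi(x2, y2, tau)$value, closed, tolerance = 0.1 * closed)
  # discrete conditioning uses class-wise ranks and stays near the same value
  cl <- factor(rep(c("a", "b"), n / 2))
  expect_equal(cmi(x2, y2, cl)$value, closed, tolerance = 0.1 * closed)
})

test_that("plugin MI reproduces exact discrete values", {
  tabs <- figure2_tables()
  expect_identical(mi_plugin_discrete(tabs$redundancy$mx,
                                      tabs$redundancy$tau)$value, 1)
  x <- rep(c(0, 1), 10)
  expect_identical(mi_plugin_discrete(x, x)$value, 1)
  # any 3-symbol joint table matches direct summation
  set.seed(6)
  a <- sample(1:3, 60, replace = TRUE)
  b <- sample(1:3, 60, replace = TRUE)
  p <- table(a, b) / 60
  pa <- rowSums(p); pb <- colSums(p)
  direct <- sum(p * log2(p / outer(pa, pb)), na.rm = TRUE)
  expect_equal(mi_plugin_discrete(a, b)$value, direct, tolerance = 1e-12)
  expect_error(mi_plugin_discrete(integer(0), integer(0)), "empty")
})

test_that("co-information satisfies the additive identity exactly and is
           near zero under independence", {
  set.seed(7)
  n <- 5000
  x <- rnorm(n); y <- rnorm(n); tau <- rnorm(n)
  ci <- co_information(x, y, tau)
  expect_lte(abs(ci$value), 0.05)
  # identity holds by construction, per call, for every estimator route
  cases <- list(
    co_information(x, y, tau),
    co_information(x + tau, y - tau, tau),
    co_information(x, y, factor(rep(1:2, n / 2))),
    co_information(round(x), round(y), factor(rep(1:2, n / 2)),
                   estimator = "plugin_discrete"))
  for (ci in cases) {
    cmp <- ci$components
    expect_identical(ci$value,
                     cmp[["mi_joint"]] - cmp[["mi_x"]] - cmp[["mi_y"]])
  }
})

test_that("signed co-information splits into rectified halves", {
  m <- matrix(c(0, -0.3, -0.3, 0), 2)
  s <- split_signed(m)
  expect_equal(s$redundant, matrix(c(0, 0.3, 0.3, 0), 2))
  expect_equal(s$synergistic, matrix(0, 2, 2))
  m2 <- matrix(c(0, 0.5, 0.5, 0), 2)
  s2 <- split_signed(m2)
  expect_equal(s2$synergistic, m2)
  expect_equal(s2$redundant, matrix(0, 2, 2))
  set.seed(8)
  r <- matrix(rnorm(25), 5); r <- r + t(r)
  sr <- split_signed(r)
  expect_equal(sr$synergistic - sr$redundant, r)
  expect_true(all(sr$redundant >= 0) && all(sr$synergistic >= 0))
  expect_error(split_signed(matrix(1:4, 2)), "symmetric")
})
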