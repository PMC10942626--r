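test_that("generation is byte-identical under the same seed", {
  sp <- synthetic_spec(n_participants = 2, n_trials = 40, n_muscles = 4,
                       n_timepoints = 5, seed = 1,
                       planted = data.frame(i = 1L, j = 2L,
                                            class = "redundant",
                                            t_from = 1L, t_to = 3L,
                                            strength = 1))
  g1 <- generate(sp)
  g2 <- generate(sp)
  expect_identical(g1$emg, g2$emg)
  expect_identical(g1$tasks[[1]]$values, g2$tasks[[1]]$values)
  # generation must not disturb the caller's RNG stream
  set.seed(42); before <- rnorm(1)
  set.seed(42); invisible(generate(sp)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("invalid planted tables are rejected", {
  base <- data.frame(i = c(1L, 2L), j = c(2L, 1L), class = "redundant",
                     t_from = 1L, t_to = 2L, strength = 1)
  expect_error(synthetic_spec(planted = base, seed = 1), "planted twice")
  syn_self <- data.frame(i = 1L, j = 1L, class = "synergistic",
                         t_from = 1L, t_to = 2L, strength = 1)
  expect_error(synthetic_spec(planted = syn_self, seed = 1), "pairwise")
  oob <- data.frame(i = 1L, j = 99L, class = "redundant",
                    t_from = 1L, t_to = 2L, strength = 1)
  expect_error(synthetic_spec(planted = oob, seed = 1), "out of bounds")
  expect_error(synthetic_spec(n_muscles = 4, planted = NULL),
               "seed is mandatory")
})

test_that("planted redundancy yields negative co-information exceeding the
           noise distribution", {
  pl <- data.frame(i = 1L, j = 2L, class = "redundant",
                   t_from = 1L, t_to = 4L, strength = 1)
  g <- generate(synthetic_spec(n_participants = 1, n_trials = 2000,
                               n_muscles = 5, n_timepoints = 4,
                               planted = pl, seed = 3))
  coi <- build_tensor(g$dataset, "all")$coi
  mp <- coi$muscle_pairs
  planted_row <- which(mp[, 1] == 1 & mp[, 2] == 2)
  planted_vals <- coi$values[planted_row, , 1]
  noise_vals <- abs(coi$values[-planted_row, , 1])
  expect_true(all(planted_vals < 0))
  expect_gt(min(abs(planted_vals)), quantile(noise_vals, 0.95))
})

test_that("planted synergy yields positive co-information exceeding the
           noise distribution", {
  pl <- data.frame(i = 2L, j = 4L, class = "synergistic",
                   t_from = 1L, t_to = 4L, strength = 1)
  g <- generate(synthetic_spec(n_participants = 1, n_trials = 2000,
                               n_muscles = 5, n_timepoints = 4,
                               planted = pl, seed = 4))
  coi <- build_tensor(g$dataset, "all")$coi
  mp <- coi$muscle_pairs
  planted_row <- which(mp[, 1] == 2 & mp[, 2] == 4)
  planted_vals <- coi$values[planted_row, , 1]
  noise_vals <- abs(coi$values[-planted_row, , 1])
  expect_true(all(planted_vals > 0))
  expect_gt(min(planted_vals), quantile(noise_vals, 0.95))
})

test_that("the four-observation truth tables carry the stated information
           structure", {
  tabs <- figure2_tables()
  r <- tabs$redundancy
  expect_identical(mi_plugin_discrete(r$mx, r$tau)$value, 1)
  expect_identical(mi_plugin_discrete(r$my, r$tau)$value, 1)
  s <- tabs$synergy
  expect_identical(mi_plugin_discrete(s$mx, s$tau)$value, 0)
  expect_identical(mi_plugin_discrete(s$my, s$tau)$value, 0)
  expect_identical(mi_plugin_discrete(cbind(s$mx, s$my), s$tau)$value, 1)
  expect_identical(s$tau, ifelse(s$mx == s$my, "L", "R"))
})

test_that("recovery scoring handles perfect, empty and partial retention", {
  g <- rank32_dataset(n_participants = 1, n_trials = 150, seed = 5)
  tens <- build_tensor(g$dataset, "redundant")
  sp <- sparsify_dual_domain(tens, n_random = 50, seed = 5)
  sc <- score_recovery(g$ground_truth, sp)
  expect_true(sc$precision >= 0 && sc$precision <= 1)
  empty <- sp
  empty$mask[] <- FALSE
  expect_equal(score_recovery(g$ground_truth, empty)$recall, 0)
  perfect <- sp
  perfect$mask[] <- FALSE
  gt <- g$ground_truth
  # mark exactly the planted entries
  mp <- sp$muscle_pairs; tp <- sp$time_pairs
  for (grp in 1:3) {
    ms <- gt$i[gt$group == grp]
    tw <- c(gt$t_from[gt$group == grp][1], gt$t_to[gt$group == grp][1])
    prs <- which(mp[, 1] %in% ms & mp[, 2] %in% ms)
    tps <- which(tp[, 1] >= tw[1] & tp[, 2] <= tw[2])
    perfect$mask[prs, tps, ] <- TRUE
  }
  sc2 <- score_recovery(g$ground_truth, perfect)
  expect_equal(sc2$precision, 1)
  expect_equal(sc2$recall, 1)
})

test_that("half-strength couplings recover between the noiseless and
           noise-only extremes", {
  vals <- sapply(c(0, 0.4, 1.2), function(str) {
    pl <- data.frame(i = 1L, j = 2L, class = "redundant",
                     t_from = 1L, t_to = 4L, strength = str)
    g <- generate(synthetic_spec(n_participants = 1, n_trials = 300,
                                 n_muscles = 4, n_timepoints = 4,
                                 planted = if (str > 0) pl else NULL,
                                 seed = 6))
    red <- build_tensor(g$dataset, "redundant")
    max(red$values)
  })
  expect_true(vals[1] < vals[2] && vals[2] < vals[3])
})
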