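test_that("the tanh dose-toxicity curve matches its printed probabilities", {
  g <- example_grid()
  scn <- tanh_scenario(g$original_levels, g)
  expect_equal(round(scn$p[4], 2), 0.09)
  expect_equal(round(scn$p[6], 2), 0.49)
  # at the fifth dose (original level 0) the curve gives exactly 1/4
  expect_equal(scn$p[5], 0.25)
  expect_equal(scn$mtd_index, 5L)
  # limits of the curve
  expect_equal(((tanh(-50) + 1) / 2)^2, 0, tolerance = 1e-10)
  expect_equal(((tanh(50) + 1) / 2)^2, 1, tolerance = 1e-10)
})

test_that("random scenarios satisfy their construction constraints", {
  g <- dose_grid(1:5, alpha = 0.3)
  for (i in 1:30) {
    pos <- ((i - 1) %% 4) + 1
    scn <- random_scenario(g, pos, seed = 900 + i)
    expect_true(all(diff(scn$p) > 0))
    expect_true(all(scn$p > 0 & scn$p < 1))
    expect_equal(scn$mtd_index, pos)
    if (pos > 1) {
      expect_gte(scn$p[pos] - scn$p[pos - 1], 0.05)
    }
    if (pos < g$K) {
      gap_up <- scn$p[pos + 1] - scn$p[pos]
      expect_gte(gap_up, 0.05)
      expect_lte(gap_up, 0.3 + 1e-9)
    }
  }
  # determinism under a fixed seed
  s1 <- random_scenario(g, 2, seed = 123)
  s2 <- random_scenario(g, 2, seed = 123)
  expect_identical(s1$p, s2$p)
})

test_that("MTD positions drawn uniformly cover the first four doses evenly", {
  g <- dose_grid(1:5, alpha = 0.3)
  set.seed(555)
  pos <- sample(1:4, 200, replace = TRUE)
  counts <- table(factor(vapply(seq_along(pos), function(i) {
    random_scenario(g, pos[i], seed = 3000 + i)$mtd_index
  }, integer(1)), levels = 1:4))
  expect_true(all(counts >= 30) && all(counts <= 70))   # about 50 each
})

test_that("exact-dose grids place the MTD at the requested location", {
  g <- random_exact_doses(5, 3, "middle", seed = 9)
  expect_equal(g$scaled_levels[3], 0.5)
  expect_true(all(abs(g$scaled_levels[-3] - 0.5) >= 0.05))
  g2 <- random_exact_doses(5, 2, "early", seed = 10)
  expect_equal(g2$scaled_levels[2], 0.3)
  expect_equal(sum(g2$scaled_levels < 0.25), 1L)
  expect_equal(sum(g2$scaled_levels > 0.35), 3L)
  g3 <- random_exact_doses(4, 4, "late", seed = 11)
  expect_equal(g3$scaled_levels[4], 0.7)
})

test_that("an overly toxic lowest dose usually terminates the trial", {
  g <- dose_grid(1:4, alpha = 0.3)
  scn <- scenario(g, c(0.95, 0.96, 0.97, 0.98))
  term <- vapply(1:20, function(i) {
    run_trial(scn, bsa_config(alpha = 0.3), seed = 40 + i)$terminated
  }, logical(1))
  # with 12 patients at the lowest dose, the observed rate is essentially
  # always above the upper Wald bound (0.576 at m = 12)
  expect_gte(mean(term), 0.9)
})

test_that("a harmless scenario climbs monotonically and stays at the top", {
  g <- dose_grid(1:5, alpha = 0.3)
  scn <- scenario(g, c(1e-5, 2e-5, 3e-5, 4e-5, 5e-5))
  r <- run_trial(scn, bsa_config(alpha = 0.3), seed = 3)
  expect_equal(r$path[1:5], 1:5)
  expect_true(all(r$path[-(1:4)] == 5))
  expect_lte(r$enrolled, 30)
  expect_equal(r$n_dlt, 0)
})

test_that("enrollment never exceeds the maximum sample size", {
  g <- dose_grid(1:5, alpha = 0.3)
  set.seed(71)
  for (i in 1:5) {
    scn <- random_scenario(g, sample(1:4, 1), seed = 600 + i)
    for (cs in list(3L, 2L, "random")) {
      r <- run_trial(scn, bsa_config(alpha = 0.3, cohort_size = cs),
                     seed = 700 + i)
      expect_lte(r$enrolled, 30)
      expect_equal(sum(r$allocations), r$enrolled)
    }
  }
})

test_that("identical seeds reproduce trials bitwise", {
  g <- dose_grid(1:5, alpha = 0.3)
  scn <- random_scenario(g, 3, seed = 88)
  r1 <- run_trial(scn, bsa_config(alpha = 0.3, cohort_size = "random"),
                  seed = 21)
  r2 <- run_trial(scn, bsa_config(alpha = 0.3, cohort_size = "random"),
                  seed = 21)
  expect_identical(r1, r2)
  s1 <- simulate_trials(scn, bsa_config(alpha = 0.3), reps = 5, seed = 31)
  s2 <- simulate_trials(scn, bsa_config(alpha = 0.3), reps = 5, seed = 31)
  expect_identical(unclass(s1), unclass(s2))
})

test_that("operating characteristics match an independent tally", {
  g <- dose_grid(1:5, alpha = 0.3)
  scn <- scenario(g, c(0.05, 0.12, 0.30, 0.55, 0.75))
  sims <- simulate_trials(scn, bsa_config(alpha = 0.3), reps = 30, seed = 17)
  oc <- operating_characteristics(sims)
  # brute-force recount
  mtd <- scn$mtd_index
  correct <- 0; at <- 0; above <- 0; dlts <- 0
  for (r in sims) {
    if (!r$terminated && !is.na(r$selected) && r$selected == mtd) {
      correct <- correct + 1
    }
    at <- at + r$allocations[mtd] / r$enrolled
    above <- above + sum(r$allocations[seq_along(r$allocations) > mtd]) /
      r$enrolled
    dlts <- dlts + r$n_dlt
  }
  expect_equal(oc$pcs, 100 * correct / 30)
  expect_equal(oc$mtd_pct, 100 * at / 30)
  expect_equal(oc$above_mtd_pct, 100 * above / 30)
  expect_equal(oc$avg_dlt, dlts / 30)
  expect_true(oc$pcs >= 0 && oc$pcs <= 100)
})

test_that("no patient is treated above an MTD at the highest dose", {
  g <- dose_grid(1:4, alpha = 0.3)
  scn <- scenario(g, c(0.02, 0.06, 0.15, 0.30))
  sims <- simulate_trials(scn, bsa_config(alpha = 0.3), reps = 10, seed = 19)
  oc <- operating_characteristics(sims)
  expect_equal(oc$above_mtd_pct, 0)
})

test_that("unit-cohort allocation concentrates on the MTD in the long run", {
  # full sequential design, long horizon, Wald action off: the modal dose of
  # the late cohorts should be the true MTD in nearly all trials
  g <- dose_grid(1:5, alpha = 0.3)
  scn <- scenario(g, c(0.05, 0.12, 0.30, 0.55, 0.75))
  cfg <- bsa_config(alpha = 0.3, cohort_size = 1, max_n = 300, wald = FALSE,
                    resolution = 64)
  hits <- vapply(1:100, function(i) {
    r <- run_trial(scn, cfg, seed = 5000 + i)
    late <- r$path[(length(r$path) - 99):length(r$path)]
    tab <- table(late)
    as.integer(names(tab)[which.max(tab)]) == scn$mtd_index
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
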