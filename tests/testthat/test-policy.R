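test_that("the two-point monotonicity adjustment averages violating pairs", {
  expect_equal(pava_adjust(c(0.1, 0.2, 0.3), c(3, 3, 3)), c(0.1, 0.2, 0.3))
  expect_equal(pava_adjust(c(0.4, 0.2), c(5, 5)), c(0.3, 0.3))
  expect_equal(pava_adjust(c(0.0, 0.5, 0.2, 0.6), c(3, 3, 3, 3)),
               c(0.0, 0.35, 0.35, 0.6))
  # untried doses are skipped, adjacency is between observed doses
  expect_equal(pava_adjust(c(0.5, NA, 0.1), c(3, 0, 3)), c(0.3, NA, 0.3))
})

test_that("Wald bounds bracket the target and shrink with sample size", {
  wb <- wald_bounds(0.3, 12, 0.05)
  # independent arithmetic: logit(0.3) -/+ z / sqrt(12 * 0.3 * 0.7)
  z <- stats::qnorm(0.95)
  c1 <- log(0.3 / 0.7) - z / sqrt(12 * 0.21)
  c2 <- log(0.3 / 0.7) + z / sqrt(12 * 0.21)
  expect_equal(unname(wb), c(1 / (1 + exp(-c1)), 1 / (1 + exp(-c2))))
  expect_equal(round(unname(wb), 3), c(0.132, 0.547))
  # xi -> 0.5 collapses the interval onto the target rate
  wb50 <- wald_bounds(0.3, 12, 0.4999)
  expect_equal(unname(wb50), c(0.3, 0.3), tolerance = 1e-3)
  widths <- vapply(c(6, 12, 24, 48), function(m) {
    diff(wald_bounds(0.3, m, 0.05))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_true(all(vapply(c(6, 12, 24), function(m) {
    wb <- wald_bounds(0.3, m, 0.05); wb[1] < 0.3 && wb[2] > 0.3
  }, logical(1))))
})

test_that("quick actions fire in the documented order", {
  g <- dose_grid(1:5, alpha = 0.3)
  cfg <- bsa_config(alpha = 0.3)
  # fast escalation while no DLT anywhere
  h <- data.frame(cohort = 1:3, dose_index = 1:3, n_patients = 3, n_dlt = 0)
  d <- next_dose(h, g, cfg)
  expect_equal(d$action, "escalate")
  expect_equal(d$next_k, 4L)
  expect_equal(d$rationale, "fast-escalation")
  # overwhelming toxicity at the lowest dose terminates the trial
  h2 <- data.frame(cohort = 1:4, dose_index = 1, n_patients = 3,
                   n_dlt = c(3, 2, 2, 2))
  d2 <- next_dose(h2, g, cfg)
  expect_equal(d2$action, "terminate-toxicity")
  expect_equal(d2$rationale, "wald-terminate")
  expect_true(is.na(d2$next_k))
  # below the m0 threshold the Bayesian step decides
  h3 <- data.frame(cohort = 1:4, dose_index = c(1, 2, 2, 2), n_patients = 3,
                   n_dlt = c(0, 1, 1, 0))
  d3 <- next_dose(h3, g, cfg)
  expect_equal(d3$rationale, "bayes")
  expect_false(is.null(d3$theta_mean))
})

test_that("an empty trial starts at the lowest dose", {
  g <- dose_grid(1:5, alpha = 0.3)
  d <- next_dose(NULL, g)
  expect_equal(d$next_k, 1L)
})

test_that("the illustration's search path and MTD are reproduced", {
  g <- example_grid()
  outcomes <- c(0, 0, 0, 0, 0, 1, 0, 1, 0, 0)
  h <- NULL
  k <- next_dose(h, g)$next_k
  path <- integer(0)
  for (i in 1:10) {
    path <- c(path, k)
    h <- rbind(h, data.frame(cohort = i, dose_index = k, n_patients = 3L,
                             n_dlt = outcomes[i]))
    if (i < 10) k <- next_dose(h, g)$next_k
  }
  expect_equal(path, c(1, 2, 3, 4, 5, 6, 5, 5, 5, 5))
  expect_equal(select_mtd(h, g), 5L)
  # the first Bayesian decision moved down into the same subinterval
  d6 <- next_dose(example_history(6), g)
  expect_equal(d6$next_k, 5L)
  expect_equal(d6$rationale, "bayes")
  # after cohort 8 the design stays at dose 5
  d8 <- next_dose(example_history(8), g)
  expect_equal(d8$action, "stay")
  expect_equal(d8$next_k, 5L)
})

test_that("MTD selection handles termination and degenerate grids", {
  g <- example_grid()
  expect_true(is.na(select_mtd(example_history(10), g, terminated = TRUE)))
  g1 <- dose_grid(1, alpha = 0.3, scaled = 0.5)
  h1 <- data.frame(cohort = 1, dose_index = 1, n_patients = 3, n_dlt = 1)
  expect_equal(select_mtd(h1, g1), 1L)
  expect_error(select_mtd(NULL, g), "empty")
})

test_that("historical pseudo-counts follow the nearest-integer rule", {
  hp <- build_pseudo_data(skeleton = 0.3, pess = 3)
  expect_equal(c(hp$a, hp$b), c(1L, 2L))
  hp2 <- build_pseudo_data(skeleton = 0.5, pess = 4)
  expect_equal(c(hp2$a, hp2$b), c(2L, 2L))
  hp0 <- build_pseudo_data(skeleton = c(0.1, 0.3), pess = c(0, 0))
  expect_equal(hp0$a, c(0L, 0L))
  expect_equal(hp0$b, c(0L, 0L))
  expect_error(build_pseudo_data(c(0.3, 0.2), c(1, 1)), "increasing")
})

test_that("zero borrowing reduces the historical design to the plain one", {
  g <- dose_grid(1:5, alpha = 0.3)
  hp0 <- build_pseudo_data(skeleton = c(0.05, 0.1, 0.2, 0.3, 0.45),
                           pess = rep(0L, 5))
  set.seed(77)
  for (i in 1:8) {
    n <- sample(2:6, 1)
    h <- data.frame(cohort = seq_len(n),
                    dose_index = pmin(cummax(sample(1:3, n, replace = TRUE)), 5),
                    n_patients = 3L,
                    n_dlt = stats::rbinom(n, 3, 0.25))
    da <- next_dose(h, g)
    db <- next_dose(h, g, historical = hp0)
    expect_identical(da$next_k, db$next_k)
    expect_identical(da$action, db$action)
  }
})

test_that("borrowed pseudo-observations shift the Bayesian decision data", {
  g <- dose_grid(1:5, alpha = 0.3)
  h <- data.frame(cohort = 1:3, dose_index = c(1, 2, 3), n_patients = 3,
                  n_dlt = c(0, 0, 1))
  hp <- build_pseudo_data(skeleton = c(0.05, 0.1, 0.2, 0.3, 0.45),
                          pess = rep(3L, 5))
  da <- next_dose(h, g)
  db <- next_dose(h, g, historical = hp)
  expect_false(isTRUE(all.equal(da$theta_mean, db$theta_mean)))
})

test_that("default prior effective sample sizes match the interval rule", {
  expect_equal(pess_default(30, 6), 2L)
  expect_equal(pess_default(30, 5), 3L)
  expect_equal(pess_default(60, 5), 6L)
  expect_equal(pess_default(60, 5, rule = "smallest"), 4L)
  expect_error(pess_default(5, 3), "manually")
})

test_that("decision trees enumerate all outcome branches", {
  g <- dose_grid(1:5, alpha = 0.3)
  h <- data.frame(cohort = 1:2, dose_index = 1:2, n_patients = 3,
                  n_dlt = c(0, 1))
  tr <- decision_tree(h, g, depth = 1L)
  expect_equal(length(tr$children), 4L)   # 0..3 DLTs in a cohort of three
  # a fully toxic cohort never escalates, and no branch skips a dose
  tr2 <- decision_tree(h, g, depth = 2L)
  check <- function(node, from) {
    k <- node$decision$next_k
    if (!is.na(k)) expect_lte(abs(k - from), 1L)
    for (ch in node$children) {
      if (!is.null(ch$n_dlt) && ch$n_dlt == 3L && !is.na(ch$decision$next_k)) {
        expect_lte(ch$decision$next_k, k)
      }
      if (!is.na(k)) check(ch, k)
    }
  }
  check(tr2, h$dose_index[nrow(h)])
})

test_that("decisions never skip doses on randomized reachable states", {
  set.seed(303)
  g <- dose_grid(1:6, alpha = 0.25)
  cfg <- bsa_config(alpha = 0.25)
  for (i in 1:10) {
    scn <- random_scenario(g, sample(1:4, 1), seed = 400 + i)
    h <- NULL
    k <- next_dose(h, g, cfg)$next_k
    for (cht in 1:10) {
      h <- rbind(h, data.frame(cohort = cht, dose_index = k, n_patients = 3L,
                               n_dlt = stats::rbinom(1, 3, scn$p[k])))
      d <- next_dose(h, g, cfg)
      if (d$action == "terminate-toxicity") break
      expect_lte(abs(d$next_k - k), 1L)
      k <- d$next_k
    }
  }
})

test_that("single-patient cohorts are coherent by exhaustive enumeration", {
  g <- dose_grid(1:5, alpha = 0.3)
  cfg <- bsa_config(alpha = 0.3, cohort_size = 1, resolution = 128)
  violations <- 0L
  rec <- function(h, k, depth) {
    for (y in 0:1) {
      h2 <- rbind(h, data.frame(cohort = nrow(h) + 1L, dose_index = k,
                                n_patients = 1L, n_dlt = y))
      d <- next_dose(h2, g, cfg)
      if ((y == 1 && d$action == "escalate") ||
          (y == 0 && d$action == "de-escalate")) {
        violations <<- violations + 1L
      }
      if (depth > 1L && d$action != "terminate-toxicity") {
        rec(h2, d$next_k, depth - 1L)
      }
    }
  }
  h0 <- data.frame(cohort = integer(0), dose_index = integer(0),
                   n_patients = integer(0), n_dlt = integer(0))
  rec(h0, 1L, 6L)
  expect_equal(violations, 0L)
})

test_that("before any toxicity the path escalates strictly to the top", {
  g <- dose_grid(1:4, alpha = 0.3)
  scn <- scenario(g, c(0.001, 0.002, 0.003, 0.004))
  r <- run_trial(scn, bsa_config(alpha = 0.3, max_n = 18), seed = 5)
  expect_equal(r$path[1:4], 1:4)
  expect_true(all(diff(r$path) >= 0))
})
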