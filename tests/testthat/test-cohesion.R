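test_that("the cohesion index has the entropy closed form and its endpoints", {
  for (k in c(2, 4, 6))
    expect_identical(cohesion_index(rep(1 / k, k)), 0)
  for (k in c(2, 4, 6))
    expect_identical(cohesion_index(c(1, rep(0, k - 1))), 1)
  # direct entropy arithmetic: 1 - H(0.75, 0.25)/log 2
  expect_equal(cohesion_index(c(0.75, 0.25)), 0.1887219, tolerance = 1e-6)

  expect_error(cohesion_index(c(0.5, 0.4)), "sum to 1")
  expect_error(cohesion_index(c(1.2, -0.2)), "non-negative")
  expect_error(cohesion_index(1), "two sites")
})

test_that("cohesion is permutation-invariant and decreases as occupancy evens", {
  set.seed(8)
  for (i in 1:10) {
    p <- stats::runif(5)
    p <- p / sum(p)
    expect_equal(cohesion_index(p), cohesion_index(sample(p)))
  }
  evenness <- sapply(c(1, 0.9, 0.75, 0.6, 0.5),
                     function(a) cohesion_index(c(a, 1 - a)))
  expect_true(all(diff(evenness) < 0))
})

test_that("multi-site initial occupancies spread scouts equally", {
  init <- cohesion_initial(cohesion_params(N = 100, z = 0.12, N_nest = 4))
  expect_identical(init$n_current, 88L)
  expect_equal(init$committed, rep(3L, 4))
  expect_equal(init$recruiting, rep(0L, 4))

  init6 <- cohesion_initial(cohesion_params(N = 100, z = 0.12, N_nest = 6))
  expect_identical(init6$n_current, 88L)
  expect_equal(init6$committed, rep(2L, 6))

  expect_error(cohesion_params(N = 100, z = 0.1, N_nest = 3), "not integer")
})

test_that("cohesion runs finish at the emigrated-fraction rule and report C", {
  cp <- cohesion_params(N = 100, N_nest = 2, z = 0.12)
  r <- cohesion_run(cp, seed = 11)
  expect_identical(r$result, "finished")
  expect_gte(sum(r$site_counts), 90)
  expect_equal(sum(r$p), 1)
  expect_equal(r$C, cohesion_index(r$p))
  expect_identical(cohesion_run(cp, seed = 11), r)  # seeded determinism
})

test_that("with two equal sites mean occupancies are exchangeable", {
  cp <- cohesion_params(N = 100, N_nest = 2, z = 0.12, alpha_leak = 0)
  b <- cohesion_batch(cp, n_runs = 400, seed = 13)
  expect_identical(b$n_unsuccessful, 0L)  # no extinction without leakage
  # shares per site average 0.5 within Monte-Carlo error
  se <- sqrt(stats::var(c(0, 1)) / b$n_finished)
  expect_lt(abs(b$p_mean[1] - 0.5), 4 * se)
})

test_that("batch accounting for cohesion runs is exhaustive", {
  cp <- cohesion_params(N = 100, N_nest = 2, z = 0.12)
  b <- cohesion_batch(cp, n_runs = 100, seed = 19)
  expect_identical(b$n_finished + b$n_unsuccessful + b$n_censored, b$n_runs)
  expect_true(b$C_mean >= 0 && b$C_mean <= 1)
})

test_that("a full-emigration finish rule under leakage is surfaced, not hung", {
  cp <- cohesion_params(N = 20, N_nest = 2, z = 0.2, alpha = 0.05,
                        alpha_leak = 0.3, finish_fraction = 1)
  b <- suppressWarnings(cohesion_batch(cp, n_runs = 30, seed = 23,
                                       t_max = 50))
  expect_identical(b$n_finished + b$n_unsuccessful + b$n_censored, 30L)
  expect_gt(b$n_unsuccessful + b$n_censored, 0L)
})
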