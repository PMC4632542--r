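test_that("initial counts scale the mean-field start and demand integrality", {
  n <- initial_counts(nest_params(H = 0.2, z = 0.3, N = 100))
  expect_equal(unclass(n),
               c(n_lc = 56L, n_hc = 14L, n_lpcom = 12L, n_hpvis = 3L,
                 n_lgcom = 12L, n_hgcom = 3L, n_lprec = 0L, n_lgrec = 0L,
                 n_hgrec = 0L))
  expect_identical(sum(n), 100L)

  n2 <- initial_counts(nest_params(H = 0, z = 0.2, N = 10))
  expect_equal(unname(n2[c("n_lc", "n_lpcom", "n_lgcom")]), c(8L, 1L, 1L))
  expect_true(all(n2[high_counts] == 0L))

  expect_error(initial_counts(nest_params(H = 0.1, z = 0.3, N = 100)),
               "not integer")
})

test_that("largest-remainder rounding is opt-in and preserves class totals", {
  p <- nest_params(H = 0.1, z = 0.3, N = 100)
  n <- initial_counts(p, rounding = "largest_remainder")
  expect_identical(sum(n), 100L)
  expect_equal(sum(n[low_counts]), round(p$L * 100))
  expect_equal(sum(n[high_counts]), round(p$H * 100))
})

test_that("the fifteen channel rates match the hand-summed oracle", {
  p <- baseline()
  ev <- event_rates(initial_counts(p), p)
  expect_identical(nrow(ev), 15L)
  # no recruiters yet: all four recruitment channels silent
  expect_equal(ev$rate[1:4], rep(0, 4))
  # conversions 1.2 + 1.2 + 0.3, switch 0.3, leakage 0.6 + 0.6 + 0.15 + 0.15
  expect_equal(sum(ev$rate), 4.5)
  expect_equal(ev$rate[5:8], c(1.2, 1.2, 0.3, 0.3))

  home <- c(80L, 20L, rep(0L, 7))
  expect_equal(event_rates(home, p)$rate, rep(0, 15))

  # with leakage off, only channels with occupied sources fire
  p0 <- nest_params(H = 0.2, z = 0.3, alpha_leak = 0)
  ev0 <- event_rates(initial_counts(p0), p0)
  src <- c(56, 56, 14, 14, 12, 12, 3, 3, 12, 12, 0, 0, 3, 3, 0)
  expect_true(all((ev0$rate > 0) <= (src > 0)))
  expect_equal(ev0$rate[9:15], rep(0, 7))
})

test_that("per-capita channel rates reproduce the mean-field derivatives", {
  # at large N the net per-capita flow of the 15 channels equals the ODE rhs
  p <- nest_params(H = 0.2, z = 0.3, N = 100000, alpha = 0.17,
                   alpha_s = 0.23, alpha_leak = 0.04)
  x <- c(0.30, 0.10, 0.10, 0.04, 0.12, 0.06, 0.13, 0.10, 0.05)
  n <- as.integer(x * p$N)
  ev <- event_rates(n, p)
  flow <- numeric(9)
  cn <- c("n_lc", "n_hc", "n_lpcom", "n_hpvis", "n_lgcom", "n_hgcom",
          "n_lprec", "n_lgrec", "n_hgrec")
  for (k in seq_len(15)) {
    flow[match(ev$from[k], cn)] <- flow[match(ev$from[k], cn)] - ev$rate[k]
    flow[match(ev$to[k], cn)] <- flow[match(ev$to[k], cn)] + ev$rate[k]
  }
  d <- ode_rhs(n / p$N, p)
  expect_equal(flow / p$N, unname(d), tolerance = 1e-12)
})

test_that("event-driven runs conserve counts and class totals at every event", {
  p <- baseline()
  r <- gillespie_run(p, seed = 5, log_events = TRUE)
  lg <- r$event_log
  expect_gt(nrow(lg), 0)
  expect_true(all(rowSums(lg[, 3:11]) == 100))
  expect_true(all(rowSums(lg[, low_counts]) == 80))
  expect_true(all(rowSums(lg[, high_counts]) == 20))
  expect_true(all(diff(lg$time) > 0))
})

test_that("identical seeds give bit-identical runs and batches", {
  p <- baseline()
  expect_identical(gillespie_run(p, seed = 99), gillespie_run(p, seed = 99))
  expect_identical(discrete_time_run(p, seed = 99, dt = 0.02),
                   discrete_time_run(p, seed = 99, dt = 0.02))
  b1 <- run_batch(p, n_runs = 50, seed = 123)
  b2 <- run_batch(p, n_runs = 50, seed = 123)
  expect_identical(b1, b2)
})

test_that("a quorum threshold below the initial scout vote is rejected", {
  p <- nest_params(z = 0.3, quorum_fraction = 0.1)
  expect_error(gillespie_run(p, seed = 1), "quorate at t = 0")
})

test_that("without leakage no run is unsuccessful", {
  p <- nest_params(H = 0.2, z = 0.3, alpha = 0.1, alpha_s = 0.1,
                   alpha_leak = 0, N = 100, quorum_fraction = 0.5)
  b <- run_batch(p, n_runs = 200, seed = 17)
  expect_identical(b$n_unsuccessful, 0L)
  expect_identical(b$n_quorate, 200L)
})

test_that("site symmetry at H = 0 gives accuracy one half", {
  p <- nest_params(H = 0, z = 0.3, alpha = 0.1, alpha_s = 0,
                   alpha_leak = 0.05, N = 100, quorum_fraction = 0.5)
  b <- run_batch(p, n_runs = 2000, seed = 31)
  se <- sqrt(0.25 / b$n_quorate)
  expect_lt(abs(b$P - 0.5), 3 * se)
})

test_that("the discrete-time engine rejects steps with large per-ant probabilities", {
  p <- baseline()
  # dt = 2 pushes the leakage probability to 0.1; the error names the channel
  expect_error(discrete_time_run(p, seed = 1, dt = 2),
               "per-ant per-step probability.*leakage")
  p2 <- nest_params(alpha = 0.2, alpha_s = 0.01, alpha_leak = 0.001)
  expect_error(discrete_time_run(p2, seed = 1, dt = 1),
               "per-ant per-step probability.*conversion")
})

test_that("the two stochastic engines agree on mean time-to-quorum", {
  p <- baseline()
  bg <- run_batch(p, n_runs = 1500, seed = 41)
  bd <- run_batch(p, n_runs = 1500, seed = 42, engine = "discrete",
                  dt = 0.01)
  # overlapping 95% confidence intervals
  expect_lt(abs(bg$T_mean - bd$T_mean),
            bg$T_ci_halfwidth + bd$T_ci_halfwidth)
})

test_that("mean occupancies approach the mean-field trajectory as N grows", {
  tg <- seq(5, 30, by = 5)
  ode <- integrate_euler(baseline(), dt = 1e-3, t_max = 30, stride = 100)
  ode_m <- as.matrix(ode[match(tg, round(ode$time, 6)), 2:10])
  gap <- sapply(c(100, 1000, 10000), function(N) {
    p <- nest_params(H = 0.2, z = 0.3, N = N)
    m <- Reduce(`+`, lapply(1:20, function(i) {
      as.matrix(abm_trajectory(p, seed = 7000 + i, times = tg)[, -1]) / N
    })) / 20
    max(abs(m - ode_m))
  })
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[3], 0.01)
})
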