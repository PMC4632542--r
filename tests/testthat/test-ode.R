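test_that("the initial condition splits scouts equally and commits by threshold", {
  x <- initial_state(nest_params(H = 0.2, z = 0.3))
  expect_equal(unclass(x),
               c(x_lc = 0.56, x_hc = 0.14, x_lpcom = 0.12, x_hpvis = 0.03,
                 x_lgcom = 0.12, x_hgcom = 0.03, x_lprec = 0, x_lgrec = 0,
                 x_hgrec = 0))
  expect_equal(sum(x), 1)

  x0 <- initial_state(nest_params(H = 0, z = 0))
  expect_equal(unname(unclass(x0)), c(1, rep(0, 8)))

  x1 <- initial_state(nest_params(H = 1, z = 0.3))
  expect_equal(unname(x1[c("x_hc", "x_hpvis", "x_hgcom")]),
               c(0.7, 0.15, 0.15))
  expect_true(all(x1[low_cols] == 0))
})

test_that("the right-hand side matches hand-substituted derivatives", {
  p <- baseline()
  d <- ode_rhs(initial_state(p), p)
  # frozen hand arithmetic at the baseline initial state
  expect_equal(unclass(d),
               c(x_lc = 0.012, x_hc = 0.003, x_lpcom = -0.018,
                 x_hpvis = -0.0045, x_lgcom = -0.018, x_hgcom = -0.0015,
                 x_lprec = 0.012, x_lgrec = 0.012, x_hgrec = 0.003))
  expect_equal(sum(d), 0)
})

test_that("the all-home state is an equilibrium and class sums are conserved", {
  p <- nest_params(H = 0.3, z = 0.2, alpha = 0.4, alpha_s = 0.2,
                   alpha_leak = 0.1)
  rest <- c(x_lc = 0.7, x_hc = 0.3, x_lpcom = 0, x_hpvis = 0, x_lgcom = 0,
            x_hgcom = 0, x_lprec = 0, x_lgrec = 0, x_hgrec = 0)
  expect_equal(unname(ode_rhs(rest, p)), rep(0, 9))

  set.seed(42)
  for (i in 1:20) {
    H <- stats::runif(1)
    x <- random_state(H)
    pr <- nest_params(H = H, z = 0.1, alpha_p = stats::runif(1),
                      alpha_g = stats::runif(1), alpha_s = stats::runif(1),
                      alpha_leak = stats::runif(1))
    d <- ode_rhs(x, pr)
    expect_equal(sum(d[low_cols]), 0, tolerance = 1e-14)
    expect_equal(sum(d[high_cols]), 0, tolerance = 1e-14)
    expect_equal(unname(d), unname(ref_rhs(x, pr$alpha_p, pr$alpha_g,
                                           pr$alpha_s, pr$alpha_leak)))
  }
})

test_that("Euler trajectories conserve class totals and total mass", {
  p <- baseline()
  tr <- integrate_euler(p, dt = 1e-3, t_max = 1000, stride = 1000)
  low <- rowSums(tr[, low_cols])
  high <- rowSums(tr[, high_cols])
  expect_lt(max(abs(low - p$L)), 1e-6)
  expect_lt(max(abs(high - p$H)), 1e-6)
  expect_lt(max(abs(low + high - 1)), 1e-6)
  expect_true(all(as.matrix(tr[, c(low_cols, high_cols)]) >= 0))
  expect_equal(tr$time[1], 0)
  expect_true(all(diff(tr$time) > 0))
  expect_equal(unname(unlist(tr[1, 2:10])),
               unname(unclass(initial_state(p))))
})

test_that("halving the Euler step barely moves the trajectory", {
  p <- baseline()
  t1 <- integrate_euler(p, dt = 1e-3, t_max = 100, stride = 10)
  t2 <- integrate_euler(p, dt = 1e-4, t_max = 100, stride = 100)
  expect_equal(dim(t1), dim(t2))
  expect_lt(max(abs(as.matrix(t1[, 2:10]) - as.matrix(t2[, 2:10]))), 1e-3)
})

test_that("votes sum the committed, recruiting and visiting compartments", {
  p <- nest_params(H = 0.4, z = 0.3)
  v0 <- votes(initial_state(p))
  expect_equal(unname(v0), c(0.15, 0.15))  # z/2 apiece

  home <- c(0.6, 0.4, rep(0, 7))
  expect_equal(unname(votes(home)), c(0, 0))

  x <- c(x_lc = 0.55, x_hc = 0.1, x_lpcom = 0, x_hpvis = 0.05,
         x_lgcom = 0.1, x_hgcom = 0, x_lprec = 0, x_lgrec = 0,
         x_hgrec = 0.2)
  expect_equal(unname(votes(x)), c(0.3, 0.05))

  tr <- integrate_euler(p, t_max = 1)
  vv <- votes(tr)
  expect_named(vv, c("time", "v_good", "v_poor"))
})

test_that("the good site always leads the vote, strictly for t > 0 when H > 0", {
  grid <- expand.grid(H = c(0.2, 0.5, 0.8), alpha = c(0.02, 0.1, 1),
                      alpha_s = c(0.01, 0.1, 1), alpha_leak = c(0, 0.05),
                      z = c(0.12, 0.3))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- nest_params(H = g$H, z = g$z, alpha = g$alpha, alpha_s = g$alpha_s,
                     alpha_leak = g$alpha_leak)
    tr <- integrate_euler(p, dt = 1e-3, t_max = 50, stride = 100)
    gap <- tr$v_good - tr$v_poor
    expect_true(all(gap >= -1e-12),
                label = sprintf("good vote dominates (row %d)", i))
    expect_true(all(gap[tr$time > 0] > 0),
                label = sprintf("strict dominance for t > 0 (row %d)", i))
    # corollary: committed and recruiter totals also favour the good site
    expect_true(all(tr$x_lgcom + tr$x_hgcom - tr$x_lpcom >= -1e-12))
    expect_true(all(tr$x_lgrec + tr$x_hgrec - tr$x_lprec >= -1e-12))
  }
})

test_that("without high-threshold ants the two new sites are symmetric", {
  p <- nest_params(H = 0, z = 0.3, alpha = 0.1, alpha_s = 0.1,
                   alpha_leak = 0.05)
  tr <- integrate_euler(p, dt = 1e-3, t_max = 100, stride = 100)
  expect_lt(max(abs(tr$v_good - tr$v_poor)), 1e-12)
})

test_that("deterministic quorum detection finds the fine-step crossing time", {
  p <- baseline()
  q <- ode_quorum_time(p, dt = 1e-3, t_max = 100)
  expect_identical(q$site, "good")
  # frozen regression value from an independent dt = 1e-5 integration
  expect_equal(q$time, 14.02236, tolerance = 1e-3)

  # quorum just above the initial scout vote: good site first, never poor
  q2 <- ode_quorum_time(p, quorum_fraction = 0.16, dt = 1e-3, t_max = 100)
  expect_identical(q2$site, "good")
  expect_lt(q2$time, q$time)

  # leakage keeps the total new-site vote below 1 forever
  q3 <- ode_quorum_time(p, quorum_fraction = 1, dt = 1e-2, t_max = 50)
  expect_null(q3$time)

  tr <- integrate_euler(p, dt = 1e-3, t_max = 100, stride = 10)
  q4 <- ode_quorum_time(tr)
  expect_equal(q4$time, q$time, tolerance = 1e-2)
  expect_identical(q4$site, "good")
})

test_that("configurations quorate at t = 0 are rejected unless overridden", {
  p <- nest_params(z = 0.3, quorum_fraction = 0.1)
  expect_error(ode_quorum_time(p), "already met")
  expect_warning(q <- ode_quorum_time(p, allow_initial_quorum = TRUE),
                 "reporting time 0")
  expect_equal(q$time, 0)
})
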