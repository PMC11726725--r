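test_that("the compiled integrator reproduces a plain-R Euler loop exactly", {
  r <- rate_constants(1.3, 0.7, 2.1, 0.4)
  tot <- totals(cA = 4, cX = 9, cY = 2.5)
  s0 <- state_from_free(1.5, 0.5, tot)
  ref <- reference_euler(s0, r, dt = 1e-3, n_steps = 25)
  tr <- integrate_mixture(s0, r, dt = 1e-3, n_steps = 25)
  expect_equal(as.matrix(tr[, c("A", "X", "Y", "AX", "XY")]),
               ref, ignore_attr = TRUE, tolerance = 1e-15)
  # and with the self-replication forcing
  ref2 <- reference_euler(s0, r, dt = 1e-3, n_steps = 25, kRR = 0.8, dR = 0.05)
  tr2 <- integrate_mixture(s0, r, forcing_replication(0.8, 0.05),
                           dt = 1e-3, n_steps = 25)
  expect_equal(as.matrix(tr2[, c("A", "X", "Y", "AX", "XY")]),
               ref2, ignore_attr = TRUE, tolerance = 1e-15)
})

test_that("an equilibrium initial state stays put", {
  eq <- full_equilibrium(table1_rates(), table1_totals())
  tr <- integrate_mixture(eq$state, table1_rates(), dt = 1e-3, n_steps = 500)
  expect_lt(max(abs(tr$A - eq$x)), 1e-12)
  expect_lt(max(abs(tr$Y - eq$state$Y)), 1e-12)
})

test_that("unforced trajectories conserve the three totals", {
  set.seed(13)
  for (i in 1:5) {
    sys <- random_system()
    s0 <- random_state(sys$tot)
    tr <- integrate_mixture(s0, sys$rates, dt = 1e-3, n_steps = 2000)
    # admissible drift: rounding only (<= 1e-9 per unit simulated time)
    expect_lt(max(abs(tr$cA - sys$tot$cA)), 1e-9 * 2)
    expect_lt(max(abs(tr$cX - sys$tot$cX)), 1e-9 * 2)
    expect_lt(max(abs(tr$cY - sys$tot$cY)), 1e-9 * 2)
  }
})

test_that("trajectories converge to the equilibrium the solver predicts", {
  set.seed(23)
  for (i in 1:20) {
    sys <- random_system()
    s0 <- random_state(sys$tot)
    eq <- full_equilibrium(sys$rates, sys$tot)
    # step chosen well inside the stability limit of the fastest mode
    rate_scale <- max(unlist(sys$rates[c("k1", "k3")])) *
      max(sys$tot$cA, sys$tot$cX, sys$tot$cY) +
      max(unlist(sys$rates[c("k2", "k4")]))
    dt <- 0.2 / rate_scale
    tr <- integrate_mixture(s0, sys$rates, dt = dt,
                            n_steps = ceiling(400 * rate_scale / 0.2),
                            record_every = 1e4)
    fin <- final_state(tr)
    expect_lt(max(abs(unlist(fin) - unlist(eq$state))), 1e-6)
  }
})

test_that("the integrator is reproducible under a seed", {
  s0 <- state_from_free(7, 24.45, table1_totals())
  f <- forcing_jump_noise(0.2, -0.075, 0.075)
  t1 <- integrate_mixture(s0, table1_rates(), f, dt = 1e-3, n_steps = 500,
                          seed = 99)
  t2 <- integrate_mixture(s0, table1_rates(), f, dt = 1e-3, n_steps = 500,
                          seed = 99)
  t3 <- integrate_mixture(s0, table1_rates(), f, dt = 1e-3, n_steps = 500,
                          seed = 100)
  expect_identical(t1$A, t2$A)
  expect_false(identical(t1$A, t3$A))
  expect_identical(attr(t1, "seed"), 99)
})

test_that("jump noise perturbs the free agent as specified", {
  s <- mixture_state(1, 2, 3, 4, 5)
  set.seed(1)
  expect_identical(unlist(jump_noise_step(s, 0, -1, 1)), unlist(s))
  s2 <- jump_noise_step(s, 1, 0.05, 0.05)
  expect_equal(s2$A, 1.05)
  expect_equal(attr(s2, "applied"), 0.05)
  expect_equal(totals_of(s2)$cA, totals_of(s)$cA + 0.05)
  # a deep negative draw clips the agent at zero
  s3 <- jump_noise_step(mixture_state(0.01, 2, 3, 4, 5), 1, -1, -1)
  expect_equal(s3$A, 0)
  expect_equal(attr(s3, "applied"), -0.01)
})

test_that("relaxation after a jump shifts the equilibrium by about delta/beta", {
  eq <- full_equilibrium(table1_rates(), table1_totals())
  delta <- 0.075
  bumped <- mixture_state(eq$state$A + delta, eq$state$X, eq$state$Y,
                          eq$state$AX, eq$state$XY)
  tr <- integrate_mixture(bumped, table1_rates(), dt = 1e-3, n_steps = 20000,
                          record_every = 1000)
  shift <- final_state(tr)$A - eq$x
  expect_equal(shift, delta / eq$beta, tolerance = 0.2)
})

test_that("the Lyapunov function vanishes only at equilibrium and decreases", {
  eq <- full_equilibrium(table1_rates(), table1_totals())
  expect_equal(lyapunov_value(eq$state, eq, table1_rates()), 0)
  expect_equal(lyapunov_derivative(eq$state, eq, table1_rates()), 0)
  s0 <- state_from_free(7, 24.45, table1_totals())
  expect_gt(lyapunov_value(s0, eq, table1_rates()), 0)
  tr <- integrate_mixture(s0, table1_rates(), dt = 1e-3, n_steps = 3000,
                          equilibrium_ref = eq)
  expect_true(all(diff(tr$V) <= 1e-12 * max(tr$V)))
})

test_that("the closed-form Lyapunov derivative is negative off equilibrium", {
  set.seed(33)
  sys <- random_system()
  eq <- full_equilibrium(sys$rates, sys$tot)
  for (i in 1:100) {
    st <- random_state(sys$tot)
    off <- abs(st$A - eq$x) > 1e-9 || abs(st$Y - eq$state$Y) > 1e-9
    if (off) expect_lt(lyapunov_derivative(st, eq, sys$rates), 0)
  }
})

test_that("a state with foreign totals is rejected by the Lyapunov functions", {
  eq <- full_equilibrium(table1_rates(), table1_totals())
  alien <- state_from_free(3, 1, totals(5, 40, 2))
  expect_error(lyapunov_value(alien, eq, table1_rates()), "totals")
  expect_error(lyapunov_derivative(alien, eq, table1_rates()), "totals")
})

test_that("uncontrolled self-replication diverges and is reported cleanly", {
  r <- table1_rates()
  s0 <- mixture_state(0.1, 0, 0, 0, 0)
  tr <- integrate_mixture(s0, r, forcing_replication(1, 0.01),
                          dt = 1e-3, n_steps = 5e4, record_every = 100)
  expect_true(diverged(tr))
  expect_true(is.finite(attr(tr, "divergence_step")))
  expect_gt(max(tr$A), 10 * 0.1)
})

test_that("a steeper ramp is buffered better by more inhibitor", {
  # falling disturbance at the set point x = 10: with anti-inhibitors and a
  # larger inhibitor pool the excursion from the set point shrinks
  r <- rate_constants(1, 1, 1, 1)
  excursion <- function(cX) {
    des <- design_concentrations(r, cA = 100, target_x = 10, cX = cX)
    eq <- full_equilibrium(r, des)
    tr <- integrate_mixture(eq$state, r, forcing_ramp_noise(-0.5),
                            dt = 1e-3, n_steps = 5000, record_every = 50)
    max(abs(tr$A - 10))
  }
  devs <- vapply(c(99, 300, 1000), excursion, numeric(1))
  expect_true(all(diff(devs) < 0))
})
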