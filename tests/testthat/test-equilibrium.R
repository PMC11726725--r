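# Central finite-difference estimate of beta = (dx/dcA)^{-1}: the oracle for
# the closed-form capacity expressions.
fd_beta <- function(x_of_cA, cA, h = 1e-5 * cA) {
  (2 * h) / (x_of_cA(cA + h) - x_of_cA(cA - h))
}

test_that("inhibitor-only equilibrium solves the worked set point", {
  eq <- simple_equilibrium(cA = 100, cX = 99, K = 1)
  expect_equal(eq$x, 10, tolerance = 1e-12)
  expect_equal(eq$eAX, 90)
  expect_equal(eq$eX, 9)
  expect_gt(eq$discriminant, 0)
})

test_that("without inhibitor the agent stays fully free", {
  expect_equal(simple_equilibrium(cA = 3.7, cX = 0, K = 0.2)$x, 3.7)
  expect_equal(simple_equilibrium(cA = 3.7, cX = 0, K = 0.2)$beta, 1)
})

test_that("the quadratic root lies in (0, cA) and satisfies the equation", {
  set.seed(21)
  for (i in 1:50) {
    cA <- runif(1, 0.1, 50); cX <- runif(1, 0.01, 100); K <- runif(1, 0.01, 10)
    x <- simple_equilibrium(cA, cX, K)$x
    expect_gt(x, 0)
    expect_lt(x, cA)
    expect_equal(x^2 + (cX - cA + K) * x - K * cA, 0,
                 tolerance = 1e-10 * max(1, K * cA))
  }
})

test_that("simple capacity matches its closed form and bounds", {
  expect_equal(simple_capacity(10, 100, 1), 200 / 110)
  # beta -> 1 as x -> cA
  expect_equal(simple_capacity(100 * (1 - 1e-9), 100, 1), 1, tolerance = 1e-6)
  expect_error(simple_capacity(100, 100, 1), "inside")
})

test_that("simple capacity equals the reciprocal sensitivity to cA", {
  set.seed(31)
  for (i in 1:20) {
    cA <- runif(1, 1, 50); cX <- runif(1, 0.1, 100); K <- runif(1, 0.05, 5)
    eq <- simple_equilibrium(cA, cX, K)
    beta_fd <- fd_beta(function(a) simple_equilibrium(a, cX, K)$x, cA)
    expect_equal(eq$beta, beta_fd, tolerance = 1e-4)
    expect_gt(eq$beta, 1)
    expect_lt(eq$beta, cA / eq$x)
  }
})

test_that("required inhibitor total inverts the simple equilibrium", {
  expect_equal(simple_required_cX(10, cA = 100, K = 1), 99)
  # cX -> 0 as the target approaches the uninhibited level
  expect_lt(simple_required_cX(100 * (1 - 1e-9), cA = 100, K = 1), 1e-6)
  set.seed(41)
  for (i in 1:50) {
    cA <- runif(1, 0.5, 50); K <- runif(1, 0.05, 5)
    target <- runif(1, 0.02, 0.98) * cA
    cX <- simple_required_cX(target, cA, K)
    expect_gt(cX, 0)
    expect_equal(simple_equilibrium(cA, cX, K)$x, target, tolerance = 1e-10)
  }
})

test_that("cubic coefficients match hand evaluation and their identities", {
  co <- cubic_coefficients(K = 1, k = 1, cA = 7, cX = 100, cY = 24.45)
  expect_equal(co$a, 0)
  expect_equal(co$b, 31.45)
  expect_equal(co$c, 486.85)
  expect_equal(co$d, -49)
  set.seed(51)
  for (i in 1:30) {
    K <- runif(1, 0.05, 5); k <- runif(1, 0.05, 5)
    cA <- runif(1, 0.5, 20); cX <- runif(1, 0, 50); cY <- runif(1, 0, 50)
    co <- cubic_coefficients(K, k, cA, cX, cY)
    expect_equal(co$b + cA * co$e, (k - K) * (cX + K) + K * cY)
    expect_equal(co$c + cA * co$f, K * cA^2)
    expect_equal(co$d + cA * co$g, K^2 * cA^2)
    expect_lt(co$d, 0)
    expect_gt(co$g, 0)
    # equal dissociation constants collapse the cubic
    expect_equal(cubic_coefficients(K, K, cA, cX, cY)$a, 0)
  }
})

test_that("full equilibrium solves the published spreadsheet set point", {
  eq <- full_equilibrium(table1_rates(), table1_totals())
  expect_equal(eq$x, 0.1, tolerance = 1e-3)
  expect_true(all(unlist(eq$state) >= 0))
  tot <- totals_of(eq$state)
  expect_equal(tot$cA, 7, tolerance = 1e-9)
  expect_equal(tot$cX, 100, tolerance = 1e-9)
  expect_equal(tot$cY, 24.45, tolerance = 1e-9)
})

test_that("no inhibitor leaves the agent free; no anti-inhibitor reduces the model", {
  r <- rate_constants(2, 1, 3, 2)
  eq0 <- full_equilibrium(r, totals(cA = 5, cX = 0, cY = 3))
  expect_equal(eq0$x, 5)
  expect_equal(eq0$state$AX, 0)
  expect_equal(eq0$state$XY, 0)
  expect_equal(eq0$state$Y, 3)
  # cY = 0: the full model must agree with the inhibitor-only quadratic,
  # whatever the XY reaction constants are
  set.seed(61)
  for (i in 1:20) {
    k1 <- runif(1, 0.2, 3); k2 <- runif(1, 0.2, 3)
    k3 <- runif(1, 0.2, 3); k4 <- runif(1, 0.2, 3)
    cA <- runif(1, 0.5, 20); cX <- runif(1, 0.1, 40)
    full <- full_equilibrium(rate_constants(k1, k2, k3, k4),
                             totals(cA, cX, 0))
    simple <- simple_equilibrium(cA, cX, k2 / k1)
    expect_equal(full$x, simple$x, tolerance = 1e-10)
  }
})

test_that("the equilibrium cubic changes sign exactly once on (0, cA)", {
  set.seed(71)
  for (i in 1:20) {
    sys <- random_system()
    kk <- dissociation_constants(sys$rates)
    co <- cubic_coefficients(kk$K, kk$k, sys$tot$cA, sys$tot$cX, sys$tot$cY)
    xs <- seq(0, sys$tot$cA, length.out = 1e4)
    L <- ((co$a * xs + co$b) * xs + co$c) * xs + co$d
    expect_equal(sum(diff(sign(L[L != 0])) != 0), 1)
  }
})

test_that("full capacity matches the reciprocal-sensitivity oracle and bounds", {
  set.seed(81)
  for (i in 1:20) {
    sys <- random_system()
    eq <- full_equilibrium(sys$rates, sys$tot)
    beta_fd <- fd_beta(function(a) {
      full_equilibrium(sys$rates, totals(a, sys$tot$cX, sys$tot$cY))$x
    }, sys$tot$cA)
    expect_equal(eq$beta, beta_fd, tolerance = 1e-4)
    expect_gt(eq$beta, 0)
    expect_lt(eq$beta, sys$tot$cA / eq$x)
  }
})

test_that("full capacity reduces to the simple-model capacity when cY = 0", {
  r <- rate_constants(1, 1, 1, 1)
  expect_equal(full_capacity(r, totals(100, 99, 0)),
               simple_capacity(10, 100, 1), tolerance = 1e-10)
})

test_that("capacity diverges as the inhibitor total drives x to zero", {
  r <- rate_constants(1, 1, 1, 1)
  cX <- c(99, 1e3, 1e4, 1e5)
  betas <- vapply(cX, function(v) full_capacity(r, totals(100, v, 0)),
                  numeric(1))
  xs <- vapply(cX, function(v)
    full_equilibrium(r, totals(100, v, 0))$x, numeric(1))
  expect_true(all(diff(xs) < 0))
  expect_true(all(diff(betas) > 0))
  expect_gt(max(betas), 1e3)
})

test_that("design coefficients are positive and reduce to the simple formula", {
  set.seed(91)
  for (i in 1:20) {
    K <- runif(1, 0.05, 5); k <- runif(1, 0.05, 5); cA <- runif(1, 0.5, 20)
    x <- runif(1, 0.02, 0.98) * cA
    co <- design_coefficients(K, k, cA, x)
    expect_gt(co$S, 0)
    expect_gt(co$T, 0)
  }
  # with no anti-inhibitor the design relation is the simple-model inverse
  des <- design_concentrations(rate_constants(1, 1, 1, 1),
                               cA = 100, target_x = 10, cY = 0)
  expect_equal(des$cX, 99, tolerance = 1e-12)
})

test_that("designed totals reproduce the published anti-inhibitor level", {
  des <- design_concentrations(table1_rates(), cA = 7, target_x = 0.1,
                               cX = 100)
  expect_equal(des$cY, 24.45, tolerance = 0.01)
})

test_that("designed totals round-trip through the equilibrium solver", {
  set.seed(101)
  for (i in 1:25) {
    r <- rate_constants(runif(1, 0.2, 3), runif(1, 0.2, 3),
                        runif(1, 0.2, 3), runif(1, 0.2, 3))
    cA <- runif(1, 0.5, 20)
    x <- runif(1, 0.05, 0.95) * cA
    des <- if (i %% 2 == 0)
      design_concentrations(r, cA, x, cX = runif(1, 20, 60))
    else
      design_concentrations(r, cA, x, cY = runif(1, 0, 5))
    eq <- full_equilibrium(r, des)
    expect_equal(eq$x, x, tolerance = 1e-8)
  }
})

test_that("infeasible or ambiguous design requests are signalled", {
  r <- rate_constants(1, 1, 1, 1)
  # a tiny fixed cX cannot support a low set point (would need cY < 0)
  expect_error(design_concentrations(r, cA = 7, target_x = 6, cX = 0.1),
               "infeasible")
  expect_error(design_concentrations(r, 7, 0.1, cX = 100, cY = 24.45),
               "exactly one")
  # neutralising more inhibitor with anti-inhibitor demands more inhibitor
  cXs <- vapply(c(0, 5, 20), function(cy)
    design_concentrations(r, cA = 7, target_x = 0.5, cY = cy)$cX, numeric(1))
  expect_true(all(diff(cXs) > 0))
})
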