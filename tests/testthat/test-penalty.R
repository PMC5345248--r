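# Penalty functions, derivatives and thresholding operators.

test_that("penalty values match closed forms and boundary behaviour", {
  lasso <- penalty_spec("lasso", lambda = 2)
  expect_equal(penalty_value(1.5, lasso), 3.0)
  scad <- penalty_spec("scad", lambda = 1)  # a = 3.7
  mcp <- penalty_spec("mcp", lambda = 1)    # a = 3
  enet <- penalty_spec("elastic_net", lambda = 2, alpha = 0.25)
  for (spec in list(lasso, scad, mcp, enet)) {
    expect_identical(penalty_value(0, spec), 0)
  }
  # SCAD/MCP plateau at (a+1) lambda^2 / 2 and a lambda^2 / 2 beyond a*lambda
  expect_equal(penalty_value(10, scad), (3.7 + 1) * 1 / 2)  # 2.35
  expect_equal(penalty_value(10, scad), penalty_value(3.7, scad))
  expect_equal(penalty_value(10, mcp), 3 / 2)
  # elastic net combines L1 and L2 parts
  expect_equal(penalty_value(2, enet), 2 * (0.25 * 2 + 0.75 * 4))
  expect_error(penalty_value(-1, lasso), "non-negative")
})

test_that("penalty derivatives match the defining piecewise forms", {
  scad <- penalty_spec("scad", lambda = 1)
  expect_equal(penalty_derivative(0.5, scad), 1)   # flat at lambda
  expect_equal(penalty_derivative(5, scad), 0)     # beyond a*lambda
  expect_equal(penalty_derivative(2, scad), (3.7 - 2) / 2.7)
  mcp <- penalty_spec("mcp", lambda = 1, a = 3)
  expect_equal(penalty_derivative(0, mcp), 1)      # lambda at the origin
  expect_equal(penalty_derivative(1.5, mcp), (3 - 1.5) / 3)
  expect_equal(penalty_derivative(4, mcp), 0)
})

test_that("penalty value is the integral of the derivative", {
  specs <- list(
    penalty_spec("lasso", lambda = 0.8),
    penalty_spec("elastic_net", lambda = 0.8, alpha = 0.4),
    penalty_spec("scad", lambda = 0.7, a = 3.7),
    penalty_spec("mcp", lambda = 0.7, a = 3)
  )
  for (spec in specs) {
    for (theta in c(0.3, 0.7, 1.5, 2.4, 5)) {
      val <- stats::integrate(function(t) penalty_derivative(t, spec),
                              0, theta, rel.tol = 1e-10)$value
      expect_equal(penalty_value(theta, spec), val, tolerance = 1e-6)
    }
  }
})

test_that("thresholding operators solve the univariate problem", {
  # fixed examples
  expect_equal(threshold(0.5, penalty_spec("lasso", lambda = 1)), 0)
  expect_equal(threshold(10, penalty_spec("scad", lambda = 1)), 10)
  mcp <- penalty_spec("mcp", lambda = 1, a = 3)
  expect_lt(abs(threshold(2, mcp) - grid_threshold(2, mcp)), 1e-4)
  expect_equal(threshold(2, mcp), 1.5, tolerance = 1e-4)
  # random instances vs the brute-force grid minimizer
  set.seed(99)
  for (i in 1:200) {
    z <- runif(1, -4, 4)
    lam <- runif(1, 0.01, 1.5)
    spec <- switch(sample(4, 1),
      penalty_spec("lasso", lambda = lam),
      penalty_spec("elastic_net", lambda = lam, alpha = runif(1, 0.1, 1)),
      penalty_spec("scad", lambda = lam, a = runif(1, 2.2, 5)),
      penalty_spec("mcp", lambda = lam, a = runif(1, 1.2, 5))
    )
    expect_lt(abs(threshold(z, spec) - grid_threshold(z, spec)), 1e-4)
  }
})

test_that("thresholds are odd, shrink, and are unbiased beyond a*lambda", {
  set.seed(7)
  zs <- runif(50, -6, 6)
  specs <- list(
    penalty_spec("lasso", lambda = 0.9),
    penalty_spec("elastic_net", lambda = 0.9, alpha = 0.6),
    penalty_spec("scad", lambda = 0.9),
    penalty_spec("mcp", lambda = 0.9)
  )
  for (spec in specs) {
    expect_equal(threshold(zs, spec), -threshold(-zs, spec))
    expect_true(all(abs(threshold(zs, spec)) <= abs(zs) + 1e-12))
  }
  # identity far out for the nonconvex penalties, persistent lasso bias
  for (fam in c("scad", "mcp")) {
    spec <- penalty_spec(fam, lambda = 0.9)
    z <- 10 * spec$a * spec$lambda
    expect_identical(threshold(z, spec), z)
  }
  lasso <- penalty_spec("lasso", lambda = 0.9)
  z <- 10 * 3.7 * 0.9
  expect_lt(threshold(z, lasso), z)
})

test_that("spec validation enforces the parameter domains", {
  expect_error(penalty_spec("lasso", lambda = -1), "non-negative")
  expect_error(penalty_spec("scad", lambda = 1, a = 2), "a > 2")
  expect_error(penalty_spec("mcp", lambda = 1, a = 1), "a > 1")
  expect_error(penalty_spec("elastic_net", lambda = 1, alpha = 0), "alpha")
  expect_error(penalty_spec("adaptive_lasso", lambda = 1), "weights")
  expect_error(penalty_spec("adaptive_lasso", lambda = 1,
                            weights = c(-1, 1)), "non-negative")
  expect_error(threshold(NaN, penalty_spec("lasso", lambda = 1)), "finite")
  # infinite adaptive weight excludes the coordinate
  w <- penalty_spec("adaptive_lasso", lambda = 0.5, weights = c(Inf, 1))
  expect_identical(threshold(3, w, weight = Inf), 0)
})
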