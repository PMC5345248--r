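# Coordinate-descent solver, OLS, adaptive lasso, stepwise baseline.

test_that("lambda = 0 recovers OLS and huge lambda empties the model", {
  d <- make_data(80, 5, beta = c(1, -2, 0.5, 0, 0), seed = 11)
  ols <- coef(lm(y ~ ., data = d))
  for (fam in c("lasso", "scad", "mcp", "elastic_net")) {
    f <- fit_penalized(d, "y", family = fam, lambda = 0, tol = 1e-12)
    expect_equal(unname(f$beta), unname(ols[-1]), tolerance = 1e-8)
    expect_equal(f$intercept, unname(ols[1]), tolerance = 1e-8)
    expect_length(f$selected, 5)
  }
  f <- fit_penalized(d, "y", family = "lasso", lambda = 1e6)
  expect_identical(unname(f$beta), rep(0, 5))
  expect_length(f$selected, 0)
  expect_equal(f$intercept, mean(d$y))
})

test_that("on an orthonormal design every family reduces to its threshold", {
  n <- 50
  X <- make_orthonormal_data(n, 3, seed = 4)
  set.seed(5)
  y <- X %*% c(1.2, -0.4, 0) + rnorm(n)
  d <- as.data.frame(X)
  d$y <- as.numeric(y)
  z <- as.numeric(crossprod(X, y - mean(y))) / n
  lam <- 0.3
  for (fam in c("lasso", "elastic_net", "scad", "mcp")) {
    f <- fit_penalized(d, "y", family = fam, lambda = lam, tol = 1e-12)
    spec <- penalty_spec(fam, lambda = lam)
    # original scale == standardized scale here (columns already unit sd)
    expect_equal(unname(f$beta), threshold(z, spec), tolerance = 1e-8,
                 label = fam)
  }
})

test_that("lasso agrees with glmnet at matched lambda", {
  skip_if_not_installed("glmnet")
  d <- make_data(100, 6, beta = c(2, -1, 0.5, 0, 0, 0), seed = 21)
  X <- as.matrix(d[paste0("x", 1:6)])
  for (lam in c(0.05, 0.2, 0.6)) {
    f <- fit_penalized(d, "y", family = "lasso", lambda = lam, tol = 1e-12)
    g <- glmnet::glmnet(X, d$y, alpha = 1, lambda = lam,
                        standardize = TRUE, thresh = 1e-14)
    expect_equal(unname(f$beta), as.numeric(g$beta), tolerance = 1e-5)
    expect_equal(f$intercept, as.numeric(g$a0), tolerance = 1e-5)
  }
})

test_that("p = 2 lasso matches a nested-grid brute-force minimizer", {
  set.seed(31)
  for (i in 1:10) {
    d <- make_data(40, 2, beta = runif(2, -2, 2), sd = runif(1, 0.3, 1.5))
    s <- std_xy(d)
    lam <- runif(1, 0.02, 0.8)
    f <- fit_penalized(d, "y", family = "lasso", lambda = lam, tol = 1e-12)
    brute <- grid_lasso_p2(s$Xs, s$yc, lam)
    expect_equal(unname(f$beta * s$xsd), brute, tolerance = 1e-3)
  }
})

test_that("descent never increases the objective and solutions are fixed points", {
  d <- make_data(60, 8, beta = c(1.5, -1, rep(0, 6)), seed = 41)
  s <- std_xy(d)
  set.seed(42)
  for (fam in c("lasso", "elastic_net", "scad", "mcp")) {
    spec <- penalty_spec(fam, lambda = 0.25)
    init <- runif(8, -2, 2)
    f <- fit_penalized(d, "y", family = fam, lambda = 0.25,
                       init = init / s$xsd)
    obj_init <- pls_objective(s$Xs, s$yc, init, spec)
    obj_fit <- pls_objective(s$Xs, s$yc, f$beta * s$xsd, spec)
    expect_lte(obj_fit, obj_init + 1e-12)
    # warm-started refit at the same lambda does not move
    f2 <- fit_penalized(d, "y", family = fam, lambda = 0.25, init = f$beta)
    expect_equal(f2$beta, f$beta, tolerance = 1e-6)
    expect_lte(f2$n_sweeps, 3)
  }
})

test_that("fits carry exact zeros and consistent bookkeeping", {
  d <- make_data(100, 10, beta = c(2, rep(0, 9)), seed = 51)
  f <- fit_penalized(d, "y", family = "scad", lambda = 0.4)
  expect_identical(f$selected, unname(which(f$beta != 0)))
  expect_true(f$converged)
  expect_lte(f$n_sweeps, 10000)
  expect_true(is.finite(f$bic))
  # predictions identical computed on either scale
  s <- std_xy(d)
  pred_std <- as.numeric(s$Xs %*% (f$beta * s$xsd)) + s$ybar
  expect_equal(predict(f, d), pred_std, tolerance = 1e-10)
  expect_error(
    fit_penalized(dplyr::mutate(d, x1 = 1), "y", "lasso", lambda = 0.1),
    "constant"
  )
})

test_that("OLS fitter handles supports, empty models and rank deficiency", {
  d <- make_data(20, 3, seed = 61)
  d$y <- 2 * d$x1
  expect_warning(f <- fit_ols(d, "y", support = 1), "floored")
  expect_equal(unname(f$beta), c(2, 0, 0), tolerance = 1e-12)
  expect_equal(f$rss, 0, tolerance = 1e-18)
  f0 <- fit_ols(d, "y", support = integer(0))
  expect_equal(f0$intercept, mean(d$y))
  expect_identical(unname(f0$beta), rep(0, 3))
  # full OLS equals the normal-equations solution
  d2 <- make_data(20, 3, beta = c(1, 2, 3), seed = 62)
  X1 <- cbind(1, as.matrix(d2[paste0("x", 1:3)]))
  ne <- solve(crossprod(X1), crossprod(X1, d2$y))
  ff <- fit_ols(d2, "y")
  expect_equal(c(ff$intercept, unname(ff$beta)), as.numeric(ne),
               tolerance = 1e-10)
  d3 <- d2
  d3$x3 <- d3$x1
  expect_error(fit_ols(d3, "y"), "rank")
})

test_that("adaptive lasso weights act as documented", {
  n <- 50
  X <- make_orthonormal_data(n, 3, seed = 71)
  set.seed(72)
  y <- X %*% c(20, -0.8, 0.1) + rnorm(n, sd = 0.4)
  d <- as.data.frame(X)
  d$y <- as.numeric(y)
  # unit weights: adaptive == plain lasso at the same lambda
  lam <- 0.2
  fa <- fit_penalized(d, "y", "adaptive_lasso", lambda = lam,
                      weights = rep(1, 3), tol = 1e-12)
  fl <- fit_penalized(d, "y", "lasso", lambda = lam, tol = 1e-12)
  expect_equal(fa$beta, fl$beta, tolerance = 1e-10)
  # orthonormal design, gamma = 1: coordinate fit = soft(z, lambda/|pilot_j|)
  z <- as.numeric(crossprod(X, y - mean(y))) / n  # = OLS pilot here
  f <- fit_adaptive_lasso(d, "y", lambda = lam, gamma = 1, tol = 1e-12)
  expect_equal(unname(f$beta),
               sign(z) * pmax(abs(z) - lam / abs(z), 0), tolerance = 1e-7)
  # near-zero weight leaves a huge coordinate essentially unpenalized
  expect_equal(unname(f$beta[1]), z[1], tolerance = 1e-2)
  # zero pilot coefficient -> infinite weight -> excluded even at lambda 0
  fz <- fit_penalized(d, "y", "adaptive_lasso", lambda = 0,
                      weights = c(Inf, 1, 1))
  expect_identical(unname(fz$beta[1]), 0)
})

test_that("stepwise selects dominant signals and respects entry order", {
  d <- make_data(200, 5, beta = c(5, 0, 0, 0, 0), sd = 0.5, seed = 81)
  f <- fit_stepwise(d, "y")
  expect_true("x1" %in% selected_vars(f))
  expect_identical(f$family, "stepwise")
  # forward path on orthogonal predictors follows |correlation with y|
  X <- make_orthonormal_data(120, 3, seed = 82)
  set.seed(83)
  y <- X %*% c(0.5, 2, -1) + rnorm(120, sd = 0.3)
  d2 <- as.data.frame(X)
  d2$y <- as.numeric(y)
  f2 <- fit_stepwise(d2, "y")
  steps <- attr(f2, "steps")
  added <- steps$term[steps$action == "add"]
  ord <- order(abs(cor(X, y)), decreasing = TRUE)
  expect_identical(added, paste0("x", ord))
  # p-value mode validates thresholds and also finds the signal
  expect_error(fit_stepwise(d, "y", "pvalue", p_enter = 0.2, p_remove = 0.1),
               "p_enter")
  f3 <- fit_stepwise(d, "y", "pvalue")
  expect_true("x1" %in% selected_vars(f3))
})

test_that("stepwise under a pure-noise null mostly selects nothing", {
  empty <- vapply(1:60, function(s) {
    d <- make_data(300, 10, seed = 4000 + s)
    length(fit_stepwise(d, "y")$selected) == 0L
  }, logical(1))
  expect_gte(mean(empty), 0.8)
})
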