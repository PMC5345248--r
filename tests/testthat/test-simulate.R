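# Simulation-study generator and study runner.

test_that("block AR(1) covariance has the stated entries and is PD", {
  s <- build_covariance(33, 8, 0.5)
  expect_equal(s[1, 2], 0.5)
  expect_equal(s[1, 3], 0.25)
  expect_equal(s[1, 9], 0)
  expect_identical(diag(s), rep(1, 33))
  expect_identical(s, t(s))
  expect_identical(build_covariance(5, 3, 0), diag(5))
  expect_gt(min(eigen(build_covariance(33, 8, 0.8))$values), 0)
  expect_error(build_covariance(5, 3, 1), "rho")
  expect_error(build_covariance(5, 7, 0.5), "block")
})

test_that("default truth has 7 nonzero effects, two in the block", {
  bt <- default_beta_true()
  expect_length(bt, 33)
  expect_identical(sum(bt != 0), 7L)
  expect_identical(which(bt != 0), c(3L, 4L, 9L, 12L, 17L, 22L, 28L))
  expect_true(all(which(bt != 0)[1:2] <= 8))
})

test_that("dataset generation calibrates the noise to the requested SNR", {
  # beta' Sigma beta = 3 with snr 3 gives sigma2 = 1
  bt <- c(sqrt(3), rep(0, 9))
  cfg <- sim_config(n = 60, p = 10, corr_block_size = 0, rho = 0, snr = 3,
                    beta_true = bt, n_reps = 1)
  sim <- generate_dataset(cfg, 1)
  expect_equal(sim$sigma2, 1)
  # empirical SNR over a large draw is within 5% of the target
  cfg2 <- sim_config(n = 20000, p = 10, corr_block_size = 4, rho = 0.5,
                     snr = 2, beta_true = c(1, -0.5, 0.3, 0, 0.4, rep(0, 5)))
  sim2 <- generate_dataset(cfg2, 7)
  X <- as.matrix(sim2$data[, 1:10])
  signal <- as.numeric(X %*% cfg2$beta_true)
  noise <- sim2$data$y - signal
  expect_equal(var(signal) / var(noise), 2, tolerance = 0.05)
  # determinism: identical replicate seed, identical bytes
  expect_identical(generate_dataset(cfg2, 3)$data,
                   generate_dataset(cfg2, 3)$data)
  expect_false(identical(generate_dataset(cfg2, 3)$data,
                         generate_dataset(cfg2, 4)$data))
  expect_error(
    generate_dataset(sim_config(n = 60, p = 10, beta_true = rep(0, 10)), 1),
    "signal"
  )
})

test_that("run_study aggregates replicate metrics per method and cell", {
  cfg <- sim_config(n = 150, p = 10, corr_block_size = 4, rho = 0.5,
                    snr = 3, beta_true = c(1, 0, 0.6, 0, 0, -0.5, rep(0, 4)),
                    n_reps = 5, seed = 9,
                    methods = c("lasso", "oracle", "ols"), n_lambda = 40)
  st <- run_study(cfg)
  expect_s3_class(st, "pensel_study")
  expect_identical(nrow(st$summary), 3L)
  expect_identical(nrow(st$replicates), 15L)
  # oracle is perfect on selection by construction
  orc <- st$summary[st$summary$method == "oracle", ]
  expect_identical(c(orc$tp, orc$fp), c(3, 0))
  # full OLS is the RME reference: identically 1
  ols_reps <- st$replicates[st$replicates$method == "ols", ]
  expect_identical(ols_reps$rme, rep(1, 5))
  # replicate-level invariants
  expect_true(all(st$replicates$tp >= 0 & st$replicates$tp <= 3))
  expect_true(all(st$replicates$fp >= 0 & st$replicates$fp <= 7))
  expect_true(all(st$replicates$tp + st$replicates$fp <= 10))
  expect_true(all(st$replicates$rme >= 0))
  # reproducible bit-for-bit under the same config
  st2 <- run_study(cfg)
  expect_identical(st$replicates, st2$replicates)
  # single replicate: MRME is that replicate's RME x 100
  cfg1 <- sim_config(n = 150, p = 10, corr_block_size = 4, rho = 0.5,
                     snr = 3, beta_true = cfg$beta_true, n_reps = 1,
                     seed = 9, methods = "oracle")
  st1 <- run_study(cfg1)
  expect_equal(st1$summary$mrme, st1$replicates$rme[1] * 100)
})

test_that("run_study crosses rho and snr grids", {
  cfg <- sim_config(n = 100, p = 8, corr_block_size = 4,
                    rho = c(0.2, 0.8), snr = c(1, 5),
                    beta_true = c(0.8, 0, -0.6, rep(0, 5)),
                    n_reps = 2, seed = 5, methods = "oracle")
  st <- run_study(cfg)
  expect_identical(nrow(st$summary), 4L)
  expect_identical(
    dplyr::distinct(st$summary[c("rho", "snr")]),
    tidyr::crossing(rho = c(0.2, 0.8), snr = c(1, 5))[c("rho", "snr")]
  )
})

test_that("oracle relative error is insensitive to the truth's magnitude", {
  base <- sim_config(n = 200, p = 12, corr_block_size = 4, rho = 0.5,
                     snr = 2, beta_true = c(0.5, -0.3, 0, 0.4, rep(0, 8)),
                     n_reps = 60, seed = 20, methods = "oracle")
  doubled <- base
  doubled$beta_true <- 2 * base$beta_true
  m1 <- run_study(base)$summary$mrme
  m2 <- run_study(doubled)$summary$mrme
  expect_lt(abs(m1 - m2), 2)
})
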