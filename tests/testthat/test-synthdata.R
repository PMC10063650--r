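test_that("covariance matrices have the stated structure and are SPD", {
  I3 <- make_covariance(3, "identity")
  expect_equal(I3, diag(3))

  S <- make_covariance(3, "toeplitz", 0.9)
  expect_equal(S[1, 2], 0.9)
  expect_equal(S[1, 3], 0.81)
  expect_equal(S, t(S))

  for (p in c(10, 100)) {
    ev <- eigen(make_covariance(p, "toeplitz", 0.9), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }

  expect_error(make_covariance(0, "identity"))
  expect_error(make_covariance(3, "toeplitz", 1))
})

test_that("coefficient draws are sparse with the stated uniform support", {
  co <- wstabsel:::with_seed(1, draw_coefficients(10, 10, c(0.5, 1.5)))
  expect_true(all(co$beta >= 0.5 & co$beta <= 1.5))
  expect_equal(co$signal_idx, 1:10)

  co <- wstabsel:::with_seed(2, draw_coefficients(500, 10, c(0.5, 1.5)))
  expect_equal(sum(co$beta == 0), 490)
  expect_length(co$signal_idx, 10)

  expect_error(draw_coefficients(5, 6))

  # symmetric support: nonzero draws average to zero over many seeds
  nz <- unlist(lapply(1:200, function(s)
    wstabsel:::with_seed(s, draw_coefficients(20, 20, c(-3, 3)))$beta))
  expect_lt(abs(mean(nz)), 0.1)
})

test_that("intercept calibration hits the target prevalence", {
  # zero coefficients: closed-form logit
  expect_equal(calibrate_intercept(numeric(10), NULL, 0.3), qlogis(0.3))
  # symmetric coefficient vector and 50% prevalence: intercept near zero
  b <- c(1.2, -1.2, 0.7, -0.7)
  expect_lt(abs(calibrate_intercept(b, diag(4), 0.5, seed = 3)), 0.05)
  # realized prevalence on a fresh draw matches a 10% target
  cfg <- scenario_config(n = 20000, p = 5, p_signal = 5,
                         beta_dist = c(0.5, 1.5), prevalence = 0.1, seed = 4)
  ds <- generate_dataset(cfg)
  expect_true(mean(ds$data$y) > 0.085 && mean(ds$data$y) < 0.115)
})

test_that("generated datasets honor shape, determinism and covariance", {
  cfg <- scenario_config(n = 200, p = 50, p_signal = 5, seed = 9)
  ds <- generate_dataset(cfg)
  expect_equal(dim(ds$data), c(200, 51))
  expect_true(all(ds$data$y %in% 0:1))
  expect_length(ds$signal_idx, 5)
  expect_equal(sum(ds$beta != 0), 5)

  ds2 <- generate_dataset(cfg)
  expect_identical(ds$data, ds2$data)

  # validation role: same true model, independent draws
  dv <- generate_dataset(cfg, role = "validation")
  expect_identical(dv$beta, ds$beta)
  expect_false(identical(dv$data$x1, ds$data$x1))
  expect_equal(dim(dv$data), dim(ds$data))

  # prevalence concentration at 50%
  cfg5 <- scenario_config(n = 500, p = 10, p_signal = 5,
                          beta_dist = c(-3, 3), prevalence = 0.5, seed = 21)
  expect_true(abs(mean(generate_dataset(cfg5)$data$y) - 0.5) < 0.1)

  # empirical column covariance of a big Toeplitz draw
  cfgT <- scenario_config(n = 20000, p = 5, p_signal = 1,
                          cov_structure = "toeplitz", seed = 13)
  Xb <- as.matrix(generate_dataset(cfgT)$data[, 1:5])
  expect_lt(max(abs(cov(Xb) - make_covariance(5, "toeplitz", 0.9))), 0.05)
})

test_that("realized prevalence across replicate datasets stays on target", {
  prev <- vapply(1:25, function(s) {
    cfg <- scenario_config(n = 400, p = 10, p_signal = 3,
                           beta_dist = c(0.5, 1.5), prevalence = 0.3, seed = s)
    mean(generate_dataset(cfg)$data$y)
  }, numeric(1))
  se <- sqrt(0.3 * 0.7 / 400) / sqrt(25)
  # mean realized rate within 3 SE of target (plus calibration slack)
  expect_lt(abs(mean(prev) - 0.3), 3 * se + 0.005)
})
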