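test_that("a dominant signal enters the path first in nearly every seed", {
  hits <- vapply(1:10, function(s) {
    d <- planted_xy(300, 20, signal = 7, beta = 3, seed = s)
    path <- fit_lasso_path(d$X, d$y)
    path$entry_order[1] == 7
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("degenerate designs leave the path well-formed", {
  # pure noise: path exists, entry order is a valid permutation prefix
  d <- planted_xy(100, 15, signal = integer(0), beta = 0, seed = 2)
  path <- fit_lasso_path(d$X, d$y)
  expect_true(all(path$entry_order %in% seq_len(15)))
  expect_false(any(duplicated(path$entry_order)))

  # duplicated column: no crash, still well-formed
  X2 <- cbind(d$X, x16 = d$X[, 1])
  path2 <- fit_lasso_path(X2, d$y)
  expect_false(any(duplicated(path2$entry_order)))

  # zero-variance column: dropped with a warning, never active
  X3 <- cbind(d$X, x16 = rep(1, 100))
  expect_warning(path3 <- fit_lasso_path(X3, d$y), "zero-variance")
  expect_false(16 %in% path3$entry_order)
  expect_true(16 %in% path3$dropped)

  expect_error(fit_lasso_path(d$X, rep(1, 100)), "both classes")
})

test_that("first_q_active takes the activation-order prefix", {
  d <- planted_xy(200, 12, signal = c(2, 5), beta = 2.5, seed = 3)
  path <- fit_lasso_path(d$X, d$y)
  expect_identical(first_q_active(path, 3), path$entry_order[1:3])
  expect_identical(first_q_active(path, 100), path$entry_order)
  expect_error(first_q_active(path, 0))
})

test_that("CV selection: 1se never larger than min, signals recovered, seeded", {
  sizes <- t(vapply(1:5, function(s) {
    d <- planted_xy(400, 40, signal = 1:5, beta = 2, seed = s)
    smin <- select_by_cv(d$X, d$y, "min", seed = s)
    s1se <- select_by_cv(d$X, d$y, "1se", seed = s)
    c(length(s1se$selected), length(smin$selected),
      all(1:5 %in% smin$selected))
  }, numeric(3)))
  expect_true(all(sizes[, 1] <= sizes[, 2]))
  expect_gte(sum(sizes[, 3]), 4)

  d <- planted_xy(200, 30, signal = 1:3, beta = 2, seed = 11)
  a <- select_by_cv(d$X, d$y, "min", seed = 42)
  b <- select_by_cv(d$X, d$y, "min", seed = 42)
  expect_identical(a$selected, b$selected)
  expect_identical(a$lambda, b$lambda)
})

test_that("unpenalized refits match a Newton oracle and screen correctly", {
  d <- planted_xy(150, 6, signal = 2, beta = 1.5, seed = 5)
  fit <- refit_logistic(d$X, d$y, c(2, 4))
  oracle <- newton_logistic(d$X[, c(2, 4)], d$y)
  expect_equal(unname(fit$coefficients), unname(oracle), tolerance = 1e-6)
  expect_false(fit$separation)
  expect_true(all(fit$wald_p >= 0 & fit$wald_p <= 1))

  # a strong signal is Wald-significant
  d2 <- planted_xy(500, 5, signal = 1, beta = 3, seed = 6)
  fit2 <- refit_logistic(d2$X, d2$y, 1:3)
  expect_lt(fit2$wald_p[1], 0.05)

  # empty subset: intercept-only model, fitted probabilities all mean(y)
  fit0 <- refit_logistic(d$X, d$y, integer(0))
  expect_equal(fit0$fitted_prob, rep(mean(d$y), 150))
  expect_length(fit0$wald_p, 0)
})

test_that("separation falls back to a flagged ridge-stabilized fit", {
  set.seed(7)
  X <- matrix(rnorm(80 * 3), 80, 3, dimnames = list(NULL, paste0("x", 1:3)))
  y <- as.integer(X[, 1] > 0)  # perfectly separable on x1
  expect_silent(fit <- refit_logistic(X, y, 1:2))
  expect_true(fit$separation)
  expect_true(all(is.finite(fit$coefficients)))
  expect_true(all(fit$fitted_prob > 0 & fit$fitted_prob < 1))
  expect_gt(auc_mw(fit$fitted_prob, y), 0.9)
})

test_that("null Wald p-values are approximately uniform", {
  pv <- vapply(1:200, function(s) {
    set.seed(s + 3000)
    X <- matrix(rnorm(120 * 2), 120, 2)
    y <- rbinom(120, 1, 0.5)
    refit_logistic(X, y, 1:2)$wald_p[1]
  }, numeric(1))
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})
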