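test_that("min-max rescaling maps AUCs to [0, 1] weights", {
  expect_equal(minmax_rescale(c(0.6, 0.8, 0.7)), c(0, 1, 0.5))
  expect_equal(minmax_rescale(c(0.7, 0.7, 0.7)), c(1, 1, 1))
  expect_equal(minmax_rescale(c(0.5, 1.0)), c(0, 1))
  expect_error(minmax_rescale(numeric(0)))
})

test_that("weighted frequencies are weighted sums with p_w over the union", {
  sc <- weighted_frequencies(list(2L, c(2L, 3L)), c(0.5, 1.0), p = 5)
  expect_equal(sc$A_w, c(0, 1.5, 1.0, 0, 0))
  expect_equal(sc$p_w, 2L)

  # a variable seen only in a zero-weight iteration scores 0 but counts in p_w
  sc2 <- weighted_frequencies(list(1L, c(1L, 2L), 3L), c(1, 1, 0), p = 4)
  expect_equal(sc2$A_w, c(2, 1, 0, 0))
  expect_equal(sc2$p_w, 3L)
  expect_identical(sc2$ever_selected, c(1L, 2L, 3L))

  expect_error(weighted_frequencies(list(1L), c(1, 2), p = 3))
})

test_that("the alpha threshold rule matches its definition and boundaries", {
  sc <- weighted_frequencies(list(1L, c(1L, 2L), 3L), c(1, 1, 0), p = 4)
  # threshold = (2 + 1 + 0) / 3 * alpha
  expect_identical(wss_threshold(sc, 1), c(1L, 2L))
  expect_identical(wss_threshold(sc, 0), c(1L, 2L, 3L))  # all ever-selected
  expect_identical(wss_threshold(sc, 100), integer(0))

  empty <- weighted_frequencies(list(integer(0)), 1, p = 3)
  expect_warning(out <- wss_threshold(empty, 1), "no variable")
  expect_identical(out, integer(0))
})

test_that("selection is antitone in alpha for arbitrary scores", {
  set.seed(42)
  for (rep in 1:20) {
    sets <- lapply(1:8, function(b) sort(sample.int(15, sample(0:5, 1))))
    w <- runif(8)
    sc <- weighted_frequencies(sets, w, p = 15)
    if (sc$p_w == 0) next
    alphas <- seq(0, 2, by = 0.25)
    sels <- lapply(alphas, function(a) wss_threshold(sc, a))
    for (k in seq_along(alphas)[-1]) {
      expect_true(all(sels[[k]] %in% sels[[k - 1]]))
    }
  }
})

test_that("streaming weighted frequencies equal a brute-force double loop", {
  set.seed(7)
  sets <- lapply(1:12, function(b) sort(sample.int(30, sample(0:6, 1))))
  w <- runif(12)
  sc <- weighted_frequencies(sets, w, p = 30)
  brute <- vapply(1:30, function(j)
    sum(vapply(1:12, function(b) w[b] * (j %in% sets[[b]]), numeric(1))),
    numeric(1))
  expect_identical(sc$A_w, brute)
})

test_that("one iteration screens the intersection and scores it by AUC", {
  d <- planted_xy(300, 20, signal = c(2, 5, 9), beta = 3, seed = 8)
  pair <- complementary_pairs(300, 1, seed = 1)[[1]]
  rec <- wss_iteration(d$X, d$y, pair, seed = 2)
  expect_true(all(rec$refit_set %in% rec$intersection))
  expect_true(all(rec$intersection %in% rec$support_half1))
  expect_true(all(rec$intersection %in% rec$support_half2))
  expect_true(all(c(2, 5, 9) %in% rec$refit_set))
  expect_gt(rec$auc, 0.8)

  # a degenerate iteration reports a tied-score AUC of 0.5 and a flag
  if (length(rec$flags) == 0) {
    set.seed(10)
    Xn <- matrix(rnorm(60 * 5), 60, 5)
    yn <- rbinom(60, 1, 0.5)
    pn <- complementary_pairs(60, 1, seed = 3)[[1]]
    recn <- wss_iteration(Xn, yn, pn, lambda_rule = "1se", seed = 4)
    if (length(recn$refit_set) == 0) {
      expect_equal(recn$auc, 0.5)
      expect_gt(length(recn$flags), 0)
    }
  }
})

test_that("the full weighted selector recovers planted signals, reproducibly", {
  d <- planted_df(250, 25, signal = c(3, 11, 17), beta = 3, seed = 9)
  fit <- wss(d, B = 10, alpha = 1, seed = 5)
  expect_true(all(c(3, 11, 17) %in% fit$selected))
  expect_true(all(fit$selected %in% fit$score$ever_selected))
  # min-max weights span [0, 1] unless every iteration had the same AUC
  if (length(unique(fit$aucs)) > 1) {
    expect_equal(range(fit$weights), c(0, 1))
  } else {
    expect_true(all(fit$weights == 1))
  }

  fit2 <- wss(d, B = 10, alpha = 1, seed = 5)
  expect_identical(fit2$score$A_w, fit$score$A_w)
  expect_identical(fit2$selected, fit$selected)

  # rethresholding reproduces the original selection at the same alpha
  expect_identical(wss_refit(fit, 1), fit$selected)
  expect_true(length(wss_refit(fit, 2)) <= length(fit$selected))

  g <- glance(fit)
  expect_equal(g$n_selected, length(fit$selected))
  expect_equal(g$p_w, fit$score$p_w)
})
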