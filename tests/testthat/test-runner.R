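test_that("stratified splits honor exact sizes and class balance", {
  d <- planted_df(408, 5, signal = 1, beta = 1, seed = 1)
  sp <- split_dataset(d, fractions = c(201, 85, 122) / 408, seed = 2)
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 201L, validation = 85L, test = 122L))

  d2 <- planted_df(252, 5, signal = 1, beta = 1, seed = 3)
  sp2 <- split_dataset(d2, fractions = c(145, 42, 65) / 252, seed = 4)
  expect_equal(unname(vapply(sp2, nrow, integer(1))), c(145L, 42L, 65L))

  # stratification: class ratio per part within one sample of the global rate
  rate <- mean(d$y)
  for (part in sp) {
    expect_lte(abs(sum(part$y) - rate * nrow(part)), 1)
  }
  expect_setequal(unlist(lapply(sp, function(x) paste(x$x1))), paste(d$x1))

  sp_b <- split_dataset(d, fractions = c(201, 85, 122) / 408, seed = 2)
  expect_identical(sp, sp_b)
  expect_error(split_dataset(d, fractions = c(0.5, 0.2)))
})

test_that("validation tuning returns the AUC-argmax with sparser tie-breaks", {
  d <- planted_df(250, 20, signal = c(2, 7, 13), beta = 3, seed = 5)
  sp <- split_dataset(d, fractions = c(0.6, 0.4), seed = 6)
  tr <- sp$part1; va <- sp$part2

  one <- tune_on_validation(tr, va, "wss", grid = 1, B = 8, seed = 7)
  expect_equal(one$best, 1)
  expect_equal(nrow(one$path), 1)

  tuned <- tune_on_validation(tr, va, "wss", grid = c(0.5, 1, 1.5), B = 8, seed = 7)
  expect_equal(max(tuned$path$auc_validation),
               tuned$path$auc_validation[tuned$path$parameter == tuned$best])
  # argmax dominates any fixed grid point on the tuning set
  expect_gte(max(tuned$path$auc_validation),
             tuned$path$auc_validation[tuned$path$parameter == 1])
  expect_s3_class(tuned$model, "refit_model")

  # equal AUC and equal sparsity: the larger (more conservative) value wins
  tie <- tune_on_validation(tr, va, "wss", grid = c(1.0, 1.01), B = 8, seed = 7)
  if (abs(diff(tie$path$auc_validation)) < 1e-12 &&
      diff(tie$path$n_selected) == 0) {
    expect_equal(tie$best, 1.01)
  }

  cp <- tune_on_validation(tr, va, "cpss", grid = c(1, 5), B = 8,
                           pi_thr = 0.6, seed = 8)
  expect_true(cp$best %in% c(1, 5))
  expect_equal(nrow(cp$path), 2)
})

test_that("scenario runs are tidy, complete and bit-reproducible", {
  cfg <- scenario_config(n = 120, p = 12, p_signal = 2, beta_dist = c(2, 3),
                         seed = 31)
  methods <- list(list(method = "cpss", B = 6, pfer_bound = 2, pi_thr = 0.6),
                  list(method = "lasso-min"))
  res <- run_scenario(cfg, methods, replicates = 2, seed = 9)
  # 2 replicates x 2 methods x 4 metrics + 2 methods x 3 stability rows
  expect_equal(nrow(res), 2 * 2 * 4 + 2 * 3)
  expect_setequal(unique(res$metric),
                  c("tpr", "ppv", "n_selected", "auc_validation",
                    "stability_jaccard", "stability_ochiai", "stability_dice"))
  expect_true(all(is.na(res$replicate[grepl("stability", res$metric)])))
  expect_true(all(res$value[res$metric %in% c("tpr", "ppv")] >= 0))

  res2 <- run_scenario(cfg, methods, replicates = 2, seed = 9)
  expect_identical(res, res2)
})

test_that("select_variables dispatches uniformly across methods", {
  d <- planted_df(200, 15, signal = c(4, 8), beta = 3, seed = 10)
  for (m in c("wss", "cpss", "lasso-min", "lasso-1se")) {
    args <- switch(m, wss = list(B = 6, alpha = 1),
                   cpss = list(B = 6, pfer_bound = 2), list())
    r <- do.call(select_variables, c(list(data = d, method = m, seed = 11), args))
    expect_true(all(c(4, 8) %in% r$selected), info = m)
    expect_equal(r$n_selected, length(r$selected))
  }
})
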