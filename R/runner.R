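# Scenario orchestration: apply a selection method to a dataset, sweep a
# simulation grid, and run the train/validation/test workflow used for real
# applications.

#' Apply one variable-selection method to a data frame
#'
#' Uniform front end over the four selectors compared in the package:
#' weighted stability selection (`"wss"`), complementary-pairs stability
#' selection (`"cpss"`), and plain CV-LASSO at `lambda_min` (`"lasso-min"`)
#' or `lambda_1se` (`"lasso-1se"`).
#'
#' @inheritParams cpss
#' @param method Method id.
#' @param ... Method parameters passed through (`alpha`, `B`, `pi_thr`,
#'   `pfer_bound`, `assumption`, `lambda_rule`, `folds`, ...).
#' @return A list: `selected` (integer predictor indices), `n_selected`,
#'   `method`, and the underlying `fit` object (for wss/cpss).
#' @export
select_variables <- function(data, method = c("wss", "cpss", "lasso-min", "lasso-1se"),
                             response = "y", seed = NULL, ...) {
  method <- match.arg(method)
  if (method %in% c("lasso-min", "lasso-1se")) {
    xy <- df_to_xy(data, response)
    rule <- if (method == "lasso-min") "min" else "1se"
    res <- select_by_cv(xy$X, xy$y, rule = rule, seed = seed, ...)
    return(list(selected = res$selected, n_selected = length(res$selected),
                method = method, fit = res))
  }
  fit <- if (method == "wss") {
    wss(data, response = response, seed = seed, ...)
  } else {
    cpss(data, response = response, seed = seed, ...)
  }
  list(selected = fit$selected, n_selected = length(fit$selected),
       method = method, fit = fit)
}

#' Stratified train/validation/test split
#'
#' Random split into as many parts as `fractions`, stratified by the
#' response so that each part's class ratio matches the global ratio up to
#' rounding. Part sizes follow largest-remainder allocation of
#' `n * fractions`.
#'
#' @inheritParams cpss
#' @param fractions Numeric vector summing to 1 (one entry per part).
#' @param stratify Stratify by the response (default `TRUE`).
#' @param seed Optional seed.
#' @return A named list of tibbles (`train`, `validation`, `test` for three
#'   fractions; `part1..k` otherwise).
#' @export
split_dataset <- function(data, response = "y", fractions = c(0.5, 0.2, 0.3),
                          stratify = TRUE, seed = NULL) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, all(fractions > 0))
  n <- nrow(data)
  k <- length(fractions)
  alloc <- function(m) {
    sizes <- floor(m * fractions)
    rem <- m * fractions - sizes
    short <- m - sum(sizes)
    if (short > 0) {
      add <- order(rem, decreasing = TRUE)[seq_len(short)]
      sizes[add] <- sizes[add] + 1L
    }
    sizes
  }
  assign_ids <- function(idx, sizes) {
    grp <- rep.int(seq_len(k), sizes)
    split(idx, grp)[as.character(seq_len(k))]
  }
  parts <- with_seed(seed, {
    if (stratify) {
      y <- data[[response]]
      out <- vector("list", k)
      for (cls in sort(unique(y))) {
        idx <- sample(which(y == cls))
        pieces <- assign_ids(idx, alloc(length(idx)))
        for (j in seq_len(k)) out[[j]] <- c(out[[j]], pieces[[j]])
      }
      out
    } else {
      assign_ids(sample.int(n), alloc(n))
    }
  })
  # largest-remainder within strata can drift one sample from the global
  # allocation; rebalance so total part sizes match alloc(n) exactly
  target <- alloc(n)
  sizes <- lengths(parts)
  while (any(sizes != target)) {
    over <- which(sizes > target)[1]
    under <- which(sizes < target)[1]
    mv <- parts[[over]][length(parts[[over]])]
    parts[[over]] <- parts[[over]][-length(parts[[over]])]
    parts[[under]] <- c(parts[[under]], mv)
    sizes <- lengths(parts)
  }
  nm <- if (k == 3L) c("train", "validation", "test") else paste0("part", seq_len(k))
  setNames(lapply(parts, function(idx) tibble::as_tibble(data[sort(idx), , drop = FALSE])), nm)
}

#' Tune a selector's parameter on a validation set
#'
#' For every value of the parameter grid the method selects variables on the
#' training data, an unpenalized refit of the selected set is scored by AUC
#' on the validation data, and the best value is returned (ties broken
#' towards the sparser selection, then the larger parameter). The final
#' model is refitted on the combined training and validation data. For
#' `"wss"` the grid is over `alpha` and the resampling is run once (alpha
#' only rethresholds the stored scores); for `"cpss"` it is over the PFER
#' bound.
#'
#' @inheritParams select_variables
#' @param train,val Data frames with identical columns.
#' @param grid Numeric parameter grid (alpha values for wss, PFER bounds for
#'   cpss).
#' @return A list: `best` (parameter value), `selected`, `model` (refit on
#'   train+val), `path` (tibble with one row per grid value: parameter,
#'   n_selected, validation AUC).
#' @export
tune_on_validation <- function(train, val, method = c("wss", "cpss"),
                               grid, response = "y", seed = NULL, ...) {
  method <- match.arg(method)
  if (length(grid) == 0L) stop("parameter grid must be non-empty", call. = FALSE)
  tr <- df_to_xy(train, response)
  evals <- if (method == "wss") {
    fit <- wss(train, response = response, seed = seed, ...)
    lapply(grid, function(a) {
      sel <- wss_refit(fit, a)
      list(param = a, selected = sel)
    })
  } else {
    xy <- tr
    B <- list(...)$B %||% 50
    pi_thr <- list(...)$pi_thr %||% 0.6
    orders <- cpss_entry_orders(xy$X, xy$y, B, seed)
    lapply(grid, function(pf) {
      q <- derive_q(pf, pi_thr, ncol(xy$X))
      sel <- cpss_select(freqs_from_orders(orders, q, ncol(xy$X)), pi_thr)
      list(param = pf, selected = sel)
    })
  }
  path <- purrr::map_dfr(evals, function(e) tibble::tibble(
    parameter = e$param, n_selected = length(e$selected),
    auc_validation = validation_auc(train, val, e$selected, response)
  ))
  ord <- order(-path$auc_validation, path$n_selected, -path$parameter)
  best_i <- ord[1]
  if (all(path$n_selected == 0)) {
    warning("every grid value selected no variables; returning intercept-only model")
  }
  combined <- dplyr::bind_rows(train, val)
  cb <- df_to_xy(combined, response)
  model <- refit_logistic(cb$X, cb$y, evals[[best_i]]$selected)
  list(best = path$parameter[best_i], selected = evals[[best_i]]$selected,
       model = model, path = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

method_label <- function(m) {
  ps <- m[setdiff(names(m), "method")]
  if (length(ps) == 0L) return(m$method)
  paste0(m$method, "(", paste(names(ps), unlist(ps), sep = "=", collapse = ","), ")")
}

#' Run one simulation scenario
#'
#' For each replicate, generates a training set and an independent
#' validation set from the scenario (same true model, fresh draws), applies
#' every method, and records TPR, PPV, selected-set size and validation AUC
#' as tidy rows. After all replicates, mean pairwise stability indices
#' (Jaccard, Ochiai, Dice) are computed across the replicate selections of
#' each method. Fully deterministic under `seed`; failed replicates are
#' recorded with `flag = "error"` rather than dropped.
#'
#' @param config A [scenario_config()]; its `seed` field is combined with
#'   `seed` and the replicate number.
#' @param methods A list of method descriptions, each a named list with a
#'   `method` element (see [select_variables()]) plus parameters, e.g.
#'   `list(list(method = "wss", alpha = 1), list(method = "cpss",
#'   pfer_bound = 1, pi_thr = 0.9, assumption = "r_concave"))`.
#' @param replicates Number of replicates (the study design uses 50).
#' @param seed Master seed.
#' @return A tibble with columns `scenario`, `method`, `replicate`
#'   (`NA` for the across-replicate stability rows), `metric`, `value`,
#'   `flag`.
#' @export
run_scenario <- function(config, methods, replicates = 50, seed = 1) {
  stopifnot(inherits(config, "scenario_config"), replicates >= 1)
  rows <- list()
  selections <- lapply(methods, function(m) vector("list", replicates))
  labels <- vapply(methods, method_label, character(1))
  scen_id <- sprintf("n%d_p%d_s%d_prev%g_%s", config$n, config$p,
                     config$p_signal, config$prevalence, config$cov_structure)
  for (r in seq_len(replicates)) {
    cfg_r <- config
    cfg_r$seed <- stream_seed(seed, 5000L + r)
    train <- generate_dataset(cfg_r, role = "train")
    val <- generate_dataset(cfg_r, role = "validation")
    for (mi in seq_along(methods)) {
      m <- methods[[mi]]
      args <- m[setdiff(names(m), "method")]
      res <- tryCatch(
        do.call(select_variables,
                c(list(data = train$data, method = m$method,
                       seed = stream_seed(seed, 9000L + 100L * r + mi)), args)),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          scenario = scen_id, method = labels[mi], replicate = r,
          metric = "failed", value = NA_real_, flag = "error")
        next
      }
      selections[[mi]][[r]] <- res$selected
      flag <- if (res$n_selected == 0L) "empty_selection" else NA_character_
      vals <- c(
        tpr = if (config$p_signal > 0) tpr(res$selected, train$signal_idx) else NA_real_,
        ppv = if (config$p_signal > 0) ppv(res$selected, train$signal_idx) else NA_real_,
        n_selected = res$n_selected,
        auc_validation = validation_auc(train$data, val$data, res$selected)
      )
      rows[[length(rows) + 1L]] <- tibble::tibble(
        scenario = scen_id, method = labels[mi], replicate = r,
        metric = names(vals), value = unname(vals), flag = flag)
    }
  }
  if (replicates >= 2) {
    for (mi in seq_along(methods)) {
      sels <- selections[[mi]][!vapply(selections[[mi]], is.null, logical(1))]
      if (length(sels) < 2L) next
      for (idx in c("jaccard", "ochiai", "dice")) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          scenario = scen_id, method = labels[mi], replicate = NA_integer_,
          metric = paste0("stability_", idx),
          value = pairwise_stability(sels, idx), flag = NA_character_)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Default parameter grids of the simulation design
#'
#' The comparison grid used throughout the simulation study: weighted
#' stability selection over `alpha` in 0.5..1.5 by 0.1, and stability
#' selection over PFER bounds \{1, 2, 5, 10\}, thresholds
#' \{0.6, 0.75, 0.9\} and the three error-bound assumptions, all with
#' `B = 50` complementary pairs.
#'
#' @return A named list with elements `wss_alphas`, `cpss_pfers`,
#'   `cpss_pithrs`, `cpss_assumptions`, `B`, `replicates`.
#' @export
default_grid <- function() {
  list(wss_alphas = seq(0.5, 1.5, by = 0.1),
       cpss_pfers = c(1, 2, 5, 10),
       cpss_pithrs = c(0.6, 0.75, 0.9),
       cpss_assumptions = c("r_concave", "unimodal", "none"),
       B = 50L, replicates = 50L)
}
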