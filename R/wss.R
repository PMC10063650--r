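#' One complementary-pair iteration of weighted stability selection
#'
#' For one half/half split: (a) a cross-validated logistic LASSO is fitted on
#' each half and the two supports intersected; (b) the intersection is
#' refitted without penalty on the full data; (c) variables significant at
#' the 5% level (two-sided Wald) are kept, giving the iteration's set; (d)
#' that set is refitted on the full data and its in-sample AUC recorded. An
#' empty intersection or an empty post-screen set yields an intercept-only
#' model whose all-tied scores give a midrank AUC of 0.5; such iterations
#' are flagged.
#'
#' @inheritParams fit_lasso_path
#' @param pair A list with integer index vectors `half1`, `half2`.
#' @param lambda_rule `"min"` or `"1se"`, the CV rule used on each half.
#' @param folds CV folds per half (default 10).
#' @param seed Optional seed for the half-sample CV fold draws.
#' @param sig_level Wald screening level (default 0.05).
#' @return A list (one iteration record): `support_half1`, `support_half2`,
#'   `intersection`, `refit_set`, `auc`, `flags`.
#' @export
wss_iteration <- function(X, y, pair, lambda_rule = c("min", "1se"),
                          folds = 10, seed = NULL, sig_level = 0.05,
                          n_lambdas = 100, lambda_min_ratio = 1e-4) {
  lambda_rule <- match.arg(lambda_rule)
  X <- as.matrix(X)
  s1 <- select_by_cv(X[pair$half1, , drop = FALSE], y[pair$half1],
                     rule = lambda_rule, folds = folds,
                     seed = if (is.null(seed)) NULL else stream_seed(seed, 1L),
                     n_lambdas = n_lambdas,
                     lambda_min_ratio = lambda_min_ratio)$selected
  s2 <- select_by_cv(X[pair$half2, , drop = FALSE], y[pair$half2],
                     rule = lambda_rule, folds = folds,
                     seed = if (is.null(seed)) NULL else stream_seed(seed, 2L),
                     n_lambdas = n_lambdas,
                     lambda_min_ratio = lambda_min_ratio)$selected
  common <- intersect(s1, s2)
  flags <- character(0)
  refit_set <- integer(0)
  auc <- 0.5
  if (length(common) == 0L) {
    flags <- c(flags, "empty_intersection")
  } else {
    screen <- refit_logistic(X, y, common)
    if (screen$separation) flags <- c(flags, "separation_screen")
    refit_set <- screen$subset[screen$wald_p < sig_level]
    if (length(refit_set) == 0L) {
      flags <- c(flags, "empty_after_screen")
    } else {
      final <- refit_logistic(X, y, refit_set)
      if (final$separation) flags <- c(flags, "separation_final")
      auc <- auc_mw(final$fitted_prob, y)
    }
  }
  list(support_half1 = s1, support_half2 = s2, intersection = common,
       refit_set = refit_set, auc = auc, flags = flags)
}

#' Min-max rescale a vector of AUCs into weights
#'
#' `w_b = (AUC_b - min) / (max - min)`. If all values are equal the weights
#' degenerate to all 1 (reducing the weighted frequency to plain
#' complementary-pair counting).
#'
#' @param auc_values Numeric vector, length >= 1.
#' @return Weights in \[0, 1\] of the same length.
#' @examples
#' minmax_rescale(c(0.6, 0.8, 0.7))  # 0, 1, 0.5
#' @export
minmax_rescale <- function(auc_values) {
  if (length(auc_values) == 0L) stop("empty input", call. = FALSE)
  rng <- range(auc_values)
  if (rng[1] == rng[2]) return(rep(1, length(auc_values)))
  (auc_values - rng[1]) / (rng[2] - rng[1])
}

#' Accumulate weighted selection frequencies
#'
#' `A_w[j] = sum_b w_b * 1{j in S_b}` — a weighted sum over iterations, not
#' an average. `p_w` counts the variables selected at least once across
#' iterations (including those whose total weight is zero).
#'
#' @param refit_sets List of per-iteration selected-variable index vectors.
#' @param weights Numeric weights aligned with `refit_sets`.
#' @param p Total number of candidate variables.
#' @return A list of class `wss_score`: `A_w` (length `p`), `p_w`,
#'   `ever_selected` (sorted union of the sets).
#' @export
weighted_frequencies <- function(refit_sets, weights, p) {
  if (length(refit_sets) != length(weights)) {
    stop("refit_sets and weights must have the same length", call. = FALSE)
  }
  A_w <- numeric(p)
  for (b in seq_along(refit_sets)) {
    s <- refit_sets[[b]]
    A_w[s] <- A_w[s] + weights[b]
  }
  ever <- sort(unique(unlist(refit_sets)))
  structure(list(A_w = A_w, p_w = length(ever), ever_selected = as.integer(ever)),
            class = "wss_score")
}

#' Threshold weighted frequencies into a selected set
#'
#' Candidates are the variables selected in at least one iteration; among
#' them, those with `A_w >= (sum(A_w) / p_w) * alpha` are selected
#' (inclusive). `alpha = 0` therefore returns every ever-selected variable;
#' large `alpha` returns the empty set. Selection is antitone in `alpha`.
#'
#' @param score A [weighted_frequencies()] result.
#' @param alpha Nonnegative threshold multiplier.
#' @return Integer indices of the selected variables.
#' @export
wss_threshold <- function(score, alpha) {
  stopifnot(inherits(score, "wss_score"), alpha >= 0)
  if (score$p_w == 0L) {
    warning("no variable was ever selected; returning an empty set")
    return(integer(0))
  }
  thr <- sum(score$A_w) / score$p_w * alpha
  score$ever_selected[score$A_w[score$ever_selected] >= thr]
}

#' Weighted stability selection
#'
#' The full selector: `B` complementary-pair iterations
#' ([wss_iteration()]), min-max rescaling of the iteration AUCs into
#' weights, weighted frequency accumulation and the alpha-threshold rule.
#' The returned object stores every iteration record for audit, and
#' [wss_refit()] rethresholds the stored scores at other `alpha` values
#' without recomputation.
#'
#' @inheritParams cpss
#' @param alpha Threshold multiplier on the mean weighted frequency
#'   (default 1); larger values select fewer variables.
#' @param lambda_rule CV rule for the half-sample LASSO fits, `"min"`
#'   (default) or `"1se"`.
#' @param folds CV folds per half (default 10).
#' @param sig_level Wald screening level (default 0.05).
#' @return An object of class `wss_fit`.
#' @examples
#' ds <- generate_dataset(scenario_config(n = 150, p = 25, p_signal = 3,
#'                                        beta_dist = c(2, 3), seed = 11))
#' fit <- wss(ds$data, B = 10, alpha = 1, seed = 1)
#' tidy(fit)
#' glance(fit)
#' @export
wss <- function(data, response = "y", B = 50, alpha = 1,
                lambda_rule = c("min", "1se"), folds = 10, seed = NULL,
                sig_level = 0.05, n_lambdas = 100, lambda_min_ratio = 1e-4) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(alpha >= 0, B >= 1)
  xy <- df_to_xy(data, response)
  p <- ncol(xy$X)
  pairs <- with_seed(if (is.null(seed)) NULL else stream_seed(seed, 101L),
                     draw_valid_pairs(xy$y, B))
  records <- lapply(seq_len(B), function(b) {
    wss_iteration(xy$X, xy$y, pairs[[b]], lambda_rule, folds,
                  seed = if (is.null(seed)) NULL else stream_seed(seed, 200L + b),
                  sig_level = sig_level, n_lambdas = n_lambdas,
                  lambda_min_ratio = lambda_min_ratio)
  })
  aucs <- vapply(records, `[[`, numeric(1), "auc")
  weights <- minmax_rescale(aucs)
  score <- weighted_frequencies(lapply(records, `[[`, "refit_set"), weights, p)
  selected <- wss_threshold(score, alpha)
  structure(
    list(score = score, selected = selected, variables = colnames(xy$X),
         alpha = alpha, B = B, weights = weights, aucs = aucs,
         iterations = records, lambda_rule = lambda_rule, folds = folds,
         p = p, response = response, seed = seed),
    class = "wss_fit"
  )
}

#' Reapply the threshold of a weighted-stability-selection fit
#'
#' Rethresholds the stored weighted frequencies at a new `alpha` without
#' refitting; used by the alpha-tuning workflow.
#'
#' @param fit A [wss()] object.
#' @param alpha New threshold multiplier.
#' @return Integer indices of the selected variables at the new `alpha`.
#' @export
wss_refit <- function(fit, alpha) {
  stopifnot(inherits(fit, "wss_fit"))
  wss_threshold(fit$score, alpha)
}

#' @export
print.wss_fit <- function(x, ...) {
  flagged <- sum(vapply(x$iterations, function(r) length(r$flags) > 0, logical(1)))
  cat(sprintf("<wss_fit> B = %d pairs, alpha = %g, lambda rule = %s\n",
              x$B, x$alpha, x$lambda_rule))
  cat(sprintf("  iteration AUC: %.3f-%.3f; %d flagged iteration(s); p_w = %d\n",
              min(x$aucs), max(x$aucs), flagged, x$score$p_w))
  cat(sprintf("  %d variable(s) selected: %s\n", length(x$selected),
              paste(x$variables[x$selected], collapse = ", ")))
  invisible(x)
}
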