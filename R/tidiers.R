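# broom-style accessors for the two fit classes.

#' Tidy a weighted-stability-selection fit
#'
#' One row per candidate variable: weighted frequency, number of iterations
#' in which it survived the Wald screen, and whether it was selected.
#'
#' @param x A [wss()] fit.
#' @param ... Unused.
#' @return A tibble sorted by decreasing weighted frequency.
#' @method tidy wss_fit
#' @export
tidy.wss_fit <- function(x, ...) {
  times <- tabulate(unlist(lapply(x$iterations, `[[`, "refit_set")), nbins = x$p)
  tibble::tibble(
    variable = x$variables %||% paste0("x", seq_len(x$p)),
    weighted_frequency = x$score$A_w,
    n_iterations = times,
    selected = seq_len(x$p) %in% x$selected
  ) |> dplyr::arrange(dplyr::desc(.data$weighted_frequency))
}

#' Glance at a weighted-stability-selection fit
#'
#' @inheritParams tidy.wss_fit
#' @return A one-row tibble: `B`, `alpha`, `p_w`, `n_selected`, `threshold`,
#'   `mean_auc`, `n_flagged`.
#' @method glance wss_fit
#' @export
glance.wss_fit <- function(x, ...) {
  tibble::tibble(
    B = x$B, alpha = x$alpha, p_w = x$score$p_w,
    n_selected = length(x$selected),
    threshold = if (x$score$p_w > 0) sum(x$score$A_w) / x$score$p_w * x$alpha else NA_real_,
    mean_auc = mean(x$aucs),
    n_flagged = sum(vapply(x$iterations, function(r) length(r$flags) > 0, logical(1)))
  )
}

#' Tidy a complementary-pairs stability-selection fit
#'
#' One row per candidate variable with its simultaneous selection frequency.
#'
#' @param x A [cpss()] fit.
#' @param ... Unused.
#' @return A tibble sorted by decreasing frequency.
#' @method tidy cpss_fit
#' @export
tidy.cpss_fit <- function(x, ...) {
  tibble::tibble(
    variable = x$variables %||% paste0("x", seq_len(x$p)),
    frequency = x$pi_tilde,
    selected = seq_len(x$p) %in% x$selected
  ) |> dplyr::arrange(dplyr::desc(.data$frequency))
}

#' Glance at a complementary-pairs stability-selection fit
#'
#' @inheritParams tidy.cpss_fit
#' @return A one-row tibble: `B`, `q`, `pi_thr`, `pfer_bound`, `assumption`,
#'   `error_bound`, `n_selected`.
#' @method glance cpss_fit
#' @export
glance.cpss_fit <- function(x, ...) {
  tibble::tibble(
    B = x$B, q = x$q, pi_thr = x$pi_thr, pfer_bound = x$pfer_bound,
    assumption = x$assumption, error_bound = x$error_bound,
    n_selected = length(x$selected)
  )
}
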