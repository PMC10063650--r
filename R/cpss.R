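#' Per-subsample selection size from a PFER bound
#'
#' Inverts the per-family error-rate bound `E(V) <= q^2 / ((2 pi_thr - 1) p)`
#' for the largest integer `q` that keeps the bound at or below
#' `pfer_bound`: `q = floor(sqrt(pfer_bound (2 pi_thr - 1) p))`, clamped to
#' at least 1.
#'
#' @param pfer_bound Target upper bound on the expected number of false
#'   selections, > 0.
#' @param pi_thr Stability threshold, in (0.5, 1).
#' @param p Number of candidate variables.
#' @return Integer `q`.
#' @examples
#' derive_q(1, 0.6, 500)   # 10
#' @export
derive_q <- function(pfer_bound, pi_thr, p) {
  if (!(pi_thr > 0.5 && pi_thr < 1)) {
    stop("pi_thr must lie in (0.5, 1)", call. = FALSE)
  }
  if (pfer_bound <= 0) stop("pfer_bound must be > 0", call. = FALSE)
  # small epsilon so exact squares (e.g. 1 * 0.2 * 500 = 100) are not lost
  # to floating-point representation of the threshold
  max(1L, as.integer(floor(sqrt(pfer_bound * (2 * pi_thr - 1) * p) + 1e-9)))
}

#' Complementary-pairs sample splits
#'
#' Each of the `B` pairs partitions `1..n` into two disjoint halves of sizes
#' `floor(n/2)` and `n - floor(n/2)`.
#'
#' @param n Sample size (>= 4).
#' @param B Number of pairs.
#' @param seed Optional seed.
#' @return A list of `B` lists, each with integer vectors `half1`, `half2`.
#' @export
complementary_pairs <- function(n, B, seed = NULL) {
  if (n < 4) stop("n must be at least 4", call. = FALSE)
  if (B < 1) stop("B must be at least 1", call. = FALSE)
  h <- floor(n / 2)
  with_seed(seed, lapply(seq_len(B), function(b) {
    half1 <- sort(sample.int(n, h))
    list(half1 = half1, half2 = setdiff(seq_len(n), half1))
  }))
}

# Draw complementary pairs, redrawing any pair whose halves would be
# single-class (max 20 redraws per pair, then error). Must be called with
# the RNG already seeded by the caller.
draw_valid_pairs <- function(y, B) {
  n <- length(y)
  h <- floor(n / 2)
  lapply(seq_len(B), function(b) {
    for (try in 1:21) {
      half1 <- sort(sample.int(n, h))
      half2 <- setdiff(seq_len(n), half1)
      if (length(unique(y[half1])) == 2L && length(unique(y[half2])) == 2L) {
        return(list(half1 = half1, half2 = half2))
      }
    }
    stop("could not draw a complementary pair with both classes in each half",
         call. = FALSE)
  })
}

# Fit a LASSO path on each half of every pair and keep only the entry
# orders. q enters later as a prefix length, so one set of paths serves any
# number of q values.
cpss_entry_orders <- function(X, y, B, seed = NULL, n_lambdas = 100,
                              lambda_min_ratio = 1e-4) {
  with_seed(seed, {
    pairs <- draw_valid_pairs(y, B)
    lapply(pairs, function(pr) {
      list(pair = pr,
           order1 = fit_lasso_path(X[pr$half1, , drop = FALSE], y[pr$half1],
                                   n_lambdas, lambda_min_ratio)$entry_order,
           order2 = fit_lasso_path(X[pr$half2, , drop = FALSE], y[pr$half2],
                                   n_lambdas, lambda_min_ratio)$entry_order)
    })
  })
}

# Simultaneous selection frequencies from stored entry orders at prefix q.
freqs_from_orders <- function(orders, q, p) {
  counts <- numeric(p)
  for (rec in orders) {
    s1 <- head(rec$order1, q)
    s2 <- head(rec$order2, q)
    both <- intersect(s1, s2)
    counts[both] <- counts[both] + 1
  }
  counts / length(orders)
}

#' Complementary-pairs simultaneous selection frequencies
#'
#' For each of `B` random half/half splits, a logistic LASSO path is fitted
#' on each half and the first `q` variables to enter each path form the two
#' half supports; a variable counts for the pair only if it lies in both.
#' The returned frequency is the fraction of pairs in which the variable was
#' simultaneously selected. Pairs with a single-class half are redrawn.
#'
#' @inheritParams fit_lasso_path
#' @param q Per-half selection size (prefix of the activation order).
#' @param B Number of complementary pairs (default 50).
#' @param seed Optional seed.
#' @return Numeric vector `pi_tilde` of length `p`, entries multiples of
#'   `1/B`, with the stored half supports attached as attribute `"supports"`.
#' @export
cpss_frequencies <- function(X, y, q, B = 50, seed = NULL, n_lambdas = 100,
                             lambda_min_ratio = 1e-4) {
  X <- as.matrix(X)
  if (q > ncol(X)) stop("q must not exceed p", call. = FALSE)
  orders <- cpss_entry_orders(X, y, B, seed, n_lambdas, lambda_min_ratio)
  pi_tilde <- freqs_from_orders(orders, q, ncol(X))
  attr(pi_tilde, "supports") <- lapply(orders, function(rec)
    list(s1 = head(rec$order1, q), s2 = head(rec$order2, q)))
  pi_tilde
}

#' Threshold a frequency vector into a stable set
#'
#' @param pi_tilde Selection-frequency vector.
#' @param pi_thr Stability threshold; selection is inclusive (`>=`).
#' @return Integer indices of the stable variables.
#' @export
cpss_select <- function(pi_tilde, pi_thr) {
  which(as.numeric(pi_tilde) >= pi_thr)
}

#' Complementary-pairs stability selection
#'
#' The full baseline selector: derives `q` from the per-family error-rate
#' bound via [derive_q()], computes simultaneous selection frequencies over
#' `B` complementary pairs and keeps variables at or above `pi_thr`. The
#' error-bound `assumption` ("none", "unimodal" or "r_concave") affects only
#' the reported expected-false-selection bound, not `q` or the selection.
#'
#' @param data A data frame containing the response column and numeric
#'   predictors.
#' @param response Name of the 0/1 response column (default `"y"`).
#' @param B Number of complementary pairs (default 50).
#' @param pfer_bound Target per-family error-rate bound (default 1).
#' @param pi_thr Stability threshold (default 0.6).
#' @param assumption Error-bound assumption for the reported bound.
#' @param seed Optional seed; the same seed reproduces the fit exactly.
#' @param n_lambdas,lambda_min_ratio Penalty-grid controls, see
#'   [fit_lasso_path()].
#' @return An object of class `cpss_fit`.
#' @examples
#' ds <- generate_dataset(scenario_config(n = 120, p = 30, p_signal = 3,
#'                                        beta_dist = c(2, 3), seed = 7))
#' fit <- cpss(ds$data, B = 10, pfer_bound = 2, pi_thr = 0.6, seed = 1)
#' tidy(fit)
#' @export
cpss <- function(data, response = "y", B = 50, pfer_bound = 1, pi_thr = 0.6,
                 assumption = c("none", "unimodal", "r_concave"),
                 seed = NULL, n_lambdas = 100, lambda_min_ratio = 1e-4) {
  assumption <- match.arg(assumption)
  xy <- df_to_xy(data, response)
  p <- ncol(xy$X)
  q <- derive_q(pfer_bound, pi_thr, p)
  pi_tilde <- cpss_frequencies(xy$X, xy$y, q, B, seed, n_lambdas,
                               lambda_min_ratio)
  sel <- cpss_select(pi_tilde, pi_thr)
  structure(
    list(pi_tilde = as.numeric(pi_tilde),
         supports = attr(pi_tilde, "supports"),
         selected = sel, variables = colnames(xy$X),
         q = q, B = B, pfer_bound = pfer_bound, pi_thr = pi_thr,
         assumption = assumption,
         error_bound = error_bound(q, p, pi_thr, B, assumption),
         p = p, response = response, seed = seed),
    class = "cpss_fit"
  )
}

#' @export
print.cpss_fit <- function(x, ...) {
  cat(sprintf("<cpss_fit> B = %d pairs, q = %d, pi_thr = %g, assumption = %s\n",
              x$B, x$q, x$pi_thr, x$assumption))
  cat(sprintf("  error bound E|S n L_theta| <= %.4g\n", x$error_bound))
  cat(sprintf("  %d variable(s) selected: %s\n", length(x$selected),
              paste(x$variables[x$selected], collapse = ", ")))
  invisible(x)
}
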