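# Error bounds for complementary-pairs stability selection.
#
# All three bounds control E|S_stable intersect L_theta|, the expected number
# of selected variables among those with low selection probability
# (theta = q/p). "none" is the basic q^2/((2 pi_thr - 1) p) bound; "unimodal"
# and "r_concave" are the refined bounds that assume the simultaneous
# selection frequency of a low-probability variable has, respectively, a
# unimodal or an r-concave distribution on the resampling grid.

# Worst-case tail P(X >= x) over r-concave distributions on the grid
# {0, 1/B, ..., 1} with mean eta. The extremal family has f^r linear on a
# support {0, ..., k} and zero beyond, i.e. f(i) proportional to
# (a + i)^(1/r); for each support endpoint k the scale a is root-found so
# the mean matches eta, and the tail is maximized over k.
rconcave_tail <- function(eta, B, r, x) {
  stopifnot(r < 0, eta >= 0, B >= 1)
  if (x <= 0) return(1)
  s <- -1 / r
  etaB <- eta * B
  jx <- ceiling(x * B - 1e-9)       # smallest grid index with i/B >= x
  if (jx > B) return(0)
  if (etaB <= 0) return(0)
  best <- 0
  k_min <- max(1L, as.integer(ceiling(2 * etaB)))
  if (k_min > B) return(1)          # mean constraint not attainable: vacuous
  for (k in k_min:B) {
    if (k / 2 <= etaB) next
    i <- 0:k
    mean_gap <- function(a) {
      w <- (a + i)^(-s)
      sum(i * w) / sum(w) - etaB
    }
    # mean rises from 0 (a -> 0) to k/2 (a -> Inf)
    a <- tryCatch(
      uniroot(mean_gap, lower = 1e-9, upper = 1e9, tol = 1e-12)$root,
      error = function(e) NA_real_
    )
    if (is.na(a)) next
    w <- (a + i)^(-s)
    w <- w / sum(w)
    tail <- if (jx > k) 0 else sum(w[(jx + 1):(k + 1)])
    if (tail > best) best <- tail
  }
  min(best, 1)
}

#' Expected-false-selection bound of complementary-pairs stability selection
#'
#' Upper bound on the expected number of low-selection-probability variables
#' (`theta = q/p`) declared stable at threshold `pi_thr` over `B`
#' complementary pairs.
#'
#' * `"none"`: `q^2 / ((2 pi_thr - 1) p)`, no distributional assumption.
#' * `"unimodal"`: assumes the simultaneous selection frequency of a
#'   low-probability variable is unimodal; closed form with branches at
#'   `pi_thr = 3/4`.
#' * `"r_concave"`: assumes the simultaneous frequency is (-1/2)-concave and
#'   the simple (2B-subsample) frequency (-1/4)-concave; the bound is `p`
#'   times the smaller of the two worst-case tails, each computed by
#'   root-finding over the extremal family (see [rconcave_tail]).
#'
#' For identical inputs the three bounds are ordered
#' `r_concave <= unimodal <= none`.
#'
#' @param q Per-half selection size.
#' @param p Number of candidate variables.
#' @param pi_thr Stability threshold, in (0.5, 1).
#' @param B Number of complementary pairs.
#' @param assumption One of `"none"`, `"unimodal"`, `"r_concave"`.
#' @return The bound (a nonnegative scalar).
#' @examples
#' error_bound(10, 500, 0.6, 50, "none")       # 1
#' error_bound(10, 500, 0.6, 50, "r_concave")  # tighter
#' @export
error_bound <- function(q, p, pi_thr, B,
                        assumption = c("none", "unimodal", "r_concave")) {
  assumption <- match.arg(assumption)
  if (!(pi_thr > 0.5 && pi_thr < 1)) {
    stop("pi_thr must lie in (0.5, 1)", call. = FALSE)
  }
  theta <- q / p
  switch(assumption,
    none = q^2 / ((2 * pi_thr - 1) * p),
    unimodal = {
      valid_from <- min(1 / 2 + theta^2, 1 / 2 + 1 / (2 * B) + 3 * theta^2 / 4)
      if (pi_thr <= valid_from) {
        stop("pi_thr too small for the unimodal bound at this theta and B",
             call. = FALSE)
      }
      if (pi_thr <= 3 / 4) {
        q^2 / p / (2 * (2 * pi_thr - 1 - 1 / (2 * B)))
      } else {
        q^2 / p * 4 * (1 - pi_thr + 1 / (2 * B)) / (1 + 1 / B)
      }
    },
    r_concave = {
      d1 <- rconcave_tail(theta^2, B, -1 / 2, 2 * pi_thr - 1)
      d2 <- rconcave_tail(theta, 2 * B, -1 / 4, pi_thr)
      p * min(1, d1, d2)
    }
  )
}
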