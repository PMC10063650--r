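#' Describe one simulation scenario
#'
#' A scenario fixes every generative knob of a synthetic dataset: sample
#' size, dimension, number of signal variables, the uniform law of the
#' nonzero coefficients, the target event prevalence, the predictor
#' covariance structure and the master seed. Predictors are multivariate
#' Gaussian with either independent columns or a Toeplitz correlation
#' `rho^|k - l|`; the response is Bernoulli through a logistic link whose
#' intercept is calibrated so that the marginal event rate matches
#' `prevalence`.
#'
#' @param n Sample size.
#' @param p Number of predictors.
#' @param p_signal Number of true signal variables (may be 0 for a pure-noise
#'   null scenario; then all coefficients are zero).
#' @param beta_dist Length-2 numeric, the support of the uniform distribution
#'   from which nonzero coefficients are drawn. The two study settings are
#'   `c(0.5, 1.5)` and `c(-3, 3)`.
#' @param prevalence Target marginal event rate, in (0, 1).
#' @param cov_structure `"identity"` or `"toeplitz"`.
#' @param toeplitz_rho Correlation base of the Toeplitz structure, in \[0, 1).
#' @param seed Master RNG seed for the scenario.
#'
#' @return An object of class `scenario_config` (a named list).
#' @examples
#' cfg <- scenario_config(n = 100, p = 20, p_signal = 3, seed = 1)
#' ds <- generate_dataset(cfg)
#' dim(ds$data)
#' @export
scenario_config <- function(n, p, p_signal,
                            beta_dist = c(0.5, 1.5),
                            prevalence = 0.5,
                            cov_structure = c("identity", "toeplitz"),
                            toeplitz_rho = 0.9,
                            seed = 1L) {
  cov_structure <- match.arg(cov_structure)
  stopifnot(length(n) == 1L, n >= 1, length(p) == 1L, p >= 1)
  if (p_signal < 0 || p_signal > p) {
    stop("p_signal must satisfy 0 <= p_signal <= p", call. = FALSE)
  }
  if (!(prevalence > 0 && prevalence < 1)) {
    stop("prevalence must lie in (0, 1)", call. = FALSE)
  }
  if (!(toeplitz_rho >= 0 && toeplitz_rho < 1)) {
    stop("toeplitz_rho must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(length(beta_dist) == 2L, beta_dist[1] <= beta_dist[2])
  structure(
    list(n = as.integer(n), p = as.integer(p), p_signal = as.integer(p_signal),
         beta_dist = as.numeric(beta_dist), prevalence = prevalence,
         cov_structure = cov_structure, toeplitz_rho = toeplitz_rho,
         seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  n = %d, p = %d, p_signal = %d\n", x$n, x$p, x$p_signal))
  cat(sprintf("  beta ~ U(%g, %g), prevalence = %g\n",
              x$beta_dist[1], x$beta_dist[2], x$prevalence))
  cat(sprintf("  covariance: %s", x$cov_structure))
  if (x$cov_structure == "toeplitz") cat(sprintf(" (rho = %g)", x$toeplitz_rho))
  cat(sprintf("\n  seed = %d\n", x$seed))
  invisible(x)
}

#' Predictor covariance matrix of a scenario
#'
#' @param p Dimension.
#' @param structure `"identity"` or `"toeplitz"`.
#' @param rho Correlation base for the Toeplitz case, `Sigma[k, l] =
#'   rho^|k - l|`; ignored for the identity.
#' @return A `p x p` symmetric positive-definite matrix.
#' @examples
#' make_covariance(3, "toeplitz", 0.9)[1, ]
#' @export
make_covariance <- function(p, structure = c("identity", "toeplitz"), rho = 0.9) {
  structure <- match.arg(structure)
  if (length(p) != 1L || p < 1) stop("p must be a positive integer", call. = FALSE)
  if (structure == "identity") return(diag(p))
  if (!(rho >= 0 && rho < 1)) stop("rho must lie in [0, 1)", call. = FALSE)
  rho^abs(outer(seq_len(p), seq_len(p), "-"))
}

#' Draw a sparse coefficient vector
#'
#' Places `p_signal` nonzero coefficients, i.i.d. uniform on `beta_dist`, at
#' column positions chosen uniformly at random without replacement; all other
#' entries are exactly zero. Uses the current RNG stream.
#'
#' @inheritParams scenario_config
#' @return A list with `beta` (length-`p` numeric) and `signal_idx` (sorted
#'   integer positions of the nonzero entries).
#' @export
draw_coefficients <- function(p, p_signal, beta_dist = c(0.5, 1.5)) {
  if (p_signal > p) stop("p_signal must not exceed p", call. = FALSE)
  beta <- numeric(p)
  idx <- integer(0)
  if (p_signal > 0) {
    idx <- sort(sample.int(p, p_signal))
    beta[idx] <- runif(p_signal, beta_dist[1], beta_dist[2])
  }
  list(beta = beta, signal_idx = idx)
}

#' Calibrate the logistic intercept to a target prevalence
#'
#' The generative model draws rows of `X` from `N_p(0, Sigma)`, so the linear
#' predictor `x'beta` is exactly `N(0, beta' Sigma beta)`. The marginal event
#' rate `E[plogis(beta0 + x'beta)]` is estimated on a fixed Monte-Carlo draw
#' of that scalar Gaussian and `beta0` is found by bisection.
#'
#' @param beta Coefficient vector.
#' @param covariance Predictor covariance matrix (or `NULL` for identity).
#' @param prevalence Target event rate in (0, 1).
#' @param mc_draws Size of the Monte-Carlo draw (default `1e5`).
#' @param tol Calibration tolerance on the achieved rate (default 0.005).
#' @param seed Optional seed for the Monte-Carlo draw.
#' @return The scalar intercept `beta0`.
#' @examples
#' calibrate_intercept(numeric(5), NULL, 0.3)  # ~ qlogis(0.3)
#' @export
calibrate_intercept <- function(beta, covariance, prevalence,
                                mc_draws = 1e5, tol = 0.005, seed = NULL) {
  if (!(prevalence > 0 && prevalence < 1)) {
    stop("prevalence must lie in (0, 1)", call. = FALSE)
  }
  s2 <- if (is.null(covariance)) sum(beta^2) else drop(crossprod(beta, covariance %*% beta))
  if (s2 < .Machine$double.eps) return(qlogis(prevalence))
  z <- with_seed(seed, rnorm(mc_draws, sd = sqrt(s2)))
  f <- function(b0) mean(plogis(b0 + z)) - prevalence
  lo <- -50; hi <- 50
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= tol / 2) return(mid)
    if (fm > 0) hi <- mid else lo <- mid
  }
  if (abs(f((lo + hi) / 2)) > tol) {
    stop("intercept bisection did not reach the prevalence tolerance", call. = FALSE)
  }
  (lo + hi) / 2
}

# Draw an n x p Gaussian matrix with the scenario's covariance. The Toeplitz
# rho^|k-l| structure is an AR(1) correlation, so columns are generated by the
# exact recursion x_k = rho x_{k-1} + sqrt(1 - rho^2) e_k (O(np), no Cholesky).
draw_predictors <- function(n, p, cov_structure, rho) {
  X <- matrix(rnorm(n * p), n, p)
  if (cov_structure == "toeplitz" && p > 1 && rho > 0) {
    s <- sqrt(1 - rho^2)
    for (k in 2:p) X[, k] <- rho * X[, k - 1] + s * X[, k]
  }
  colnames(X) <- paste0("x", seq_len(p))
  X
}

#' Generate a synthetic dataset from a scenario
#'
#' Rows of `X` are i.i.d. `N_p(0, Sigma)`; the response is
#' `y_i ~ Bernoulli(plogis(beta0 + x_i' beta))` with `beta0` calibrated to the
#' scenario's prevalence. The master seed is split into independent streams
#' for coefficients, predictors and responses; `role = "validation"` reuses
#' the coefficient stream (the same true model) but fresh predictor and
#' response streams, giving an independent set of equal dimensions.
#'
#' @param config A [scenario_config()].
#' @param role `"train"` or `"validation"`.
#' @return A list of class `sim_dataset`: `data` (a tibble with columns
#'   `x1..xp` and `y`), `beta`, `signal_idx`, `intercept`, `config`, `role`.
#' @export
generate_dataset <- function(config, role = c("train", "validation")) {
  stopifnot(inherits(config, "scenario_config"))
  role <- match.arg(role)
  role_off <- if (role == "train") 0L else 1000L
  co <- with_seed(stream_seed(config$seed, 1L),
                  draw_coefficients(config$p, config$p_signal, config$beta_dist))
  Sigma <- if (config$cov_structure == "identity") NULL else
    make_covariance(config$p, "toeplitz", config$toeplitz_rho)
  b0 <- calibrate_intercept(co$beta, Sigma, config$prevalence,
                            seed = stream_seed(config$seed, 2L))
  X <- with_seed(stream_seed(config$seed, 3L + role_off),
                 draw_predictors(config$n, config$p, config$cov_structure,
                                 config$toeplitz_rho))
  pr <- plogis(b0 + drop(X %*% co$beta))
  y <- with_seed(stream_seed(config$seed, 4L + role_off),
                 rbinom(config$n, 1L, pr))
  data <- tibble::as_tibble(as.data.frame(X))
  data$y <- as.integer(y)
  structure(
    list(data = data, beta = co$beta, signal_idx = co$signal_idx,
         intercept = b0, config = config, role = role),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %s, n = %d, p = %d, %d signal variable(s), mean(y) = %.3f\n",
              x$role, nrow(x$data), ncol(x$data) - 1L,
              length(x$signal_idx), mean(x$data$y)))
  invisible(x)
}
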