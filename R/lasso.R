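# Run a glmnet call muffling its small-lambda convergence chatter, which is
# routine for logistic paths pushed deep into the p > n regime; the returned
# (possibly truncated) path is still well-formed.
quiet_glmnet <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("glmnet C\\+\\+ code|Convergence for .*lambda", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

#' Fit a logistic LASSO regularization path
#'
#' Thin wrapper around [glmnet::glmnet()] (binomial family) that records, for
#' every variable, the largest penalty at which it first becomes active, and
#' the resulting first-activation order. Columns are standardized to unit
#' variance inside the solver; coefficients are reported on the original
#' scale. Zero-variance columns are dropped with a warning and reported as
#' never active.
#'
#' @param X Numeric matrix, `n x p`.
#' @param y Binary response vector (0/1), both classes present.
#' @param n_lambdas Length of the log-spaced penalty grid (default 100).
#' @param lambda_min_ratio Ratio of the smallest to the largest penalty
#'   (default `1e-4`).
#' @return An object of class `lasso_path`: the glmnet `fit`, `lambdas`,
#'   `entry_order` (variable indices in first-activation order),
#'   `first_active` (per-variable index into `lambdas` of first activation,
#'   `NA` if never active), and `dropped` (zero-variance columns).
#' @seealso [first_q_active()], [select_by_cv()]
#' @export
fit_lasso_path <- function(X, y, n_lambdas = 100, lambda_min_ratio = 1e-4) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stop("y must contain both classes", call. = FALSE)
  p <- ncol(X)
  sds <- apply(X, 2, sd)
  keep <- which(sds > 0)
  if (length(keep) < p) {
    warning(sprintf("%d zero-variance column(s) dropped from the path",
                    p - length(keep)))
  }
  if (length(keep) < 2L) stop("need at least 2 non-constant columns", call. = FALSE)
  fit <- quiet_glmnet(
    glmnet::glmnet(X[, keep, drop = FALSE], y, family = "binomial",
                   nlambda = n_lambdas, lambda.min.ratio = lambda_min_ratio,
                   standardize = TRUE))
  # beta is p_keep x nlambda; first lambda index at which each row is nonzero
  bmat <- as.matrix(fit$beta) != 0
  first_keep <- apply(bmat, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
  first_active <- rep(NA_integer_, p)
  first_active[keep] <- first_keep
  # order by activation index; ties broken by larger |coef| at activation,
  # then by column index (deterministic)
  act <- which(!is.na(first_active))
  if (length(act)) {
    mag <- vapply(act, function(j) {
      k <- first_active[j]
      abs(as.matrix(fit$beta)[match(j, keep), k])
    }, numeric(1))
    entry_order <- act[order(first_active[act], -mag, act)]
  } else {
    entry_order <- integer(0)
  }
  structure(
    list(fit = fit, lambdas = fit$lambda, entry_order = entry_order,
         first_active = first_active, kept = keep,
         dropped = setdiff(seq_len(p), keep), p = p),
    class = "lasso_path"
  )
}

#' First q variables to enter a LASSO path
#'
#' @param path A [fit_lasso_path()] object.
#' @param q Maximum number of variables (>= 1).
#' @return Integer vector of at most `q` variable indices, in activation
#'   order; shorter if the path activates fewer variables.
#' @export
first_q_active <- function(path, q) {
  stopifnot(inherits(path, "lasso_path"))
  if (length(q) != 1L || q < 1) stop("q must be >= 1", call. = FALSE)
  head(path$entry_order, q)
}

# Deterministic stratified fold assignment: cases and controls are permuted
# separately and dealt round-robin into folds.
stratified_folds <- function(y, folds, seed = NULL) {
  with_seed(seed, {
    foldid <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      foldid[idx] <- rep_len(seq_len(folds), length(idx))
    }
    foldid
  })
}

#' Cross-validated LASSO support
#'
#' Selects the penalty by stratified K-fold cross-validation of the binomial
#' deviance ([glmnet::cv.glmnet()]): `rule = "min"` takes the deviance-
#' minimizing lambda, `rule = "1se"` the largest lambda whose mean CV
#' deviance stays within one standard error of the minimum. If a class has
#' fewer members than `folds`, the fold count is reduced with a warning.
#'
#' @inheritParams fit_lasso_path
#' @param rule `"min"` or `"1se"`.
#' @param folds Number of CV folds (default 10).
#' @param seed Optional seed for fold assignment.
#' @return A list: `selected` (integer support at the chosen lambda),
#'   `lambda`, `rule`, and the underlying `cvfit`.
#' @export
select_by_cv <- function(X, y, rule = c("min", "1se"), folds = 10,
                         seed = NULL, n_lambdas = 100,
                         lambda_min_ratio = 1e-4) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stop("y must contain both classes", call. = FALSE)
  ncls <- min(table(y))
  if (ncls < folds) {
    folds <- max(2L, as.integer(ncls))
    warning(sprintf("class too small for requested folds; using %d folds", folds))
  }
  foldid <- stratified_folds(y, folds, seed)
  cvfit <- quiet_glmnet(
    glmnet::cv.glmnet(X, y, family = "binomial",
                      type.measure = "deviance", foldid = foldid,
                      nlambda = n_lambdas,
                      lambda.min.ratio = lambda_min_ratio,
                      standardize = TRUE))
  lam <- if (rule == "min") cvfit$lambda.min else cvfit$lambda.1se
  b <- coef(cvfit, s = lam)[-1, 1]
  list(selected = which(b != 0), lambda = lam, rule = rule, cvfit = cvfit)
}

#' Unpenalized logistic refit of a variable subset
#'
#' Maximum-likelihood logistic regression with intercept on the given
#' columns, with two-sided Wald p-values against the standard normal. On
#' detected separation or non-convergence the fit falls back to a
#' ridge-stabilized Newton solver (fixed small L2 penalty on the slopes) so
#' that fitted probabilities and an AUC remain computable; the result is
#' flagged. Aliased (rank-deficient) columns are dropped with a warning.
#'
#' @inheritParams fit_lasso_path
#' @param subset Integer indices of the columns to refit; may be empty, in
#'   which case an intercept-only model is returned.
#' @param ridge_lambda L2 strength of the stabilized fallback (default 1e-3,
#'   on standardized-scale slopes).
#' @return An object of class `refit_model`: `subset`, `coefficients`
#'   (intercept first), `wald_p` (named, one per retained variable),
#'   `fitted_prob`, `separation` flag, `aliased` columns.
#' @export
refit_logistic <- function(X, y, subset, ridge_lambda = 1e-3) {
  X <- as.matrix(X)
  n <- length(y)
  subset <- as.integer(subset)
  if (length(subset) == 0L) {
    p0 <- mean(y)
    return(structure(
      list(subset = integer(0),
           coefficients = c(`(Intercept)` = qlogis(max(min(p0, 1 - 1e-12), 1e-12))),
           wald_p = setNames(numeric(0), character(0)),
           fitted_prob = rep(p0, n), separation = FALSE, aliased = integer(0)),
      class = "refit_model"
    ))
  }
  if (length(subset) >= n / 2) {
    stop("subset too large relative to the sample size", call. = FALSE)
  }
  Xs <- X[, subset, drop = FALSE]
  nm <- colnames(X)[subset]
  if (is.null(nm)) nm <- paste0("x", subset)
  colnames(Xs) <- nm
  sep <- FALSE
  fit <- withCallingHandlers(
    glm.fit(cbind(`(Intercept)` = 1, Xs), y, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  aliased <- which(is.na(coef(fit)[-1]))
  if (length(aliased)) {
    warning(sprintf("%d aliased column(s) dropped in refit", length(aliased)))
    return(refit_logistic(X, y, subset[-aliased], ridge_lambda))
  }
  if (!sep && fit$converged) {
    cf <- coef(fit)
    # Wald SEs from the unscaled covariance of the IRLS fit
    w <- fit$weights
    Xd <- cbind(1, Xs)
    XtWX <- crossprod(Xd * sqrt(w))
    cov <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(cov)) {
      sep <- TRUE
    } else {
      se <- sqrt(diag(cov))
      z <- cf / se
      pv <- 2 * pnorm(-abs(z))
      return(structure(
        list(subset = subset, coefficients = cf,
             wald_p = setNames(pv[-1], nm),
             fitted_prob = fit$fitted.values, separation = FALSE,
             aliased = integer(0)),
        class = "refit_model"
      ))
    }
  }
  rf <- ridge_logistic(Xs, y, ridge_lambda)
  structure(
    list(subset = subset, coefficients = rf$coefficients,
         wald_p = setNames(rf$wald_p, nm),
         fitted_prob = rf$fitted_prob, separation = TRUE,
         aliased = integer(0)),
    class = "refit_model"
  )
}

# Newton solver for logistic regression with a fixed L2 penalty on the
# slopes (never the intercept); used as a stabilized fallback under
# separation. SEs are taken from the penalized observed information.
ridge_logistic <- function(Xs, y, lambda, max_iter = 100, tol = 1e-8) {
  n <- nrow(Xs); k <- ncol(Xs)
  Xd <- cbind(`(Intercept)` = 1, Xs)
  pen <- diag(c(0, rep(lambda * n, k)), k + 1)
  b <- numeric(k + 1)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% b)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xd * sqrt(w)) + pen
    g <- crossprod(Xd, y - mu) - pen %*% b
    step <- solve(H, g)
    b <- b + drop(step)
    if (max(abs(step)) < tol) break
  }
  cov <- solve(crossprod(Xd * sqrt(pmax(plogis(drop(Xd %*% b)) *
                                          (1 - plogis(drop(Xd %*% b))), 1e-10))) + pen)
  se <- sqrt(diag(cov))
  z <- b / se
  list(coefficients = setNames(drop(b), colnames(Xd)),
       wald_p = (2 * pnorm(-abs(z)))[-1],
       fitted_prob = plogis(drop(Xd %*% b)))
}

#' @export
print.refit_model <- function(x, ...) {
  cat(sprintf("<refit_model> %d variable(s)%s\n", length(x$subset),
              if (x$separation) " [ridge-stabilized]" else ""))
  if (length(x$subset)) print(round(x$coefficients, 4))
  invisible(x)
}

#' Predicted event probabilities of a refit model on new data
#'
#' @param object A [refit_logistic()] fit.
#' @param newX Numeric matrix with the same columns as the training matrix.
#' @param ... Unused.
#' @return Vector of probabilities.
#' @export
predict.refit_model <- function(object, newX, ...) {
  newX <- as.matrix(newX)
  eta <- object$coefficients[1]
  if (length(object$subset)) {
    eta <- eta + drop(newX[, object$subset, drop = FALSE] %*%
                        object$coefficients[-1])
  } else {
    eta <- rep(eta, nrow(newX))
  }
  plogis(eta)
}

#' @importFrom stats glm.fit pnorm
NULL
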