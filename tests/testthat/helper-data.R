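# Small planted-signal designs used across tests. Built in code, no fixtures.

# Gaussian X with `signal` columns carrying coefficient `beta`; balanced
# logistic response.
planted_xy <- function(n, p, signal, beta = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  b <- numeric(p)
  b[signal] <- beta
  y <- rbinom(n, 1, plogis(drop(X %*% b)))
  list(X = X, y = y, beta = b, signal = signal)
}

planted_df <- function(n, p, signal, beta = 3, seed = 1) {
  xy <- planted_xy(n, p, signal, beta, seed)
  d <- tibble::as_tibble(as.data.frame(xy$X))
  d$y <- xy$y
  d
}

# Plain Newton-Raphson logistic solver; independent oracle for refits.
newton_logistic <- function(X, y, max_iter = 50, tol = 1e-12) {
  Xd <- cbind(1, X)
  b <- numeric(ncol(Xd))
  for (i in seq_len(max_iter)) {
    mu <- plogis(drop(Xd %*% b))
    W <- mu * (1 - mu)
    step <- solve(crossprod(Xd * sqrt(W)), crossprod(Xd, y - mu))
    b <- b + drop(step)
    if (max(abs(step)) < tol) break
  }
  b
}
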