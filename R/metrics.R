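#' True positive rate of a selection
#'
#' Fraction of the true signal variables that the selection recovered.
#'
#' @param selected Indices (or names) of the selected variables.
#' @param signal Indices (or names) of the true signal variables; must be
#'   non-empty.
#' @return A rate in \[0, 1\].
#' @export
tpr <- function(selected, signal) {
  if (length(signal) == 0L) stop("signal set must be non-empty for TPR", call. = FALSE)
  length(intersect(selected, signal)) / length(signal)
}

#' Positive predictive value of a selection
#'
#' Fraction of the selected variables that are true signals. An empty
#' selection has PPV 0 by convention.
#'
#' @inheritParams tpr
#' @return A rate in \[0, 1\].
#' @export
ppv <- function(selected, signal) {
  if (length(selected) == 0L) return(0)
  length(intersect(selected, signal)) / length(selected)
}

#' Set-similarity indices
#'
#' Jaccard `|A n B| / |A u B|`, Otsuka-Ochiai `|A n B| / sqrt(|A| |B|)` and
#' Sorensen-Dice `2 |A n B| / (|A| + |B|)`. Two empty sets have similarity 1
#' (perfect agreement on selecting nothing); exactly one empty set gives 0.
#'
#' @param s1,s2 Index (or name) vectors.
#' @return A value in \[0, 1\].
#' @examples
#' jaccard(1:3, 2:4)  # 0.5
#' ochiai(1:3, 2:4)   # 2/3
#' dice(1:3, 2:4)     # 2/3
#' @export
jaccard <- function(s1, s2) {
  s1 <- unique(s1); s2 <- unique(s2)
  if (length(s1) == 0L && length(s2) == 0L) return(1)
  if (length(s1) == 0L || length(s2) == 0L) return(0)
  length(intersect(s1, s2)) / length(union(s1, s2))
}

#' @rdname jaccard
#' @export
ochiai <- function(s1, s2) {
  s1 <- unique(s1); s2 <- unique(s2)
  if (length(s1) == 0L && length(s2) == 0L) return(1)
  if (length(s1) == 0L || length(s2) == 0L) return(0)
  length(intersect(s1, s2)) / sqrt(length(s1) * length(s2))
}

#' @rdname jaccard
#' @export
dice <- function(s1, s2) {
  s1 <- unique(s1); s2 <- unique(s2)
  if (length(s1) == 0L && length(s2) == 0L) return(1)
  if (length(s1) == 0L || length(s2) == 0L) return(0)
  2 * length(intersect(s1, s2)) / (length(s1) + length(s2))
}

#' Mean pairwise selection stability across replicates
#'
#' Arithmetic mean of a set-similarity index over all `D (D - 1) / 2`
#' unordered pairs of replicate selections, computed exactly.
#'
#' @param selections A list of `D >= 2` index vectors.
#' @param index `"jaccard"`, `"ochiai"` or `"dice"`.
#' @return The mean pairwise similarity.
#' @export
pairwise_stability <- function(selections, index = c("jaccard", "ochiai", "dice")) {
  index <- match.arg(index)
  D <- length(selections)
  if (D < 2L) stop("need at least two selections", call. = FALSE)
  f <- switch(index, jaccard = jaccard, ochiai = ochiai, dice = dice)
  prs <- combn(D, 2)
  mean(vapply(seq_len(ncol(prs)), function(k)
    f(selections[[prs[1, k]]], selections[[prs[2, k]]]), numeric(1)))
}

#' Area under the ROC curve (Mann-Whitney, midrank ties)
#'
#' `P(score_case > score_control) + P(tie) / 2`, computed from midranks. If
#' only one class is present, 0.5 is returned with a warning.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Binary labels (0/1) aligned with `scores`.
#' @return AUC in \[0, 1\].
#' @examples
#' auc_mw(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
auc_mw <- function(scores, labels) {
  if (length(scores) == 0L) stop("empty input", call. = FALSE)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) {
    warning("only one class present; AUC set to 0.5")
    return(0.5)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Validation AUC of a selected variable set
#'
#' Refits an unpenalized logistic model with the selected columns on the
#' training data and scores its predicted probabilities on the held-out
#' data. An empty selection scores 0.5.
#'
#' @param train,val Data frames with identical predictor columns and the
#'   response column.
#' @param selected Integer indices into the predictor columns (response
#'   excluded), or a character vector of predictor names.
#' @param response Name of the response column.
#' @return AUC on the held-out data.
#' @export
validation_auc <- function(train, val, selected, response = "y") {
  tr <- df_to_xy(train, response)
  va <- df_to_xy(val, response)
  if (!identical(colnames(tr$X), colnames(va$X))) {
    stop("train and validation predictor columns differ", call. = FALSE)
  }
  if (is.character(selected)) selected <- match(selected, colnames(tr$X))
  if (length(selected) == 0L) return(0.5)
  fit <- refit_logistic(tr$X, tr$y, selected)
  auc_mw(predict(fit, va$X), va$y)
}
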