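#' Logistic (sigmoid) function
#'
#' @param x Numeric vector on the logit scale.
#' @return `1 / (1 + exp(-x))`.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Clip probabilities away from 0 and 1
#'
#' Keeps logits finite; the propensity module clips all emitted scores with
#' the default `eps` so matching distances are always defined.
#'
#' @param p Numeric vector of probabilities.
#' @param eps Clipping bound; scores end up in `[eps, 1 - eps]`.
#' @return Clipped vector.
#' @export
clip_prob <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

#' Log-odds of a (clipped) probability
#'
#' @param p Numeric vector of probabilities; clipped via [clip_prob()] first.
#' @param eps Clipping bound passed to [clip_prob()].
#' @return `log(p / (1 - p))`.
#' @export
logit <- function(p, eps = 1e-6) {
  p <- clip_prob(p, eps)
  log(p / (1 - p))
}

#' Nearest-rank percentile
#'
#' The p-th nearest-rank percentile of `x` is the `ceiling(p/100 * n)`-th
#' order statistic. Used for the 99th-percentile spend cap.
#'
#' @param x Numeric vector (length >= 1).
#' @param p Percentile in (0, 100].
#' @return A single number, an element of `x`.
#' @export
nearest_rank <- function(x, p) {
  if (length(x) == 0) rlang::abort("nearest_rank() needs a non-empty vector")
  sort(x)[max(1L, ceiling(p / 100 * length(x)))]
}

# Rank-based (Wilcoxon) AUC of scores against binary labels.
auc_rank <- function(score, label) {
  label <- as.logical(label)
  n1 <- sum(label)
  n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Abort unless `cond`, with a data-oriented message.
check_that <- function(cond, msg, class = "pupmatch_error") {
  if (!isTRUE(cond)) rlang::abort(msg, class = class)
  invisible(TRUE)
}

# Column-wise cumulative sum of a dense matrix (few columns, many rows);
# done as one BLAS product with an upper-triangular ones matrix.
col_cumsum <- function(m) {
  u <- matrix(0, ncol(m), ncol(m))
  u[upper.tri(u, diag = TRUE)] <- 1
  m %*% u
}
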