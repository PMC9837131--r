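## internal numerical helpers

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

sigmoid <- function(x) plogis(x)

## Euler-Mascheroni constant
.euler <- -digamma(1)

#' Rank-based ROC-AUC
#'
#' Area under the ROC curve computed by the rank (Mann-Whitney) identity,
#' used for the per-epoch training trace and topic-number selection.
#'
#' @param score numeric vector of scores (higher = more likely positive).
#' @param y binary 0/1 outcome vector of the same length.
#' @return AUC in \[0, 1\]; `NA` if either class is empty.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
#' @export
roc_auc <- function(score, y) {
  stopifnot(length(score) == length(y))
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## derive a bounded child seed from a master seed and a stage tag, so that
## pipeline stages are independently reproducible from one --seed
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## dense numeric matrix from possibly-sparse input
as_dense <- function(X) {
  if (inherits(X, "Matrix")) X <- as.matrix(X)
  storage.mode(X) <- "double"
  X
}
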