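#' Poisson log-likelihood of a binary patient vector under a topic model
#'
#' Computes `log p(x | Phi, theta)` for one patient or a batch. The model
#' rate is `m = Phi %*% theta`. Two observation links are supported for
#' binary data:
#' \describe{
#'   \item{`"poisson"`}{binary entries treated literally as counts:
#'     `sum(x * log(m) - m)` (the `x!` term vanishes for x in \{0,1\}).}
#'   \item{`"bernoulli-poisson"`}{a latent Poisson count is thresholded at
#'     one, so `P(x = 1) = 1 - exp(-m)`:
#'     `sum(x * log(1 - exp(-m)) - (1 - x) * m)`.}
#' }
#'
#' @param x binary vector (length V) or V x N matrix.
#' @param Phi V x K topic matrix, columns on the simplex.
#' @param theta nonnegative topic-weight vector (length K) or K x N matrix.
#' @param link observation link, `"poisson"` (default) or
#'   `"bernoulli-poisson"`.
#' @param floor small positive rate floor guarding `log(0)`.
#' @return scalar log-likelihood summed over all entries.
#' @examples
#' Phi <- matrix(c(0.5, 0.5), 2, 1)
#' poisson_loglik(c(0, 1), Phi, 2)   # rates (1, 1): 0*log(1)-1 + 1*log(1)-1
#' @export
poisson_loglik <- function(x, Phi, theta,
                           link = c("poisson", "bernoulli-poisson"),
                           floor = 1e-10) {
  link <- match.arg(link)
  x <- as.matrix(x); theta <- as.matrix(theta)
  if (nrow(theta) != ncol(Phi))
    stop("theta has ", nrow(theta), " rows but Phi has ", ncol(Phi), " columns")
  if (nrow(x) != nrow(Phi))
    stop("x has ", nrow(x), " rows but Phi has ", nrow(Phi))
  m <- Phi %*% theta
  if (any(m < 0)) stop("negative Poisson rate: Phi %*% theta must be nonnegative")
  if (link == "poisson") {
    sum(x * log(m + floor) - m)
  } else {
    p1 <- -expm1(-m)
    sum(x * log(p1 + floor) - (1 - x) * m)
  }
}

#' Reparameterized Weibull sampling
#'
#' Draws `theta = scale * (-log(1 - u))^(1/shape)` from a Weibull
#' distribution via the inverse-CDF transform of uniform draws, the
#' reparameterization used to backpropagate through the variational
#' posterior. With `u = 1 - exp(-1)` the draw equals `scale` exactly; with
#' `shape = 1` draws are exponential with mean `scale`.
#'
#' @param u uniform draws in (0, 1); vector, matrix, or a single integer
#'   count `n` when `random = TRUE`.
#' @param shape,scale positive Weibull parameters, recycled against `u`.
#' @return Weibull draws with the shape of `u`.
#' @examples
#' sample_weibull(1 - exp(-1), shape = 2, scale = 3)  # exactly 3
#' @export
sample_weibull <- function(u, shape, scale) {
  if (any(shape <= 0) || any(scale <= 0))
    stop("Weibull shape and scale must be positive")
  if (any(u <= 0 | u >= 1)) stop("uniform draws must lie strictly in (0, 1)")
  scale * (-log1p(-u))^(1 / shape)
}

#' Analytic KL divergence from a Weibull to a Gamma distribution
#'
#' `KL(Weibull(shape_w, scale_w) || Gamma(shape_g, rate_g))`, the
#' regularization term of the evidence lower bound. Assembled from the
#' Weibull identities `E[log theta] = log(scale_w) - gamma_E / shape_w`,
#' `E[theta] = scale_w * Gamma(1 + 1/shape_w)` and the Weibull entropy
#' `gamma_E (1 - 1/shape_w) + log(scale_w / shape_w) + 1`, where `gamma_E`
#' is the Euler-Mascheroni constant. Equals zero iff both distributions are
#' the same exponential (`shape_w = shape_g = 1`, `scale_w = 1 / rate_g`).
#'
#' @param shape_w,scale_w Weibull posterior parameters (> 0), vectorized.
#' @param shape_g,rate_g Gamma prior shape and rate (> 0).
#' @return KL divergence(s), nonnegative.
#' @examples
#' kl_weibull_gamma(1, 2, 1, 0.5)  # same exponential: 0
#' @export
kl_weibull_gamma <- function(shape_w, scale_w, shape_g, rate_g) {
  if (any(shape_w <= 0) || any(scale_w <= 0) || any(shape_g <= 0) || any(rate_g <= 0))
    stop("all Weibull and Gamma parameters must be strictly positive")
  shape_g * .euler / shape_w - .euler + log(shape_w) -
    shape_g * log(scale_w) - 1 - shape_g * log(rate_g) + lgamma(shape_g) +
    rate_g * scale_w * gamma(1 + 1 / shape_w)
}

## partial derivatives of kl_weibull_gamma, used by the trainer
kl_weibull_gamma_grad <- function(shape_w, scale_w, shape_g, rate_g) {
  g1 <- gamma(1 + 1 / shape_w)
  list(
    shape = -shape_g * .euler / shape_w^2 + 1 / shape_w -
      rate_g * scale_w * g1 * digamma(1 + 1 / shape_w) / shape_w^2,
    scale = -shape_g / scale_w + rate_g * g1
  )
}

#' Monte-Carlo evidence lower bound
#'
#' Evaluates the ELBO `sum_n [ E_q log p(x_n | Phi, theta_n) - KL(q || p) ]`
#' for given Weibull posterior parameters, drawing `S` reparameterized
#' samples per patient for the expectation term. When called on a
#' mini-batch, multiply by `N / batch` for full-data comparability (the
#' trainer does this internally).
#'
#' @param X binary V x N matrix.
#' @param Phi V x K topic matrix.
#' @param shape_w,scale_w K x N Weibull posterior parameter matrices.
#' @param prior length-2 numeric `c(shape, rate)` of the Gamma prior.
#' @param S Monte-Carlo samples per patient (default 1).
#' @param link observation link, see [poisson_loglik()].
#' @param u optional array of uniform draws `dim = c(K, N, S)` for
#'   deterministic evaluation; drawn internally when `NULL`.
#' @return scalar ELBO estimate.
#' @export
spfa_elbo <- function(X, Phi, shape_w, scale_w, prior = c(0.5, 1), S = 1,
                      link = "poisson", u = NULL) {
  X <- as_dense(X)
  K <- ncol(Phi); N <- ncol(X)
  stopifnot(nrow(shape_w) == K, ncol(shape_w) == N,
            all(dim(scale_w) == dim(shape_w)))
  if (is.null(u)) u <- array(runif(K * N * S, 1e-12, 1 - 1e-12), c(K, N, S))
  ll <- 0
  for (s in seq_len(S)) {
    th <- sample_weibull(u[, , s, drop = TRUE], shape_w, scale_w)
    ll <- ll + poisson_loglik(X, Phi, matrix(th, K, N), link = link) / S
  }
  ll - sum(kl_weibull_gamma(shape_w, scale_w, prior[1], prior[2]))
}

#' Normalize topic weights to topic proportions
#'
#' Per-patient normalization `theta / sum(theta)` so each column is a point
#' on the simplex and patients are comparable regardless of overall event
#' volume.
#'
#' @param theta nonnegative vector or K x N matrix of topic weights.
#' @return object of the same shape with columns summing to one.
#' @examples
#' normalize_proportions(c(1, 1, 2))
#' @export
normalize_proportions <- function(theta) {
  if (is.matrix(theta)) {
    cs <- colSums(theta)
    if (any(cs <= 0) || any(theta < 0))
      stop("topic weights must be nonnegative with positive per-patient sums")
    sweep(theta, 2, cs, "/")
  } else {
    s <- sum(theta)
    if (s <= 0 || any(theta < 0))
      stop("topic weights must be nonnegative with a positive sum")
    theta / s
  }
}

#' Count active topics under the shrinkage criterion
#'
#' The Gamma prior prunes topics the corpus does not need; a topic is
#' declared active when its corpus-mean proportion is at least `tau`
#' (default `1 / (10 K)`, a tenth of the uniform share).
#'
#' @param proportions K x N matrix of per-patient topic proportions.
#' @param tau activity threshold on the corpus-mean proportion.
#' @return list with `n_active`, integer vector `active` of topic indices,
#'   and the corpus `mean_proportion` per topic.
#' @export
active_topics <- function(proportions, tau = 1 / (10 * nrow(proportions))) {
  mp <- rowMeans(proportions)
  act <- which(mp >= tau)
  list(n_active = length(act), active = act, mean_proportion = mp)
}
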