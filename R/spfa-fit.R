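## Supervised Poisson factor analysis: model fitting.
##
## The generative model is X ~ Poisson(Phi Theta) with Phi columns on the
## simplex and theta_n ~ Gamma(shape, rate) per topic. Inference is
## auto-encoding variational: a one-hidden-layer encoder maps each binary
## patient vector to per-topic Weibull posterior parameters (shape, scale),
## topic weights are drawn by the inverse-CDF reparameterization, and the
## objective ELBO + zeta * log p(y | theta) is maximized by Adam. Phi is
## parameterized by unconstrained logits mapped through a column softmax so
## every update step keeps its columns exactly on the simplex.

.spfa_init <- function(V, K, hidden) {
  list(
    W1 = matrix(rnorm(hidden * V, 0, 0.05), hidden, V),
    b1 = numeric(hidden),
    Wk = matrix(rnorm(K * hidden, 0, 0.05), K, hidden),
    bk = rep(0.55, K),               # softplus(0.55) ~ 1: shape starts near 1
    Wl = matrix(rnorm(K * hidden, 0, 0.05), K, hidden),
    bl = rep(0.55, K),
    B  = matrix(rnorm(V * K, 0, 0.1), V, K),  # Phi logits
    w  = numeric(K),
    b0 = 0
  )
}

.softmax_cols <- function(B) {
  E <- exp(sweep(B, 2, apply(B, 2, max), "-"))
  sweep(E, 2, colSums(E), "/")
}

## Encoder forward pass: binary features -> Weibull (shape, scale).
## Smooth positive link (softplus) with floor 1e-4 for numerical stability.
.spfa_encode <- function(pars, X, floor_par = 1e-4) {
  H <- tanh(pars$W1 %*% X + pars$b1)
  list(H = H,
       Ak = pars$Wk %*% H + pars$bk,
       Al = pars$Wl %*% H + pars$bl,
       floor = floor_par)
}

## Objective (to be maximized) and analytic gradients for one batch, with
## the uniform draws u (K x B x S array) held fixed so the mapping is
## deterministic and differentiable -- this is also the surface the
## finite-difference correctness test exercises.
.spfa_objective_grad <- function(pars, X, y = NULL, prior = c(0.5, 1),
                                 zeta = 1, link = "poisson", u,
                                 scale = 1, grads = TRUE) {
  V <- nrow(X); Bn <- ncol(X); K <- ncol(pars$B)
  if (length(dim(u)) == 2L) u <- array(u, c(dim(u), 1L))
  S <- dim(u)[3]
  eps <- 1e-10; fl <- 1e-4
  enc <- .spfa_encode(pars, X, fl)
  kw <- softplus(enc$Ak) + fl
  lw <- softplus(enc$Al) + fl
  Phi <- .softmax_cols(pars$B)

  KL <- kl_weibull_gamma(kw, lw, prior[1], prior[2])
  dKL <- if (grads) kl_weibull_gamma_grad(kw, lw, prior[1], prior[2])

  rec <- 0; sup <- 0
  Gk <- Gl <- matrix(0, K, Bn)
  GPhi <- matrix(0, V, K)
  gw <- numeric(K); gb0 <- 0
  for (s in seq_len(S)) {
    us <- matrix(u[, , s], K, Bn)
    e <- -log1p(-us)
    tt <- e^(1 / kw)
    th <- lw * tt
    m <- Phi %*% th + eps
    if (link == "poisson") {
      rec <- rec + sum(X * log(m) - m) / S
      dm <- X / m - 1
    } else {
      p1 <- -expm1(-m)
      rec <- rec + sum(X * log(p1 + eps) - (1 - X) * m) / S
      dm <- X * exp(-m) / (p1 + eps) - (1 - X)
    }
    Gth <- crossprod(Phi, dm)
    if (!is.null(y)) {
      pr <- sigmoid(drop(crossprod(pars$w, th)) + pars$b0)
      sup <- sup + sum(y * log(pr + eps) + (1 - y) * log(1 - pr + eps)) / S
      resid <- y - pr
      Gth <- Gth + zeta * outer(pars$w, resid)
      gw <- gw + zeta * drop(th %*% resid) / S
      gb0 <- gb0 + zeta * sum(resid) / S
    }
    if (grads) {
      Gl <- Gl + (Gth * tt) / S
      Gk <- Gk + (Gth * (-th * log(e) / kw^2)) / S
      GPhi <- GPhi + (dm %*% t(th)) / S
    }
  }
  value <- scale * (rec - sum(KL) + zeta * sup)
  parts <- c(reconstruction = rec, kl = sum(KL), supervised = sup)
  if (!grads) return(list(value = value, parts = parts))

  Gk <- Gk - dKL$shape
  Gl <- Gl - dKL$scale
  GAk <- Gk * sigmoid(enc$Ak)
  GAl <- Gl * sigmoid(enc$Al)
  GH <- crossprod(pars$Wk, GAk) + crossprod(pars$Wl, GAl)
  GA1 <- GH * (1 - enc$H^2)
  g <- list(
    W1 = GA1 %*% t(X), b1 = rowSums(GA1),
    Wk = GAk %*% t(enc$H), bk = rowSums(GAk),
    Wl = GAl %*% t(enc$H), bl = rowSums(GAl),
    B  = Phi * sweep(GPhi, 2, colSums(Phi * GPhi), "-"),
    w  = gw, b0 = gb0
  )
  g <- lapply(g, function(x) x * scale)
  list(value = value, parts = parts, grads = g)
}

.spfa_train_once <- function(X, y, K, zeta, prior, link, hidden, epochs,
                             batch_size, lr, lr_phi, lr_decay, S, langevin,
                             verbose) {
  V <- nrow(X); N <- ncol(X)
  pars <- .spfa_init(V, K, hidden)
  mom <- lapply(pars, function(p) p * 0)
  vel <- mom
  b1a <- 0.9; b2a <- 0.999; epsA <- 1e-8; t_adam <- 0
  trace <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(N)
    nb <- ceiling(N / batch_size)
    obj <- el <- sp <- 0
    rate_mult <- lr_decay^((ep - 1) / epochs)
    for (ib in seq_len(nb)) {
      idx <- ord[((ib - 1) * batch_size + 1):min(ib * batch_size, N)]
      Xb <- X[, idx, drop = FALSE]
      u <- array(runif(K * length(idx) * S, 1e-6, 1 - 1e-6),
                 c(K, length(idx), S))
      og <- .spfa_objective_grad(pars, Xb, y[idx], prior, zeta, link, u,
                                 scale = N / length(idx))
      if (!is.finite(og$value)) {
        bad <- names(og$parts)[!is.finite(og$parts)]
        stop("non-finite training objective at epoch ", ep,
             " (offending term: ",
             if (length(bad)) paste(bad, collapse = ", ") else "total",
             ")")
      }
      obj <- obj + og$value / nb
      el <- el + (og$parts["reconstruction"] - og$parts["kl"]) *
        (N / length(idx)) / nb
      sp <- sp + og$parts["supervised"] * (N / length(idx)) / nb
      t_adam <- t_adam + 1
      for (nm in names(pars)) {
        gr <- og$grads[[nm]]
        mom[[nm]] <- b1a * mom[[nm]] + (1 - b1a) * gr
        vel[[nm]] <- b2a * vel[[nm]] + (1 - b2a) * gr^2
        step <- (if (nm == "B") lr_phi else lr) * rate_mult *
          (mom[[nm]] / (1 - b1a^t_adam)) /
          (sqrt(vel[[nm]] / (1 - b2a^t_adam)) + epsA)
        if (langevin && nm == "B")
          step <- step + sqrt(2 * lr_phi * rate_mult) * 1e-3 *
            matrix(rnorm(length(pars$B)), nrow(pars$B), ncol(pars$B))
        pars[[nm]] <- pars[[nm]] + step
      }
    }
    ## full-data deterministic diagnostics on the posterior mean weights
    enc <- .spfa_encode(pars, X)
    kw <- softplus(enc$Ak) + 1e-4
    lw <- softplus(enc$Al) + 1e-4
    th <- lw * gamma(1 + 1 / kw)
    auc <- NA_real_
    if (!is.null(y))
      auc <- roc_auc(drop(crossprod(pars$w, th)) + pars$b0, y)
    prop <- normalize_proportions(th)
    act <- active_topics(prop)$n_active
    trace[[ep]] <- data.frame(epoch = ep, objective = obj, elbo = el,
                              supervised = sp, auc = auc, n_active = act)
    if (verbose && (ep %% 25 == 0 || ep == epochs))
      message(sprintf("epoch %d  objective %.1f  auc %s  active %d",
                      ep, obj, format(round(auc, 3)), act))
  }
  list(pars = pars, trace = do.call(rbind, trace), theta = th)
}

#' Fit a supervised Poisson factor analysis model
#'
#' Decomposes a binary patient-by-feature matrix into `K` clinical topics
#' with per-patient nonnegative topic weights, optionally guided by a
#' binary outcome through a logistic head on the weights. Training
#' maximizes the evidence lower bound of the Poisson factor model (Gamma
#' prior on weights, amortized Weibull posterior) plus `zeta` times the
#' outcome log-likelihood, by mini-batch Adam with a decaying learning
#' rate. The Gamma prior shrinks the weights of topics the corpus does not
#' need, so the effective number of topics can end well below `K` (see
#' [active_topics()]).
#'
#' @param X binary feature matrix, features in rows and patients in
#'   columns (V x N), dense or `Matrix` sparse.
#' @param y optional binary outcome per patient (length N); `NULL` fits
#'   the unsupervised model.
#' @param K number of topics (default 40, a cohort-scale setting; use
#'   less for small corpora).
#' @param zeta weight of the supervised term (default 1; 0 recovers the
#'   unsupervised objective exactly).
#' @param prior Gamma prior `c(shape, rate)` on topic weights; the default
#'   `c(0.5, 1)` realizes the shrinkage behaviour.
#' @param link observation link for binary data, `"poisson"` (entries as
#'   counts, the default) or `"bernoulli-poisson"` (thresholded latent
#'   count, statistically well-specified for binarized data).
#' @param hidden encoder hidden-layer width.
#' @param epochs,batch_size,lr,lr_phi,lr_decay optimization controls:
#'   epochs, mini-batch size, Adam step sizes for the encoder/classifier
#'   and for the topic logits, and the end-of-training learning-rate decay
#'   factor (rates are multiplied by `lr_decay^(epoch/epochs)`).
#' @param S Monte-Carlo samples per patient per step (default 1).
#' @param restarts independent initializations; the fit with the best
#'   final-epoch objective is kept.
#' @param langevin add small Gaussian noise to the topic-logit updates
#'   (a Langevin-style variant of the Phi update).
#' @param seed integer seed; fits are bit-reproducible given the seed.
#' @param verbose print progress every 25 epochs.
#' @return an object of class `"spfa"`: a list with the topic matrix
#'   `Phi` (V x K, columns on the simplex), encoder and classifier
#'   parameters, posterior-mean training weights `theta` (K x N), the
#'   per-epoch `trace` (objective, ELBO, supervised term, training AUC,
#'   active-topic count), the Gamma `prior`, fitting `config`, and
#'   feature/patient names taken from `dimnames(X)`.
#' @seealso [predict.spfa()], [subphenotype()], [topic_stats()],
#'   [simulate_cohort()]
#' @examples
#' sim <- simulate_corpus(V = 30, N = 120, K_true = 3, seed = 1)
#' fit <- spfa(sim$X, K = 5, epochs = 30, batch_size = 60, seed = 1)
#' fit
#' @export
spfa <- function(X, y = NULL, K = 40, zeta = 1, prior = c(0.5, 1),
                 link = c("poisson", "bernoulli-poisson"), hidden = 64,
                 epochs = 300, batch_size = 250, lr = 0.01, lr_phi = 0.05,
                 lr_decay = 0.1, S = 1, restarts = 1, langevin = FALSE,
                 seed = 1, verbose = FALSE) {
  link <- match.arg(link)
  X <- as_dense(X)
  if (!all(X %in% c(0, 1))) stop("X must be a binary 0/1 matrix")
  if (!is.null(y)) {
    y <- as.integer(y)
    if (length(y) != ncol(X)) stop("length(y) must equal ncol(X)")
    if (!all(y %in% 0:1)) stop("y must be binary 0/1")
  }
  stopifnot(K >= 1, zeta >= 0, S >= 1, epochs >= 1,
            length(prior) == 2, all(prior > 0))
  batch_size <- min(batch_size, ncol(X))

  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(derive_seed(seed, paste0("spfa-fit-", r)))
    fit <- .spfa_train_once(X, y, K, zeta, prior, link, hidden, epochs,
                            batch_size, lr, lr_phi, lr_decay, S, langevin,
                            verbose)
    if (is.null(best) ||
        fit$trace$objective[epochs] > best$trace$objective[epochs])
      best <- fit
  }
  Phi <- .softmax_cols(best$pars$B)
  colnames(Phi) <- paste0("T", seq_len(K))
  rownames(Phi) <- rownames(X)
  theta <- best$theta
  dimnames(theta) <- list(colnames(Phi), colnames(X))
  structure(list(
    Phi = Phi,
    encoder = best$pars[c("W1", "b1", "Wk", "bk", "Wl", "bl")],
    classifier = list(coef = setNames(best$pars$w, colnames(Phi)),
                      intercept = best$pars$b0),
    theta = theta,
    prior = setNames(prior, c("shape", "rate")),
    trace = best$trace,
    config = list(K = K, zeta = zeta, link = link, hidden = hidden,
                  epochs = epochs, batch_size = batch_size, lr = lr,
                  lr_phi = lr_phi, lr_decay = lr_decay, S = S,
                  restarts = restarts, langevin = langevin, seed = seed),
    supervised = !is.null(y),
    y = y,
    feature_names = rownames(X),
    patient_ids = colnames(X),
    call = match.call()
  ), class = "spfa")
}

#' Infer topic weights for (new) patients
#'
#' Runs the fitted encoder on binary patient vectors and returns either
#' posterior-mean topic weights (`E[theta] = scale * Gamma(1 + 1/shape)`,
#' deterministic), normalized topic proportions, a reparameterized
#' posterior sample, or the SAE outcome probability from the logistic
#' head.
#'
#' @param object fitted [spfa()] model.
#' @param newdata binary V x N matrix in the model's feature space;
#'   defaults to the training matrix representation via stored weights
#'   (requires `newdata` for anything not cached).
#' @param type `"weights"` (K x N posterior means), `"proportions"`
#'   (columns on the simplex), `"sample"` (one reparameterized draw), or
#'   `"response"` (outcome probability per patient).
#' @param seed seed for `type = "sample"`.
#' @param ... unused.
#' @return matrix (weights/proportions/sample) or numeric vector
#'   (response).
#' @export
predict.spfa <- function(object, newdata = NULL,
                         type = c("weights", "proportions", "sample",
                                  "response"),
                         seed = 1, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    th <- object$theta
  } else {
    newdata <- as_dense(newdata)
    if (nrow(newdata) != nrow(object$Phi))
      stop("newdata has ", nrow(newdata), " features but the model was fit with ",
           nrow(object$Phi))
    enc <- .spfa_encode(object$encoder, newdata)
    kw <- softplus(enc$Ak) + 1e-4
    lw <- softplus(enc$Al) + 1e-4
    th <- if (type == "sample") {
      set.seed(derive_seed(seed, "spfa-predict-sample"))
      u <- matrix(runif(length(kw), 1e-12, 1 - 1e-12), nrow(kw), ncol(kw))
      sample_weibull(u, kw, lw)
    } else {
      lw * gamma(1 + 1 / kw)
    }
    dimnames(th) <- list(colnames(object$Phi), colnames(newdata))
  }
  switch(type,
    weights = th,
    sample = th,
    proportions = normalize_proportions(th),
    response = sigmoid(drop(crossprod(object$classifier$coef, th)) +
                         object$classifier$intercept))
}

#' @export
print.spfa <- function(x, ...) {
  cfg <- x$config
  act <- active_topics(normalize_proportions(x$theta))
  cat("Supervised Poisson factor analysis\n")
  cat(sprintf("  features: %d   patients: %d   topics: %d (%d active)\n",
              nrow(x$Phi), ncol(x$theta), cfg$K, act$n_active))
  cat(sprintf("  link: %s   prior: Gamma(%.2g, %.2g)   zeta: %g\n",
              cfg$link, x$prior[1], x$prior[2], cfg$zeta))
  tr <- x$trace[nrow(x$trace), ]
  cat(sprintf("  final objective: %.1f", tr$objective))
  if (x$supervised) cat(sprintf("   training AUC: %.3f", tr$auc))
  cat("\n")
  invisible(x)
}

#' @export
summary.spfa <- function(object, top = 5, ...) {
  prop <- normalize_proportions(object$theta)
  act <- active_topics(prop)
  tops <- apply(object$Phi, 2, function(p)
    paste(head(rownames(object$Phi)[order(-p)], top), collapse = ", "))
  out <- list(
    call = object$call,
    config = object$config,
    n_active = act$n_active,
    topic_table = data.frame(
      topic = colnames(object$Phi),
      mean_proportion = act$mean_proportion,
      active = seq_len(ncol(object$Phi)) %in% act$active,
      top_features = tops,
      row.names = NULL),
    final = object$trace[nrow(object$trace), ],
    supervised = object$supervised)
  class(out) <- "summary.spfa"
  out
}

#' @export
print.summary.spfa <- function(x, ...) {
  cat("Supervised Poisson factor analysis\n\nCall:\n  ")
  print(x$call)
  cat(sprintf("\n%d of %d topics active (corpus-mean proportion >= 1/(10K))\n\n",
              x$n_active, x$config$K))
  tt <- x$topic_table
  tt$mean_proportion <- round(tt$mean_proportion, 4)
  print(tt[order(-tt$mean_proportion), ], row.names = FALSE)
  cat(sprintf("\nFinal objective %.1f", x$final$objective))
  if (x$supervised) cat(sprintf(", training AUC %.3f", x$final$auc))
  cat("\n")
  invisible(x)
}

#' Extract fitted coefficients
#'
#' `which = "classifier"` returns the logistic outcome head (intercept and
#' one coefficient per topic); `which = "topics"` returns the topic matrix
#' `Phi`.
#'
#' @param object fitted [spfa()] model.
#' @param which `"classifier"` or `"topics"`.
#' @param ... unused.
#' @export
coef.spfa <- function(object, which = c("classifier", "topics"), ...) {
  which <- match.arg(which)
  if (which == "topics") return(object$Phi)
  c("(Intercept)" = object$classifier$intercept, object$classifier$coef)
}

#' Plot the training trace of an SPFA fit
#'
#' Objective per epoch, with the training AUC overlaid for supervised
#' fits.
#'
#' @param x fitted [spfa()] model.
#' @param ... passed to [plot()].
#' @export
plot.spfa <- function(x, ...) {
  tr <- x$trace
  op <- par(mar = c(4, 4, 2, 4))
  on.exit(par(op))
  plot(tr$epoch, tr$objective, type = "l", xlab = "epoch",
       ylab = "objective", main = "SPFA training", ...)
  if (x$supervised && any(is.finite(tr$auc))) {
    par(new = TRUE)
    plot(tr$epoch, tr$auc, type = "l", lty = 2, axes = FALSE,
         xlab = "", ylab = "", ylim = c(0.5, 1))
    axis(4)
    legend("bottomright", c("objective", "training AUC"), lty = 1:2,
           bty = "n")
  }
  invisible(x)
}

#' Simulate binary data from a fitted SPFA model
#'
#' Draws new patients from the fitted generative model: topic weights from
#' the Gamma prior, counts from `Poisson(Phi theta)`, binarized.
#'
#' @param object fitted [spfa()] model.
#' @param nsim number of simulated matrices.
#' @param seed integer seed.
#' @param N patients per simulated matrix (default: training N).
#' @param ... unused.
#' @return list of `nsim` binary V x N matrices.
#' @export
simulate.spfa <- function(object, nsim = 1, seed = 1, N = NULL, ...) {
  N <- N %||% ncol(object$theta)
  set.seed(derive_seed(seed, "spfa-simulate"))
  K <- ncol(object$Phi); V <- nrow(object$Phi)
  lapply(seq_len(nsim), function(i) {
    Theta <- matrix(rgamma(K * N, object$prior["shape"],
                           object$prior["rate"]), K, N)
    Xs <- matrix(rpois(V * N, object$Phi %*% Theta), V, N)
    Xs[Xs > 1] <- 1
    rownames(Xs) <- rownames(object$Phi)
    Xs
  })
}
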