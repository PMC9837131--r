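## Topic triage against the SAE outcome: group-level mean topic weights,
## Mann-Whitney U tests, category assignment, NPMI coherence and
## top-feature summaries.

#' Mean topic weight of a patient group
#'
#' Arithmetic mean of normalized topic proportions over the group's
#' members, per topic; a simplex point for any non-empty group.
#'
#' @param prop patients x K matrix of topic proportions (or an `spfa`
#'   fit).
#' @param members logical or integer index of group members.
#' @return named numeric vector of length K summing to one.
#' @export
mean_topic_weight <- function(prop, members) {
  prop <- .prop_from(prop)
  m <- prop[members, , drop = FALSE]
  if (nrow(m) == 0) stop("empty group")
  colMeans(m)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact null enumeration when the combined sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections. Constant pooled data (a degenerate comparison)
#' returns p = 1 with a warning.
#'
#' @param a,b numeric samples for the two groups.
#' @return two-sided p-value.
#' @examples
#' mwu_test(c(1, 2, 3), c(4, 5, 6))  # exact: 2 / choose(6, 3) = 0.1
#' @export
mwu_test <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    warning("constant pooled data; degenerate comparison, p = 1")
    return(1)
  }
  ties <- any(duplicated(pooled))
  exact <- (length(a) + length(b) <= 12) && !ties
  suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE,
                alternative = "two.sided")$p.value)
}

#' Categorize topics by outcome alignment
#'
#' A topic is SAE-aligned when its Mann-Whitney p-value is at most
#' `alpha` and its mean topic weight is larger in the SAE group;
#' non-SAE-aligned when significant in the other direction; shared when
#' not significant but its pooled mean topic weight ranks in the top
#' `top_m`; otherwise unselected.
#'
#' @param mtw_sae,mtw_nonsae mean-topic-weight vectors of the two groups.
#' @param p per-topic Mann-Whitney p-values.
#' @param pooled_mtw pooled-corpus mean topic weights used for the
#'   shared-topic rank (default: average of the two group vectors).
#' @param alpha significance level (default 0.05).
#' @param top_m rank cutoff for shared topics (default 3).
#' @return character vector of categories.
#' @export
classify_topics <- function(mtw_sae, mtw_nonsae, p,
                            pooled_mtw = (mtw_sae + mtw_nonsae) / 2,
                            alpha = 0.05, top_m = 3) {
  stopifnot(length(mtw_sae) == length(mtw_nonsae),
            length(p) == length(mtw_sae))
  rk <- rank(-pooled_mtw, ties.method = "min")
  ifelse(p <= alpha & mtw_sae > mtw_nonsae, "SAE-aligned",
    ifelse(p <= alpha & mtw_sae < mtw_nonsae, "nonSAE-aligned",
      ifelse(rk <= top_m, "shared", "unselected")))
}

#' NPMI coherence of a topic's top features
#'
#' Mean normalized pointwise mutual information over all pairs of the
#' given features, with probabilities estimated as patient-level
#' occurrence fractions in the corpus:
#' `NPMI(i, j) = log((P(i,j) + eps) / (P(i) P(j))) / (-log(P(i,j) + eps))`.
#' Bounded in \[-1, 1\]; 1 for perfectly co-occurring pairs, near 0 for
#' independent ones.
#'
#' @param features indices (or names) of at least two features.
#' @param X binary feature-by-patient corpus matrix.
#' @param eps floor guarding empty co-occurrence (default 1e-10).
#' @return mean pairwise NPMI.
#' @export
npmi_coherence <- function(features, X, eps = 1e-10) {
  X <- as_dense(X)
  if (length(features) < 2) stop("need at least two features")
  if (ncol(X) == 0) stop("empty corpus")
  sub <- X[features, , drop = FALSE]
  pv <- rowMeans(sub)
  pairs <- utils::combn(length(features), 2)
  vals <- apply(pairs, 2, function(ij) {
    pij <- mean(sub[ij[1], ] * sub[ij[2], ]) + eps
    log(pij / (pv[ij[1]] * pv[ij[2]] + eps)) / (-log(pij))
  })
  mean(vals)
}

#' Top features of each topic with patient prevalence
#'
#' For each topic, the `M` features with the largest loadings, together
#' with each feature's prevalence among the topic's dominant patients
#' (patients whose largest topic proportion is that topic). Topics with no
#' dominant patients report missing prevalence.
#'
#' @param fit fitted [spfa()] model.
#' @param X binary feature-by-patient matrix (default: not needed if only
#'   loadings are wanted, but prevalence requires it).
#' @param M features per topic (default 5).
#' @return list of data.frames (feature, loading, prevalence), one per
#'   topic, loadings non-increasing.
#' @export
top_features <- function(fit, X = NULL, M = 5) {
  prop <- predict(fit, type = "proportions")
  dom <- apply(prop, 2, which.max)
  lapply(seq_len(ncol(fit$Phi)), function(k) {
    ord <- order(-fit$Phi[, k])[seq_len(min(M, nrow(fit$Phi)))]
    prev <- rep(NA_real_, length(ord))
    if (!is.null(X)) {
      mem <- which(dom == k)
      if (length(mem))
        prev <- rowMeans(as_dense(X)[ord, mem, drop = FALSE])
    }
    data.frame(feature = (fit$feature_names %||%
                            paste0("f", seq_len(nrow(fit$Phi))))[ord],
               loading = fit$Phi[ord, k], prevalence = prev,
               row.names = NULL)
  })
}

#' Per-topic outcome statistics and triage
#'
#' Computes, for every topic: the mean topic weight in the SAE and
#' non-SAE groups, the two-sided Mann-Whitney p-value comparing the
#' topic's proportions between the groups, the triage category
#' ([classify_topics()]), and (when the corpus is supplied) the NPMI
#' coherence of the topic's top `M` features.
#'
#' @param object fitted [spfa()] model or patients x K proportions
#'   matrix.
#' @param group two-level grouping: the SAE/non-SAE subgroup from
#'   [subphenotype()], or the outcome vector itself (1 = SAE group).
#' @param X optional binary corpus for coherence.
#' @param alpha,top_m triage parameters (see [classify_topics()]).
#' @param M top features per topic for coherence.
#' @return data.frame with one row per topic: `topic`, `mtw_sae`,
#'   `mtw_nonsae`, `p_value`, `category`, `npmi` (NA without `X`).
#' @export
topic_stats <- function(object, group, X = NULL, alpha = 0.05, top_m = 3,
                        M = 5) {
  prop <- .prop_from(object)
  stopifnot(length(group) == nrow(prop))
  if (is.numeric(group)) group <- ifelse(group == 1, "SAE", "non-SAE")
  if (!all(group %in% c("SAE", "non-SAE")))
    stop("group must be binary (0/1 or 'SAE'/'non-SAE')")
  sae <- group == "SAE"
  if (!any(sae) || all(sae)) stop("both groups must be non-empty")
  mtw1 <- mean_topic_weight(prop, sae)
  mtw0 <- mean_topic_weight(prop, !sae)
  p <- vapply(seq_len(ncol(prop)), function(k)
    mwu_test(prop[sae, k], prop[!sae, k]), 0)
  cat_ <- classify_topics(mtw1, mtw0, p, alpha = alpha, top_m = top_m)
  npmi <- rep(NA_real_, ncol(prop))
  if (!is.null(X) && inherits(object, "spfa")) {
    tf <- top_features(object, M = M)
    npmi <- vapply(tf, function(d)
      npmi_coherence(match(d$feature, object$feature_names), X), 0)
  }
  data.frame(topic = colnames(prop) %||% paste0("T", seq_len(ncol(prop))),
             mtw_sae = unname(mtw1), mtw_nonsae = unname(mtw0),
             p_value = p, category = cat_, npmi = npmi, row.names = NULL)
}

#' Select the number of topics by coherence and classification
#'
#' Fits the supervised model for each candidate `K` on all samples,
#' records mean NPMI coherence over active topics and the training
#' ROC-AUC, and chooses the `K` with the best AUC among candidates whose
#' coherence is within `tol` of the maximum (ties toward the smallest
#' `K`). Failed fits are recorded and skipped.
#'
#' @param X binary feature-by-patient matrix.
#' @param y binary outcome.
#' @param K_grid candidate topic counts.
#' @param tol coherence tolerance below the maximum (default 0.05).
#' @param M top features per topic for coherence.
#' @param seed integer seed.
#' @param ... further arguments to [spfa()].
#' @return list with chosen `K`, the diagnostics `table` (K, npmi, auc,
#'   error), and the per-K fits.
#' @export
select_num_topics <- function(X, y, K_grid, tol = 0.05, M = 5, seed = 1,
                              ...) {
  if (length(K_grid) == 0) stop("empty topic-count grid")
  rows <- list(); fits <- list()
  for (K in K_grid) {
    res <- tryCatch({
      fit <- spfa(X, y, K = K, seed = seed, ...)
      prop <- predict(fit, type = "proportions")
      act <- active_topics(prop)$active
      tf <- top_features(fit, M = M)
      np <- mean(vapply(act, function(k)
        npmi_coherence(match(tf[[k]]$feature, fit$feature_names), X), 0))
      auc <- fit$trace$auc[nrow(fit$trace)]
      fits[[as.character(K)]] <- fit
      data.frame(K = K, npmi = np, auc = auc, error = NA_character_)
    }, error = function(e)
      data.frame(K = K, npmi = NA_real_, auc = NA_real_,
                 error = conditionMessage(e)))
    rows[[as.character(K)]] <- res
  }
  tab <- do.call(rbind, rows); rownames(tab) <- NULL
  ok <- tab[is.na(tab$error) | tab$error == "", ]
  if (nrow(ok) == 0) stop("all candidate fits failed")
  eligible <- ok[ok$npmi >= max(ok$npmi, na.rm = TRUE) - tol, ]
  chosen <- eligible$K[order(-eligible$auc, eligible$K)][1]
  list(K = chosen, table = tab, fits = fits)
}

#' Greedy cosine matching of topic matrices
#'
#' Matches each reference topic to its best-remaining fitted topic by
#' cosine similarity (greedy, highest-similarity reference first) and
#' returns the per-reference similarities; used to score topic recovery
#' against a ground truth.
#'
#' @param Phi_ref,Phi_fit V x K matrices (column topics); `Phi_fit` may
#'   have more columns than `Phi_ref`.
#' @return numeric vector of matched cosines, one per reference topic,
#'   with the matched fitted index as names.
#' @export
topic_cosine_match <- function(Phi_ref, Phi_fit) {
  cn <- function(M) sweep(M, 2, sqrt(colSums(M^2)), "/")
  S <- crossprod(cn(Phi_ref), cn(Phi_fit))
  used <- integer(0)
  sims <- numeric(nrow(S)); match_idx <- integer(nrow(S))
  for (i in order(-apply(S, 1, max))) {
    j <- order(-S[i, ])
    j <- j[!(j %in% used)][1]
    sims[i] <- S[i, j]; match_idx[i] <- j
    used <- c(used, j)
  }
  names(sims) <- match_idx
  sims
}
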