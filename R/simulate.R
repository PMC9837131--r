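## Synthetic-cohort generators. These produce data with exactly the
## statistical structure the model assumes -- Dirichlet topics, Gamma topic
## weights, Poisson emission with optional binarization, and outcome labels
## driven by normalized topic proportions -- so that every pipeline stage
## has a ground truth to be tested against without access to real EHR data.

#' Generate a ground-truth Poisson-factor corpus
#'
#' Draws a topic matrix with `Dirichlet(eta)` columns, i.i.d.
#' `Gamma(theta_shape, theta_rate)` topic weights per patient and topic,
#' Poisson counts at rate `Phi %*% Theta`, and (by default) binarizes the
#' counts, mirroring a binary patient-by-feature matrix. Small `eta`
#' yields near-disjoint topic supports, as sparse clinical topics have.
#'
#' An optional two-regime structure plants outcome-linked topics: patients
#' in the boosted regime have their `planted` topic weights multiplied by
#' `boost`, creating two patient populations with distinct topic usage.
#'
#' @param V,N,K_true features, patients, true topics.
#' @param eta Dirichlet concentration of topic columns (default 0.1).
#' @param theta_shape,theta_rate Gamma parameters of true topic weights
#'   (default `Gamma(2, 1)`, giving EHR-like matrix sparsity at the
#'   default dimensions).
#' @param binarize clip counts to \{0, 1\} (default `TRUE`).
#' @param planted integer indices of outcome-linked topics, or `NULL` for
#'   no regime structure.
#' @param boost multiplier applied to planted topic weights in the boosted
#'   regime (alternating patients).
#' @param seed integer seed; output is bit-reproducible.
#' @return list with binary (or count) matrix `X` (V x N), true `Phi`
#'   (V x K), true `Theta` (K x N), logical `regime` (boosted per patient,
#'   or `NULL`), `planted`, and the generator `config`.
#' @examples
#' sim <- simulate_corpus(V = 40, N = 100, K_true = 4, seed = 1)
#' dim(sim$X)
#' @export
simulate_corpus <- function(V = 200, N = 2000, K_true = 8, eta = 0.1,
                            theta_shape = 2, theta_rate = 1,
                            binarize = TRUE, planted = NULL, boost = 6,
                            seed = 1) {
  stopifnot(V > 0, N > 0, K_true > 0, eta > 0, theta_shape > 0,
            theta_rate > 0)
  set.seed(derive_seed(seed, "simulate-corpus"))
  Phi <- matrix(rgamma(V * K_true, eta, 1), V, K_true)
  Phi <- sweep(Phi, 2, colSums(Phi), "/")   # columns ~ Dirichlet(eta)
  Theta <- matrix(rgamma(K_true * N, theta_shape, theta_rate), K_true, N)
  regime <- NULL
  if (!is.null(planted)) {
    stopifnot(all(planted >= 1), all(planted <= K_true))
    regime <- rep(c(TRUE, FALSE), length.out = N)
    Theta[planted, regime] <- Theta[planted, regime] * boost
  }
  X <- matrix(rpois(V * N, Phi %*% Theta), V, N)
  if (binarize) X[X > 1] <- 1
  rownames(X) <- rownames(Phi) <- paste0("f", seq_len(V))
  colnames(X) <- colnames(Theta) <- paste0("p", seq_len(N))
  colnames(Phi) <- rownames(Theta) <- paste0("T", seq_len(K_true))
  list(X = X, Phi = Phi, Theta = Theta, regime = regime, planted = planted,
       config = list(V = V, N = N, K_true = K_true, eta = eta,
                     theta_shape = theta_shape, theta_rate = theta_rate,
                     binarize = binarize, planted = planted, boost = boost,
                     seed = seed))
}

#' Generate outcome labels from true topic proportions
#'
#' Draws `y_n ~ Bernoulli(plogis(beta . prop_n + b0))` where `prop_n` are
#' the normalized topic proportions, so the planted outcome signal is
#' scale-free with respect to a patient's overall event volume.
#'
#' @param Theta K x N matrix of true topic weights.
#' @param beta length-K coefficient vector on topic proportions.
#' @param b0 intercept.
#' @param seed integer seed.
#' @return list with binary `y` (length N) and the true probabilities `p`.
#' @export
simulate_labels <- function(Theta, beta, b0 = 0, seed = 1) {
  stopifnot(length(beta) == nrow(Theta))
  prop <- normalize_proportions(Theta)
  p <- sigmoid(drop(crossprod(prop, beta)) + b0)
  set.seed(derive_seed(seed, "simulate-labels"))
  list(y = rbinom(ncol(Theta), 1, p), p = p)
}

#' Generate the default planted-outcome synthetic cohort
#'
#' The package's reference scenario: a two-regime corpus
#' ([simulate_corpus()] with planted topics) plus outcome labels whose
#' regime-mean log-odds differ by `log_odds_gap`. The coefficient vector
#' puts equal weight on the planted topics, scaled so the mean linear
#' predictor differs by `log_odds_gap` between the two regimes, with the
#' intercept centered midway (prevalence near one half). The defaults
#' emulate a cohort in which outcome-linked topic usage nearly determines
#' subgroup membership, as observed in strongly separated clinical
#' cohorts.
#'
#' @param V,N,K_true corpus dimensions (defaults 200, 2000, 8).
#' @param planted outcome-linked topic indices (default topics 1 and 2).
#' @param boost regime boost of planted topic weights (default 6).
#' @param log_odds_gap difference in regime-mean log-odds of the outcome
#'   (default 10).
#' @param seed integer seed.
#' @param ... further arguments to [simulate_corpus()].
#' @return list as [simulate_corpus()] plus `y`, true probabilities `p`,
#'   `beta`, `b0`.
#' @examples
#' sim <- simulate_cohort(V = 50, N = 200, K_true = 4, seed = 1)
#' table(sim$y)
#' @export
simulate_cohort <- function(V = 200, N = 2000, K_true = 8, planted = c(1, 2),
                            boost = 6, log_odds_gap = 10, seed = 1, ...) {
  sim <- simulate_corpus(V = V, N = N, K_true = K_true, planted = planted,
                         boost = boost, seed = seed, ...)
  prop <- normalize_proportions(sim$Theta)
  ps <- colSums(prop[planted, , drop = FALSE])
  gap_prop <- mean(ps[sim$regime]) - mean(ps[!sim$regime])
  sc <- log_odds_gap / gap_prop
  beta <- numeric(K_true)
  beta[planted] <- sc
  b0 <- -sc * mean(c(mean(ps[sim$regime]), mean(ps[!sim$regime])))
  lab <- simulate_labels(sim$Theta, beta, b0, seed = seed)
  c(sim, list(y = lab$y, p = lab$p, beta = beta, b0 = b0,
              log_odds_gap = log_odds_gap))
}

#' Generate a longitudinal event stream with known cohort structure
#'
#' Builds a synthetic long-format clinical event table (one row per event:
#' patient, date, code system, code, hospitalization/death flags) together
#' with the exact cohort the builder should recover from it: planted index
#' dates, a planted binary baseline feature matrix, and planted SAE
#' labels. Used as the round-trip oracle for [build_cohort()].
#'
#' Each patient receives demographic events (age, sex, race), a random set
#' of baseline diagnosis/drug events strictly before the index date, one
#' or more target-drug events starting at the index date, and, for planted
#' SAE patients, a flagged event inside the follow-up window. Non-SAE
#' patients receive no flagged events inside the window (a flagged event
#' may appear after the window to exercise the window bound).
#'
#' @param n_patients number of patients.
#' @param n_codes number of distinct diagnosis codes (drug codes:
#'   `ceiling(n_codes / 2)`).
#' @param target_drug target drug code string.
#' @param sae_rate fraction of patients with a planted SAE.
#' @param followup_extension_days follow-up extension after the last
#'   target-drug event (default 30).
#' @param seed integer seed.
#' @return list with `events` (data.frame), `config` (a [cohort_config()]
#'   to rebuild with) and `truth`: `index_date` (named Date vector),
#'   `y` (named 0/1), `features` (patient x feature binary matrix of
#'   baseline diagnosis/drug indicators), plus demographic assignments.
#' @export
simulate_event_stream <- function(n_patients = 50, n_codes = 12,
                                  target_drug = "RX_TARGET",
                                  sae_rate = 0.4,
                                  followup_extension_days = 30,
                                  seed = 1) {
  set.seed(derive_seed(seed, "simulate-events"))
  pid <- sprintf("P%03d", seq_len(n_patients))
  dx_codes <- sprintf("DX%02d", seq_len(n_codes))
  rx_codes <- sprintf("RX%02d", seq_len(ceiling(n_codes / 2)))
  origin <- as.Date("2015-01-01")
  index_date <- origin + sample(100:400, n_patients, replace = TRUE)
  age <- sample(45:90, n_patients, replace = TRUE)
  sex <- sample(c("F", "M"), n_patients, replace = TRUE)
  race <- sample(c("White", "Black", "Asian", "Other"), n_patients,
                 replace = TRUE)
  y <- as.integer(runif(n_patients) < sae_rate)
  feat_names <- c(paste0("dx:", dx_codes), paste0("rx:", rx_codes))
  feats <- matrix(0L, n_patients, length(feat_names),
                  dimnames = list(pid, feat_names))
  rows <- list()
  add <- function(p, d, sys, code, hosp = FALSE, death = FALSE)
    rows[[length(rows) + 1L]] <<- data.frame(
      patient_id = p, date = d, code_system = sys, code = code,
      hospitalization_flag = hosp, death_flag = death)
  for (i in seq_len(n_patients)) {
    add(pid[i], index_date[i] - 1, "demographic", paste0("age:", age[i]))
    add(pid[i], index_date[i] - 1, "demographic", paste0("sex:", sex[i]))
    add(pid[i], index_date[i] - 1, "demographic", paste0("race:", race[i]))
    ## baseline events, strictly before index
    ndx <- sample(2:5, 1)
    for (cd in sample(dx_codes, ndx)) {
      add(pid[i], index_date[i] - sample(10:90, 1), "diagnosis", cd)
      feats[i, paste0("dx:", cd)] <- 1L
    }
    nrx <- sample(1:3, 1)
    for (cd in sample(rx_codes, nrx)) {
      add(pid[i], index_date[i] - sample(10:90, 1), "drug", cd)
      feats[i, paste0("rx:", cd)] <- 1L
    }
    ## target-drug events define index and follow-up end
    n_rxt <- sample(1:3, 1)
    rxt_dates <- index_date[i] + sort(c(0, sample(1:60, n_rxt - 1)))
    for (d in rxt_dates) add(pid[i], as.Date(d, origin = "1970-01-01"),
                             "drug", target_drug)
    last_drug <- max(rxt_dates)
    if (y[i] == 1L) {
      add(pid[i], as.Date(last_drug + sample(1:followup_extension_days, 1),
                          origin = "1970-01-01"),
          "diagnosis", sample(dx_codes, 1), hosp = TRUE)
    } else if (runif(1) < 0.3) {
      ## flagged event strictly outside the window: must not flip the label
      add(pid[i], as.Date(last_drug + followup_extension_days +
                            sample(5:30, 1), origin = "1970-01-01"),
          "diagnosis", sample(dx_codes, 1), hosp = TRUE)
    }
  }
  events <- do.call(rbind, rows)
  events <- events[order(events$patient_id, events$date), ]
  rownames(events) <- NULL
  names(index_date) <- names(y) <- pid
  list(events = events,
       config = cohort_config(target_drug_codes = target_drug,
                              followup_extension_days = followup_extension_days),
       truth = list(index_date = index_date, y = y, features = feats,
                    age = setNames(age, pid), sex = setNames(sex, pid),
                    race = setNames(race, pid)))
}
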