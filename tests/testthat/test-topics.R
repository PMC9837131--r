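# topic triage: mean topic weights, Mann-Whitney tests, categories,
# coherence, top features, topic-number selection

test_that("mean topic weight is the group mean of proportions", {
  prop <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5))
  expect_equal(mean_topic_weight(prop, 1), c(1, 0))
  expect_equal(mean_topic_weight(prop, 1:2), c(0.5, 0.5))
  expect_equal(sum(mean_topic_weight(prop, c(1, 3))), 1)
  expect_error(mean_topic_weight(prop, integer(0)), "empty")
})

test_that("the exact MWU p-value matches full enumeration", {
  # A = {1,2,3} vs B = {4,5,6}: 2 of the choose(6,3) = 20 labelings are as
  # or more extreme, so the two-sided exact p is 0.1
  expect_equal(mwu_test(c(1, 2, 3), c(4, 5, 6)), 0.1, tolerance = 1e-12)
  expect_warning(p <- mwu_test(c(2, 2), c(2, 2, 2)), "constant")
  expect_equal(p, 1)
  # symmetry
  set.seed(8)
  a <- rnorm(15); b <- rnorm(20) + 1
  expect_equal(mwu_test(a, b), mwu_test(b, a))
  # monotone under a large shift of one group
  expect_lt(mwu_test(a, b + 10), mwu_test(a, b) + 1e-12)
})

test_that("the large-sample MWU approximation tracks a permutation oracle", {
  set.seed(21)
  a <- rnorm(30); b <- rnorm(30) + 0.45
  p_approx <- mwu_test(a, b)
  # permutation oracle on the U statistic, 1e5 resamples
  pooled <- rank(c(a, b))
  u_obs <- sum(pooled[1:30]) - 30 * 31 / 2
  set.seed(22)
  u_perm <- replicate(1e5, {
    idx <- sample.int(60, 30)
    sum(pooled[idx]) - 30 * 31 / 2
  })
  p_perm <- mean(abs(u_perm - 450) >= abs(u_obs - 450))
  expect_lt(abs(p_approx - p_perm), 0.005)
})

test_that("topic categories follow the significance and rank rules", {
  expect_equal(classify_topics(0.08, 0.02, 0.01, top_m = 0), "SAE-aligned")
  expect_equal(classify_topics(0.02, 0.08, 0.01, top_m = 0),
               "nonSAE-aligned")
  mtw1 <- c(0.4, 0.3, 0.2, 0.1)
  mtw0 <- c(0.4, 0.3, 0.2, 0.1)
  p <- c(0.3, 0.01, 0.5, 0.6)
  cats <- classify_topics(mtw1, mtw0 + c(0, -0.01, 0, 0), p, top_m = 2)
  expect_equal(cats[1], "shared")       # rank 1, not significant
  expect_equal(cats[2], "SAE-aligned")  # significant, larger in SAE
  expect_equal(cats[4], "unselected")
  # categories always partition the topics
  expect_true(all(cats %in% c("SAE-aligned", "nonSAE-aligned", "shared",
                              "unselected")))
})

test_that("NPMI reproduces hand-computed values on a 4-patient corpus", {
  # patients (columns): f1 and f2 co-occur in exactly the two patients
  # where either appears; f3 appears in all four
  X <- matrix(c(1, 1, 1,
                1, 1, 1,
                0, 0, 1,
                0, 0, 1), 3, 4)
  rownames(X) <- c("f1", "f2", "f3")
  # perfect association: P(1)=P(2)=P(12)=0.5 -> NPMI = 1
  expect_equal(npmi_coherence(c("f1", "f2"), X), 1, tolerance = 1e-6)
  # f3 is constant: P(3)=1, P(13)=0.5 -> npmi pair (1,3):
  # log(0.5 / (0.5 * 1)) / -log(0.5) = 0
  hand_13 <- log(0.5 / 0.5) / (-log(0.5))
  expect_equal(npmi_coherence(c("f1", "f3"), X), hand_13, tolerance = 1e-6)
  # three-feature mean equals the average of the three hand pairs
  hand_mean <- mean(c(1, hand_13, hand_13))
  expect_equal(npmi_coherence(c("f1", "f2", "f3"), X), hand_mean,
               tolerance = 1e-5)
  # independence -> approximately 0
  set.seed(3)
  Xi <- matrix(rbinom(2 * 4000, 1, 0.5), 2, 4000)
  expect_lt(abs(npmi_coherence(1:2, Xi)), 0.05)
  # bounded in [-1, 1] even for never-co-occurring features
  Xn <- matrix(c(1, 0, 0, 1), 2, 2)
  v <- npmi_coherence(1:2, Xn)
  expect_gte(v, -1); expect_lte(v, 1)
})

test_that("top features are sorted with dominant-patient prevalence", {
  Phi <- matrix(c(0.5, 0.3, 0.15, 0.05,
                  0.1, 0.2, 0.3, 0.4), 4, 2)
  theta <- matrix(c(rep(c(3, 1), 4), rep(c(1, 3), 1)), 2, 5)
  X <- matrix(c(1, 1, 0, 0,
                1, 0, 0, 0,
                1, 1, 1, 0,
                0, 1, 0, 0,
                1, 1, 1, 1), 4, 5)
  fit <- structure(list(Phi = Phi, theta = theta,
                        feature_names = paste0("f", 1:4),
                        classifier = list(coef = c(0, 0), intercept = 0)),
                   class = "spfa")
  tf <- top_features(fit, X, M = 3)
  expect_equal(tf[[1]]$feature, c("f1", "f2", "f3"))
  expect_true(all(diff(tf[[1]]$loading) <= 0))
  # topic 1 dominates patients 1-4; f1 present in 3 of them
  expect_equal(tf[[1]]$prevalence[1], 0.75)
})

test_that("topic stats integrate MTW, MWU and categories per topic", {
  set.seed(12)
  prop <- normalize_proportions(matrix(rgamma(4 * 80, 2, 1), 4, 80))
  prop[1, 1:40] <- prop[1, 1:40] + 1   # topic 1 elevated in group 1
  prop <- normalize_proportions(prop)
  y <- rep(1:0, each = 40)
  ts <- topic_stats(t(prop), y)
  expect_equal(nrow(ts), 4)
  expect_equal(ts$category[1], "SAE-aligned")
  expect_equal(sum(ts$mtw_sae), 1, tolerance = 1e-8)
  expect_equal(sum(ts$mtw_nonsae), 1, tolerance = 1e-8)
  expect_true(all(ts$p_value >= 0 & ts$p_value <= 1))
})

test_that("topic-number selection returns the diagnostics table", {
  sim <- simulate_corpus(V = 30, N = 200, K_true = 3, seed = 15)
  y <- simulate_labels(sim$Theta, c(5, -5, 0), seed = 15)$y
  sel <- select_num_topics(sim$X, y, K_grid = c(3, 5), epochs = 15,
                           batch_size = 100, seed = 1)
  expect_equal(nrow(sel$table), 2)
  expect_true(sel$K %in% c(3, 5))
  expect_true(all(is.na(sel$table$error)))
})

test_that("the rank AUC agrees with a hand-ranked 10-point oracle", {
  y <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  s <- c(9, 8, 7, 3, 6, 5, 4, 2, 1, 0)
  # hand count of concordant pairs among the 4 x 6 = 24: the positive
  # scored 3 beats scores 2,1,0 -> 3; the others beat all six -> 18+3 = 21
  expect_equal(roc_auc(s, y), 21 / 24)
})
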