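# clustering, cluster-count selection, subgroup alignment and purity

test_that("k-means separates point masses and is seed-deterministic", {
  x <- rbind(matrix(rep(c(1, 0), 10), 10, 2, byrow = TRUE),
             matrix(rep(c(0, 1), 10), 10, 2, byrow = TRUE))
  y <- rep(c(1, 0), each = 10)
  s1 <- subphenotype(x / rowSums(x), y, C = 2, seed = 4)
  expect_equal(length(unique(s1$cluster[1:10])), 1)
  expect_equal(length(unique(s1$cluster[11:20])), 1)
  expect_false(s1$cluster[1] == s1$cluster[11])
  s2 <- subphenotype(x / rowSums(x), y, C = 2, seed = 4)
  expect_identical(s1$cluster, s2$cluster)
  expect_error(subphenotype(x / rowSums(x), y, C = 25), "smaller")
})

test_that("k-means with restarts attains the exhaustive best-WCSS partition", {
  # 9 points in 3 planted blobs: small enough to enumerate all labelings
  set.seed(33)
  pts <- rbind(matrix(rnorm(6, 0, 0.05), 3, 2),
               matrix(rnorm(6, 3, 0.05), 3, 2),
               matrix(rnorm(6, c(0, 6), 0.05), 3, 2))
  wcss <- function(lab) {
    sum(vapply(unique(lab), function(l) {
      m <- pts[lab == l, , drop = FALSE]
      sum(sweep(m, 2, colMeans(m))^2)
    }, 0))
  }
  labs <- as.matrix(expand.grid(rep(list(1:3), 9)))
  ok <- apply(labs, 1, function(l) length(unique(l)) == 3)
  best <- min(apply(labs[ok, ], 1, wcss))
  set.seed(2)
  km <- kmeans(pts, 3, nstart = 10)
  expect_equal(km$tot.withinss, best, tolerance = 1e-8)
})

test_that("silhouette selection recovers planted blob counts", {
  set.seed(11)
  blobs <- rbind(matrix(rnorm(60, 0, 0.05), 30, 2),
                 matrix(rnorm(60, 2, 0.05), 30, 2),
                 matrix(rnorm(60, c(0, 4), 0.05), 30, 2))
  sel <- select_num_clusters(blobs / rowSums(abs(blobs) + 3), C_grid = 2:6,
                             seed = 1)
  expect_equal(sel$C, 3)
  expect_equal(nrow(sel$table), 5)

  # a single blob has low silhouette everywhere
  one <- matrix(rnorm(500, 5, 0.5), 100, 5)
  sel1 <- select_num_clusters(one, C_grid = 2:5, seed = 1)
  expect_lt(max(sel1$table$silhouette), 0.3)
})

test_that("two far clusters of equal size give near-perfect silhouette", {
  x <- rbind(matrix(c(0, 0.001, 0, 0.001), 2, 2),
             matrix(c(10, 10.001, 10, 10.001), 2, 2))
  cl <- rep(1:2, each = 2)
  expect_gt(silhouette_score(x, cl), 0.99)
})

test_that("purity reproduces the printed-count arithmetic", {
  # 1915 of 1935 with the outcome: 99.0%; 3014 of 3063 without: 98.4%
  g <- rep(c("sae", "non"), c(1935, 3063))
  y <- c(rep(1, 1915), rep(0, 20), rep(0, 3014), rep(1, 49))
  p <- cluster_outcome_purity(g, y)
  expect_equal(round(100 * p$frac_sae[p$group == "sae"], 1), 99.0)
  expect_equal(round(100 * p$frac_nonsae[p$group == "non"], 1), 98.4)
  expect_equal(cluster_outcome_purity(rep("a", 4), rep(1, 4))$frac_sae, 1)
  expect_error(cluster_outcome_purity(character(0), numeric(0)))
})

test_that("purity is invariant under cluster relabeling and conserves counts", {
  set.seed(6)
  cl <- sample(1:3, 60, replace = TRUE)
  y <- rbinom(60, 1, 0.4)
  p1 <- cluster_outcome_purity(cl, y)
  relab <- c(3, 1, 2)[cl]
  p2 <- cluster_outcome_purity(relab, y)
  expect_setequal(p1$frac_sae, p2$frac_sae)
  expect_equal(sum(p1$n_sae), sum(y))
  expect_equal(sum(p1$n), 60)
})

test_that("majority rule maps clusters to subgroups with ties going to SAE", {
  y <- c(rep(1, 9), 0, rep(0, 9), 1, 1, 0)   # 90%, 10%, 50% clusters
  cl <- rep(1:3, c(10, 10, 2))
  expect_message(st <- subphenotype(matrix(c(rep(0, 10), rep(1, 10),
                                             rep(0.5, 2),
                                             rep(1, 10), rep(0, 10),
                                             rep(0.5, 2)), 22, 2),
                                    y, C = 3, seed = 8), "tied")
  pur <- st$purity
  lookup <- st$subgroup_of_cluster
  expect_equal(unname(lookup[as.character(
    pur$group[abs(pur$frac_sae - 0.9) < 1e-9])]), "SAE")
  expect_equal(unname(lookup[as.character(
    pur$group[abs(pur$frac_sae - 0.1) < 1e-9])]), "non-SAE")
  expect_equal(unname(lookup[as.character(
    pur$group[abs(pur$frac_sae - 0.5) < 1e-9])]), "SAE")
})

test_that("the planted two-regime cohort is recovered with high purity", {
  sim <- simulate_cohort(V = 60, N = 600, K_true = 5, planted = c(1, 2),
                         seed = 19)
  prop <- t(normalize_proportions(sim$Theta))
  st <- subphenotype(prop, sim$y, C = 2, seed = 3)
  gp <- st$group_purity
  expect_gte(gp$frac_sae[gp$group == "SAE"], 0.9)
  # subgroup membership mirrors the planted regimes
  agree <- mean((st$subgroup == "SAE") == sim$regime)
  expect_gt(max(agree, 1 - agree), 0.85)
})

test_that("the 2-D embedding is deterministic and separates planted blobs", {
  set.seed(9)
  x <- rbind(matrix(rnorm(100, 0, 0.1), 50, 2),
             matrix(rnorm(100, 5, 0.1), 50, 2))
  e1 <- embed_2d(x, seed = 1)
  e2 <- embed_2d(x, seed = 1)
  expect_identical(e1, e2)
  expect_equal(nrow(e1), 100)
  d_between <- sqrt(sum((colMeans(e1[1:50, ]) - colMeans(e1[51:100, ]))^2))
  spread <- quantile(sqrt(rowSums(sweep(e1[1:50, ], 2,
                                        colMeans(e1[1:50, ]))^2)), 0.95)
  expect_gt(d_between, spread)
  expect_error(embed_2d(x[1:5, ]), "at least 10")
})
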