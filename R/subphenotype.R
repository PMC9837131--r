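## Subphenotyping: k-means in topic-proportion space, silhouette-based
## choice of the cluster count, and alignment of clusters with the SAE
## outcome. Clustering operates on normalized proportions so distances are
## scale-free with respect to a patient's overall event volume.

.prop_from <- function(object) {
  if (inherits(object, "spfa")) t(predict(object, type = "proportions"))
  else if (is.matrix(object)) {
    ## rows are patients; a K x N matrix with simplex columns is transposed
    if (all(abs(colSums(object) - 1) < 1e-6) &&
        !all(abs(rowSums(object) - 1) < 1e-6)) t(object) else object
  } else stop("expected an spfa fit or a matrix of topic proportions")
}

#' Mean silhouette score for a clustering
#'
#' Euclidean silhouette averaged over (a seeded subsample of) patients;
#' used to pick the number of clusters.
#'
#' @param x patients x dims numeric matrix.
#' @param cl integer cluster assignment.
#' @param max_n subsample cap for the pairwise-distance computation.
#' @param seed subsampling seed.
#' @return mean silhouette width.
#' @export
silhouette_score <- function(x, cl, max_n = 5000, seed = 1) {
  if (nrow(x) > max_n) {
    set.seed(derive_seed(seed, "silhouette-subsample"))
    keep <- sort(sample.int(nrow(x), max_n))
    x <- x[keep, , drop = FALSE]; cl <- cl[keep]
  }
  if (length(unique(cl)) < 2) return(NA_real_)
  mean(cluster::silhouette(cl, dist(x))[, "sil_width"])
}

#' Select the number of clusters by silhouette
#'
#' Runs seeded k-means for each candidate `C` and returns the full
#' silhouette table and the argmax (ties broken toward the smallest `C`).
#'
#' @param prop patients x K matrix of topic proportions (or an `spfa`
#'   fit).
#' @param C_grid candidate cluster counts (each in `[2, N - 1]`).
#' @param restarts k-means restarts per candidate.
#' @param seed integer seed.
#' @param max_n silhouette subsample cap.
#' @return list with `C` (chosen) and `table` (data.frame `C`,
#'   `silhouette`).
#' @export
select_num_clusters <- function(prop, C_grid = 2:8, restarts = 10,
                                seed = 1, max_n = 5000) {
  prop <- .prop_from(prop)
  if (length(C_grid) == 0) stop("empty cluster-count grid")
  C_grid <- C_grid[C_grid >= 2 & C_grid < nrow(prop)]
  sil <- vapply(C_grid, function(C) {
    set.seed(derive_seed(seed, paste0("kmeans-", C)))
    km <- kmeans(prop, centers = C, nstart = restarts, iter.max = 50)
    silhouette_score(prop, km$cluster, max_n = max_n, seed = seed)
  }, 0)
  tab <- data.frame(C = C_grid, silhouette = sil)
  list(C = C_grid[which.max(sil)], table = tab)
}

#' Per-group outcome purity
#'
#' For each group, the fraction of members with and without the outcome,
#' e.g. 1915 of 1935 patients gives 99.0% SAE purity.
#'
#' @param group group membership vector (cluster ids or subgroup labels).
#' @param y binary 0/1 outcome aligned to `group`.
#' @return data.frame with per-group `n`, `n_sae`, `frac_sae`,
#'   `frac_nonsae` (fractions rounded in the printed summary only).
#' @examples
#' cluster_outcome_purity(rep(c("a", "b"), c(4, 4)), c(1, 1, 1, 0, 0, 0, 0, 1))
#' @export
cluster_outcome_purity <- function(group, y) {
  stopifnot(length(group) == length(y))
  if (length(group) == 0 || any(table(group) == 0)) stop("empty group")
  n <- tapply(y, group, length)
  n1 <- tapply(y, group, sum)
  data.frame(group = names(n), n = as.integer(n), n_sae = as.integer(n1),
             frac_sae = as.numeric(n1 / n),
             frac_nonsae = as.numeric(1 - n1 / n), row.names = NULL)
}

#' Cluster patients in topic space and align clusters with the outcome
#'
#' K-means on topic proportions (squared-Euclidean, best of `restarts`
#' seeded initializations), with the number of clusters either fixed or
#' chosen by mean silhouette over `C_grid`. Each cluster is then assigned
#' to the SAE subgroup iff its outcome fraction exceeds one half (an exact
#' tie goes to the SAE subgroup, the conservative choice for safety
#' screening, and is logged).
#'
#' @param object fitted [spfa()] model or a patients x K (or K x N)
#'   matrix of topic proportions.
#' @param y binary 0/1 outcome per patient (defaults to the outcome
#'   stored in the fit).
#' @param C number of clusters; `NULL` selects by silhouette.
#' @param C_grid candidate counts when selecting.
#' @param restarts k-means restarts.
#' @param seed integer seed (clustering is deterministic given it).
#' @param max_n silhouette subsample cap.
#' @return object of class `"spfa_subtypes"`: `cluster` (per patient),
#'   `centers`, chosen `C`, `silhouette` table (when selected),
#'   `subgroup_of_cluster`, per-patient `subgroup`, `purity` (per
#'   cluster) and `group_purity` (per subgroup).
#' @examples
#' sim <- simulate_cohort(V = 40, N = 200, K_true = 4, seed = 2)
#' st <- subphenotype(normalize_proportions(sim$Theta), sim$y, C = 2)
#' st$group_purity
#' @export
subphenotype <- function(object, y = NULL, C = NULL, C_grid = 2:8,
                         restarts = 10, seed = 1, max_n = 5000) {
  prop <- .prop_from(object)
  if (is.null(y) && inherits(object, "spfa")) y <- object$y
  if (is.null(y)) stop("an outcome vector y is required")
  stopifnot(length(y) == nrow(prop))
  sil_tab <- NULL
  if (is.null(C)) {
    sel <- select_num_clusters(prop, C_grid, restarts, seed, max_n)
    C <- sel$C; sil_tab <- sel$table
  }
  if (C >= nrow(prop)) stop("C must be smaller than the number of patients")
  set.seed(derive_seed(seed, paste0("kmeans-", C)))
  km <- kmeans(prop, centers = C, nstart = restarts, iter.max = 50)
  pur <- cluster_outcome_purity(km$cluster, y)
  tie <- pur$frac_sae == 0.5
  if (any(tie))
    message("cluster(s) ", paste(pur$group[tie], collapse = ", "),
            " tied at 50% SAE; assigned to the SAE subgroup")
  sub_of_cl <- ifelse(pur$frac_sae >= 0.5, "SAE", "non-SAE")
  names(sub_of_cl) <- pur$group
  subgroup <- sub_of_cl[as.character(km$cluster)]
  gp <- cluster_outcome_purity(subgroup, y)
  structure(list(cluster = km$cluster, centers = km$centers, C = C,
                 silhouette = sil_tab, subgroup_of_cluster = sub_of_cl,
                 subgroup = unname(subgroup), purity = pur,
                 group_purity = gp, y = y, seed = seed),
            class = "spfa_subtypes")
}

#' @export
print.spfa_subtypes <- function(x, ...) {
  cat(sprintf("Patient subphenotypes: %d clusters", x$C))
  if (!is.null(x$silhouette))
    cat(sprintf(" (silhouette-selected, max %.3f)",
                max(x$silhouette$silhouette)))
  cat("\n\nPer-cluster outcome purity:\n")
  p <- x$purity
  p$frac_sae <- sprintf("%.1f%%", 100 * p$frac_sae)
  p$frac_nonsae <- sprintf("%.1f%%", 100 * p$frac_nonsae)
  p$subgroup <- x$subgroup_of_cluster[p$group]
  print(p, row.names = FALSE)
  cat("\nSubgroup purity:\n")
  g <- x$group_purity
  for (i in seq_len(nrow(g))) {
    pure <- if (g$group[i] == "SAE") g$frac_sae[i] else g$frac_nonsae[i]
    cat(sprintf("  %s group: %d of %d patients (%.1f%%) %s SAEs\n",
                g$group[i], if (g$group[i] == "SAE") g$n_sae[i]
                else g$n[i] - g$n_sae[i], g$n[i], 100 * pure,
                if (g$group[i] == "SAE") "encountered" else "free of"))
  }
  invisible(x)
}

#' Deterministic 2-D embedding for cluster visualization
#'
#' Projects patient vectors onto their first two principal components
#' (centered, unscaled) for plotting clusters and outcomes; coordinates
#' are deterministic given the seed (used only to break exact ties by an
#' infinitesimal jitter-free sign convention).
#'
#' @param x patients x dims numeric matrix (e.g. topic proportions).
#' @param seed integer seed (kept for interface stability; the projection
#'   itself is deterministic).
#' @return N x 2 matrix of coordinates.
#' @export
embed_2d <- function(x, seed = 1) {
  x <- .prop_from(x)
  if (nrow(x) < 10) stop("need at least 10 rows to embed")
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = 2)
  co <- pc$x[, 1:2, drop = FALSE]
  ## fixed sign convention so runs are comparable
  for (j in 1:2) if (co[which.max(abs(co[, j])), j] < 0) co[, j] <- -co[, j]
  colnames(co) <- c("dim1", "dim2")
  co
}
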