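## Trait-level screening: 2x2 contingency tables comparing SAE vs non-SAE
## groups and the associated chi-square / exact tests, the machinery
## behind a cohort characteristics table.

#' 2x2 trait-by-outcome contingency table
#'
#' @param trait binary 0/1 trait vector.
#' @param y binary 0/1 outcome vector of the same length.
#' @return 2x2 integer matrix: rows trait yes/no, columns outcome 1/0,
#'   i.e. `a = `, trait present with outcome, etc., with margins equal to
#'   the group sizes.
#' @examples
#' trait_contingency(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
trait_contingency <- function(trait, y) {
  if (length(trait) != length(y)) stop("trait and y lengths differ")
  stopifnot(all(trait %in% 0:1), all(y %in% 0:1))
  matrix(c(sum(trait == 1 & y == 1), sum(trait == 0 & y == 1),
           sum(trait == 1 & y == 0), sum(trait == 0 & y == 0)),
         2, 2, dimnames = list(trait = c("yes", "no"),
                               outcome = c("sae", "nonsae")))
}

#' Association test for a 2x2 table
#'
#' Pearson chi-square without continuity correction (default), the
#' Yates-corrected variant, or Fisher's exact two-sided test. A table with
#' a zero margin has no defined association and returns p = 1 with a
#' warning.
#'
#' @param table 2x2 count matrix, e.g. from [trait_contingency()].
#' @param variant `"pearson"`, `"yates"` or `"fisher"`.
#' @return list with `statistic` (NA for fisher) and `p_value`.
#' @examples
#' tab <- matrix(c(77, 270, 163, 229), 2, 2)
#' assoc_test(tab)$p_value
#' @export
assoc_test <- function(table, variant = c("pearson", "yates", "fisher")) {
  variant <- match.arg(variant)
  stopifnot(is.matrix(table), all(dim(table) == 2), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("zero margin: association undefined, p = 1")
    return(list(statistic = NA_real_, p_value = 1))
  }
  if (variant == "fisher") {
    list(statistic = NA_real_,
         p_value = fisher.test(table, alternative = "two.sided")$p.value)
  } else {
    ht <- suppressWarnings(chisq.test(table, correct = variant == "yates"))
    list(statistic = unname(ht$statistic), p_value = ht$p.value)
  }
}

#' Cohort characteristics table
#'
#' Overall and per-outcome-group counts with percentages and chi-square
#' p-values for a set of binary traits, ordered by overall prevalence
#' (the layout of a study-population characteristics table). Percentages
#' are printed to one decimal.
#'
#' @param traits binary traits x patients matrix (e.g. rows of a cohort
#'   feature matrix), or a patients-length vector for a single trait.
#' @param y binary 0/1 outcome.
#' @param variant test variant passed to [assoc_test()].
#' @return data.frame of class `"spfa_cohort_summary"` with columns
#'   `trait`, `overall_n`, `overall_pct`, `sae_n`, `sae_pct`, `nonsae_n`,
#'   `nonsae_pct`, `p_value`, sorted by decreasing overall prevalence.
#' @export
cohort_summary <- function(traits, y, variant = "pearson") {
  if (is.null(dim(traits))) traits <- matrix(traits, 1,
                                             dimnames = list("trait", NULL))
  traits <- as_dense(traits)
  stopifnot(ncol(traits) == length(y))
  n <- length(y); n1 <- sum(y == 1); n0 <- n - n1
  rows <- lapply(seq_len(nrow(traits)), function(i) {
    tr <- traits[i, ]
    tab <- trait_contingency(tr, y)
    data.frame(trait = rownames(traits)[i] %||% paste0("trait", i),
               overall_n = sum(tr), overall_pct = 100 * sum(tr) / n,
               sae_n = tab["yes", "sae"],
               sae_pct = 100 * tab["yes", "sae"] / n1,
               nonsae_n = tab["yes", "nonsae"],
               nonsae_pct = 100 * tab["yes", "nonsae"] / n0,
               p_value = assoc_test(tab, variant)$p_value)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$overall_n, out$trait), ]
  rownames(out) <- NULL
  class(out) <- c("spfa_cohort_summary", "data.frame")
  out
}

#' @export
print.spfa_cohort_summary <- function(x, ...) {
  d <- as.data.frame(x)
  fmt <- function(n, p) sprintf("%d (%.1f)", n, p)
  cat(sprintf("%-28s %-14s %-14s %-14s %s\n", "Trait, No. (%)", "Overall",
              "SAE", "non-SAE", "p"))
  for (i in seq_len(nrow(d)))
    cat(sprintf("%-28s %-14s %-14s %-14s %s\n", d$trait[i],
                fmt(d$overall_n[i], d$overall_pct[i]),
                fmt(d$sae_n[i], d$sae_pct[i]),
                fmt(d$nonsae_n[i], d$nonsae_pct[i]),
                ifelse(d$p_value[i] < 0.001, "<0.001",
                       sprintf("%.3f", d$p_value[i]))))
  invisible(x)
}
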