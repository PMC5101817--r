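# Nonparametric two-sample machinery: Wilcoxon rank-sum tests (exact
# enumeration for small tie-free samples, tie-corrected normal
# approximation otherwise) with rank-biserial effect sizes, applied to
# every feature contrast.

#' Wilcoxon rank-sum test with an exact/approximate switch
#'
#' Computes the Mann-Whitney U statistic of the focal sample `x` (number
#' of (x, y) pairs with x > y, ties counted half via midranks). When
#' `min(n1, n2) <= 8` and the pooled sample is tie-free the two-sided
#' p-value comes from exact enumeration of the null distribution
#' (`p = 2 * min(tail probabilities)`, capped at 1); otherwise from the
#' normal approximation with tie-corrected variance and continuity
#' correction. The computation is delegated to [stats::wilcox.test()] with
#' the switch above imposed.
#'
#' @param x Numeric vector, the focal sample (n1 >= 1).
#' @param y Numeric vector, the comparison sample (n2 >= 1).
#' @return A `rank_test` object: list with `U`, `n1`, `n2`, `p_two_sided`,
#'   `method` (`"exact"` or `"normal_approx"`), `rank_biserial`,
#'   `tie_corrected`.
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4))  # exact p = 1/3
#' @export
rank_sum_test <- function(x, y) {
  x <- as.numeric(x[!is.na(x)])
  y <- as.numeric(y[!is.na(y)])
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stopf("rank_sum_test: empty sample")
  pooled <- c(x, y)
  if (all(pooled == pooled[1])) {
    # degenerate case (every value identical): no evidence of a shift
    return(structure(list(U = n1 * n2 / 2, n1 = n1, n2 = n2,
                          p_two_sided = 1, method = "normal_approx",
                          rank_biserial = 0, tie_corrected = TRUE),
                     class = "rank_test"))
  }
  ties <- anyDuplicated(pooled) > 0
  exact <- min(n1, n2) <= 8 && !ties
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE))
  U <- unname(ht$statistic)
  p <- min(ht$p.value, 1)
  structure(list(U = U, n1 = n1, n2 = n2, p_two_sided = p,
                 method = if (exact) "exact" else "normal_approx",
                 rank_biserial = rank_biserial(U, n1, n2),
                 tie_corrected = ties && !exact),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum (%s%s): U = %.1f (n1 = %d, n2 = %d), two-sided p = %.4g, rank-biserial r = %.3f\n",
              x$method, if (x$tie_corrected) ", tie-corrected" else "",
              x$U, x$n1, x$n2, x$p_two_sided, x$rank_biserial))
  invisible(x)
}

#' Rank-biserial correlation from a U statistic
#'
#' `r = 2 U / (n1 n2) - 1`, in `[-1, 1]`; +1 means every focal value
#' exceeds every comparison value.
#'
#' @param U Mann-Whitney U of the focal sample.
#' @param n1,n2 Sample sizes.
#' @return Effect size in `[-1, 1]`.
#' @export
rank_biserial <- function(U, n1, n2) {
  stopifnot(U >= 0, U <= n1 * n2)
  2 * U / (n1 * n2) - 1
}

star_code <- function(p, thresholds = c(0.05, 0.01)) {
  thresholds <- sort(thresholds, decreasing = TRUE)
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    strrep("*", sum(pp < thresholds))
  }, character(1))
}

#' Contrast every feature between the two gene classes
#'
#' Runs [rank_sum_test()] per feature column of a gene feature table,
#' splitting rows by a class partition. Missing values are excluded
#' per-feature with counts reported; a feature that is entirely missing in
#' one class yields a flagged (NA) row rather than an error. Raw p-values
#' are reported with a star code at the conventional thresholds
#' (`* p < 0.05`, `** p < 0.01`); no multiple-testing adjustment is applied
#' by default, Holm-adjusted p-values are added with `adjust = "holm"`.
#'
#' @param features `data.frame` with a `gene_id` column and numeric feature
#'   columns (as from [feature_table()], optionally with an `omega` column).
#' @param partition A `class_partition` over the `gene_id`s.
#' @param columns Feature columns to test; defaults to all numeric columns.
#' @param alpha Star thresholds (descending).
#' @param adjust `"none"` (default) or `"holm"`.
#' @return `data.frame` with one row per feature: sample sizes, `U`,
#'   `p`, `method`, `rank_biserial`, `stars` (and `p_adj` when adjusted).
#' @export
compare_all_features <- function(features, partition, columns = NULL,
                                 alpha = c(0.05, 0.01),
                                 adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(features), "gene_id" %in% names(features),
            inherits(partition, "class_partition"))
  if (is.null(columns)) {
    columns <- names(features)[vapply(features, is.numeric, logical(1))]
  }
  focal <- features[features$gene_id %in% partition$focal, , drop = FALSE]
  comp <- features[features$gene_id %in% partition$complement, , drop = FALSE]
  rows <- lapply(columns, function(cn) {
    xv <- focal[[cn]]; yv <- comp[[cn]]
    n_missing <- sum(is.na(xv)) + sum(is.na(yv))
    xv <- xv[!is.na(xv)]; yv <- yv[!is.na(yv)]
    if (length(xv) == 0 || length(yv) == 0) {
      if (n_missing > 0) {
        nt_log("compare_all_features: feature '%s' missing for an entire class; flagged", cn)
      }
      return(data.frame(feature = cn, n_focal = length(xv),
                        n_complement = length(yv), n_excluded = n_missing,
                        U = NA_real_, p = NA_real_, method = NA_character_,
                        rank_biserial = NA_real_, stringsAsFactors = FALSE))
    }
    if (n_missing > 0) {
      nt_log("compare_all_features: feature '%s': %d value(s) missing, excluded",
             cn, n_missing)
    }
    rt <- rank_sum_test(xv, yv)
    data.frame(feature = cn, n_focal = rt$n1, n_complement = rt$n2,
               n_excluded = n_missing, U = rt$U, p = rt$p_two_sided,
               method = rt$method, rank_biserial = rt$rank_biserial,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "holm") out$p_adj <- p.adjust(out$p, method = "holm")
  out$stars <- star_code(out$p, alpha)
  rownames(out) <- NULL
  out
}
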