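#' Group-level rank comparison
#'
#' Compares per-subject values across groups (e.g. conditions) with the
#' standard nonparametric tests: the Friedman paired test when `paired`
#' is requested and every subject has a complete row, the Kruskal-Wallis
#' test otherwise. This mirrors the availability rule used when a hub
#' type is missing for some subjects: incomplete cases force the
#' unpaired test. Post-hoc pairwise Wilcoxon comparisons with Bonferroni
#' correction are reported when the omnibus test rejects.
#'
#' @param values numeric matrix, subjects x groups (column names are
#'   group labels); `NA` marks a missing value.
#' @param paired request the paired (Friedman) test when complete.
#' @param alpha significance level for the post-hoc stage.
#' @return An object of class `group_result`: list with `test`,
#'   `statistic`, `p_value`, `posthoc` (data frame or `NULL`), `groups`.
#' @export
compare_groups <- function(values, paired = TRUE, alpha = 0.05) {
  values <- as.matrix(values)
  if (ncol(values) < 2) stop("need at least 2 groups")
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("G%d", seq_len(ncol(values)))
  complete <- stats::complete.cases(values)
  use_friedman <- paired && all(complete)
  if (use_friedman) {
    ft <- friedman.test(values)
    test <- "friedman"; stat <- unname(ft$statistic); p <- ft$p.value
  } else {
    keep <- !is.na(values)
    long_vals <- values[keep]
    long_grp <- factor(col(values)[keep], labels = colnames(values))
    kt <- kruskal.test(long_vals, long_grp)
    test <- "kruskal-wallis"; stat <- unname(kt$statistic); p <- kt$p.value
  }
  posthoc <- NULL
  if (is.finite(p) && p < alpha) {
    keep <- !is.na(values)
    pw <- suppressWarnings(
      pairwise.wilcox.test(values[keep],
                           factor(col(values)[keep], labels = colnames(values)),
                           p.adjust.method = "bonferroni",
                           paired = use_friedman, exact = FALSE))
    m <- pw$p.value
    posthoc <- data.frame(group1 = rownames(m)[row(m)[!is.na(m)]],
                          group2 = colnames(m)[col(m)[!is.na(m)]],
                          p_adjusted = m[!is.na(m)], row.names = NULL)
  }
  structure(list(test = test, statistic = stat, p_value = p,
                 posthoc = posthoc, groups = colnames(values)),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("<group_result> %s: statistic = %.4g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  if (!is.null(x$posthoc)) {
    cat("  post-hoc (Bonferroni-adjusted pairwise Wilcoxon):\n")
    for (i in seq_len(nrow(x$posthoc)))
      cat(sprintf("    %s vs %s: p = %.4g\n", x$posthoc$group1[i],
                  x$posthoc$group2[i], x$posthoc$p_adjusted[i]))
  }
  invisible(x)
}
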