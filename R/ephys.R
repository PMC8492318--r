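#' Compare electrophysiology features across TF-defined groups
#'
#' Patch-Seq style analysis: per feature, a two-sided Mann-Whitney U test
#' of the dual-positive ("Both") group against each other group, with
#' Benjamini-Hochberg adjustment across the full feature x comparison
#' family and significance stars (* adjusted p < 0.05, ** < 0.01).
#' Comparisons involving a group with fewer than `min_cells` cells are
#' reported as underpowered and not tested. Uses the same Mann-Whitney
#' and BH implementation as the transcript group tests.
#'
#' @param table data.frame with a group label column and numeric feature
#'   columns (e.g. from [simulate_ephys()], or a real Patch-Seq table
#'   whose labels came from [binarize_and_classify()]).
#' @param features Feature column names; default every numeric column
#'   except the group and donor columns.
#' @param group_col Name of the group label column (default
#'   `"tf_group"`).
#' @param min_cells Minimum cells per group for a comparison to be tested
#'   (default 3).
#' @return data.frame of class `group_test_result`: `feature`, `group1`,
#'   `group2`, `n1`, `n2`, `median1`, `median2`, `statistic`, `p`,
#'   `p_adj`, `stars`, `tested`. Rows are ordered by feature then by
#'   comparison group.
#' @export
compare_ephys_groups <- function(table, features = NULL,
                                 group_col = "tf_group", min_cells = 3L) {
  if (!group_col %in% names(table)) stop("missing group column '", group_col, "'")
  groups <- as.character(table[[group_col]])
  if (is.null(features)) {
    numeric_cols <- names(table)[vapply(table, is.numeric, logical(1))]
    features <- setdiff(numeric_cols, c(group_col, "donor"))
  }
  if (!length(features)) stop("no feature columns to test")
  present <- tf_group_levels[tf_group_levels %in% unique(groups)]
  if (length(present) < 2L) stop("need at least two non-empty groups")
  if (!"Both" %in% present) stop("'Both' group is empty")
  others <- setdiff(present, "Both")
  n_by_group <- table(factor(groups, levels = present))

  rows <- list()
  k <- 0L
  for (feat in features) {
    v <- table[[feat]]
    for (g in others) {
      x <- v[groups == "Both"]
      y <- v[groups == g]
      testable <- length(x) >= min_cells && length(y) >= min_cells
      tt <- if (testable) mwu_test(x, y) else list(statistic = NA_real_,
                                                  p.value = NA_real_)
      k <- k + 1L
      rows[[k]] <- data.frame(
        feature = feat, group1 = "Both", group2 = g,
        n1 = length(x), n2 = length(y),
        median1 = stats::median(x), median2 = stats::median(y),
        statistic = tt$statistic, p = tt$p.value, tested = testable,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  out$p_adj[out$tested] <- bh_adjust(out$p[out$tested])
  out$stars <- sig_stars(out$p_adj)
  rownames(out) <- NULL
  class(out) <- c("group_test_result", class(out))
  out
}
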