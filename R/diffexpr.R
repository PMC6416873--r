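#' Row-wise pooled-variance two-sample t statistics
#'
#' Vectorized Student t-test (pooled variance, df = n1 + n2 - 2) for every
#' gene row of a matrix, comparing two sample index sets. Genes with zero
#' pooled variance get t = 0, p = 1.
#'
#' @param m Numeric matrix (genes x samples).
#' @param idx1,idx2 Column indices (or logical masks) of the two groups,
#'   each of size >= 2.
#' @return List with numeric vectors `t`, `p`, `mean1`, `mean2`, `df`.
#' @keywords internal
row_ttest <- function(m, idx1, idx2) {
  x1 <- m[, idx1, drop = FALSE]
  x2 <- m[, idx2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 samples")
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2L
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  degenerate <- se == 0 | !is.finite(se)
  t[degenerate] <- 0
  p <- 2 * stats::pt(-abs(t), df)
  p[degenerate] <- 1
  list(t = t, p = p, mean1 = m1, mean2 = m2, df = df)
}

#' Welch variant of [row_ttest()]
#' @inheritParams row_ttest
#' @keywords internal
row_ttest_welch <- function(m, idx1, idx2) {
  x1 <- m[, idx1, drop = FALSE]
  x2 <- m[, idx2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 samples")
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  t <- (m1 - m2) / sqrt(se2)
  degenerate <- se2 == 0 | !is.finite(se2)
  t[degenerate] <- 0
  df[degenerate] <- n1 + n2 - 2L
  p <- 2 * stats::pt(-abs(t), df)
  p[degenerate] <- 1
  list(t = t, p = p, mean1 = m1, mean2 = m2, df = df)
}

#' Per-gene two-group differential expression statistics
#'
#' Computes, for every gene, the two-sample t statistic between the two
#' label groups, the two-sided p-value, the orientation-free linear-scale
#' fold difference, and a Benjamini-Hochberg adjusted p-value (informational
#' only; selection uses raw thresholds).
#'
#' @param x An `ExpressionMatrix` on the analysis scale (typically `log2`).
#' @param groups Vector of two distinct labels, one per sample (same order
#'   as columns), or a logical vector marking group 1.
#' @param var_equal If `TRUE` (default) the classical pooled-variance Student
#'   test; otherwise Welch.
#' @param input_scale Scale used for the fold difference; `"log2"` means
#'   group means are exponentiated before the ratio. Defaults to the
#'   matrix's own tag.
#' @param pseudo Pseudocount guarding zero linear-scale means in the fold
#'   ratio.
#' @return `data.frame` with columns `gene_id`, `mean1`, `mean2`, `t`, `p`,
#'   `fold_difference`, `direction` (`up_in_group1`/`up_in_group2`), `fdr`.
#' @examples
#' m <- matrix(rnorm(40), 4, 10,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
#' em <- expression_matrix(m + 10, "log2")
#' two_sample_ttest(em, rep(c("a", "b"), each = 5))
#' @export
two_sample_ttest <- function(x, groups, var_equal = TRUE,
                             input_scale = NULL, pseudo = 1e-9) {
  if (is.logical(groups)) groups <- ifelse(groups, "group1", "group2")
  groups <- as.character(groups)
  if (length(groups) != ncol(x))
    stop("'groups' must have one label per sample")
  lv <- sort(unique(groups))
  if (length(lv) != 2L) stop("exactly two groups required")
  idx1 <- groups == lv[1]; idx2 <- groups == lv[2]
  tt <- if (var_equal) row_ttest(unclass(x), idx1, idx2)
        else row_ttest_welch(unclass(x), idx1, idx2)
  scale <- if (is.null(input_scale)) {
    if (inherits(x, "ExpressionMatrix")) expr_scale(x) else "log2"
  } else input_scale
  fd <- fold_from_means(tt$mean1, tt$mean2, scale, pseudo)
  data.frame(
    gene_id = rownames(x),
    mean1 = tt$mean1, mean2 = tt$mean2,
    t = tt$t, p = tt$p,
    fold_difference = fd,
    direction = ifelse(tt$t >= 0, "up_in_group1", "up_in_group2"),
    fdr = stats::p.adjust(tt$p, "BH"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# orientation-free max/min fold ratio of linear-scale group means
fold_from_means <- function(m1, m2, scale, pseudo = 1e-9) {
  if (scale == "log2") { m1 <- 2^m1; m2 <- 2^m2 }
  both_zero <- m1 == 0 & m2 == 0
  m1 <- pmax(m1, 0) + ifelse(m1 == 0, pseudo, 0)
  m2 <- pmax(m2, 0) + ifelse(m2 == 0, pseudo, 0)
  fd <- pmax(m1, m2) / pmin(m1, m2)
  fd[both_zero] <- 1
  fd
}

#' Orientation-free fold difference between two groups
#'
#' Ratio max(m1, m2) / min(m1, m2) of the linear-scale group mean
#' expressions; log2-scale input is exponentiated first. Genes with both
#' group means zero report a fold difference of 1.
#'
#' @inheritParams two_sample_ttest
#' @return Named numeric vector of fold differences (>= 1).
#' @export
fold_change <- function(x, groups, input_scale = NULL, pseudo = 1e-9) {
  if (is.logical(groups)) groups <- ifelse(groups, "group1", "group2")
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  if (length(lv) != 2L) stop("exactly two groups required")
  scale <- if (is.null(input_scale)) {
    if (inherits(x, "ExpressionMatrix")) expr_scale(x) else "log2"
  } else input_scale
  m1 <- rowMeans(x[, groups == lv[1], drop = FALSE])
  m2 <- rowMeans(x[, groups == lv[2], drop = FALSE])
  stats::setNames(fold_from_means(m1, m2, scale, pseudo), rownames(x))
}

#' Select differentially expressed genes
#'
#' Filters a [two_sample_ttest()] table by raw p-value and (optionally) fold
#' difference, and orders the survivors by ascending p, ties broken by
#' descending |t| then gene ID.
#'
#' @param stats `data.frame` from [two_sample_ttest()].
#' @param p_threshold Keep genes with `p < p_threshold`.
#' @param fc_threshold If non-`NULL`, additionally require
#'   `fold_difference >= fc_threshold` (the >= 3-fold expression-difference
#'   rule uses 3).
#' @return Ordered character vector of gene IDs.
#' @export
select_genes <- function(stats, p_threshold = 0.05, fc_threshold = NULL) {
  if (nrow(stats) == 0L) stop("'stats' is empty")
  keep <- stats$p < p_threshold
  if (!is.null(fc_threshold)) keep <- keep & stats$fold_difference >= fc_threshold
  sel <- stats[keep, , drop = FALSE]
  sel <- sel[order(sel$p, -abs(sel$t), sel$gene_id), , drop = FALSE]
  sel$gene_id
}
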