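#' Mutation matrix container
#'
#' Binary gene x sample mutation indicators plus per-sample total mutation
#' counts and the size in Mb of the targeted region the totals refer to.
#' Totals must be at least the per-sample indicator column sums (a gene
#' panel is a subset of all mutated genes).
#'
#' @param indicator Binary (0/1) gene x sample matrix with dimnames.
#' @param total_mutations Integer vector, one per sample (default: the
#'   indicator column sums).
#' @param target_region_Mb Positive region size in megabases.
#' @return Object of class `"mutation_matrix"`.
#' @export
mutation_matrix <- function(indicator, total_mutations = NULL,
                            target_region_Mb = 1) {
  if (!is.matrix(indicator) || is.null(rownames(indicator)) ||
      is.null(colnames(indicator)))
    stop("'indicator' must be a matrix with gene rownames and sample colnames")
  if (!all(indicator %in% c(0, 1))) stop("indicator entries must be 0/1")
  if (target_region_Mb <= 0) stop("target_region_Mb must be > 0")
  csum <- colSums(indicator)
  if (is.null(total_mutations)) total_mutations <- csum
  if (length(total_mutations) != ncol(indicator))
    stop("one total per sample required")
  if (any(total_mutations < csum))
    stop("total_mutations below panel column sums for sample(s): ",
         paste(colnames(indicator)[total_mutations < csum], collapse = ", "))
  structure(list(indicator = indicator,
                 total_mutations = stats::setNames(as.numeric(total_mutations),
                                                   colnames(indicator)),
                 target_region_Mb = target_region_Mb),
            class = "mutation_matrix")
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("mutation_matrix: %d genes x %d samples, region %.2f Mb\n",
              nrow(x$indicator), ncol(x$indicator), x$target_region_Mb))
  invisible(x)
}

#' Collapse a MAF-like table to a binary mutation matrix
#'
#' @param maf `data.frame` with columns `sample_id`, `gene` (and optionally
#'   `variant_class`, ignored for the indicator).
#' @param samples Optional full sample universe (samples without any
#'   mutation get all-zero columns).
#' @inheritParams mutation_matrix
#' @return A [mutation_matrix()].
#' @export
maf_to_matrix <- function(maf, samples = NULL, total_mutations = NULL,
                          target_region_Mb = 1) {
  if (!all(c("sample_id", "gene") %in% colnames(maf)))
    stop("MAF table needs columns 'sample_id' and 'gene'")
  samples <- if (is.null(samples)) sort(unique(maf$sample_id)) else samples
  genes <- sort(unique(maf$gene))
  ind <- matrix(0, length(genes), length(samples),
                dimnames = list(genes, samples))
  hit <- unique(maf[, c("gene", "sample_id")])
  ind[cbind(match(hit$gene, genes), match(hit$sample_id, samples))] <- 1
  mutation_matrix(ind, total_mutations, target_region_Mb)
}

#' Per-group mutation frequencies for the most frequently mutated genes
#'
#' Genes are ranked by overall mutation frequency (ties by gene ID) and the
#' per-group mutated fraction of each of the `top_n` nonzero genes is
#' reported as counts and a percentage.
#'
#' @param mut A [mutation_matrix()].
#' @param groups Character vector, one group label per sample.
#' @param top_n How many genes to report (default 15).
#' @param digits Decimal places of the percentage (default 1, as printed in
#'   mutation-frequency figures).
#' @return `data.frame`: `gene`, `group`, `mutated`, `total`, `percent`.
#' @export
mutation_frequency_table <- function(mut, groups, top_n = 15L, digits = 1L) {
  if (length(groups) != ncol(mut$indicator))
    stop("'groups' must have one label per sample")
  gtab <- table(groups)
  if (any(gtab == 0)) stop("empty group")
  overall <- rowMeans(mut$indicator)
  nz <- overall > 0
  ord <- order(-overall, rownames(mut$indicator))
  ord <- ord[nz[ord]]
  genes <- rownames(mut$indicator)[utils::head(ord, top_n)]
  rows <- list()
  for (g in genes) for (grp in names(gtab)) {
    sel <- groups == grp
    k <- sum(mut$indicator[g, sel]); n <- sum(sel)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g, group = grp, mutated = k, total = n,
      percent = round(100 * k / n, digits),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Closed form `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with df = 1
#' and a two-sided p-value from the chi-square distribution. No continuity
#' correction by default; the Yates-corrected statistic is available via
#' `correction = "yates"`.
#'
#' @param a,b,c,d Nonnegative integer cell counts: rows are mutated / not
#'   mutated, columns are the two groups, i.e. `a/(a+b)` vs `c/(c+d)` is the
#'   comparison of mutated fractions. (So 7/27 vs 7/76 is
#'   `chi_square_2x2(7, 20, 7, 69)`.)
#' @param correction `"none"` (default) or `"yates"`.
#' @return List of class `"contingency_result"`: `table`, `chi2`, `df`,
#'   `p_value`, `correction`.
#' @export
chi_square_2x2 <- function(a, b, c, d, correction = c("none", "yates")) {
  correction <- match.arg(correction)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be nonnegative integers")
  N <- sum(cells)
  if (N < 1) stop("empty table")
  tab <- matrix(cells, 2L, 2L, byrow = TRUE,
                dimnames = list(c("groupA", "groupB"),
                                c("mutated", "not_mutated")))
  marg <- (a + b) * (c + d) * (a + c) * (b + d)
  if (marg == 0) stop("zero marginal row or column: test undefined")
  num <- abs(a * d - b * c)
  if (correction == "yates") num <- max(0, num - N / 2)
  chi2 <- N * num^2 / marg
  structure(list(table = tab, chi2 = chi2, df = 1L,
                 p_value = stats::pchisq(chi2, 1L, lower.tail = FALSE),
                 correction = correction),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("chi2 = %.4f, df = %d, p = %.4g (correction: %s)\n",
              x$chi2, x$df, x$p_value, x$correction))
  invisible(x)
}

#' Per-sample tumor mutational burden
#'
#' @param mut A [mutation_matrix()].
#' @return Named numeric vector of mutations per Mb
#'   (`total_mutations / target_region_Mb`).
#' @export
mutation_burden <- function(mut) {
  if (mut$target_region_Mb <= 0) stop("nonpositive region size")
  mut$total_mutations / mut$target_region_Mb
}

#' Compare mutation burden between two groups
#'
#' `method = "mann_whitney"` runs a Wilcoxon rank-sum test on the per-sample
#' burdens; `method = "binned_chisq"` bins samples by mutation count and
#' runs an r x 2 Pearson chi-square on the bin x group counts.
#'
#' @param burdens Numeric vector of per-sample burdens (or raw counts for
#'   the binned test).
#' @param groups Two-level grouping vector aligned with `burdens`.
#' @param method `"mann_whitney"` (default) or `"binned_chisq"`.
#' @param breaks Bin breakpoints for the binned test; default bins are
#'   0-100, 101-500, >500 mutations.
#' @return List: `method`, `p_value`, plus `statistic` and (for the binned
#'   test) the bin count table.
#' @export
compare_burden <- function(burdens, groups,
                           method = c("mann_whitney", "binned_chisq"),
                           breaks = c(-Inf, 100, 500, Inf)) {
  method <- match.arg(method)
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  if (length(lv) != 2L) stop("exactly two groups required")
  if (any(table(groups) == 0)) stop("empty group")
  if (method == "mann_whitney") {
    wt <- suppressWarnings(stats::wilcox.test(burdens[groups == lv[1]],
                                              burdens[groups == lv[2]],
                                              exact = FALSE, correct = TRUE))
    p <- wt$p.value
    # a fully tied pooled sample has zero rank variance: no evidence at all
    if (is.nan(p)) p <- 1
    list(method = method, statistic = unname(wt$statistic), p_value = p)
  } else {
    bins <- cut(burdens, breaks = breaks)
    tab <- table(bins, groups)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp_counts == 0)) stop("binned test has expected count 0")
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(method = method, statistic = unname(ct$statistic),
         p_value = ct$p.value, table = tab)
  }
}

#' Microsatellite instability call
#'
#' MSI-H (high-frequency microsatellite instability) is called when strictly
#' more than 30% of the assayed microsatellite markers show allelic shifts.
#'
#' @param unstable_markers Number of markers with allelic shifts.
#' @param total_markers Number of markers examined (>= 1).
#' @return `"MSI-H"` or `"non-MSI-H"`.
#' @export
msi_call <- function(unstable_markers, total_markers) {
  if (total_markers < 1) stop("total_markers must be >= 1")
  if (unstable_markers < 0 || unstable_markers > total_markers)
    stop("unstable_markers must be in 0..total_markers")
  if (unstable_markers / total_markers > 0.30) "MSI-H" else "non-MSI-H"
}
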