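#' Counts-per-million scaling
#'
#' Rescales every sample column of a raw count matrix so that it sums to one
#' million: `value[g, j] = counts[g, j] / sum_g counts[g, j] * 1e6`.
#'
#' @param counts An [expression_matrix()] on the `counts` scale.
#' @return An `ExpressionMatrix` on the `cpm` scale; each column sums to 1e6.
#' @export
cpm <- function(counts) {
  if (expr_scale(counts) != "counts") stop("cpm() expects a counts-scale matrix")
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("all-zero sample column(s): ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  retag(sweep(unclass(counts), 2L, tot, "/") * 1e6, "cpm")
}

#' Quantile normalization
#'
#' Forces all sample columns to share one empirical distribution: the mean of
#' the column-wise order statistics. Within each column ranks are preserved;
#' tied values receive the mean of the reference values at their tied ranks.
#' On tie-free input the operation is exactly idempotent and every column's
#' sorted values equal the reference; tie-averaging perturbs both properties
#' slightly where ties occur.
#'
#' @param x An `ExpressionMatrix` (any non-counts scale) or numeric matrix.
#' @return An `ExpressionMatrix` on the same scale tag as the input.
#' @export
quantile_normalize <- function(x) {
  scale <- if (inherits(x, "ExpressionMatrix")) expr_scale(x) else "log2"
  if (ncol(x) < 2L) stop("quantile normalization needs >= 2 samples")
  if (anyNA(x)) stop("missing values present")
  m <- unclass(x)
  ref <- rowMeans(apply(m, 2L, sort))
  out <- apply(m, 2L, function(col) {
    v <- ref[rank(col, ties.method = "first")]
    stats::ave(v, rank(col, ties.method = "min"), FUN = mean)
  })
  dimnames(out) <- dimnames(x)
  retag(out, scale)
}

#' Log2 transform with pseudocount
#'
#' @param x Nonnegative `ExpressionMatrix`.
#' @param pseudocount Positive offset added before taking logs (default 1).
#' @return An `ExpressionMatrix` on the `log2` scale.
#' @export
log2_transform <- function(x, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (any(x < 0)) stop("negative values cannot be log2-transformed")
  retag(log2(unclass(x) + pseudocount), "log2")
}

#' Iterative median centering across genes and samples
#'
#' Subtracts gene (row) medians, then sample (column) medians, iterating
#' until all row and column medians are within `tol` of zero or `max_iter`
#' passes have run.
#'
#' @param x An `ExpressionMatrix`.
#' @param tol Convergence tolerance on the largest absolute median
#'   (default 1e-6).
#' @param max_iter Iteration cap (default 10).
#' @return An `ExpressionMatrix` (same scale tag) with attribute
#'   `median_center_converged` (logical) and `median_center_iterations`.
#' @export
median_center <- function(x, tol = 1e-6, max_iter = 10L) {
  scale <- expr_scale(x)
  m <- unclass(x)
  conv <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    m <- m - apply(m, 1L, stats::median)
    m <- sweep(m, 2L, apply(m, 2L, stats::median))
    worst <- max(abs(apply(m, 1L, stats::median)),
                 abs(apply(m, 2L, stats::median)))
    if (worst <= tol) { conv <- TRUE; break }
  }
  if (!conv)
    warning(sprintf("median centering hit the %d-iteration cap", max_iter))
  out <- retag(m, scale)
  attr(out, "median_center_converged") <- conv
  attr(out, "median_center_iterations") <- it
  out
}

#' Standard RNA-seq normalization chain
#'
#' Counts per million, quantile normalization, log2 transform, and iterative
#' median centering, in that order. The alternative order (log2 before
#' quantile normalization) is available via `log2_first = TRUE` for
#' sensitivity analysis.
#'
#' @param counts A counts-scale `ExpressionMatrix`.
#' @param pseudocount Pseudocount for the log2 stage (on the CPM scale).
#' @param log2_first If `TRUE`, apply log2 before quantile normalization.
#' @return A `log2`-scale `ExpressionMatrix`, median-centered.
#' @export
normalize_rnaseq <- function(counts, pseudocount = 1, log2_first = FALSE) {
  x <- cpm(counts)
  if (log2_first) {
    x <- quantile_normalize(log2_transform(x, pseudocount))
  } else {
    x <- log2_transform(quantile_normalize(x), pseudocount)
  }
  median_center(x)
}

#' Per-gene z-standardization within one dataset
#'
#' Each gene row is scaled to mean 0 and standard deviation 1 (sample sd,
#' denominator n - 1). Constant rows are set to all zeros with a warning
#' rather than producing non-finite values.
#'
#' @param x An `ExpressionMatrix`.
#' @return An `ExpressionMatrix` on the `standardized` scale.
#' @export
zscore_within_dataset <- function(x) {
  m <- unclass(x)
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  const <- sd == 0 | !is.finite(sd)
  if (any(const)) {
    warning(sprintf("%d constant gene row(s) set to zero: %s",
                    sum(const),
                    paste(utils::head(rownames(m)[const], 5L), collapse = ", ")))
    sd[const] <- 1
  }
  out <- (m - mu) / sd
  out[const, ] <- 0
  retag(out, "standardized")
}

#' Pool standardized datasets over their shared gene set
#'
#' Restricts each dataset to the intersection of gene IDs, concatenates the
#' sample columns (sample IDs prefixed with the dataset name to guarantee
#' uniqueness), and quantile-normalizes the pooled matrix.
#'
#' @param datasets Named list of `standardized`-scale `ExpressionMatrix`
#'   objects; names are used as cohort prefixes.
#' @return An `ExpressionMatrix` on the `pooled` scale.
#' @export
pool_datasets <- function(datasets) {
  if (length(datasets) < 2L) stop("pooling needs >= 2 datasets")
  if (is.null(names(datasets)) || any(names(datasets) == ""))
    stop("'datasets' must be a named list (cohort IDs)")
  genes <- Reduce(intersect, lapply(datasets, rownames))
  if (length(genes) == 0L) stop("empty gene-ID intersection across datasets")
  cols <- lapply(names(datasets), function(nm) {
    d <- datasets[[nm]][genes, , drop = FALSE]
    colnames(d) <- paste(nm, colnames(d), sep = ":")
    unclass(d)
  })
  pooled <- do.call(cbind, cols)
  out <- quantile_normalize(retag(pooled, "standardized"))
  retag(unclass(out), "pooled")
}
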