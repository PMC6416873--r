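#' Centered-correlation distance between samples
#'
#' `d(i, j) = 1 - r(i, j)` where `r` is the Pearson correlation of the two
#' sample profiles over the selected gene list (means subtracted, hence
#' "centered"). Symmetric, zero diagonal, range [0, 2]. A constant sample
#' profile has undefined correlation; its distance to every other sample is
#' set to the maximum (2) with a warning.
#'
#' @param x An `ExpressionMatrix` (genes x samples).
#' @param genes Optional character vector restricting the profile to a gene
#'   list (default: all genes).
#' @return Symmetric sample x sample distance matrix.
#' @export
centered_correlation_distance <- function(x, genes = NULL) {
  m <- restrict_genes(x, genes)
  if (ncol(m) < 2L) stop("need >= 2 samples")
  if (nrow(m) < 2L) stop("need >= 2 genes")
  sds <- apply(m, 2L, stats::sd)
  const <- sds == 0
  r <- suppressWarnings(stats::cor(m))
  d <- 1 - r
  if (any(const)) {
    warning("constant sample profile(s): ",
            paste(colnames(m)[const], collapse = ", "),
            "; distances set to maximum (2)")
    d[const, ] <- 2; d[, const] <- 2
  }
  diag(d) <- 0
  d
}

restrict_genes <- function(x, genes) {
  m <- unclass(x)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing))
      stop("genes not in matrix: ", paste(utils::head(missing, 5L), collapse = ", "))
    m <- m[genes, , drop = FALSE]
  }
  m
}

# 1 - cor between one centroid and a matrix of centroids (columns)
centroid_dist_to <- function(cent, others) {
  as.vector(1 - stats::cor(cent, others))
}

#' Agglomerative centroid-linkage clustering under centered correlation
#'
#' Bottom-up clustering of samples in which every cluster is represented by
#' its centroid (the per-gene mean of its member profiles) and the distance
#' between two clusters is the centered-correlation distance between their
#' centroids, recomputed after each merge. This is the Cluster-3.0 style
#' definition: Lance-Williams centroid updates assume squared Euclidean
#' distance and do not apply under a correlation metric. Merge heights are
#' recorded as produced; centroid linkage can produce inversions, which are
#' reported via the `inversions` attribute, not hidden.
#'
#' Tie-breaking on equal merge distances is deterministic: the pair of
#' clusters with the lexicographically smallest creation indices is merged
#' (singletons are numbered 1..n in input order; merged clusters continue
#' the numbering).
#'
#' @inheritParams centered_correlation_distance
#' @return Object of class `"centroid_dendrogram"`: list with `merge`
#'   (n-1 x 2, [stats::hclust()] convention: negative entries are singleton
#'   sample indices, positive entries earlier merge steps), `height`, `size`
#'   (cluster size after each merge), `labels` (sample IDs), and an
#'   `inversions` attribute flagging non-monotone heights.
#' @export
centroid_linkage <- function(x, genes = NULL) {
  m <- restrict_genes(x, genes)
  n <- ncol(m)
  if (n < 2L) stop("need >= 2 samples")
  labels <- colnames(m)
  # active clusters: creation id, hclust merge code, member sample indices
  ids <- seq_len(n)
  codes <- -seq_len(n)
  members <- as.list(seq_len(n))
  cent <- m                           # centroid matrix, one column per cluster
  D <- centered_correlation_distance(x, genes)
  diag(D) <- Inf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  size <- integer(n - 1L)
  for (step in seq_len(n - 1L)) {
    # smallest distance; ties -> lexicographically smallest creation-id pair
    idx <- which(D == min(D), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    pair_ids <- cbind(pmin(ids[idx[, 1]], ids[idx[, 2]]),
                      pmax(ids[idx[, 1]], ids[idx[, 2]]))
    best <- order(pair_ids[, 1], pair_ids[, 2])[1]
    i <- idx[best, 1]; j <- idx[best, 2]
    height[step] <- D[i, j]
    merge[step, ] <- sort(c(codes[i], codes[j]))
    new_members <- c(members[[i]], members[[j]])
    size[step] <- length(new_members)
    new_cent <- rowMeans(m[, new_members, drop = FALSE])
    # drop j, replace i by the merged cluster
    keep <- setdiff(seq_along(ids), c(i, j))
    ids <- c(ids[keep], n + step)
    codes <- c(codes[keep], step)
    members <- c(members[keep], list(new_members))
    cent <- cbind(cent[, keep, drop = FALSE], new_cent)
    D <- D[keep, keep, drop = FALSE]
    if (length(keep)) {
      dnew <- centroid_dist_to(new_cent, cent[, seq_along(keep), drop = FALSE])
      D <- rbind(cbind(D, dnew), c(dnew, Inf))
    } else {
      D <- matrix(Inf, 1L, 1L)
    }
  }
  out <- list(merge = merge, height = height, size = size, labels = labels)
  attr(out, "inversions") <- which(diff(height) < 0)
  class(out) <- "centroid_dendrogram"
  out
}

#' @export
print.centroid_dendrogram <- function(x, ...) {
  cat(sprintf("centroid-linkage dendrogram: %d samples, %d merges\n",
              length(x$labels), length(x$height)))
  inv <- attr(x, "inversions")
  if (length(inv))
    cat(sprintf("  %d height inversion(s) at step(s): %s\n",
                length(inv), paste(inv, collapse = ", ")))
  invisible(x)
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last k - 1 merges. Cluster labels are 1..k ordered by
#' descending cluster size, ties by smallest member sample index.
#'
#' @param dend A [centroid_linkage()] dendrogram.
#' @param k Number of clusters, 1 <= k <= n.
#' @return `data.frame` with columns `sample_id` and `cluster` (integer).
#' @export
cut_clusters <- function(dend, k = 2L) {
  n <- length(dend$labels)
  if (k < 1L || k > n) stop("k must be in 1..", n)
  parent <- integer(n + n - 1L)        # union-find over singletons + merges
  grp <- rep(NA_integer_, n)
  # apply the first n - k merges
  comp <- as.list(seq_len(n))
  nodes <- vector("list", n - 1L)
  for (step in seq_len(n - k)) {
    get <- function(code) if (code < 0) comp[[-code]] else nodes[[code]]
    nodes[[step]] <- c(get(dend$merge[step, 1]), get(dend$merge[step, 2]))
  }
  used <- rep(FALSE, n)
  clusters <- list()
  if (n - k >= 1L) {
    # top-level clusters: merge nodes not absorbed into later merges
    absorbed <- rep(FALSE, n - k)
    for (step in seq_len(n - k)) for (side in 1:2) {
      code <- dend$merge[step, side]
      if (code > 0) absorbed[code] <- TRUE
    }
    for (step in which(!absorbed)) {
      clusters <- c(clusters, list(nodes[[step]]))
      used[nodes[[step]]] <- TRUE
    }
  }
  for (i in which(!used)) clusters <- c(clusters, list(i))
  stopifnot(length(clusters) == k)
  ord <- order(-vapply(clusters, length, 1L),
               vapply(clusters, min, 1L))
  for (lab in seq_along(ord)) grp[clusters[[ord[lab]]]] <- lab
  data.frame(sample_id = dend$labels, cluster = grp,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same samples.
#'
#' @param a,b Two label vectors of equal length.
#' @return Numeric scalar (1 = identical partitions, ~0 = chance).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
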