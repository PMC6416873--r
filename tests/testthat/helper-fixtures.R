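# Small fixture builders shared across test files.

# tiny expression matrix with generated dimnames
em <- function(values, nrow, ncol, scale = "log2") {
  m <- matrix(values, nrow, ncol,
              dimnames = list(sprintf("g%02d", seq_len(nrow)),
                              sprintf("s%02d", seq_len(ncol))))
  expression_matrix(m, scale)
}

# single-cohort config with a given per-subtype composition
one_cohort_config <- function(comp, effect = 2.0, seed = 1, n_genes = 2000,
                              n_sig = 200, batch_sd = 0.5, ...) {
  simulation_config(n_genes = n_genes, cohorts = list(A = comp),
                    n_signature_genes_per_subtype = n_sig,
                    signature_log2_effect = effect,
                    batch_log2_sd = batch_sd, seed = seed, ...)
}

# normalized single-cohort fixture: log2 matrix + truth + signature
normalized_fixture <- function(comp, effect = 2.0, seed = 1, ...) {
  ex <- simulate_expression(one_cohort_config(comp, effect, seed, ...))
  list(x = suppressWarnings(normalize_rnaseq(ex$expression$A)),
       truth = ex$truth, signature = ex$signature)
}

# independent brute-force centroid-linkage agglomerator: recomputes ALL
# pairwise centroid distances from scratch at every step (oracle for
# centroid_linkage); same tie rule (smallest creation-index pair).
naive_centroid_linkage <- function(m) {
  n <- ncol(m)
  clusters <- lapply(seq_len(n), identity)
  ids <- seq_len(n)
  codes <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(clusters)
    best <- NULL
    for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
      ci <- rowMeans(m[, clusters[[i]], drop = FALSE])
      cj <- rowMeans(m[, clusters[[j]], drop = FALSE])
      d <- 1 - stats::cor(ci, cj)
      pid <- sort(c(ids[i], ids[j]))
      better <- is.null(best) || d < best$d ||
        (d == best$d && (pid[1] < best$pid[1] ||
                           (pid[1] == best$pid[1] && pid[2] < best$pid[2])))
      if (better) best <- list(i = i, j = j, d = d, pid = pid)
    }
    merge[step, ] <- sort(c(codes[best$i], codes[best$j]))
    height[step] <- best$d
    newc <- c(clusters[[best$i]], clusters[[best$j]])
    keep <- setdiff(seq_len(k), c(best$i, best$j))
    clusters <- c(clusters[keep], list(newc))
    ids <- c(ids[keep], n + step)
    codes <- c(codes[keep], step)
  }
  list(merge = merge, height = height)
}
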