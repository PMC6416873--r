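#' Run the full analysis pipeline on a simulated cohort fixture
#'
#' Sequences the computational arm end to end: simulate a multi-cohort
#' fixture, normalize each cohort (CPM, quantile, log2, median-center),
#' z-standardize per cohort and pool with quantile normalization, select
#' differentially expressed genes between the two ground-truth clusters,
#' cluster the pooled samples with centroid linkage and cut at `k`, run
#' leave-one-out cross-validation of the four-subtype BCCP decision tree,
#' compute mutation-frequency and burden statistics per assigned cluster,
#' and estimate checkpoint- and mTOR-inhibitor responder fractions per
#' cluster. All stage outputs are written as tab-separated tables and a
#' manifest with MD5 checksums is returned; identical config + seed gives
#' identical checksums.
#'
#' @param sim_config A [simulation_config()].
#' @param out_dir Output directory.
#' @param k Number of clusters to cut (default 2).
#' @param de_p,de_fc Differential-expression thresholds (raw p, optional
#'   fold difference).
#' @param alpha,top_n Subtype gene-selection parameters for the BCCP stage.
#' @param node_order,threshold Decision-tree parameters.
#' @param rates Checkpoint response rates per subtype.
#' @param pathway_response_rate mTOR pathway-inhibitor response rate.
#' @param driver Driver gene for the mTOR estimate (default "PIK3CA").
#' @param run_loocv If `FALSE`, skip the (slower) cross-validation stage.
#' @return List: `manifest` (stage, file, md5), `cluster_ari`,
#'   `loocv_accuracy` (or `NA`), `responders` table, and the per-stage
#'   objects.
#' @export
run_pipeline <- function(sim_config = simulation_config(), out_dir,
                         k = 2L, de_p = 0.05, de_fc = NULL,
                         alpha = 0.001, top_n = 200L,
                         node_order = c("EBV", "MSI", "GS"),
                         threshold = 0.5,
                         rates = default_response_rates(),
                         pathway_response_rate = 0.35,
                         driver = "PIK3CA", run_loocv = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  stage <- c()
  emit <- function(df, name, stg) {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files[name] <<- p
    stage[name] <<- stg
    p
  }

  # stage 1: simulate
  fixture <- simulate_cohort_fixture(sim_config)
  fx_files <- write_fixture(fixture, file.path(out_dir, "fixture"))
  for (nm in names(fx_files)) { files[nm] <- fx_files[nm]; stage[nm] <- "simulate" }
  message(sprintf("[simulate] %d cohort(s), %d genes, %d samples",
                  length(fixture$expression), sim_config$n_genes,
                  nrow(fixture$annotation)))

  # stage 2: normalize per cohort, standardize, pool
  norm <- lapply(fixture$expression, normalize_rnaseq)
  std <- lapply(norm, zscore_within_dataset)
  pooled <- if (length(std) >= 2L) pool_datasets(std) else {
    x <- std[[1]]
    colnames(x) <- paste(names(std)[1], colnames(x), sep = ":")
    retag(unclass(x), "pooled")
  }
  write_expression(pooled, file.path(out_dir, "pooled.tsv"))
  files["pooled"] <- file.path(out_dir, "pooled.tsv"); stage["pooled"] <- "normalize"
  ann <- fixture$annotation
  pooled_ids <- paste(ann$cohort, ann$sample_id, sep = ":")
  stopifnot(setequal(pooled_ids, colnames(pooled)))
  pooled <- retag(unclass(pooled)[, pooled_ids, drop = FALSE], "pooled")
  message(sprintf("[normalize] pooled matrix %d x %d", nrow(pooled), ncol(pooled)))

  # stage 3: differential expression between ground-truth clusters
  de_stats <- two_sample_ttest(pooled, ann$cluster, input_scale = "log2")
  de_genes <- select_genes(de_stats, p_threshold = de_p, fc_threshold = de_fc)
  emit(de_stats[match(de_genes, de_stats$gene_id), ], "de_genes", "de")
  message(sprintf("[de] %d genes at p < %g", length(de_genes), de_p))
  if (length(de_genes) < 2L) stop("[de] fewer than 2 genes selected")

  # stage 4: clustering
  dend <- centroid_linkage(pooled, genes = de_genes)
  assign <- cut_clusters(dend, k = k)
  ari <- adjusted_rand_index(assign$cluster, ann$cluster)
  emit(assign, "clusters", "cluster")
  emit(data.frame(left = dend$merge[, 1], right = dend$merge[, 2],
                  height = dend$height, size = dend$size), "dendrogram",
       "cluster")
  message(sprintf("[cluster] k = %d, ARI vs truth = %.3f", k, ari))

  # stage 5: subtype classification (LOOCV, no selection leakage)
  loocv_acc <- NA_real_
  if (run_loocv) {
    cv <- loocv(pooled, ann$subtype, alpha = alpha, top_n = top_n,
                node_order = node_order, threshold = threshold)
    loocv_acc <- cv$accuracy
    emit(cv$calls, "subtype_calls", "subtype")
    emit(cv$performance, "subtype_performance", "subtype")
    message(sprintf("[subtype] LOOCV accuracy = %.3f", loocv_acc))
  }

  # stage 6: mutation statistics per assigned cluster
  mut <- fixture$mutations
  idx <- match(paste(ann$cohort, ann$sample_id, sep = ":"), assign$sample_id)
  grp <- paste0("C-", as.character(utils::as.roman(assign$cluster[idx])))
  freq <- mutation_frequency_table(mut, grp, top_n = 15L)
  emit(freq, "mutation_frequencies", "mutstats")
  burden <- mutation_burden(mut)
  emit(data.frame(sample_id = names(burden), burden = burden, group = grp),
       "mutation_burden", "mutstats")
  cmp <- NULL
  if (length(unique(grp)) == 2L) {
    cmp <- compare_burden(burden, grp)
    emit(data.frame(comparison = paste(sort(unique(grp)), collapse = " vs "),
                    method = cmp$method, p_value = cmp$p_value),
         "burden_test", "mutstats")
    message(sprintf("[mutstats] burden %s p = %.3g", cmp$method, cmp$p_value))
  }

  # stage 7: responder estimation per assigned cluster
  groups <- list()
  for (cl in sort(unique(grp))) {
    sel <- grp == cl
    if (!any(sel)) next
    sf <- table(factor(ann$subtype[sel], levels = GC_SUBTYPES))
    sf <- as.numeric(sf) / sum(sf)
    names(sf) <- GC_SUBTYPES
    dfrac <- if (driver %in% rownames(mut$indicator))
      mean(mut$indicator[driver, sel]) else 0
    groups[[cl]] <- list(subtype_fractions = sf, driver_fraction = dfrac)
  }
  resp <- summarize_groups(groups, rates = rates,
                           pathway_response_rate = pathway_response_rate)
  emit(resp, "responders", "responders")
  message(sprintf("[responders] %d estimate(s) written", nrow(resp)))

  manifest <- data.frame(stage = unname(stage[names(files)]),
                         output = names(files),
                         file = unname(files),
                         md5 = unname(tools::md5sum(unname(files))),
                         stringsAsFactors = FALSE)
  manifest_path <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(manifest = manifest, cluster_ari = ari, loocv_accuracy = loocv_acc,
       responders = resp, fixture = fixture, pooled = pooled,
       de_genes = de_genes, assignment = assign, burden_test = cmp)
}
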