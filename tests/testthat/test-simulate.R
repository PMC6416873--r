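test_that("configs are validated", {
  expect_error(simulation_config(n_genes = 100,
                                 n_signature_genes_per_subtype = 30),
               "exceeds n_genes")
  expect_error(simulation_config(cohorts = list(A = c(EBV = 0, MSI = 0,
                                                      GS = 0, CIN = 0))),
               "no samples")
  expect_error(simulation_config(cohorts = list(A = c(XYZ = 5))),
               "must map subtypes")
  expect_error(simulation_config(driver_freqs = list(P = c(EBV = 1.4))),
               "\\[0, 1\\]")
  expect_error(simulation_config(dispersion = 0))
})

test_that("identical config + seed reproduces identical fixtures", {
  cfg <- one_cohort_config(c(EBV = 3, MSI = 3, GS = 3, CIN = 3),
                           seed = 51, n_genes = 300, n_sig = 30)
  f1 <- simulate_cohort_fixture(cfg)
  f2 <- simulate_cohort_fixture(cfg)
  expect_identical(unclass(f1$expression$A), unclass(f2$expression$A))
  expect_identical(f1$mutations$indicator, f2$mutations$indicator)
  expect_identical(f1$truth, f2$truth)
  # a different seed changes the counts
  f3 <- simulate_cohort_fixture(one_cohort_config(
    c(EBV = 3, MSI = 3, GS = 3, CIN = 3), seed = 52,
    n_genes = 300, n_sig = 30))
  expect_false(identical(unclass(f1$expression$A), unclass(f3$expression$A)))
})

test_that("adding a cohort does not perturb existing cohorts", {
  base <- simulation_config(n_genes = 300,
                            n_signature_genes_per_subtype = 30,
                            cohorts = list(TCGA = c(EBV = 3, MSI = 3,
                                                    GS = 3, CIN = 3)),
                            seed = 53)
  ext <- simulation_config(n_genes = 300,
                           n_signature_genes_per_subtype = 30,
                           cohorts = list(TCGA = c(EBV = 3, MSI = 3,
                                                   GS = 3, CIN = 3),
                                          CCLE = c(MSI = 4, CIN = 4)),
                           seed = 53)
  e1 <- simulate_expression(base)
  e2 <- simulate_expression(ext)
  expect_identical(unclass(e1$expression$TCGA), unclass(e2$expression$TCGA))
  expect_equal(length(e2$expression), 2L)
})

test_that("simulated structure is as planted", {
  cfg <- one_cohort_config(c(EBV = 4, MSI = 4, GS = 4, CIN = 4), seed = 54,
                           n_genes = 400, n_sig = 40)
  ex <- simulate_expression(cfg)
  counts <- ex$expression$A
  expect_identical(expr_scale(counts), "counts")
  expect_true(all(counts >= 0))
  expect_true(all(counts == round(counts)))
  # signature blocks are disjoint and of the configured size
  sig <- ex$signature
  expect_equal(unname(lengths(sig)), rep(40L, 4))
  expect_equal(anyDuplicated(unlist(sig)), 0L)
  # annotation, truth, expression share the sample universe in order
  expect_identical(ex$annotation$sample_id, colnames(counts))
  expect_identical(ex$truth$sample_id, ex$annotation$sample_id)
  expect_true(all(ex$truth$subtype %in% c("EBV", "MSI", "GS", "CIN")))
  # planted signature genes are elevated in their subtype
  norm <- suppressWarnings(normalize_rnaseq(counts))
  for (s in names(sig)) {
    in_s <- ex$truth$subtype == s
    delta <- mean(norm[sig[[s]], in_s]) - mean(norm[sig[[s]], !in_s])
    expect_gt(delta, 0.5)
  }
})

test_that("null generator plants nothing: t-test positives track alpha", {
  fx <- normalized_fixture(c(GS = 15, MSI = 15), effect = 0, seed = 55,
                           n_genes = 4000, batch_sd = 0)
  res <- two_sample_ttest(fx$x, fx$truth$subtype)
  hits <- sum(res$p < 0.05)
  bounds <- qbinom(c(0.005, 0.995), nrow(res), 0.05)
  expect_gte(hits, bounds[1])
  expect_lte(hits, bounds[2])
})

test_that("mutation burden means follow the configured Poisson rates", {
  comp <- c(EBV = 40, MSI = 40, GS = 40, CIN = 40)
  cfg <- one_cohort_config(comp, seed = 56, n_genes = 100, n_sig = 10,
                           burden_mean_per_Mb = c(MSI = 40, CIN = 5,
                                                  EBV = 10, GS = 5),
                           target_region_Mb = 1)
  ex <- simulate_expression(cfg)
  mut <- simulate_mutations(cfg, ex$truth)
  burden <- mutation_burden(mut)
  for (s in names(comp)) {
    mu <- cfg$burden_mean_per_Mb[[s]]
    got <- mean(burden[ex$truth$subtype == s])
    se <- sqrt(mu / comp[[s]])
    expect_lt(abs(got - mu), 3 * se)
  }
  # determinism
  mut2 <- simulate_mutations(cfg, ex$truth)
  expect_identical(mut$indicator, mut2$indicator)
  expect_identical(mut$total_mutations, mut2$total_mutations)
  # unknown subtype rejected
  bad <- ex$truth; bad$subtype[1] <- "QQQ"
  expect_error(simulate_mutations(cfg, bad), "unknown subtype")
})

test_that("zero driver frequency yields zero mutations in that group", {
  cfg <- one_cohort_config(c(GS = 20, MSI = 20), seed = 57, n_genes = 100,
                           n_sig = 10,
                           driver_freqs = list(
                             PIK3CA = c(MSI = 0.8, GS = 0),
                             CDH1 = c(MSI = 0, GS = 0.5)))
  ex <- simulate_expression(cfg)
  mut <- simulate_mutations(cfg, ex$truth)
  gs <- ex$truth$subtype == "GS"
  expect_equal(sum(mut$indicator["PIK3CA", gs]), 0)
  expect_equal(sum(mut$indicator["CDH1", !gs]), 0)
  expect_gt(sum(mut$indicator["PIK3CA", !gs]), 0)
})

test_that("fixtures round-trip through the tab-separated writers", {
  cfg <- simulation_config(n_genes = 120, n_signature_genes_per_subtype = 10,
                           cohorts = list(TCGA = c(EBV = 2, MSI = 2,
                                                   GS = 2, CIN = 2),
                                          CCLE = c(MSI = 3, CIN = 3),
                                          PDX = c(MSI = 2, CIN = 1)),
                           seed = 58)
  fx <- simulate_cohort_fixture(cfg)
  dir <- withr::local_tempdir()
  paths <- write_fixture(fx, dir)
  # 3 expression files + annotation + truth + maf + matrix + totals
  expect_length(paths, 8)
  expect_true(all(file.exists(paths)))
  back <- read_fixture(dir)
  for (cohort in names(fx$expression)) {
    expect_equal(unclass(back$expression[[cohort]]),
                 unclass(fx$expression[[cohort]]), ignore_attr = TRUE)
    expect_identical(expr_scale(back$expression[[cohort]]), "counts")
  }
  expect_equal(back$annotation, fx$annotation)
  expect_equal(back$truth, fx$truth)
  expect_equal(back$mutations$indicator[rownames(fx$mutations$indicator), ],
               fx$mutations$indicator)
  expect_equal(unname(back$mutations$total_mutations),
               unname(fx$mutations$total_mutations))
  # degenerate fixture rejected before writing
  fx_bad <- fx
  fx_bad$expression$TCGA <- fx$expression$TCGA[, 0]
  expect_error(write_fixture(fx_bad, dir), "empty-sample")
})
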