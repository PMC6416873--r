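#' Simulation configuration for synthetic multi-cohort fixtures
#'
#' Parameterizes a negative-binomial bulk-expression simulator with four
#' planted subtype signatures (EBV, MSI, GS, CIN), per-cohort batch shifts,
#' and subtype-dependent mutation burden. Defaults emulate the structure of
#' a pooled TCGA-like diffuse gastric cancer cohort: the default subtype
#' composition (6 EBV, 7 MSI, 12 GS, 17 CIN) matches the printed composition
#' of the diffuse-type cases available for subtype analysis.
#'
#' @param n_genes Number of genes (>= 4 x `n_signature_genes_per_subtype`).
#' @param cohorts Named list: cohort ID -> named integer vector of samples
#'   per subtype over EBV/MSI/GS/CIN (zeros allowed).
#' @param n_signature_genes_per_subtype Disjoint signature block size per
#'   subtype.
#' @param signature_log2_effect Mean log2 up-shift of a subtype's signature
#'   genes in that subtype (>= 0).
#' @param baseline_log_mean_sd Length-2 numeric: mean and sd of the
#'   per-gene baseline log2 relative expression.
#' @param dispersion Negative-binomial dispersion (> 0; `size = 1 /
#'   dispersion`).
#' @param batch_log2_sd Per-cohort, per-gene additive batch shift scale on
#'   the log2 scale (>= 0).
#' @param library_size_range Length-2 positive: uniform range of per-sample
#'   library sizes.
#' @param burden_mean_per_Mb Named numeric: expected mutations/Mb per
#'   subtype.
#' @param target_region_Mb Size of the sequenced region in Mb (> 0).
#' @param driver_freqs Named list: driver gene -> named probability vector
#'   over groups (subtype labels, or cluster labels `I`/`II`).
#' @param seed Integer master seed; identical config + seed reproduces
#'   byte-identical fixtures.
#' @return Validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 2000L,
                              cohorts = list(TCGA = c(EBV = 6L, MSI = 7L,
                                                      GS = 12L, CIN = 17L)),
                              n_signature_genes_per_subtype = 200L,
                              signature_log2_effect = 2.0,
                              baseline_log_mean_sd = c(3, 2),
                              dispersion = 0.1,
                              batch_log2_sd = 0.5,
                              library_size_range = c(5e5, 2e6),
                              burden_mean_per_Mb = c(EBV = 10, MSI = 40,
                                                     GS = 5, CIN = 5),
                              target_region_Mb = 1,
                              driver_freqs = list(
                                PIK3CA = c(EBV = 0.50, MSI = 0.40,
                                           GS = 0.05, CIN = 0.05),
                                CDH1 = c(EBV = 0.05, MSI = 0.05,
                                         GS = 0.35, CIN = 0.03),
                                ARID1A = c(EBV = 0.55, MSI = 0.45,
                                           GS = 0.10, CIN = 0.10),
                                TP53 = c(EBV = 0.10, MSI = 0.30,
                                         GS = 0.20, CIN = 0.70)),
                              seed = 1L) {
  stopifnot(n_genes >= 1, n_signature_genes_per_subtype >= 1,
            signature_log2_effect >= 0, dispersion > 0, batch_log2_sd >= 0,
            length(baseline_log_mean_sd) == 2, baseline_log_mean_sd[2] >= 0,
            length(library_size_range) == 2, all(library_size_range >= 1),
            target_region_Mb > 0)
  if (4L * n_signature_genes_per_subtype > n_genes)
    stop("4 x n_signature_genes_per_subtype exceeds n_genes")
  if (length(cohorts) == 0L || is.null(names(cohorts)))
    stop("'cohorts' must be a named list")
  for (nm in names(cohorts)) {
    v <- cohorts[[nm]]
    if (is.null(names(v)) || !all(names(v) %in% GC_SUBTYPES))
      stop("cohort '", nm, "' must map subtypes in {EBV, MSI, GS, CIN}")
    if (any(v < 0) || any(v != round(v)))
      stop("sample counts must be nonnegative integers")
  }
  if (sum(unlist(cohorts)) == 0L) stop("no samples in any subtype")
  if (any(burden_mean_per_Mb <= 0)) stop("burden means must be > 0")
  for (g in names(driver_freqs)) {
    f <- driver_freqs[[g]]
    if (any(f < 0 | f > 1)) stop("driver frequencies must lie in [0, 1]")
  }
  structure(list(n_genes = as.integer(n_genes), cohorts = cohorts,
                 n_signature_genes_per_subtype =
                   as.integer(n_signature_genes_per_subtype),
                 signature_log2_effect = signature_log2_effect,
                 baseline_log_mean_sd = baseline_log_mean_sd,
                 dispersion = dispersion, batch_log2_sd = batch_log2_sd,
                 library_size_range = library_size_range,
                 burden_mean_per_Mb = burden_mean_per_Mb,
                 target_region_Mb = target_region_Mb,
                 driver_freqs = driver_freqs, seed = as.integer(seed)),
            class = "simulation_config")
}

# shared (cohort-independent) structure drawn under the master seed
simulation_universe <- function(config) {
  set.seed(config$seed)
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  baseline <- stats::rnorm(config$n_genes, config$baseline_log_mean_sd[1],
                           config$baseline_log_mean_sd[2])
  names(baseline) <- genes
  sig_pool <- sample(genes, 4L * config$n_signature_genes_per_subtype)
  signature <- split(sig_pool,
                     rep(GC_SUBTYPES,
                         each = config$n_signature_genes_per_subtype))
  list(genes = genes, baseline = baseline, signature = signature)
}

# deterministic substream seed per cohort (kept < 2^31)
cohort_seed <- function(config, i, salt) {
  (config$seed %% 100000L) + salt + 1000L * i
}

#' Simulate multi-cohort expression counts with planted subtype signatures
#'
#' Per-gene baseline log2 means are Normal; each subtype's signature genes
#' are up-shifted by `signature_log2_effect` in samples of that subtype;
#' every cohort adds its own per-gene Normal(0, `batch_log2_sd`) shift on
#' the log2 scale. Log2 means are converted to per-sample proportions,
#' scaled by a uniform library size, and counts are drawn from a negative
#' binomial with the configured dispersion. A single master seed drives one
#' substream per cohort, so adding a cohort leaves the others unchanged.
#'
#' @param config A [simulation_config()].
#' @return List: `expression` (named list of counts-scale
#'   [expression_matrix()] per cohort), `annotation` (pooled `data.frame`:
#'   `sample_id`, `cohort`, `histology`, `subtype`, `cluster`), `truth`
#'   (`sample_id`, `subtype`, `cluster`), `signature` (gene list per
#'   subtype).
#' @export
simulate_expression <- function(config) {
  uni <- simulation_universe(config)
  expr <- list()
  ann <- list()
  size <- 1 / config$dispersion
  for (i in seq_along(config$cohorts)) {
    cname <- names(config$cohorts)[i]
    comp <- config$cohorts[[i]]
    comp <- comp[comp > 0]
    n_c <- sum(comp)
    if (n_c == 0L) next
    set.seed(cohort_seed(config, i, 77000L))
    batch <- stats::rnorm(config$n_genes, 0, config$batch_log2_sd)
    subtype_of <- rep(names(comp), comp)
    sids <- unlist(lapply(names(comp), function(s)
      sprintf("%s_%s_%02d", cname, s, seq_len(comp[[s]]))))
    libs <- round(stats::runif(n_c, config$library_size_range[1],
                               config$library_size_range[2]))
    counts <- matrix(0, config$n_genes, n_c,
                     dimnames = list(uni$genes, sids))
    for (j in seq_len(n_c)) {
      l <- uni$baseline + batch
      sig <- uni$signature[[subtype_of[j]]]
      l[sig] <- l[sig] + config$signature_log2_effect
      p <- 2^l; p <- p / sum(p)
      counts[, j] <- stats::rnbinom(config$n_genes, mu = p * libs[j],
                                    size = size)
    }
    expr[[cname]] <- expression_matrix(counts, "counts")
    ann[[cname]] <- data.frame(
      sample_id = sids, cohort = cname, histology = "diffuse",
      subtype = subtype_of,
      cluster = ifelse(subtype_of == "GS", "I", "II"),
      stringsAsFactors = FALSE)
  }
  annotation <- do.call(rbind, ann)
  rownames(annotation) <- NULL
  list(expression = expr, annotation = annotation,
       truth = annotation[, c("sample_id", "subtype", "cluster")],
       signature = uni$signature)
}

#' Simulate per-sample mutation profiles
#'
#' Per-sample total mutation counts are Poisson with mean
#' `burden_mean_per_Mb[subtype] x target_region_Mb`; driver-gene indicators
#' are Bernoulli with group-dependent frequencies (the group key is the
#' sample's subtype if present in the frequency map, else its cluster
#' label). Totals are raised to the indicator column sums where needed so
#' that panel mutations never exceed the total.
#'
#' @param config A [simulation_config()].
#' @param truth `data.frame` with `sample_id`, `subtype`, `cluster` (and
#'   optionally `cohort`) covering all samples, as produced by
#'   [simulate_expression()].
#' @return A [mutation_matrix()] over the driver genes.
#' @export
simulate_mutations <- function(config, truth) {
  if (!all(c("sample_id", "subtype") %in% colnames(truth)))
    stop("truth labels need 'sample_id' and 'subtype'")
  unknown <- setdiff(truth$subtype, GC_SUBTYPES)
  if (length(unknown))
    stop("unknown subtype in truth labels: ", paste(unknown, collapse = ", "))
  set.seed(cohort_seed(config, length(config$cohorts) + 1L, 88000L))
  n <- nrow(truth)
  mu <- config$burden_mean_per_Mb[truth$subtype] * config$target_region_Mb
  totals <- stats::rpois(n, mu)
  drivers <- names(config$driver_freqs)
  ind <- matrix(0, length(drivers), n,
                dimnames = list(drivers, truth$sample_id))
  for (g in drivers) {
    f <- config$driver_freqs[[g]]
    prob <- vapply(seq_len(n), function(j) {
      if (truth$subtype[j] %in% names(f)) f[[truth$subtype[j]]]
      else if ("cluster" %in% colnames(truth) &&
               truth$cluster[j] %in% names(f)) f[[truth$cluster[j]]]
      else 0
    }, numeric(1))
    ind[g, ] <- stats::rbinom(n, 1L, prob)
  }
  mutation_matrix(ind, pmax(totals, colSums(ind)), config$target_region_Mb)
}

#' Simulate a complete cohort fixture
#'
#' @param config A [simulation_config()].
#' @return List of class `"cohort_fixture"`: `expression`, `annotation`,
#'   `truth`, `signature`, `mutations`, `config`.
#' @export
simulate_cohort_fixture <- function(config) {
  ex <- simulate_expression(config)
  mut <- simulate_mutations(config, ex$truth)
  structure(c(ex, list(mutations = mut, config = config)),
            class = "cohort_fixture")
}

#' Write / read a cohort fixture as tab-separated text
#'
#' Writes one expression table per cohort (`expression_<cohort>.tsv`), a
#' pooled annotation table, a MAF-like mutation table plus per-sample
#' totals, and the ground-truth labels. `read_fixture()` round-trips the
#' files losslessly.
#'
#' @param fixture A [simulate_cohort_fixture()] result.
#' @param dir Writable directory (created if absent).
#' @return `write_fixture()`: named character vector of the files written.
#' @export
write_fixture <- function(fixture, dir) {
  if (length(fixture$expression) == 0L ||
      any(vapply(fixture$expression, ncol, 1L) == 0L))
    stop("fixture contains an empty-sample cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (cname in names(fixture$expression)) {
    p <- file.path(dir, paste0("expression_", cname, ".tsv"))
    write_expression(fixture$expression[[cname]], p)
    paths[paste0("expression_", cname)] <- p
  }
  tsv <- function(df, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths["annotation"] <- tsv(fixture$annotation, "annotation")
  paths["truth"] <- tsv(fixture$truth, "truth")
  ind <- fixture$mutations$indicator
  hits <- which(ind == 1, arr.ind = TRUE)
  maf <- data.frame(sample_id = colnames(ind)[hits[, 2]],
                    gene = rownames(ind)[hits[, 1]],
                    variant_class = "SNV", stringsAsFactors = FALSE)
  maf <- maf[order(maf$sample_id, maf$gene), , drop = FALSE]
  paths["mutations_maf"] <- tsv(maf, "mutations_maf")
  # the binary matrix keeps never-mutated panel genes, which a MAF cannot
  paths["mutation_matrix"] <- tsv(
    data.frame(gene = rownames(ind), ind, check.names = FALSE),
    "mutation_matrix")
  paths["mutation_totals"] <- tsv(
    data.frame(sample_id = colnames(ind),
               total_mutations = fixture$mutations$total_mutations,
               target_region_Mb = fixture$mutations$target_region_Mb,
               stringsAsFactors = FALSE),
    "mutation_totals")
  paths
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  efiles <- list.files(dir, pattern = "^expression_.*\\.tsv$",
                       full.names = TRUE)
  expr <- lapply(efiles, read_expression)
  names(expr) <- sub("^expression_(.*)\\.tsv$", "\\1", basename(efiles))
  rd <- function(name) utils::read.delim(file.path(dir, paste0(name, ".tsv")),
                                         stringsAsFactors = FALSE)
  annotation <- rd("annotation")
  truth <- rd("truth")
  totals <- rd("mutation_totals")
  bin <- utils::read.delim(file.path(dir, "mutation_matrix.tsv"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  ind <- as.matrix(bin[, -1, drop = FALSE])
  rownames(ind) <- bin$gene
  ind <- ind[, totals$sample_id, drop = FALSE]
  mut <- mutation_matrix(ind, total_mutations = totals$total_mutations,
                         target_region_Mb = totals$target_region_Mb[1])
  list(expression = expr, annotation = annotation, truth = truth,
       mutations = mut)
}
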