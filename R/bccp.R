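GC_SUBTYPES <- c("EBV", "MSI", "GS", "CIN")

#' Select subtype-specific gene panels
#'
#' For each subtype, a gene enters the panel iff its pooled-variance
#' two-sample t-test against each one of the other subtypes individually is
#' significant at `alpha` and the sign of t is the same in all comparisons
#' (the gene is consistently up or consistently down in the subtype).
#' Candidates are ranked by the maximum of their pairwise p-values ascending
#' (most uniformly significant first), ties by descending mean |t| then gene
#' ID, and each panel is truncated to `top_n` genes.
#'
#' @param x An `ExpressionMatrix` on the analysis scale.
#' @param subtype_labels Character vector, one subtype per sample.
#' @param alpha Per-comparison significance level (default 0.001).
#' @param top_n Panel size cap (default 200).
#' @param require_sign_consistency If `FALSE`, drop the same-sign
#'   requirement across the pairwise comparisons.
#' @return Named list (one element per subtype) of panels: each a list with
#'   `subtype`, `genes` (ordered character vector), and `stats` (per-gene
#'   t and p for every pairwise comparison plus the ranking key).
#' @export
select_subtype_genes <- function(x, subtype_labels, alpha = 0.001,
                                 top_n = 200L,
                                 require_sign_consistency = TRUE) {
  subtype_labels <- as.character(subtype_labels)
  if (length(subtype_labels) != ncol(x))
    stop("'subtype_labels' must have one label per sample")
  subtypes <- intersect(GC_SUBTYPES, unique(subtype_labels))
  if (length(subtypes) < 2L) subtypes <- sort(unique(subtype_labels))
  counts <- table(subtype_labels)
  if (any(counts < 2L))
    stop("subtype(s) with < 2 samples: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  m <- unclass(x)
  # one t-test per unordered subtype pair, reused for both orientations
  pair_t <- list(); pair_p <- list()
  combs <- utils::combn(subtypes, 2L, simplify = FALSE)
  for (pr in combs) {
    tt <- row_ttest(m, subtype_labels == pr[1], subtype_labels == pr[2])
    key <- paste(pr, collapse = "|")
    pair_t[[key]] <- tt$t
    pair_p[[key]] <- tt$p
  }
  get_tp <- function(s, r) {
    key1 <- paste(c(s, r), collapse = "|")
    if (!is.null(pair_t[[key1]])) return(list(t = pair_t[[key1]], p = pair_p[[key1]]))
    key2 <- paste(c(r, s), collapse = "|")
    list(t = -pair_t[[key2]], p = pair_p[[key2]])
  }
  out <- list()
  for (s in subtypes) {
    others <- setdiff(subtypes, s)
    tmat <- sapply(others, function(r) get_tp(s, r)$t)
    pmat <- sapply(others, function(r) get_tp(s, r)$p)
    if (is.null(dim(tmat))) { tmat <- cbind(tmat); pmat <- cbind(pmat) }
    sig <- rowSums(pmat < alpha) == length(others)
    if (require_sign_consistency) {
      same_sign <- abs(rowSums(sign(tmat))) == length(others)
      sig <- sig & same_sign
    }
    maxp <- apply(pmat, 1L, max)
    mean_abs_t <- rowMeans(abs(tmat))
    cand <- which(sig)
    ord <- cand[order(maxp[cand], -mean_abs_t[cand], rownames(m)[cand])]
    keep <- utils::head(ord, top_n)
    stats <- data.frame(gene_id = rownames(m)[keep],
                        max_p = maxp[keep],
                        mean_abs_t = mean_abs_t[keep],
                        row.names = NULL, stringsAsFactors = FALSE)
    for (j in seq_along(others)) {
      stats[[paste0("t_vs_", others[j])]] <- tmat[keep, j]
      stats[[paste0("p_vs_", others[j])]] <- pmat[keep, j]
    }
    out[[s]] <- list(subtype = s, genes = rownames(m)[keep], stats = stats)
  }
  out
}

#' Fit a one-vs-rest Bayesian compound covariate predictor
#'
#' The compound covariate score of sample j is `c_j = sum_i t_i x_ij`, where
#' the weights t_i are the training-set two-sample t statistics (positive
#' class vs rest) of the panel genes. Class-conditional densities of the
#' score are Normal with class-specific means and a pooled within-class
#' standard deviation; class priors default to (0.5, 0.5).
#'
#' @param x Training `ExpressionMatrix`.
#' @param positive Logical vector marking the positive-class samples.
#' @param panel A panel from [select_subtype_genes()], or a character vector
#'   of gene IDs.
#' @param priors Length-2 numeric (positive, rest), summing to 1.
#' @return Object of class `"bccp_model"`: `positive_class`, `genes`,
#'   `weights`, `class_means` (positive, rest), `pooled_sd`, `priors`.
#' @export
fit_bccp <- function(x, positive, panel, priors = c(0.5, 0.5)) {
  genes <- if (is.list(panel)) panel$genes else panel
  positive_class <- if (is.list(panel)) panel$subtype else "positive"
  if (length(genes) == 0L) stop("empty gene panel")
  if (!is.logical(positive) || length(positive) != ncol(x))
    stop("'positive' must be a logical vector over samples")
  if (sum(positive) < 2L || sum(!positive) < 2L)
    stop("both classes need >= 2 samples")
  if (abs(sum(priors) - 1) > 1e-9 || any(priors < 0))
    stop("priors must be nonnegative and sum to 1")
  m <- unclass(x)[genes, , drop = FALSE]
  tt <- row_ttest(m, positive, !positive)
  w <- tt$t
  scores <- as.vector(crossprod(m, w))
  mu_pos <- mean(scores[positive]); mu_neg <- mean(scores[!positive])
  n1 <- sum(positive); n2 <- sum(!positive)
  sp2 <- (sum((scores[positive] - mu_pos)^2) +
          sum((scores[!positive] - mu_neg)^2)) / (n1 + n2 - 2L)
  sd <- sqrt(sp2)
  if (sd == 0) stop("pooled standard deviation of compound scores is zero")
  structure(list(positive_class = positive_class, genes = genes,
                 weights = stats::setNames(w, genes),
                 class_means = c(positive = mu_pos, rest = mu_neg),
                 pooled_sd = sd, priors = priors),
            class = "bccp_model")
}

#' @export
print.bccp_model <- function(x, ...) {
  cat(sprintf("BCCP model [%s vs rest]: %d genes, class means %.3f / %.3f, sd %.3f\n",
              x$positive_class, length(x$genes),
              x$class_means[1], x$class_means[2], x$pooled_sd))
  invisible(x)
}

#' Posterior probability of the positive class
#'
#' `posterior = prior+ phi(c; mu+, sd) / (prior+ phi(c; mu+, sd) +
#' prior- phi(c; mu-, sd))` with `phi` the Normal density and `c` the
#' compound covariate score of the sample. Computed on the log scale for
#' numerical stability; the result lies in (0, 1) for non-degenerate priors.
#'
#' @param model A [fit_bccp()] model.
#' @param newx Expression for the new sample(s): numeric vector named by
#'   gene, or a genes x samples matrix, on the training analysis scale.
#' @param strict If `TRUE` (default), missing panel genes are an error;
#'   otherwise they are dropped, the remaining weights rescaled to preserve
#'   the total absolute weight, and a warning is emitted.
#' @return Numeric vector of posteriors, one per sample.
#' @export
predict_posterior <- function(model, newx, strict = TRUE) {
  if (is.null(dim(newx))) newx <- cbind(sample = newx)
  m <- unclass(newx)
  present <- model$genes %in% rownames(m)
  w <- model$weights
  if (!all(present)) {
    if (strict)
      stop("missing panel gene(s): ",
           paste(utils::head(model$genes[!present], 5L), collapse = ", "))
    warning(sprintf("dropping %d missing panel gene(s); weights rescaled",
                    sum(!present)))
    w <- w[present]
    w <- w * sum(abs(model$weights)) / sum(abs(w))
  }
  scores <- as.vector(crossprod(m[names(w), , drop = FALSE], w))
  posterior_from_score(model, scores)
}

posterior_from_score <- function(model, scores) {
  pr <- model$priors
  if (pr[1] == 0) return(rep(0, length(scores)))
  if (pr[1] == 1) return(rep(1, length(scores)))
  lpos <- log(pr[1]) + stats::dnorm(scores, model$class_means[1],
                                    model$pooled_sd, log = TRUE)
  lneg <- log(pr[2]) + stats::dnorm(scores, model$class_means[2],
                                    model$pooled_sd, log = TRUE)
  stats::plogis(lpos - lneg)
}

#' Classify samples through a one-vs-rest decision tree
#'
#' Nodes are visited in `node_order` (default EBV, MSI, GS with CIN as the
#' terminal remainder): at each node, if the one-vs-rest posterior of that
#' subtype is >= `threshold` the sample takes that label and the descent
#' stops; otherwise the next node is evaluated. A sample rejected at every
#' node takes the remainder label. A node whose model is `NULL` (e.g. no
#' panel genes survived selection) records an `NA` posterior and is skipped.
#'
#' @param models Named list of [fit_bccp()] models (or `NULL` elements).
#' @param newx Genes x samples matrix on the training analysis scale.
#' @param node_order Subtypes evaluated as tree nodes, in order.
#' @param remainder Terminal label for samples rejected at every node
#'   (default: the subtype among [models] not in `node_order`, else "CIN").
#' @param threshold Posterior acceptance threshold (default 0.5).
#' @param strict Passed to [predict_posterior()].
#' @return `data.frame` with `sample_id`, one posterior column per node,
#'   `label`, and `tree_path` (comma-separated visited nodes).
#' @export
classify_decision_tree <- function(models, newx,
                                   node_order = c("EBV", "MSI", "GS"),
                                   remainder = NULL, threshold = 0.5,
                                   strict = TRUE) {
  if (is.null(dim(newx))) newx <- cbind(sample = newx)
  if (!all(node_order %in% names(models)))
    stop("'node_order' must name fitted models")
  if (is.null(remainder)) {
    left <- setdiff(names(models), node_order)
    remainder <- if (length(left)) left[1] else "CIN"
  }
  ns <- ncol(newx)
  post <- matrix(NA_real_, ns, length(node_order),
                 dimnames = list(colnames(newx), node_order))
  label <- rep(NA_character_, ns)
  path <- rep("", ns)
  open <- rep(TRUE, ns)
  for (node in node_order) {
    if (!any(open)) break
    mdl <- models[[node]]
    idx <- which(open)
    path[idx] <- ifelse(path[idx] == "", node, paste(path[idx], node, sep = ","))
    if (is.null(mdl)) next
    p <- predict_posterior(mdl, newx[, idx, drop = FALSE], strict = strict)
    post[idx, node] <- p
    hit <- p >= threshold
    label[idx[hit]] <- node
    open[idx[hit]] <- FALSE
  }
  label[is.na(label)] <- remainder
  out <- data.frame(sample_id = colnames(newx), post, label = label,
                    tree_path = path, row.names = NULL,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out
}

#' Leave-one-out cross-validation of the full subtype classifier
#'
#' For every held-out sample, subtype-specific gene selection *and* all
#' one-vs-rest model fits are repeated on the remaining samples (no feature
#' selection leakage), and the held-out sample is classified through the
#' decision tree. Subtypes whose in-fold panel is empty contribute a skipped
#' node (see [classify_decision_tree()]).
#'
#' @inheritParams select_subtype_genes
#' @param node_order,threshold Passed to [classify_decision_tree()].
#' @return List with `calls` (per-sample data.frame: truth, label),
#'   `confusion` (truth x predicted table), `accuracy`, and `performance`
#'   (per-subtype sensitivity and specificity).
#' @export
loocv <- function(x, subtype_labels, alpha = 0.001, top_n = 200L,
                  node_order = c("EBV", "MSI", "GS"), threshold = 0.5) {
  subtype_labels <- as.character(subtype_labels)
  counts <- table(subtype_labels)
  if (any(counts < 3L))
    stop("LOOCV needs >= 3 samples per subtype; short: ",
         paste(names(counts)[counts < 3L], collapse = ", "))
  subtypes <- intersect(GC_SUBTYPES, names(counts))
  if (length(subtypes) < 2L) subtypes <- sort(names(counts))
  node_order <- intersect(node_order, subtypes)
  remainder <- setdiff(subtypes, node_order)[1]
  if (is.na(remainder)) {   # every subtype is a node: last one falls through
    remainder <- node_order[length(node_order)]
    node_order <- node_order[-length(node_order)]
  }
  n <- ncol(x)
  labels_out <- character(n)
  for (j in seq_len(n)) {
    train <- unclass(x)[, -j, drop = FALSE]
    train_em <- retag(train, if (inherits(x, "ExpressionMatrix")) expr_scale(x) else "log2")
    lab <- subtype_labels[-j]
    panels <- select_subtype_genes(train_em, lab, alpha = alpha, top_n = top_n)
    models <- lapply(subtypes, function(s) {
      pan <- panels[[s]]
      if (is.null(pan) || length(pan$genes) == 0L) return(NULL)
      fit_bccp(train_em, lab == s, pan)
    })
    names(models) <- subtypes
    call <- classify_decision_tree(models, unclass(x)[, j, drop = FALSE],
                                   node_order = node_order,
                                   remainder = remainder,
                                   threshold = threshold)
    labels_out[j] <- call$label
  }
  truth <- factor(subtype_labels, levels = subtypes)
  pred <- factor(labels_out, levels = subtypes)
  confusion <- table(truth = truth, predicted = pred)
  acc <- mean(labels_out == subtype_labels)
  perf <- do.call(rbind, lapply(subtypes, function(s) {
    tp <- sum(truth == s & pred == s); fn <- sum(truth == s & pred != s)
    tn <- sum(truth != s & pred != s); fp <- sum(truth != s & pred == s)
    data.frame(subtype = s,
               sensitivity = tp / (tp + fn),
               specificity = tn / (tn + fp),
               stringsAsFactors = FALSE)
  }))
  list(calls = data.frame(sample_id = colnames(x), truth = subtype_labels,
                          label = labels_out, stringsAsFactors = FALSE),
       confusion = confusion, accuracy = acc, performance = perf)
}

#' Sensitivity/specificity as a function of the posterior threshold
#'
#' Sweeps a threshold grid over per-sample one-vs-rest posteriors: at
#' threshold t a sample is called positive for a subtype iff its posterior
#' is >= t. Sensitivity is non-increasing and specificity non-decreasing in
#' t.
#'
#' @param posteriors Samples x subtypes numeric matrix of one-vs-rest
#'   posteriors.
#' @param truth Character vector of true subtypes, one per sample.
#' @param thresholds Numeric grid (default `seq(0, 1, 0.05)`).
#' @return Long `data.frame`: `subtype`, `threshold`, `sensitivity`,
#'   `specificity`.
#' @export
sens_spec_curve <- function(posteriors, truth,
                            thresholds = seq(0, 1, by = 0.05)) {
  if (nrow(posteriors) != length(truth))
    stop("posteriors and truth are not aligned")
  subtypes <- colnames(posteriors)
  rows <- list()
  for (s in subtypes) {
    pos <- truth == s
    if (!any(pos)) stop("empty truth class: ", s)
    p <- posteriors[, s]
    for (t in thresholds) {
      rows[[length(rows) + 1L]] <- data.frame(
        subtype = s, threshold = t,
        sensitivity = mean(p[pos] >= t),
        specificity = mean(p[!pos] < t),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
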