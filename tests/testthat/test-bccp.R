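test_that("subtype panels recover planted signatures without contamination", {
  fx <- normalized_fixture(c(EBV = 30, MSI = 30, GS = 30, CIN = 30),
                           effect = 2.0, seed = 21)
  panels <- select_subtype_genes(fx$x, fx$truth$subtype,
                                 alpha = 0.001, top_n = 200)
  for (s in names(panels)) {
    expect_gte(mean(fx$signature[[s]] %in% panels[[s]]$genes), 0.90)
    others <- unlist(fx$signature[setdiff(names(fx$signature), s)])
    expect_lt(mean(panels[[s]]$genes %in% others), 0.05)
  }
  # truncation honors top_n and the documented rank order
  p10 <- select_subtype_genes(fx$x, fx$truth$subtype, top_n = 10)
  for (s in names(p10)) {
    expect_length(p10[[s]]$genes, 10)
    expect_identical(p10[[s]]$genes, panels[[s]]$genes[1:10])
    expect_false(is.unsorted(p10[[s]]$stats$max_p))
  }
})

test_that("null fixtures yield essentially empty panels", {
  fx <- normalized_fixture(c(EBV = 20, MSI = 20, GS = 20, CIN = 20),
                           effect = 0, seed = 22, batch_sd = 0)
  panels <- select_subtype_genes(fx$x, fx$truth$subtype, alpha = 0.001)
  total <- sum(vapply(panels, function(p) length(p$genes), 1L))
  expect_lte(total, 5)  # ~2000 genes x (0.001)^3-scale joint rate
})

test_that("select_subtype_genes rejects under-populated subtypes", {
  fx <- normalized_fixture(c(EBV = 5, MSI = 5), seed = 23,
                           n_genes = 200, n_sig = 20)
  labels <- fx$truth$subtype
  labels[labels == "MSI"][2:5] <- "EBV"
  expect_error(select_subtype_genes(fx$x, labels), "< 2 samples")
})

test_that("compound covariate model has the declared structure", {
  set.seed(24)
  # one informative gene, symmetric classes
  m <- rbind(g1 = c(-1, -1, 1, 1) + rnorm(4, 0, 0.05),
             g2 = rnorm(4, 0, 0.05))
  colnames(m) <- sprintf("s%d", 1:4)
  x <- expression_matrix(m, "log2")
  mod <- fit_bccp(x, c(TRUE, TRUE, FALSE, FALSE), c("g1", "g2"))
  expect_s3_class(mod, "bccp_model")
  # weights are the training t statistics
  tt <- two_sample_ttest(x, c("a", "a", "b", "b"))
  expect_equal(unname(mod$weights), tt$t, tolerance = 1e-12)
  # scores of a 1-gene toy check the c = t * x arithmetic by hand
  m1 <- rbind(g1 = c(0, 1, 4, 5))
  colnames(m1) <- sprintf("s%d", 1:4)
  x1 <- expression_matrix(m1, "log2")
  mod1 <- fit_bccp(x1, c(TRUE, TRUE, FALSE, FALSE), "g1")
  t1 <- two_sample_ttest(x1, c("a", "a", "b", "b"))$t
  expect_equal(unname(mod1$class_means),
               c(mean(t1 * c(0, 1)), mean(t1 * c(4, 5))), tolerance = 1e-12)
  expect_equal(sum(mod1$priors), 1)
  expect_error(fit_bccp(x, c(TRUE, TRUE, FALSE, FALSE), character(0)),
               "empty")
  const <- expression_matrix(
    matrix(2, 1, 4, dimnames = list("g1", sprintf("s%d", 1:4))), "log2")
  expect_error(fit_bccp(const, c(TRUE, TRUE, FALSE, FALSE), "g1"),
               "pooled standard deviation")
})

test_that("posterior equals the brute-force Normal-density oracle", {
  set.seed(25)
  worst <- 0
  for (i in 1:1000) {
    mu <- sort(rnorm(2, 0, 5))
    sd <- runif(1, 0.1, 3)
    pr <- runif(1, 0.05, 0.95)
    model <- structure(list(positive_class = "X", genes = "g1",
                            weights = c(g1 = 1),
                            class_means = c(positive = mu[2], rest = mu[1]),
                            pooled_sd = sd, priors = c(pr, 1 - pr)),
                       class = "bccp_model")
    c_score <- rnorm(1, mu[sample(2, 1)], sd)
    got <- predict_posterior(model, c(g1 = c_score))
    oracle <- pr * dnorm(c_score, mu[2], sd) /
      (pr * dnorm(c_score, mu[2], sd) + (1 - pr) * dnorm(c_score, mu[1], sd))
    worst <- max(worst, abs(got - oracle))
    # mathematically in (0, 1); saturates to the boundary in doubles only
    # when one class density underflows
    expect_true(got >= 0 && got <= 1)
  }
  expect_lt(worst, 1e-12)
})

test_that("posterior symmetry, midpoint, and degenerate priors behave", {
  model <- structure(list(positive_class = "X", genes = "g1",
                          weights = c(g1 = 1),
                          class_means = c(positive = 2, rest = -2),
                          pooled_sd = 1, priors = c(0.5, 0.5)),
                     class = "bccp_model")
  # score midway between the class means with equal priors -> 0.5
  expect_equal(predict_posterior(model, c(g1 = 0)), 0.5)
  # c = mu+ with mu- 6 sd away: phi(0) / (phi(0) + phi(6))
  model6 <- model; model6$class_means <- c(positive = 0, rest = 6)
  expect_equal(predict_posterior(model6, c(g1 = 0)),
               dnorm(0) / (dnorm(0) + dnorm(6)), tolerance = 1e-15)
  # label swap maps p -> 1 - p under equal priors
  swapped <- model
  swapped$class_means <- rev(model$class_means)
  names(swapped$class_means) <- c("positive", "rest")
  for (c_val in c(-3, -0.5, 0, 1.7)) {
    expect_equal(predict_posterior(model, c(g1 = c_val)) +
                   predict_posterior(swapped, c(g1 = c_val)),
                 1, tolerance = 1e-12)
  }
  # degenerate priors pin the posterior
  p1 <- model; p1$priors <- c(1, 0)
  expect_equal(predict_posterior(p1, c(g1 = -100)), 1)
  p0 <- model; p0$priors <- c(0, 1)
  expect_equal(predict_posterior(p0, c(g1 = 100)), 0)
  # posterior is monotone in the score when mu+ > mu-
  scores <- seq(-5, 5, length.out = 25)
  posts <- vapply(scores, function(s) predict_posterior(model, c(g1 = s)), 1)
  expect_false(is.unsorted(posts))
  # strict mode errors on missing genes; lenient drops and warns
  expect_error(predict_posterior(model, c(gX = 1)), "missing panel gene")
  model2 <- model
  model2$genes <- c("g1", "g2"); model2$weights <- c(g1 = 1, g2 = 1)
  expect_warning(predict_posterior(model2, c(g1 = 0), strict = FALSE),
                 "dropping")
})

test_that("decision tree labels every sample exactly once, in node order", {
  mk <- function(mu_pos) structure(
    list(positive_class = "X", genes = "g1", weights = c(g1 = 1),
         class_means = c(positive = mu_pos, rest = -mu_pos),
         pooled_sd = 1, priors = c(0.5, 0.5)), class = "bccp_model")
  models <- list(EBV = mk(5), MSI = mk(5), GS = mk(5), CIN = mk(5))
  newx <- rbind(g1 = c(a = 5, b = -5))
  call <- classify_decision_tree(models, newx)
  # sample a accepted at the first node; sample b falls through to CIN
  expect_identical(call$label, c("EBV", "CIN"))
  expect_identical(call$tree_path[1], "EBV")
  expect_identical(call$tree_path[2], "EBV,MSI,GS")
  expect_true(all(!is.na(call$label)))
  # NULL node model is skipped
  models$EBV <- NULL
  models <- models[c("EBV", "MSI", "GS", "CIN")[c(2, 3, 4)]]
  call2 <- classify_decision_tree(c(list(EBV = NULL), models), newx)
  expect_identical(call2$label, c("MSI", "CIN"))
  expect_true(is.na(call2$EBV[1]))
  expect_error(classify_decision_tree(models, newx,
                                      node_order = c("EBV", "ZZZ")),
               "node_order")
})

test_that("sens/spec curve matches a brute-force count oracle", {
  set.seed(26)
  post <- matrix(runif(60), 20, 3,
                 dimnames = list(NULL, c("EBV", "MSI", "GS")))
  truth <- sample(c("EBV", "MSI", "GS"), 20, replace = TRUE)
  th <- seq(0, 1, 0.1)
  curve <- sens_spec_curve(post, truth, th)
  for (i in seq_len(nrow(curve))) {
    s <- curve$subtype[i]; t <- curve$threshold[i]
    pos <- truth == s
    expect_equal(curve$sensitivity[i],
                 sum(post[pos, s] >= t) / sum(pos))
    expect_equal(curve$specificity[i],
                 sum(post[!pos, s] < t) / sum(!pos))
  }
  # monotone in threshold per subtype
  for (s in colnames(post)) {
    sub <- curve[curve$subtype == s, ]
    expect_false(is.unsorted(-sub$sensitivity))
    expect_false(is.unsorted(sub$specificity))
  }
  expect_equal(unique(curve$sensitivity[curve$threshold == 0]), 1)
  expect_error(sens_spec_curve(post, rep("EBV", 20)), "empty truth class")
})

test_that("LOOCV separates a forced 1-gene toy and repeats selection in-fold", {
  set.seed(27)
  # 4 subtypes x 4 samples, one perfectly separating gene block each
  n_per <- 4
  labels <- rep(c("EBV", "MSI", "GS", "CIN"), each = n_per)
  m <- matrix(rnorm(16 * 40, 0, 0.1), 40, 16,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:16)))
  for (i in seq_along(unique(labels))) {
    s <- unique(labels)[i]
    m[((i - 1) * 5 + 1):(i * 5), labels == s] <-
      m[((i - 1) * 5 + 1):(i * 5), labels == s] + 4
  }
  cv <- loocv(expression_matrix(m, "log2"), labels, alpha = 0.01, top_n = 5)
  expect_equal(cv$accuracy, 1.0)
  expect_equal(sum(cv$confusion), 16)
  expect_true(all(diag(cv$confusion) == n_per))
  expect_equal(cv$performance$sensitivity, rep(1, 4))
  expect_equal(cv$performance$specificity, rep(1, 4))
  expect_error(loocv(expression_matrix(m, "log2"),
                     c(labels[-1], "EBV2")), ">= 3 samples")
})

test_that("LOOCV on pure noise stays at chance (no selection leakage)", {
  accs <- c(); n_tot <- 0; hits <- 0
  for (seed in 31:35) {
    fx <- normalized_fixture(c(EBV = 8, MSI = 8, GS = 8, CIN = 8),
                             effect = 0, seed = seed,
                             n_genes = 500, n_sig = 50, batch_sd = 0)
    cv <- loocv(fx$x, fx$truth$subtype, alpha = 0.001, top_n = 200)
    hits <- hits + sum(cv$calls$label == cv$calls$truth)
    n_tot <- n_tot + nrow(cv$calls)
  }
  bounds <- qbinom(c(0.005, 0.995), n_tot, 0.25)
  expect_gte(hits, bounds[1])
  expect_lte(hits, bounds[2])
})
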