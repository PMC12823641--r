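test_that("AUC follows the rank-sum identity", {
  expect_equal(auc_empirical(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))$auc, 0.75)
  expect_equal(auc_empirical(rep(0.3, 10), rep_len(c(1, 0), 10))$auc, 0.5)
  # monotone transforms leave the rank statistic unchanged
  set.seed(1)
  s <- rnorm(50); y <- rbinom(50, 1, 0.5); y[1] <- 1; y[2] <- 0
  expect_equal(auc_empirical(exp(3 * s), y)$auc, auc_empirical(s, y)$auc)
  expect_error(auc_empirical(s, rep(1, 50)), "both classes")
})

test_that("rank-sum AUC equals the trapezoidal ROC area, with ties", {
  set.seed(2)
  for (i in 1:400) {
    n <- sample(4:40, 1)
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # heavy ties
    y <- rbinom(n, 1, 0.5); y[1] <- 1; y[2] <- 0
    roc <- auc_empirical(s, y)
    expect_equal(roc$auc, roc_trapezoid(roc$curve), tolerance = 1e-12)
    expect_equal(roc$curve$fpr[1], 0); expect_equal(roc$curve$tpr[1], 0)
    expect_equal(roc$curve$fpr[nrow(roc$curve)], 1)
    expect_equal(roc$curve$tpr[nrow(roc$curve)], 1)
    # complement symmetry is exact under mid-ranks
    expect_equal(roc$auc + auc_empirical(-s, y)$auc, 1, tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC on random score sets", {
  library(pROC)
  set.seed(3)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    s <- round(rnorm(n), 1)
    y <- rbinom(n, 1, 0.5); y[1] <- 1; y[2] <- 0
    ours <- auc_empirical(s, y)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("naive Bayes scoring matches e1071's reference predictions", {
  arch <- sample_architecture(c(dominant = 15, null = 5), 0.01, seed = 11)
  tt <- make_train_test(arch, 100, 100, master_seed = 12)
  sc <- fit_predict("NB", tt$train, tt$test)
  fit <- e1071::naiveBayes(
    x = apply(tt$train$genotypes, 2, as.numeric),
    y = factor(tt$train$phenotype, levels = 0:1))
  raw <- predict(fit, apply(tt$test$genotypes, 2, as.numeric), type = "raw")
  expect_equal(as.numeric(sc), log(raw[, "1"] / raw[, "0"]), tolerance = 1e-10)
})

test_that("a perfectly separating site yields AUC 1 for every family", {
  G <- matrix(rep(c(2L, 0L), each = 40), ncol = 1)
  y <- rep(c(1L, 0L), each = 40)
  train <- make_cohort(G, y)
  test <- make_cohort(G[c(1:10, 41:50), , drop = FALSE], y[c(1:10, 41:50)])
  for (fam in c("LR", "NB", "RF", "NN")) {
    sc <- fit_predict(fam, train, test, seed = 5)
    expect_equal(auc_empirical(sc, test$phenotype)$auc, 1,
                 tolerance = 1e-9, label = paste("AUC for", fam))
  }
})

test_that("null architectures and permuted labels both give chance AUC", {
  arch <- sample_architecture(c(null = 60), 0, seed = 21)
  tt <- make_train_test(arch, 200, 200, master_seed = 22)
  for (fam in c("LR", "NB", "RF", "NN")) {
    sc <- fit_predict(fam, tt$train, tt$test, seed = 23)
    expect_lt(abs(auc_empirical(sc, tt$test$phenotype)$auc - 0.5), 0.12)
  }
  # real signal, destroyed by permuting the training labels
  arch2 <- sample_architecture(c(dominant = 100), 0.005, seed = 24)
  tt2 <- make_train_test(arch2, 1000, 1000, master_seed = 25)
  sc_true <- fit_predict("LR", tt2$train, tt2$test)
  auc_true <- auc_empirical(sc_true, tt2$test$phenotype)$auc
  perm <- make_cohort(tt2$train$genotypes,
                      withr::with_seed(26, sample(tt2$train$phenotype)))
  sc_perm <- fit_predict("LR", perm, tt2$test)
  auc_perm <- auc_empirical(sc_perm, tt2$test$phenotype)$auc
  expect_gt(auc_true, 0.7)
  expect_lt(abs(auc_perm - 0.5), 0.1)
})

test_that("per-individual predictions serialize to TSV", {
  arch <- sample_architecture(c(additive = 8), 0.003, seed = 71)
  tt <- make_train_test(arch, 25, 25, master_seed = 72)
  sc <- fit_predict("LR", tt$train, tt$test)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_predictions_tsv(sc, tt$test, path)
  df <- read.table(path, header = TRUE, sep = "\t")
  expect_named(df, c("iid", "label", "score", "classifier", "fs_flag"))
  expect_equal(nrow(df), 50L)
  expect_equal(df$classifier[1], "LR")
  expect_equal(df$score, as.numeric(sc), tolerance = 1e-9)
})

test_that("stochastic families are deterministic given a seed", {
  arch <- sample_architecture(c(additive = 20, null = 5), 0.005, seed = 31)
  tt <- make_train_test(arch, 120, 120, master_seed = 32)
  for (fam in c("RF", "NN")) {
    s1 <- fit_predict(fam, tt$train, tt$test, seed = 33)
    s2 <- fit_predict(fam, tt$train, tt$test, seed = 33)
    expect_identical(as.numeric(s1), as.numeric(s2))
  }
})

test_that("classifier specs validate their hyperparameters", {
  expect_equal(classifier_spec("RF", num_trees = 100)$params$num_trees, 100)
  expect_error(classifier_spec("LR", trees = 5), "unknown hyperparameters")
  expect_error(classifier_spec("SVM"))
  expect_error(fit_predict("LR", make_cohort(matrix(0:1, 2, 1), c(1, 0)),
                           make_cohort(matrix(0:1, 2, 2), c(1, 0))),
               "share site order")
})

test_that("an unpenalized LASSO pass retains every site", {
  arch <- sample_architecture(c(additive = 40, null = 5), 0.005, seed = 41)
  co <- simulate_cohort(arch, 300, 300, seed = 42)
  mask <- lasso_select(co, lambda_grid = 0, min_fraction = 0.1, seed = 43)
  expect_false(mask$failed)
  expect_equal(mask$fraction_retained, 1.0)
  expect_identical(mask$retained, co$site_ids)
})

test_that("retained-set size is non-increasing in the LASSO penalty", {
  arch <- sample_architecture(c(additive = 60, null = 10), 0.004, seed = 51)
  co <- simulate_cohort(arch, 400, 400, seed = 52)
  sizes <- sapply(seq(0, 0.05, by = 0.01), function(lam) {
    m <- lasso_select(co, lambda_grid = lam, min_fraction = 0, seed = 53)
    if (m$failed) 0L else length(m$retained)
  })
  expect_true(all(diff(sizes) <= 0))
  # an impossible retention floor reports failure rather than a tiny mask
  strict <- lasso_select(co, lambda_grid = 0.05, min_fraction = 0.99, seed = 54)
  expect_true(strict$failed)
  expect_error(lasso_select(co, lambda_grid = numeric()), "non-empty")
})

test_that("LASSO depletes null sites when the signal is strong", {
  null_share <- replicate(10, NA_real_)
  for (r in 1:10) {
    arch <- sample_architecture(default_counts("additive"), 0.0075,
                                seed = derive_seed(600, r, "arch"))
    co <- simulate_cohort(arch, 1000, 1000, seed = derive_seed(600, r, "cohort"))
    # positive penalties only: the unpenalized grid point trivially keeps all
    # sites, so depletion is a property of the penalized path
    mask <- lasso_select(co, lambda_grid = seq(0.01, 0.05, by = 0.01),
                         seed = derive_seed(600, r, "lasso"))
    if (!mask$failed) {
      null_ids <- arch$sites$site_id[arch$sites$mode == "null"]
      null_share[r] <- mean(mask$retained %in% null_ids)
    }
  }
  null_share <- null_share[!is.na(null_share)]
  expect_gt(length(null_share), 5)
  expect_lt(mean(null_share), 50 / 550)
})

test_that("random forests outperform the neural network at weak recessive signal", {
  aucs <- sapply(1:10, function(r) {
    arch <- sample_architecture(default_counts("recessive"), 0.003,
                                seed = derive_seed(610, r, "arch"))
    tt <- make_train_test(arch, 1000, 1000, master_seed = derive_seed(610, r, "c"))
    sapply(c(RF = "RF", NN = "NN"), function(fam) {
      sc <- fit_predict(fam, tt$train, tt$test, seed = derive_seed(610, r, fam))
      auc_empirical(sc, tt$test$phenotype)$auc
    })
  })
  expect_gt(mean(aucs["RF", ]), mean(aucs["NN", ]))
})

test_that("LASSO feature selection barely moves the AUC", {
  for (dh in c(0.002, 0.005)) {
    diffs <- sapply(1:10, function(r) {
      arch <- sample_architecture(default_counts("additive"), dh,
                                  seed = derive_seed(620, dh, r, "arch"))
      tt <- make_train_test(arch, default_n, default_n,
                            master_seed = derive_seed(620, dh, r, "c"))
      mask <- lasso_select(tt$train, seed = derive_seed(620, dh, r, "l"))
      sc_off <- fit_predict("LR", tt$train, tt$test)
      sc_on <- if (mask$failed) sc_off else fit_predict("LR", tt$train, tt$test, mask = mask)
      auc_empirical(sc_on, tt$test$phenotype)$auc -
        auc_empirical(sc_off, tt$test$phenotype)$auc
    })
    expect_lte(abs(mean(diffs)), 0.01)
  }
})
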