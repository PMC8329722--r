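test_that("confusion rates follow their definitions and FPR + TNR = 1", {
  m <- confusion_metrics(tp = 5, fn = 5, tn = 8, fp = 2)
  expect_equal(m$tpr, 0.5)
  expect_equal(m$tnr, 0.8)
  expect_equal(m$fpr, 0.2)

  b <- confusion_metrics(tp = 1, fn = 0, tn = 0, fp = 10)
  expect_equal(b$tpr, 1)
  expect_equal(b$tnr, 0)
  expect_equal(b$fpr, 1)

  set.seed(2)
  for (i in 1:50) {
    cnt <- as.list(sample(0:30, 4, replace = TRUE) + c(1, 0, 1, 0))
    names(cnt) <- c("tp", "fp", "tn", "fn")
    m <- do.call(confusion_metrics, cnt)
    expect_equal(m$fpr + m$tnr, 1)
  }
  expect_error(confusion_metrics(0, 1, 1, 0), "TPR undefined")
  expect_error(confusion_metrics(1, 0, 0, 1), "TNR/FPR undefined")

  cc <- threshold_confusion(c(.9, .6, .4, .2), c(1, 0, 1, 0), threshold = .5)
  expect_identical(cc, list(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
})

test_that("ROC/AUC equals the exhaustive pairwise statistic, ties at 1/2", {
  expect_equal(roc_and_auc(c(.9, .8, .2, .1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_and_auc(c(.1, .2, .8, .9), c(1, 1, 0, 0))$auc, 0)
  expect_equal(roc_and_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)

  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(10:40, 1)
    scores <- round(runif(n), 1)  # coarse grid forces ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    got <- roc_and_auc(scores, labels)
    expect_equal(got$auc, brute_auc(scores, labels))
    # curve runs monotonically from (0,0) to (1,1)
    expect_equal(got$roc_points$fpr[1], 0)
    expect_equal(got$roc_points$tpr[1], 0)
    expect_equal(tail(got$roc_points$fpr, 1), 1)
    expect_equal(tail(got$roc_points$tpr, 1), 1)
    expect_true(all(diff(got$roc_points$fpr) >= 0))
    expect_true(all(diff(got$roc_points$tpr) >= 0))
  }
  expect_error(roc_and_auc(c(.1, .2), c(1, 1)), "both classes")
})

test_that("ROC/AUC agrees with an independent library implementation", {
  set.seed(99)
  scores <- round(runif(80), 2)
  labels <- rbinom(80, 1, 0.4)
  ours <- roc_and_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref)
})

test_that("cross-validation: report structure, determinism, stratification", {
  sim <- small_sim(seed = 61)
  fm <- build_feature_matrix(sim$annotation, sim$gwas, sim$eqtl)
  labs <- build_label_sets(sim$gene_disease, sim$network, sim$annotation)
  rep1 <- cross_validate(fm, labs, k = 5, seed = 3)
  rep2 <- cross_validate(fm, labs, k = 5, seed = 3)
  expect_identical(rep1$per_fold_auc, rep2$per_fold_auc)
  expect_identical(rep1$fold_assignment, rep2$fold_assignment)
  expect_equal(rep1$average_auc, mean(rep1$per_fold_auc))
  expect_length(rep1$per_fold_auc, 5)
  # each labeled gene appears in exactly one fold, classes split evenly
  expect_length(rep1$fold_assignment,
                length(labs$positives) + length(labs$negatives))
  per_fold_pos <- table(rep1$fold_assignment[labs$positives])
  expect_lte(diff(range(per_fold_pos)), 1)

  expect_error(cross_validate(fm, labs, k = 10000), "smaller k")
  one_class <- setNames(rep(1, length(labs$positives)), labs$positives)
  expect_error(cross_validate(fm, one_class), "both classes")
  expect_error(classifier_spec("boosted_stump"), "available")
})

test_that("per-fold AUC aggregation is the arithmetic mean", {
  rep <- cv_report(c(0.8, 0.9, 1.0))
  expect_equal(rep$average_auc, 0.9)
  expect_error(cv_report(c(0.5, 1.2)))
})

test_that("nested grid search runs on training folds and records the choice", {
  sim <- small_sim(seed = 63, n_genes = 120, n_causal = 40)
  fm <- build_feature_matrix(sim$annotation, sim$gwas, sim$eqtl)
  labs <- build_label_sets(sim$gene_disease, sim$network, sim$annotation)
  grid <- expand.grid(ntree = c(50, 100), mtry = c("sqrt"),
                      stringsAsFactors = FALSE)
  spec <- classifier_spec("random_forest", grid = grid)
  rep <- cross_validate(fm, labs, spec, k = 3, seed = 5, inner_k = 2)
  expect_length(rep$hyperparameters, 3)
  for (h in rep$hyperparameters) {
    expect_true(h$ntree %in% grid$ntree)
  }
  rep_again <- cross_validate(fm, labs, spec, k = 3, seed = 5, inner_k = 2)
  expect_identical(rep$hyperparameters, rep_again$hyperparameters)
})

test_that("classifier comparison pairs fold assignments and ranks by AUC", {
  sim <- small_sim(seed = 65, n_genes = 150, n_causal = 50)
  fm <- build_feature_matrix(sim$annotation, sim$gwas, sim$eqtl)
  labs <- build_label_sets(sim$gene_disease, sim$network, sim$annotation)
  reps <- compare_classifiers(fm, labs,
                              specs = list("random_forest", "naive_bayes",
                                           "svm"),
                              k = 4, seed = 11)
  folds <- lapply(reps, `[[`, "fold_assignment")
  expect_identical(folds[[1]], folds[[2]])
  expect_identical(folds[[2]], folds[[3]])
  aucs <- vapply(reps, `[[`, numeric(1), "average_auc")
  expect_true(all(diff(aucs) <= 0))
  expect_error(compare_classifiers(fm, labs, specs = list("svm")),
               "at least two")

  # duplicated spec under the same seed gives identical reports
  two <- compare_classifiers(fm, labs,
                             specs = list(classifier_spec("naive_bayes"),
                                          classifier_spec("naive_bayes")),
                             k = 4, seed = 11)
  expect_identical(two[[1]]$per_fold_auc, two[[2]]$per_fold_auc)
})

test_that("planted signal beats the permutation null; constant features do not", {
  sim <- small_sim(seed = 67, n_genes = 200, n_causal = 60,
                   causal_beta_a = 0.05, eqtl_signal_prob = 1)
  fm <- build_feature_matrix(sim$annotation, sim$gwas, sim$eqtl)
  labs <- build_label_sets(sim$gene_disease, sim$network, sim$annotation)
  reps <- compare_classifiers(fm, labs,
                              specs = list("random_forest", "svm",
                                           "naive_bayes"),
                              k = 4, seed = 13)
  null_auc <- vapply(1:10, function(s) {
    yp <- permuted_label_vector(labs, s)
    cross_validate(fm, yp, classifier_spec("naive_bayes"), k = 4,
                   seed = s)$average_auc
  }, numeric(1))
  cutoff <- 0.5 + 3 * stats::sd(null_auc)
  for (r in reps) expect_gt(r$average_auc, cutoff)

  fm_const <- fm
  fm_const[paste0("P_p", 1:5)] <- 0.5
  fm_const[paste0("P_T", 1:5)] <- 0.5
  for (nm in c("random_forest", "naive_bayes", "svm")) {
    rep_const <- suppressWarnings(
      cross_validate(fm_const, labs, classifier_spec(nm), k = 4, seed = 17))
    expect_equal(rep_const$average_auc, 0.5)
  }
})

test_that("final model training is reproducible and guards column order", {
  sim <- small_sim(seed = 69, n_genes = 120, n_causal = 40)
  fm <- build_feature_matrix(sim$annotation, sim$gwas, sim$eqtl)
  labs <- build_label_sets(sim$gene_disease, sim$network, sim$annotation)
  m1 <- train_final(fm, labs, seed = 4)
  m2 <- train_final(fm, labs, seed = 4)
  probe <- predict_candidates(m1, fm, labs$candidates)
  probe2 <- predict_candidates(m2, fm, labs$candidates)
  expect_identical(probe, probe2)
  expect_identical(m1$fingerprint, m2$fingerprint)

  fm_perm <- fm[, c("gene_id", paste0("P_T", 1:5), paste0("P_p", 1:5),
                    "n_mapped_snps", "selected_snps")]
  expect_error(predict_candidates(m1, fm_perm, labs$candidates),
               "do not match")

  imp <- feature_importance(m1)
  expect_identical(names(imp), c(paste0("P_p", 1:5), paste0("P_T", 1:5)))
  expect_true(all(imp >= 0))
  expect_error(feature_importance(train_final(fm, labs,
                                              classifier_spec("naive_bayes"),
                                              seed = 4)),
               "random_forest")
})
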