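# Cross-validated classification and evaluation: stratified k-fold CV with
# optional nested grid search, ROC/AUC, confusion metrics, and a paired
# multi-classifier comparison harness.

#' Confusion-matrix rates
#'
#' Sensitivity (TPR), specificity (TNR) and fall-out (FPR) from raw counts:
#' TPR = TP / (TP + FN), TNR = TN / (TN + FP), FPR = FP / (FP + TN) = 1 - TNR.
#'
#' @param tp,fp,tn,fn Non-negative counts at a fixed decision threshold.
#' @return Named list with `tpr`, `tnr`, `fpr`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fn == 0) stop("TPR undefined: no positive instances (TP + FN = 0)")
  if (tn + fp == 0) {
    stop("TNR/FPR undefined: no negative instances (TN + FP = 0)")
  }
  list(tpr = tp / (tp + fn), tnr = tn / (tn + fp), fpr = fp / (fp + tn))
}

#' Confusion counts from scores at a decision threshold
#'
#' @param scores Numeric positive-class scores.
#' @param labels Binary labels (0/1 or logical).
#' @param threshold Scores `>= threshold` are called positive. Default 0.5.
#' @return Named list with `tp`, `fp`, `tn`, `fn`.
#' @export
threshold_confusion <- function(scores, labels, threshold = 0.5) {
  y <- as.integer(as.logical(labels))
  call_pos <- scores >= threshold
  list(tp = sum(call_pos & y == 1), fp = sum(call_pos & y == 0),
       tn = sum(!call_pos & y == 0), fn = sum(!call_pos & y == 1))
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the distinct score values, computing
#' (FPR, TPR) at each, and integrates by the trapezoidal rule — so tied
#' scores contribute 1/2, making the AUC identical to the normalized
#' Mann-Whitney pair-count statistic.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels Binary labels (0/1 or logical); both classes must occur.
#' @return List with `roc_points` (`data.frame`: `threshold`, `fpr`, `tpr`,
#'   from (0,0) to (1,1)) and `auc`.
#' @export
roc_and_auc <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(y), !anyNA(scores), !anyNA(y))
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC undefined: both classes must be present")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- y[o]
  cut <- cumsum(rle(s)$lengths)   # last index of each distinct score
  tpr <- c(0, cumsum(y)[cut] / n_pos)
  fpr <- c(0, cumsum(1 - y)[cut] / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(roc_points = data.frame(threshold = c(Inf, s[cut]),
                               fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Specify a classifier
#'
#' @param name One of `"random_forest"` (randomForest), `"svm"` (e1071,
#'   RBF kernel with Platt-scaled probabilities), `"naive_bayes"` (e1071),
#'   or `"neural_net"` (a small single-hidden-layer feed-forward network via
#'   nnet; the optional deep-learning comparator).
#' @param params Named list overriding the per-classifier defaults
#'   (random_forest: `ntree = 500`, `mtry = "sqrt"`, `nodesize = 1`;
#'   svm: `cost = 1`, `gamma = NULL` (1/p); naive_bayes: `laplace = 0`;
#'   neural_net: `size = 8`, `decay = 0.01`, `maxit = 200`).
#' @param grid Optional `data.frame` of hyperparameter combinations for
#'   nested grid search (see [cross_validate()]); `NULL` disables the search.
#'   [default_grid()] supplies a small documented grid per classifier.
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(name, params = list(), grid = NULL) {
  known <- c("random_forest", "svm", "naive_bayes", "neural_net")
  if (!name %in% known) {
    stop("unknown classifier '", name, "'; available: ",
         paste(known, collapse = ", "))
  }
  defaults <- switch(name,
    random_forest = list(ntree = 500, mtry = "sqrt", nodesize = 1),
    svm = list(cost = 1, gamma = NULL),
    naive_bayes = list(laplace = 0),
    neural_net = list(size = 8, decay = 0.01, maxit = 200))
  defaults[names(params)] <- params
  structure(list(name = name, params = defaults, grid = grid),
            class = "classifier_spec")
}

#' @rdname classifier_spec
#' @export
default_grid <- function(name) {
  switch(name,
    random_forest = expand.grid(ntree = c(100, 300, 500),
                                mtry = c("sqrt", "log2"),
                                stringsAsFactors = FALSE),
    svm = expand.grid(cost = c(0.1, 1, 10), gamma = c(0.01, 0.1)),
    naive_bayes = data.frame(laplace = c(0, 1)),
    neural_net = expand.grid(size = c(4, 8), decay = c(0.001, 0.01)),
    stop("unknown classifier '", name, "'"))
}

resolve_mtry <- function(mtry, p) {
  if (is.numeric(mtry)) return(as.integer(mtry))
  switch(as.character(mtry),
         sqrt = max(1L, floor(sqrt(p))),
         log2 = max(1L, floor(log2(p))),
         stop("mtry must be numeric, 'sqrt' or 'log2'"))
}

fit_classifier <- function(spec, X, y, seed) {
  set.seed(seed)
  yf <- factor(y, levels = c(0, 1))
  p <- spec$params
  # degenerate design: no column varies, so no split exists — fall back to
  # a class-prior model rather than handing randomForest an unsplittable X
  if (spec$name == "random_forest" &&
      all(vapply(X, function(col) length(unique(col)) == 1L, logical(1)))) {
    return(structure(list(prior = mean(y == 1)), class = "prior_fit"))
  }
  switch(spec$name,
    random_forest = randomForest::randomForest(
      x = X, y = yf, ntree = p$ntree,
      mtry = resolve_mtry(p$mtry, ncol(X)), nodesize = p$nodesize),
    svm = {
      args <- list(x = as.matrix(X), y = yf, kernel = "radial",
                   cost = p$cost, probability = TRUE)
      if (!is.null(p$gamma)) args$gamma <- p$gamma
      do.call(e1071::svm, args)
    },
    naive_bayes = e1071::naiveBayes(x = X, y = yf, laplace = p$laplace),
    neural_net = {
      if (!requireNamespace("nnet", quietly = TRUE)) {
        stop("the neural_net classifier requires the 'nnet' package")
      }
      nnet::nnet(x = as.matrix(X), y = as.numeric(y), size = p$size,
                 decay = p$decay, maxit = p$maxit, entropy = TRUE,
                 trace = FALSE)
    })
}

predict_prob <- function(spec, fit, X) {
  if (inherits(fit, "prior_fit")) return(rep(fit$prior, nrow(X)))
  switch(spec$name,
    random_forest = unname(predict(fit, X, type = "prob")[, "1"]),
    svm = {
      pr <- predict(fit, as.matrix(X), probability = TRUE)
      unname(attr(pr, "probabilities")[, "1"])
    },
    naive_bayes = unname(predict(fit, X, type = "raw")[, "1"]),
    neural_net = as.numeric(predict(fit, as.matrix(X))))
}

# Align a feature matrix and label sets into (X, y, gene_id) for training.
training_frame <- function(features, labels) {
  if (inherits(labels, "label_sets")) {
    lab <- setNames(
      rep(c(1, 0), c(length(labels$positives), length(labels$negatives))),
      c(labels$positives, labels$negatives))
  } else if (is.data.frame(labels)) {
    keep <- labels$label %in% c("positive", "negative")
    lab <- setNames(as.integer(labels$label[keep] == "positive"),
                    labels$gene_id[keep])
  } else {
    lab <- labels  # named 0/1 vector
  }
  idx <- which(features$gene_id %in% names(lab))
  X <- features[idx, feature_cols(), drop = FALSE]
  rownames(X) <- NULL
  list(X = X, y = unname(lab[features$gene_id[idx]]),
       gene_id = features$gene_id[idx])
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k) {
      stop(sprintf(
        "class %s has %d members, fewer than k = %d folds; use a smaller k",
        cls, length(idx), k))
    }
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# Pick the best grid row by inner stratified CV on the training data only.
grid_search <- function(spec, X, y, grid, inner_k, seed) {
  mean_auc <- vapply(seq_len(nrow(grid)), function(j) {
    sp <- classifier_spec(spec$name,
                          params = utils::modifyList(spec$params,
                                                     as.list(grid[j, , drop = FALSE])))
    folds <- stratified_folds(y, inner_k, sub_seed(seed, j))
    aucs <- vapply(seq_len(inner_k), function(f) {
      tr <- folds != f
      fit <- fit_classifier(sp, X[tr, , drop = FALSE], y[tr],
                            sub_seed(seed, 100 * j + f))
      roc_and_auc(predict_prob(sp, fit, X[!tr, , drop = FALSE]), y[!tr])$auc
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  as.list(grid[which.max(mean_auc), , drop = FALSE])
}

new_cv_report <- function(classifier, per_fold_auc, roc, hyperparameters,
                          fold_assignment, seed, n) {
  structure(list(classifier = classifier,
                 per_fold_auc = per_fold_auc,
                 average_auc = mean(per_fold_auc),
                 roc_points = roc,
                 hyperparameters = hyperparameters,
                 fold_assignment = fold_assignment,
                 seed = seed, n = n),
            class = "cv_report")
}

#' Aggregate per-fold AUC values into a CV report
#'
#' The aggregation used by [cross_validate()]: the average AUC is the
#' arithmetic mean of the per-fold AUCs.
#'
#' @param per_fold_auc Numeric vector of per-fold AUCs, each in \[0, 1\].
#' @param classifier Classifier name for the report.
#' @return A `cv_report` object (without ROC points or fold assignment).
#' @export
cv_report <- function(per_fold_auc, classifier = "external") {
  stopifnot(length(per_fold_auc) >= 1,
            all(per_fold_auc >= 0), all(per_fold_auc <= 1))
  new_cv_report(classifier, per_fold_auc, roc = NULL, hyperparameters = NULL,
                fold_assignment = NULL, seed = NA_integer_,
                n = length(per_fold_auc))
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %s, %d folds, average AUC %.3f\n",
              x$classifier, length(x$per_fold_auc), x$average_auc))
  cat("  per-fold AUC:", paste(sprintf("%.3f", x$per_fold_auc),
                               collapse = " "), "\n")
  invisible(x)
}

cross_validate_core <- function(X, y, gene_id, spec, folds, k, seed,
                                inner_k) {
  oof <- numeric(length(y))
  per_fold <- numeric(k)
  chosen <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    sp <- spec
    if (!is.null(spec$grid)) {
      best <- grid_search(spec, X[tr, , drop = FALSE], y[tr], spec$grid,
                          inner_k, sub_seed(seed, 1000 + f))
      sp <- classifier_spec(spec$name,
                            params = utils::modifyList(spec$params, best))
      chosen[[f]] <- best
    } else {
      chosen[[f]] <- spec$params
    }
    fit <- fit_classifier(sp, X[tr, , drop = FALSE], y[tr],
                          sub_seed(seed, 10 + f))
    scores <- predict_prob(sp, fit, X[!tr, , drop = FALSE])
    oof[!tr] <- scores
    per_fold[f] <- roc_and_auc(scores, y[!tr])$auc
  }
  new_cv_report(spec$name, per_fold,
                roc = roc_and_auc(oof, y)$roc_points,
                hyperparameters = chosen,
                fold_assignment = setNames(folds, gene_id),
                seed = seed, n = length(y))
}

#' Stratified k-fold cross-validation of a gene classifier
#'
#' Genes in the positive and negative label sets are split into k
#' class-stratified folds; each fold is held out once, the classifier is
#' fitted on the rest, and the held-out AUC is recorded. The report's
#' average AUC is the mean over folds; pooled out-of-fold scores give the
#' ROC points. When the spec carries a hyperparameter `grid`, each outer
#' training fold runs an inner `inner_k`-fold stratified CV over the grid
#' (training data only — no leakage into the held-out fold) and refits with
#' the best combination.
#'
#' @param features Feature matrix from [build_feature_matrix()].
#' @param labels A `label_sets` object, a `data.frame` (`gene_id`, `label`),
#'   or a named 0/1 vector.
#' @param spec A [classifier_spec()]. Default: random forest.
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling folds and every stochastic fit.
#' @param inner_k Inner folds for grid search (default 3).
#' @return A `cv_report`.
#' @export
cross_validate <- function(features, labels,
                           spec = classifier_spec("random_forest"),
                           k = 10, seed = 1, inner_k = 3) {
  tf <- training_frame(features, labels)
  if (length(unique(tf$y)) < 2) {
    stop("both classes must be present in the training labels")
  }
  folds <- stratified_folds(tf$y, k, sub_seed(seed, 1))
  cross_validate_core(tf$X, tf$y, tf$gene_id, spec, folds, k, seed, inner_k)
}

#' Compare classifiers under identical fold assignments
#'
#' Runs [cross_validate()] for each spec with one shared stratified fold
#' partition, so per-fold AUCs are paired across classifiers. Reports are
#' sorted by average AUC, best first; the pooled ROC points in each report
#' can be overlaid for a comparison figure.
#'
#' @inheritParams cross_validate
#' @param specs List of [classifier_spec()] objects or classifier names;
#'   at least two.
#' @return A named list of `cv_report`s sorted by decreasing average AUC.
#' @export
compare_classifiers <- function(features, labels,
                                specs = list("random_forest", "svm",
                                             "naive_bayes"),
                                k = 10, seed = 1, inner_k = 3) {
  if (length(specs) < 2) stop("need at least two classifier specs to compare")
  specs <- lapply(specs, function(s) {
    if (is.character(s)) classifier_spec(s) else s
  })
  tf <- training_frame(features, labels)
  folds <- stratified_folds(tf$y, k, sub_seed(seed, 1))
  reports <- lapply(specs, function(sp) {
    cross_validate_core(tf$X, tf$y, tf$gene_id, sp, folds, k, seed, inner_k)
  })
  names(reports) <- vapply(specs, `[[`, character(1), "name")
  reports[order(-vapply(reports, `[[`, numeric(1), "average_auc"))]
}

#' Train the final classifier on all labeled genes
#'
#' @inheritParams cross_validate
#' @return A `gene_classifier`: the fitted model plus its spec, feature
#'   column order, seed, class counts, and a training-set fingerprint, so
#'   downstream predictions are auditable and column order is enforced.
#' @export
train_final <- function(features, labels,
                        spec = classifier_spec("random_forest"), seed = 1) {
  tf <- training_frame(features, labels)
  if (length(unique(tf$y)) < 2) {
    stop("both classes must be present in the training labels")
  }
  fit <- fit_classifier(spec, tf$X, tf$y, sub_seed(seed, 7))
  structure(list(fit = fit, spec = spec, feature_cols = colnames(tf$X),
                 seed = seed,
                 class_counts = c(positive = sum(tf$y == 1),
                                  negative = sum(tf$y == 0)),
                 fingerprint = list(n = nrow(tf$X),
                                    feature_sum = round(sum(tf$X), 6))),
            class = "gene_classifier")
}

#' @export
print.gene_classifier <- function(x, ...) {
  cat(sprintf("gene_classifier: %s trained on %d genes (%d+/%d-), seed %d\n",
              x$spec$name, x$fingerprint$n, x$class_counts["positive"],
              x$class_counts["negative"], x$seed))
  invisible(x)
}

#' Impurity-based feature importance of a trained forest
#'
#' Raw mean-decrease-in-Gini scores from the fitted random forest; no
#' adjustment or interpretation beyond the forest's own accounting.
#'
#' @param model A `gene_classifier` with a random-forest fit.
#' @return Named numeric vector, one value per feature column.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "gene_classifier"))
  if (model$spec$name != "random_forest" ||
      inherits(model$fit, "prior_fit")) {
    stop("impurity importance is only available for random_forest models")
  }
  imp <- randomForest::importance(model$fit)
  setNames(imp[, 1], rownames(imp))
}
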