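classifier_families <- c("naive_bayes", "nu_svm", "neural_net",
                         "decision_tree", "random_forest")

#' Classifier specification
#'
#' The five classifier families evaluated by the pipeline, with their
#' published hyperparameters as defaults: Gaussian naive Bayes; nu-SVM with
#' RBF kernel (`gamma = 0.14`, `nu = 0.5`); a deep neural network with
#' hidden layers (30, 30, 30, 10), ReLU activation, Adam solver and L2
#' regularization 1e-4; an unrestricted decision tree; and a random forest
#' of 100 trees.
#'
#' @param family one of `"naive_bayes"`, `"nu_svm"`, `"neural_net"`,
#'   `"decision_tree"`, `"random_forest"`.
#' @param ... family-specific hyperparameter overrides (`gamma`, `nu`,
#'   `svr_mode` for the SVM; `hidden`, `l2`, `epochs`, `lr` for the neural
#'   net; `ntree` for the forest).
#' @param seed integer seed for stochastic learners.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = classifier_families, ..., seed = 1L) {
  family <- match.arg(family)
  defaults <- switch(family,
    naive_bayes = list(),
    nu_svm = list(gamma = 0.14, nu = 0.5, svr_mode = FALSE),
    neural_net = list(hidden = c(30L, 30L, 30L, 10L), l2 = 1e-4,
                      epochs = 500L, lr = 1e-3),
    decision_tree = list(),
    random_forest = list(ntree = 100L))
  hp <- utils::modifyList(defaults, list(...))
  if (family == "nu_svm") {
    if (hp$gamma <= 0) stop("`gamma` must be positive")
    if (hp$nu <= 0 || hp$nu > 1) stop("`nu` must be in (0, 1]")
  }
  if (family == "random_forest" && hp$ntree < 1)
    stop("`ntree` must be >= 1")
  if (family == "neural_net" && any(hp$hidden < 1))
    stop("hidden layer sizes must be positive")
  structure(list(family = family, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- paste(names(x$hyperparameters),
              vapply(x$hyperparameters, function(v)
                paste(format(v), collapse = ","), character(1)),
              sep = "=", collapse = ", ")
  cat(sprintf("<classifier_spec %s%s>\n", x$family,
              if (nzchar(hp)) paste0(" (", hp, ")") else ""))
  invisible(x)
}

# Fit one classifier on a numeric matrix X and 0/1 labels y.
fit_classifier <- function(spec, X, y, seed) {
  yf <- factor(y, levels = c(0L, 1L))
  hp <- spec$hyperparameters
  model <- switch(spec$family,
    naive_bayes = e1071::naiveBayes(as.data.frame(X), yf),
    nu_svm = if (isTRUE(hp$svr_mode)) {
      e1071::svm(X, as.numeric(y), type = "nu-regression", kernel = "radial",
                 gamma = hp$gamma, nu = hp$nu, scale = FALSE)
    } else {
      e1071::svm(X, yf, type = "nu-classification", kernel = "radial",
                 gamma = hp$gamma, nu = hp$nu, scale = FALSE)
    },
    neural_net = mlp_fit(X, y, hidden = hp$hidden, l2 = hp$l2,
                         epochs = hp$epochs, lr = hp$lr, seed = seed),
    decision_tree = {
      df <- as.data.frame(X)
      df$.y <- yf
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(minsplit = 2L,
                                                  minbucket = 1L, cp = 0,
                                                  maxdepth = 30L, xval = 0L))
    },
    random_forest = with_seed(seed,
      randomForest::randomForest(X, yf, ntree = hp$ntree)))
  list(spec = spec, model = model)
}

# Predict 0/1 labels and a continuous positive-class score.
predict_classifier <- function(fit, X) {
  spec <- fit$spec; model <- fit$model
  switch(spec$family,
    naive_bayes = {
      p <- predict(model, as.data.frame(X), type = "raw")[, "1"]
      list(label = as.integer(p >= 0.5), score = p)
    },
    nu_svm = if (isTRUE(spec$hyperparameters$svr_mode)) {
      s <- as.numeric(predict(model, X))
      list(label = as.integer(s >= 0.5), score = s)
    } else {
      pr <- predict(model, X, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # decision value is signed towards the first class of the colname pair
      first <- strsplit(colnames(dv)[1], "/")[[1]][1]
      s <- if (identical(first, "1")) dv[, 1] else -dv[, 1]
      list(label = as.integer(as.character(pr)), score = as.numeric(s))
    },
    neural_net = {
      p <- mlp_predict(model, X)
      list(label = as.integer(p >= 0.5), score = p)
    },
    decision_tree = {
      p <- predict(model, as.data.frame(X), type = "prob")[, "1"]
      list(label = as.integer(p >= 0.5), score = p)
    },
    random_forest = {
      p <- predict(model, X, type = "prob")[, "1"]
      list(label = as.integer(p >= 0.5), score = p)
    })
}

#' Stratified fold assignment
#'
#' Partitions samples into `k` folds preserving the class balance: every
#' fold's positive count is within one of its proportional share, and fold
#' sizes differ by at most one. Deterministic for a fixed seed.
#'
#' @param labels binary (0/1) label vector.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return Integer vector of fold ids (1..k), one per sample.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  labels <- as.integer(labels)
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be >= 2")
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (any(counts < k))
    stop("each class needs at least k = ", k, " members; class sizes: ",
         paste(counts, collapse = ", "))
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in c(1L, 0L)) {
      idx <- sample(which(labels == cls))
      n_c <- length(idx)
      sizes <- rep(n_c %/% k, k)
      r <- n_c %% k
      if (r > 0) {
        # positives take extras from the first folds, negatives from the
        # last, keeping total fold sizes within one of n/k
        extras <- if (cls == 1L) seq_len(r) else k - seq_len(r) + 1L
        sizes[extras] <- sizes[extras] + 1L
      }
      fold[idx] <- rep(seq_len(k), sizes)
    }
  })
  fold
}

cv_metric_names <- c("sensitivity", "specificity", "precision", "accuracy",
                     "f1", "auc", "fpr", "fnr")

#' Cross-validated evaluation of one classifier
#'
#' Stratified k-fold cross-validation over the cohort feature table. By
#' default the standardize+PCA reduction is fitted inside each training
#' fold and applied to the held-out fold, so no preprocessing statistics
#' leak across the split; `pca_global = TRUE` instead fits the reduction
#' once on the full table (the optimistic whole-dataset variant).
#'
#' @param table feature table from [extract_feature_table()].
#' @param spec a [classifier_spec()].
#' @param k number of folds (default 10).
#' @param seed integer seed controlling fold assignment and stochastic
#'   learners.
#' @param threshold PCA cumulative-variance threshold (default 0.99).
#' @param pca_global fit the reduction on the full table instead of per
#'   fold.
#' @return An object of class `cv_result` with `per_fold` (data frame of
#'   per-fold metrics), `averaged` (their arithmetic mean), `folds`, `spec`,
#'   `seed`, and provenance flags.
#' @export
cross_validate <- function(table, spec, k = 10L, seed = 1L,
                           threshold = 0.99, pca_global = FALSE) {
  stopifnot(inherits(spec, "classifier_spec"))
  labels <- as.integer(table$label)
  folds <- stratified_folds(labels, k, seed)
  global_model <- if (pca_global) fit_reduction(table, threshold) else NULL

  per_fold <- vector("list", k)
  for (i in seq_len(k)) {
    train <- table[folds != i, , drop = FALSE]
    test <- table[folds == i, , drop = FALSE]
    if (length(unique(train$label)) < 2L)
      stop("degenerate fold ", i, ": training set has a single class")
    rm_ <- if (pca_global) global_model
           else suppressWarnings(fit_reduction(train, threshold))
    red_train <- apply_reduction(rm_, train)
    red_test <- apply_reduction(rm_, test)
    xcols <- setdiff(names(red_train), c("sample_id", "label"))
    Xtr <- as.matrix(red_train[, xcols, drop = FALSE])
    Xte <- as.matrix(red_test[, xcols, drop = FALSE])
    fit <- fit_classifier(spec, Xtr, red_train$label,
                          seed = derive_seed(spec$seed, seed * 100L + i))
    pred <- predict_classifier(fit, Xte)
    ytrue <- red_test$label
    ms <- metrics_from_confusion(
      tp = sum(pred$label == 1L & ytrue == 1L),
      fp = sum(pred$label == 1L & ytrue == 0L),
      fn = sum(pred$label == 0L & ytrue == 1L),
      tn = sum(pred$label == 0L & ytrue == 0L))
    ms$auc <- if (length(unique(ytrue)) < 2L) {
      warning("fold ", i, ": single-class test set, AUC recorded as 0")
      0
    } else auc_score(pred$score, ytrue)
    per_fold[[i]] <- data.frame(fold = i, as.data.frame(ms[cv_metric_names]))
  }
  per_fold <- do.call(rbind, per_fold)
  averaged <- colMeans(per_fold[, cv_metric_names, drop = FALSE])
  structure(
    list(spec = spec,
         per_fold = per_fold,
         averaged = averaged,
         folds = folds,
         k = as.integer(k),
         seed = as.integer(seed),
         pca_global = isTRUE(pca_global),
         permuted = FALSE),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result %s%s: %d-fold, F1 = %.3f, AUC = %.3f>\n",
              x$spec$family, if (x$permuted) " [permuted labels]" else "",
              x$k, x$averaged[["f1"]], x$averaged[["auc"]]))
  invisible(x)
}

#' Label-permutation over-fitting control
#'
#' Permutes the outcome labels uniformly at random (preserving the class
#' balance) and reruns the full cross-validated evaluation. A pipeline free
#' of leakage and over-fitting artifacts scores at chance level on the
#' permuted cohort.
#'
#' @inheritParams cross_validate
#' @param permutation_seed seed for the label permutation (defaults to
#'   `seed`).
#' @return A `cv_result` with `permuted = TRUE`.
#' @export
permutation_control <- function(table, spec, k = 10L, seed = 1L,
                                threshold = 0.99, pca_global = FALSE,
                                permutation_seed = seed) {
  perm <- with_seed(permutation_seed, sample(nrow(table)))
  table$label <- table$label[perm]
  res <- cross_validate(table, spec, k = k, seed = seed,
                        threshold = threshold, pca_global = pca_global)
  res$permuted <- TRUE
  res$permutation_seed <- as.integer(permutation_seed)
  res
}

#' Select the best cross-validation result
#'
#' Picks the result with the highest fold-averaged F1; ties are broken by
#' higher fold-averaged AUC, then by alphabetical classifier family name.
#'
#' @param results non-empty list of `cv_result` objects.
#' @return The winning `cv_result`.
#' @export
select_best <- function(results) {
  if (!length(results)) stop("`results` must be a non-empty list")
  f1 <- vapply(results, function(r) r$averaged[["f1"]], numeric(1))
  auc <- vapply(results, function(r) r$averaged[["auc"]], numeric(1))
  fam <- vapply(results, function(r) r$spec$family, character(1))
  results[[order(-f1, -auc, fam)[1]]]
}
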