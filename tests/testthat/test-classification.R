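test_that("stratified folds preserve class balance within one", {
  # exact divisibility: 100 samples, 50 positive, k = 10
  labels <- rep(c(0L, 1L), 50)
  f <- stratified_folds(labels, 10, seed = 1)
  for (i in 1:10) {
    expect_equal(sum(labels[f == i] == 1L), 5L)
    expect_equal(sum(labels[f == i] == 0L), 5L)
  }

  # the 134-sample, 71-positive cohort: per-fold positives in {7, 8}
  labels <- c(rep(1L, 71), rep(0L, 63))
  f <- stratified_folds(labels, 10, seed = 2)
  pos <- vapply(1:10, function(i) sum(labels[f == i] == 1L), integer(1))
  sizes <- vapply(1:10, function(i) sum(f == i), integer(1))
  expect_true(all(pos %in% c(7L, 8L)))
  expect_equal(sum(pos), 71L)
  expect_true(max(sizes) - min(sizes) <= 1L)
  expect_true(all(abs(sizes - 13.4) <= 1))
  # exact partition
  expect_equal(sort(unlist(lapply(1:10, function(i) which(f == i)))),
               seq_along(labels))

  # determinism
  expect_identical(f, stratified_folds(labels, 10, seed = 2))
  expect_false(identical(f, stratified_folds(labels, 10, seed = 3)))

  expect_error(stratified_folds(c(rep(1L, 5), rep(0L, 50)), 10), "at least")
})

test_that("stratification stays within one of the proportional share", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(30:200, 1)
    npos <- sample(12:(n - 12), 1)
    k <- sample(2:10, 1)
    if (min(npos, n - npos) < k) next
    labels <- sample(c(rep(1L, npos), rep(0L, n - npos)))
    f <- stratified_folds(labels, k, seed = rep)
    pos <- vapply(1:k, function(i) sum(labels[f == i] == 1L), integer(1))
    sizes <- vapply(1:k, function(i) sum(f == i), integer(1))
    expect_true(all(abs(pos - npos / k) <= 1))
    expect_true(all(abs(sizes - n / k) <= 1))
  }
})

test_that("a perfectly separable table is solved by the decision tree", {
  tab <- toy_feature_table(60, sep = 8, seed = 6)
  res <- cross_validate(tab, classifier_spec("decision_tree"), k = 5,
                        seed = 1)
  expect_equal(res$averaged[["f1"]], 1.0)
  expect_equal(res$averaged[["accuracy"]], 1.0)
})

test_that("all five classifier families run and recover strong signal", {
  tab <- toy_feature_table(80, sep = 4, seed = 10)
  for (fam in c("naive_bayes", "nu_svm", "neural_net", "decision_tree",
                "random_forest")) {
    res <- cross_validate(tab, classifier_spec(fam), k = 5, seed = 2)
    expect_s3_class(res, "cv_result")
    expect_equal(nrow(res$per_fold), 5L)
    expect_gt(res$averaged[["auc"]], 0.9)
  }
})

test_that("no-signal tables score at chance", {
  tab <- toy_feature_table(100, sep = 0, seed = 12)
  res <- cross_validate(tab, classifier_spec("random_forest"), k = 10,
                        seed = 3)
  expect_gt(res$averaged[["auc"]], 0.35)
  expect_lt(res$averaged[["auc"]], 0.65)
})

test_that("cross-validation is deterministic given seeds", {
  tab <- toy_feature_table(60, sep = 1, seed = 20)
  r1 <- cross_validate(tab, classifier_spec("random_forest"), k = 5, seed = 7)
  r2 <- cross_validate(tab, classifier_spec("random_forest"), k = 5, seed = 7)
  expect_identical(r1$per_fold, r2$per_fold)
  r3 <- cross_validate(tab, classifier_spec("neural_net"), k = 5, seed = 7)
  r4 <- cross_validate(tab, classifier_spec("neural_net"), k = 5, seed = 7)
  expect_identical(r3$per_fold, r4$per_fold)
})

test_that("pca_global reuses one reduction for all folds", {
  tab <- toy_feature_table(60, sep = 1, seed = 22)
  rg <- cross_validate(tab, classifier_spec("naive_bayes"), k = 5, seed = 1,
                       pca_global = TRUE)
  rl <- cross_validate(tab, classifier_spec("naive_bayes"), k = 5, seed = 1)
  expect_true(rg$pca_global)
  expect_false(rl$pca_global)
  expect_s3_class(rg, "cv_result")
})

test_that("permutation control preserves the label multiset and kills signal", {
  tab <- toy_feature_table(80, sep = 4, seed = 30)
  res <- permutation_control(tab, classifier_spec("decision_tree"), k = 5,
                             seed = 2, permutation_seed = 11)
  expect_true(res$permuted)
  expect_equal(res$permutation_seed, 11L)

  # paired comparison over seeds: permuted AUC well below unpermuted
  unperm <- cross_validate(tab, classifier_spec("random_forest"), k = 5,
                           seed = 2)
  perm_auc <- vapply(1:5, function(ps)
    permutation_control(tab, classifier_spec("random_forest"), k = 5,
                        seed = 2, permutation_seed = ps)$averaged[["auc"]],
    numeric(1))
  expect_true(all(unperm$averaged[["auc"]] - perm_auc > 0.2))
})

test_that("select_best maximizes F1 with AUC then family-name tie-breaks", {
  mk <- function(fam, f1, auc) {
    structure(list(spec = classifier_spec(fam),
                   averaged = c(f1 = f1, auc = auc)),
              class = "cv_result")
  }
  got <- select_best(list(mk("naive_bayes", 0.71, 0.70),
                          mk("nu_svm", 0.74, 0.77),
                          mk("decision_tree", 0.60, 0.58)))
  expect_equal(got$spec$family, "nu_svm")
  one <- mk("random_forest", 0.5, 0.5)
  expect_identical(select_best(list(one)), one)
  tie <- select_best(list(mk("nu_svm", 0.7, 0.75),
                          mk("random_forest", 0.7, 0.77)))
  expect_equal(tie$spec$family, "random_forest")
  alpha <- select_best(list(mk("nu_svm", 0.7, 0.75),
                            mk("decision_tree", 0.7, 0.75)))
  expect_equal(alpha$spec$family, "decision_tree")
  expect_error(select_best(list()), "non-empty")
})

test_that("classifier specs validate their hyperparameters", {
  expect_error(classifier_spec("nu_svm", gamma = -1), "gamma")
  expect_error(classifier_spec("nu_svm", nu = 1.5), "nu")
  expect_error(classifier_spec("random_forest", ntree = 0), "ntree")
  expect_error(classifier_spec("neural_net", hidden = c(30, 0)), "positive")
  sp <- classifier_spec("nu_svm")
  expect_equal(sp$hyperparameters$gamma, 0.14)
  expect_equal(sp$hyperparameters$nu, 0.5)
  nn <- classifier_spec("neural_net")
  expect_equal(nn$hyperparameters$hidden, c(30L, 30L, 30L, 10L))
  expect_equal(nn$hyperparameters$l2, 1e-4)
  expect_equal(classifier_spec("random_forest")$hyperparameters$ntree, 100L)
})
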