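test_that("precision and recall follow their defining ratios", {
  counts <- list(TP = 90, FP = 10, FN = 10, TN = 0)
  pr <- precision_recall(counts)
  expect_equal(unname(pr), c(0.9, 0.9))
  perfect <- list(TP = 50, FP = 0, FN = 0, TN = 50)
  expect_equal(unname(precision_recall(perfect)), c(1, 1))
  expect_error(precision_recall(list(TP = 0, FP = 0, FN = 5, TN = 5)),
               "precision")
  expect_error(precision_recall(list(TP = 0, FP = 5, FN = 0, TN = 5)),
               "recall")
})

test_that("the macro-averaged F-score matches hand arithmetic", {
  # perfect classifier: each class term is 1/2
  perfect_lp <- list(TP = 40, FP = 0, FN = 0, TN = 40)
  perfect_nlp <- list(TP = 40, FP = 0, FN = 0, TN = 40)
  expect_equal(f_avg(perfect_lp, perfect_nlp), 1)
  # P = R = 0.9 for both classes: 0.45 + 0.45
  c9 <- list(TP = 90, FP = 10, FN = 10, TN = 890)
  expect_equal(f_avg(c9, c9), 0.9)
  # one class perfect, the other P = R = 0.5: 0.5 + 0.25
  half <- list(TP = 50, FP = 50, FN = 50, TN = 50)
  expect_equal(f_avg(perfect_lp, half), 0.75)
})

test_that("f_avg is symmetric under swapping the class labels", {
  set.seed(8)
  for (i in 1:25) {
    pred <- sample(c("LP", "NLP"), 60, replace = TRUE)
    truth <- sample(c("LP", "NLP"), 60, replace = TRUE)
    c_lp <- confusion_counts(pred, truth, "LP")
    c_nlp <- confusion_counts(pred, truth, "NLP")
    ok <- c_lp$TP + c_lp$FP > 0 && c_lp$TP + c_lp$FN > 0 &&
      c_nlp$TP + c_nlp$FP > 0 && c_nlp$TP + c_nlp$FN > 0
    if (!ok) next
    expect_equal(f_avg(c_lp, c_nlp), f_avg(c_nlp, c_lp))
    expect_equal(c_lp$TP + c_lp$FP + c_lp$FN + c_lp$TN, 60)
  }
})

test_that("ROC/AUC handles the canonical cases", {
  sep <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sep$auc, 1)
  set.seed(9)
  null <- roc_auc(runif(4000), sample(c(TRUE, FALSE), 4000, replace = TRUE))
  expect_lt(abs(null$auc - 0.5), 0.05)
  # four scores: AUC = concordant pairs / 4
  ex <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(ex$auc, 3 / 4)
  expect_error(roc_auc(c(0.1, 0.9), c(TRUE, TRUE)), "both classes")
})

test_that("sweep AUC equals pairwise concordance, including ties", {
  set.seed(10)
  for (i in 1:60) {
    n <- sample(5:40, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    labels <- runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels)$auc,
                 auc_concordance(scores, labels), tolerance = 1e-12)
  }
})

test_that("sweep AUC agrees with an independent ROC implementation", {
  set.seed(12)
  scores <- c(rnorm(60, 0.6, 0.2), rnorm(60, 0.4, 0.2))
  labels <- rep(c(TRUE, FALSE), each = 60)
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                         quiet = TRUE))))
  expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-10)
})

test_that("classification reports assemble all patch metrics", {
  truth <- factor(rep(c("LP", "NLP"), each = 50), levels = c("NLP", "LP"))
  prob <- c(runif(50, 0.6, 1), runif(50, 0, 0.4))
  rep <- classification_report(prob, truth)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$f_avg, 1)
  expect_equal(rep$auc, 1)
  expect_equal(rep$confusion_lp$TP, 50)
})

test_that("cross-validation folds are stratified, sized and seeded", {
  y <- factor(rep(c("LP", "NLP"), each = 400), levels = c("NLP", "LP"))
  f1 <- lungseg:::stratified_folds(y, 8, seed = 1)
  expect_equal(as.vector(table(f1)), rep(100L, 8))       # 800/8 per fold
  per_class <- table(f1, y)
  expect_true(all(per_class == 50L))                     # stratification
  expect_identical(f1, lungseg:::stratified_folds(y, 8, seed = 1))
  expect_false(identical(f1, lungseg:::stratified_folds(y, 8, seed = 2)))
})

test_that("cross-validation of a separable dataset is near-perfect", {
  d <- separable_patchset(120, seed = 13)
  cv <- cross_validate(d$x, d$y, cnn_config(epochs = 4, batch_size = 32),
                       n_folds = 4, seed = 1)
  expect_length(cv$folds, 4)
  expect_gte(cv$mean[["f_avg"]], 0.99)
  expect_gte(cv$mean[["auc"]], 0.99)
  expect_error(cross_validate(d$x, d$y, n_folds = 1000), "n_folds")
})

test_that("the one-at-a-time sweep varies exactly one parameter per row", {
  d <- separable_patchset(60, seed = 14)
  tab <- cnn_param_sweep(d$x, d$y,
                         base_config = cnn_config(epochs = 2, batch_size = 32),
                         variations = list(learning_rate = c(0.005),
                                           pooling = "avg"),
                         seed = 1)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$parameter, c("base", "learning_rate", "pooling"))
  expect_true(all(tab$f_avg >= 0 & tab$f_avg <= 1))
})
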