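# Confusion matrices, one-vs-rest metrics, ROC/AUC, k-fold aggregation.

test_that("confusion matrix accumulates counts against a brute tally", {
  expect_equal(confusion_matrix(1:3, 1:3, 3), diag(3), ignore_attr = TRUE)
  cm <- confusion_matrix(c(1, 1, 2, 3), rep(1, 4), 3)
  expect_identical(cm[, 1], c(2L, 1L, 1L))
  expect_identical(sum(cm), 4L)
  set.seed(1)
  truth <- sample(1:3, 30, replace = TRUE)
  pred <- sample(1:3, 30, replace = TRUE)
  cm <- confusion_matrix(truth, pred, 3)
  for (i in 1:3) for (j in 1:3)
    expect_identical(cm[i, j], sum(truth == i & pred == j))
  rn <- confusion_matrix(truth, pred, 3, normalize = "row")
  expect_equal(rowSums(rn), rep(1, 3))
  expect_error(confusion_matrix(1:3, 1:2, 3), "length")
})

test_that("per-class metrics follow the published binary formulas", {
  # TP=8 FP=2 FN=1 TN=89
  cm <- matrix(0L, 2, 2)
  cm[1, 1] <- 8L; cm[2, 1] <- 2L; cm[1, 2] <- 1L; cm[2, 2] <- 89L
  m <- class_metrics(cm, 1)
  expect_equal(m$precision, 0.8)
  expect_equal(m$sensitivity, 8 / 9)
  expect_equal(m$specificity, 89 / 91)
  expect_equal(m$f_score, 16 / 19)
  expect_equal(m$accuracy, 0.97)
  # integer identity
  expect_identical(m$sensitivity * (m$TP + m$FN), 8)

  perfect <- diag(3) * 5L
  p <- class_metrics(perfect, 2)
  expect_true(all(unlist(p[c("precision", "sensitivity", "specificity",
                             "f_score", "accuracy")]) == 1))

  # absent class: sensitivity 0-flagged, specificity 1
  cm0 <- matrix(0L, 3, 3)
  cm0[1, 1] <- 4L; cm0[2, 2] <- 6L
  d <- class_metrics(cm0, 3)
  expect_identical(d$sensitivity, 0)
  expect_identical(d$specificity, 1)
  expect_true("sensitivity" %in% d$degenerate)
})

test_that("ROC/AUC matches the rank-statistic oracle and closed forms", {
  # one-hot probabilities: AUC 1
  truth <- c(1, 1, 2, 2)
  probs <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  expect_equal(roc_auc(truth, probs, 1)$auc, 1)
  # uninformative constant probabilities: AUC 0.5
  flat <- matrix(0.5, 4, 2)
  expect_equal(roc_auc(truth, flat, 1)$auc, 0.5)
  # single-class truth is flagged undefined
  expect_true(roc_auc(rep(1, 4), probs, 1)$undefined)
  # monotone staircase from (0,0) to (1,1)
  set.seed(2)
  truth <- sample(1:2, 20, replace = TRUE)
  score <- runif(20)
  probs <- cbind(score, 1 - score)
  rc <- roc_auc(truth, probs, 1)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
  expect_equal(c(rc$fpr[1], rc$tpr[1]), c(0, 0))
  expect_equal(c(utils::tail(rc$fpr, 1), utils::tail(rc$tpr, 1)), c(1, 1))
  # rank oracle equivalence on random instances (with ties)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    truth <- sample(1:3, n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    score <- round(runif(n), 2)   # ties likely
    probs <- cbind(score, (1 - score) / 2, (1 - score) / 2)
    a <- roc_auc(truth, probs, 1)$auc
    o <- auc_rank_oracle(truth, score, 1)
    if (!is.na(o)) expect_equal(a, o, tolerance = 1e-12)
  }
})

test_that("cross-validation aggregates per-fold reports", {
  # tiny but real: 3 classes x 15 sources, 16x16 patches, 2-epoch folds
  set.seed(5)
  patches <- replicate(45, matrix(runif(256) * 255, 16, 16),
                       simplify = FALSE)
  labels <- rep(c("Dic", "El", "Ech"), each = 15)
  # inject a strong class signal so training is not vacuous
  for (i in 1:45) {
    k <- match(labels[i], c("Dic", "El", "Ech"))
    patches[[i]][(k * 4 - 3):(k * 4), ] <- 255
  }
  ds <- assemble_dataset(patches, labels, "refined8", augment = FALSE)
  ds$y <- match(labels, c("Dic", "El", "Ech"))   # compact 3-class indices
  ds$scheme$classes <- c("Dic", "El", "Ech")
  plan <- kfold_split(ds, k = 5, seed = 3)
  spec <- network_spec(3, input_size = 16, conv_filters = c(3, 4),
                       conv_kernels = c(3, 3), fc_units = 6, dropout = 0)
  rep <- cross_validate(ds, plan, spec,
                        train_config(lr = 0.05, batch_size = 5,
                                     epochs = 2, seed = 1))
  expect_length(rep$folds, 5)
  evalerr <- vapply(rep$folds, `[[`, 0, "eval_error")
  expect_identical(rep$mean_accuracy, mean(1 - evalerr))
  # evaluation sets partition the dataset
  expect_identical(sum(vapply(rep$folds, `[[`, 0L, "n_val")),
                   length(ds$y))
  for (f in rep$folds) expect_identical(sum(f$confusion), f$n_val)
})

test_that("class distribution report matches a brute tally", {
  preds <- c("Dic", "Dic", "El", "Sk", "Dic")
  tab <- report_class_distribution(preds)
  expect_identical(tab$count[tab$class == "Dic"], 3L)
  expect_identical(sum(tab$count), 5L)
  one <- report_class_distribution(rep("El", 4))
  expect_identical(nrow(one), 1L)
  grp <- report_class_distribution(preds, group = c(1, 1, 1, 2, 2))
  expect_identical(sum(grp$count), 5L)
})
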