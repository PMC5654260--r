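# Confusion matrices, one-vs-rest per-class metrics, ROC/AUC and k-fold
# aggregation. Per-class metrics follow the binary one-vs-rest reduction:
# precision TP/(TP+FP), sensitivity TP/(TP+FN), specificity TN/(FP+TN),
# F-score 2TP/(2TP+FP+FN), accuracy (TP+TN)/(TP+FP+FN+TN). Note the
# per-class accuracy is the binary reduction, not multiclass trace
# accuracy; both are reported under distinct names.

#' Confusion matrix
#'
#' @param truth,pred integer labels in `1..n`.
#' @param n number of classes.
#' @param normalize `"none"` for counts or `"row"` for true-class
#'   normalization (each row sums to 1).
#' @return `n x n` matrix, rows = true class, columns = predicted class.
#' @export
confusion_matrix <- function(truth, pred, n, normalize = c("none", "row")) {
  normalize <- match.arg(normalize)
  if (length(truth) != length(pred))
    stop("truth and pred must have the same length")
  stopifnot(all(truth >= 1), all(truth <= n), all(pred >= 1), all(pred <= n))
  cm <- matrix(0L, n, n)
  for (i in seq_along(truth))
    cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  if (normalize == "row") {
    rs <- rowSums(cm)
    cm <- cm / ifelse(rs == 0, 1, rs)
  }
  cm
}

#' One-vs-rest metrics for one class of a confusion matrix
#'
#' Rates with a 0/0 numerator are defined as 0 and flagged in
#' `degenerate`.
#' @param cm count confusion matrix.
#' @param i class index.
#' @return list: `TP`, `FP`, `FN`, `TN`, `precision`, `sensitivity`,
#'   `specificity`, `f_score`, `accuracy`, `degenerate` (character vector
#'   of flagged rates).
#' @export
class_metrics <- function(cm, i) {
  total <- sum(cm)
  TP <- cm[i, i]
  FP <- sum(cm[, i]) - TP
  FN <- sum(cm[i, ]) - TP
  TN <- total - TP - FP - FN
  degenerate <- character(0)
  rate <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      return(0)
    }
    num / den
  }
  list(TP = TP, FP = FP, FN = FN, TN = TN,
       precision = rate(TP, TP + FP, "precision"),
       sensitivity = rate(TP, TP + FN, "sensitivity"),
       specificity = rate(TN, FP + TN, "specificity"),
       f_score = rate(2 * TP, 2 * TP + FP + FN, "f_score"),
       accuracy = rate(TP + TN, total, "accuracy"),
       degenerate = degenerate)
}

#' One-vs-rest ROC curve and AUC
#'
#' Sweeps all distinct probability thresholds for class `i` (equal scores
#' are grouped, giving the standard staircase); AUC by the trapezoid rule.
#' If the truth contains a single class the result is flagged undefined.
#'
#' @param truth integer labels.
#' @param probs probability matrix, items x classes.
#' @param i class index (the positive class).
#' @return list: `fpr`, `tpr` (monotone from (0,0) to (1,1)), `auc`,
#'   `undefined`.
#' @export
roc_auc <- function(truth, probs, i) {
  score <- probs[, i]
  pos <- truth == i
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    return(list(fpr = c(0, 1), tpr = c(0, 1), auc = NA_real_,
                undefined = TRUE))
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; p <- pos[ord]
  # group tied scores
  grp <- cumsum(c(TRUE, diff(s) != 0))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- which(c(diff(grp) != 0, TRUE))
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc, undefined = FALSE)
}

#' Macro-averaged one-vs-rest AUC
#' @inheritParams roc_auc
#' @param n number of classes.
#' @return mean AUC over classes with defined curves.
#' @export
macro_auc <- function(truth, probs, n = ncol(probs)) {
  aucs <- vapply(seq_len(n), function(i) roc_auc(truth, probs, i)$auc, 0)
  mean(aucs, na.rm = TRUE)
}

#' k-fold cross-validation of the CNN
#'
#' Trains one model per fold on its training set, evaluates on the held-out
#' validation set, and aggregates per-fold training/evaluation errors into
#' a mean +/- sd accuracy report with confusion matrices and macro AUCs.
#'
#' @param ds a `labeled_dataset`.
#' @param plan a [kfold_split()] fold plan.
#' @param spec a [network_spec()] (output dimension must match the
#'   scheme).
#' @param config a [train_config()]; each fold trains with seed
#'   `config$seed + fold`.
#' @param verbose print progress.
#' @return `cv_report` list: per-fold `folds` (train_error, eval_error,
#'   confusion, macro_auc, history), `mean_accuracy`, `sd_accuracy`,
#'   `mean_train_accuracy`, `sd_train_accuracy`.
#' @export
cross_validate <- function(ds, plan, spec, config = train_config(),
                           verbose = FALSE) {
  k <- attr(plan, "k")
  stopifnot(k >= 2, spec$n_classes == length(ds$scheme$classes))
  folds <- vector("list", k)
  for (j in seq_len(k)) {
    mem <- fold_members(plan, j)
    cfg <- config
    cfg$seed <- config$seed + j
    model <- train_cnn(ds$x[, , mem$train, drop = FALSE], ds$y[mem$train],
                       spec, cfg, verbose = verbose)
    pr <- predict_cnn(model, ds$x[, , mem$val, drop = FALSE])
    truth <- ds$y[mem$val]
    cm <- confusion_matrix(truth, pr$labels, spec$n_classes)
    acc <- sum(diag(cm)) / sum(cm)
    folds[[j]] <- list(
      fold = j,
      n_train = length(mem$train), n_val = length(mem$val),
      train_error = utils::tail(model$history$train_error, 1),
      eval_error = 1 - acc,
      confusion = cm,
      macro_auc = macro_auc(truth, pr$probs),
      history = model$history)
    if (verbose)
      message(sprintf("fold %d: eval error %.4f", j, 1 - acc))
  }
  evalacc <- vapply(folds, function(f) 1 - f$eval_error, 0)
  trainacc <- vapply(folds, function(f) 1 - f$train_error, 0)
  structure(list(folds = folds,
                 mean_accuracy = mean(evalacc), sd_accuracy = sd(evalacc),
                 mean_train_accuracy = mean(trainacc),
                 sd_train_accuracy = sd(trainacc)),
            class = "cv_report")
}
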