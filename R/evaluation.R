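#' One-vs-all ROC curve and AUC
#'
#' The multiclass problem is evaluated as one binary problem per class:
#' the class of interest is positive, everything else negative, and the
#' positive-class predicted probability is the score. The threshold set
#' is the unique observed scores plus a sentinel above all of them, so
#' the curve is the exact step function from (0,0) to (1,1); AUC is its
#' trapezoidal integral, which equals the probability that a random
#' positive outranks a random negative (ties counted 1/2).
#'
#' @param scores Per-vector probability rows ([predict_proba()] output, a
#'   matrix, or a single numeric score vector for the positive class).
#' @param truth Character vector of true labels, parallel to `scores`.
#' @param positive_class The label treated as positive.
#' @return A `roc_result`: list with `class_label`, `thresholds`
#'   (descending), `fpr`, `tpr` (nondecreasing, from 0 to 1) and `auc`.
#' @export
one_vs_all_roc <- function(scores, truth, positive_class) {
  score <- if (is.null(dim(scores)) && !is.data.frame(scores)) {
    as.numeric(scores)
  } else {
    m <- as.matrix(scores)
    assert_that(positive_class %in% colnames(m),
                sprintf("No probability column for class '%s'.",
                        positive_class))
    m[, positive_class]
  }
  assert_that(length(score) == length(truth),
              "`scores` and `truth` must be parallel.")
  pos <- truth == positive_class
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    abort(sprintf("Class '%s' needs both positives and negatives (%d/%d).",
                  positive_class, n_pos, n_neg),
          class = "cytofp_roc_error")
  }
  thresholds <- c(Inf, sort(unique(score), decreasing = TRUE))
  tpr <- vapply(thresholds, function(t) sum(pos & score >= t) / n_pos,
                numeric(1))
  fpr <- vapply(thresholds, function(t) sum(!pos & score >= t) / n_neg,
                numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(class_label = positive_class, thresholds = thresholds,
                 fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %s vs rest: AUC %.4f (%d threshold points)\n",
              x$class_label, x$auc, length(x$thresholds)))
  invisible(x)
}

#' One-vs-all ROC for every class
#'
#' @inheritParams one_vs_all_roc
#' @return Named list of `roc_result`, one per class (lexicographic).
#' @export
all_class_rocs <- function(scores, truth) {
  labs <- sort(intersect(colnames(as.matrix(scores)), unique(truth)))
  setNames(lapply(labs, function(l) one_vs_all_roc(scores, truth, l)), labs)
}

#' Confusion matrix
#'
#' @param pred,truth Parallel label vectors.
#' @return Integer matrix; entry `(t, p)` counts vectors with truth `t`
#'   predicted `p`. Row sums equal per-class support.
#' @export
confusion_matrix <- function(pred, truth) {
  assert_that(length(pred) == length(truth),
              "`pred` and `truth` must be parallel.")
  labs <- sort(unique(c(pred, truth)))
  m <- table(factor(truth, levels = labs), factor(pred, levels = labs))
  out <- matrix(as.integer(m), length(labs), length(labs),
                dimnames = list(truth = labs, predicted = labs))
  out
}

#' Per-class probability distribution summary
#'
#' For each true class, the five-number summary (minimum, lower hinge,
#' median, upper hinge, maximum) of every class's predicted probability
#' across that true class's vectors — the data behind per-class
#' classification-probability box plots.
#'
#' @param scores Probability rows ([predict_proba()] output or matrix).
#' @param truth Parallel true labels.
#' @return Tibble with columns `truth`, `class`, `min`, `q1`, `median`,
#'   `q3`, `max`, `mean`.
#' @export
class_probability_summary <- function(scores, truth) {
  m <- as.matrix(scores)
  assert_that(nrow(m) == length(truth),
              "`scores` and `truth` must be parallel.")
  rows <- list()
  for (t in sort(unique(truth))) {
    sub <- m[truth == t, , drop = FALSE]
    for (cl in colnames(m)) {
      fn <- stats::fivenum(sub[, cl])
      rows[[length(rows) + 1]] <- tibble(
        truth = t, class = cl, min = fn[1], q1 = fn[2], median = fn[3],
        q3 = fn[4], max = fn[5], mean = mean(sub[, cl]))
    }
  }
  bind_rows(rows)
}

#' Gedeon-style variable importance for the feed-forward network
#'
#' Propagates absolute weight magnitudes through the first two hidden
#' layers: for input `i`, `score_i = sum_j P_ij * Q_j` with
#' `P_ij = |w1_ij| / sum_i' |w1_i'j|` (share of hidden unit `j`'s
#' incoming weight carried by input `i`) and
#' `Q_j = sum_k |w2_jk| / sum_j' |w2_j'k|` (how strongly unit `j` feeds
#' the second hidden layer). Per-variable scores are normalized to a
#' maximum of 1; per-block scores are the sums of the (normalized)
#' per-variable scores over each channel block — with 1000-event chunks,
#' `V1..V1000` is FSC-A, `V1001..V2000` SSC-A and `V2001..V3000`
#' AmCyan-A.
#'
#' Defined only for the `DL` classifier (the method reads the network's
#' layer weights).
#'
#' @param model A trained `cytofp_classifier` with `algorithm = "DL"`.
#' @param block_channels Channel names for the consecutive equal blocks
#'   of input variables (default the three analysis channels).
#' @return An `importance_report`: list with `per_variable` (tibble
#'   `variable, index, score`) and `per_block` (tibble `channel, score`).
#' @export
gedeon_importance <- function(model, block_channels = analysis_channels()) {
  stopifnot(inherits(model, "cytofp_classifier"))
  if (model$algorithm != "DL") {
    abort(sprintf(
      "Variable importance is defined for the DL network only (got %s).",
      model$algorithm), class = "cytofp_unsupported_model")
  }
  W1 <- abs(model$fit$net$W[[1]])
  W2 <- abs(model$fit$net$W[[2]])
  P <- sweep(W1, 2, pmax(colSums(W1), 1e-300), "/")     # inputs x h1
  Q <- rowSums(sweep(W2, 2, pmax(colSums(W2), 1e-300), "/"))  # h1
  score <- as.numeric(P %*% Q)
  score <- score / max(score)
  p <- length(score)
  per_variable <- tibble(variable = paste0("V", seq_len(p)),
                         index = seq_len(p), score = score)
  n_blocks <- length(block_channels)
  assert_that(p %% n_blocks == 0,
              "Input length is not divisible into equal channel blocks.")
  b <- p / n_blocks
  per_block <- tibble(
    channel = block_channels,
    score = vapply(seq_len(n_blocks), function(i) {
      sum(score[((i - 1) * b + 1):(i * b)])
    }, numeric(1)))
  structure(list(per_variable = per_variable, per_block = per_block),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat("<importance_report> per-channel block scores:\n")
  print(x$per_block)
  invisible(x)
}

#' Model-comparison report tables
#'
#' `accuracy_table()` builds the comparison layout with one row per class
#' (plus `Overall`) and one column per algorithm; `auc_table()` does the
#' same for one-vs-all AUCs (no macro/micro averaging — per-class values
#' only).
#'
#' @param models Named list of trained classifiers (names are the column
#'   headers, e.g. `GB`, `NB`, `DRF`, `DL`).
#' @param test Labelled fingerprint tibble.
#' @return A tibble.
#' @export
accuracy_table <- function(models, test) {
  labs <- sort(unique(test$label))
  cols <- lapply(models, function(m) {
    acc <- accuracy(m, test)
    c(acc$per_class[labs], Overall = acc$overall)
  })
  bind_cols(tibble(putative_group = c(labs, "Overall")),
            as_tibble(as.data.frame(cols, check.names = FALSE)))
}

#' @rdname accuracy_table
#' @export
auc_table <- function(models, test) {
  labs <- sort(unique(test$label))
  cols <- lapply(models, function(m) {
    probs <- predict_proba(m, test)
    vapply(labs, function(l) one_vs_all_roc(probs, test$label, l)$auc,
           numeric(1))
  })
  bind_cols(tibble(putative_group = labs),
            as_tibble(as.data.frame(cols, check.names = FALSE)))
}

#' ROC points of every class for one model, as a tidy tibble
#'
#' @param model A trained classifier.
#' @param test Labelled fingerprint tibble.
#' @return Tibble `class, threshold, fpr, tpr, auc`.
#' @export
roc_points <- function(model, test) {
  probs <- predict_proba(model, test)
  rocs <- all_class_rocs(probs, test$label)
  bind_rows(lapply(rocs, function(r) {
    tibble(class = r$class_label, threshold = r$thresholds, fpr = r$fpr,
           tpr = r$tpr, auc = r$auc)
  }))
}
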