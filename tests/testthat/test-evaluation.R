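# Mann-Whitney pair-counting oracle: fraction of (positive, negative)
# pairs ranked correctly, ties counted 1/2
mw_auc <- function(score, pos) {
  sp <- score[pos]
  sn <- score[!pos]
  total <- 0
  for (p in sp) for (n in sn) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(sp) * length(sn))
}

test_that("trapezoidal AUC equals the pair-counting oracle to 1e-12", {
  # hand-listed score set with ties across classes
  score <- c(0.9, 0.8, 0.8, 0.6, 0.4, 0.4, 0.2, 0.1)
  truth <- c("pos", "pos", "neg", "pos", "neg", "pos", "neg", "neg")
  r <- one_vs_all_roc(score, truth, "pos")
  expect_equal(r$auc, mw_auc(score, truth == "pos"), tolerance = 1e-12)
  # randomized property: many score lists, heavy ties via rounding
  for (seed in 1:20) {
    sc <- round(cytofp:::with_seed(seed, runif(30)), 1)
    tr <- rep(c("pos", "neg"), 15)
    r2 <- one_vs_all_roc(sc, tr, "pos")
    expect_equal(r2$auc, mw_auc(sc, tr == "pos"), tolerance = 1e-12)
  }
})

test_that("ROC endpoints, monotonicity and degenerate rankings behave", {
  r <- one_vs_all_roc(c(0.9, 0.8, 0.2, 0.1), c("p", "p", "n", "n"), "p")
  expect_equal(r$auc, 1.0)
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(tail(r$fpr, 1), tail(r$tpr, 1)), c(1, 1))
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  # label-independent constant scores -> chance
  r2 <- one_vs_all_roc(rep(0.5, 10), rep(c("p", "n"), 5), "p")
  expect_equal(r2$auc, 0.5)
  expect_error(one_vs_all_roc(c(0.1, 0.2), c("p", "p"), "p"),
               class = "cytofp_roc_error")
})

test_that("AUC agrees with pROC on a random case", {
  skip_if_not_installed("pROC")
  sc <- cytofp:::with_seed(7, runif(50))
  tr <- rep(c("p", "n"), 25)
  ours <- one_vs_all_roc(sc, tr, "p")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = tr, predictor = sc,
                                        levels = c("n", "p"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("one-vs-all AUC is near 0.5 for label-independent scores", {
  aucs <- vapply(1:10, function(seed) {
    sc <- cytofp:::with_seed(seed, runif(200))
    tr <- rep(c("a", "b", "c", "d"), 50)
    one_vs_all_roc(sc, tr, "a")$auc
  }, numeric(1))
  # n_pos = 50, n_neg = 150 -> SE of AUC roughly sqrt(1/12 * (1/50 + 1/150))
  se <- sqrt((1 / 50 + 1 / 150) / 12)
  expect_true(all(abs(aucs - 0.5) < 3 * se))
})

test_that("confusion matrices count pairs and conserve totals", {
  pred <- c("a", "b", "a", "b")
  truth <- c("a", "b", "b", "b")
  cm <- confusion_matrix(pred, truth)
  expect_equal(cm["a", "a"], 1L)
  expect_equal(cm["b", "b"], 2L)
  expect_equal(cm["b", "a"], 1L)
  expect_equal(sum(cm), 4L)
  expect_equal(unname(rowSums(cm)), c(1L, 3L))
  # identical vectors -> diagonal
  cm2 <- confusion_matrix(truth, truth)
  expect_equal(sum(cm2) - sum(diag(cm2)), 0L)
})

test_that("per-class recall from the confusion matrix equals accuracy()'s", {
  ds <- dplyr::filter(small_ds(), label %in% c("GLUC", "ACET", "PROP"))
  m <- train_classifier(model_spec("NB"), ds)
  pred <- predict_class(m, ds)
  cm <- confusion_matrix(pred, ds$label)
  acc <- accuracy(m, ds)
  for (lab in rownames(cm)) {
    expect_equal(cm[lab, lab] / sum(cm[lab, ]),
                 unname(acc$per_class[lab]))
  }
  expect_equal(sum(cm), nrow(ds))
})

test_that("class probability summaries reproduce analytic box plots", {
  # uniform predictor over 4 classes: every median 0.25
  probs <- matrix(0.25, 20, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  truth <- rep(c("a", "b", "c", "d"), 5)
  cs <- class_probability_summary(probs, truth)
  expect_true(all(cs$median == 0.25))
  # perfect predictor: own-class median 1
  perfect <- diag(4)[match(truth, c("a", "b", "c", "d")), ]
  colnames(perfect) <- c("a", "b", "c", "d")
  cp <- class_probability_summary(perfect, truth)
  own <- dplyr::filter(cp, truth == class)
  expect_true(all(own$median == 1))
  other <- dplyr::filter(cp, truth != class)
  expect_true(all(other$median == 0))
})

test_that("a cleanly separated class dominates its own predicted probability", {
  ds <- small_ds()
  m <- train_classifier(model_spec("NB"), ds)
  cs <- class_probability_summary(predict_proba(m, ds), ds$label)
  for (lab in unique(ds$label)) {
    own <- dplyr::filter(cs, truth == lab, class == lab)$median
    others <- dplyr::filter(cs, truth == lab, class != lab)$median
    expect_true(all(own > others))
  }
})

test_that("Gedeon importance matches a hand computation on a 2-2-2 network", {
  W1 <- rbind(c(1, -2), c(3, 4))    # inputs x hidden1
  W2 <- rbind(c(-5, 6), c(7, 8))    # hidden1 x hidden2
  model <- structure(list(
    algorithm = "DL", labels = c("x", "y"), n_features = 2,
    spec = model_spec("DL"),
    fit = list(net = list(W = list(W1, W2, diag(2)),
                          b = list(c(0, 0), c(0, 0), c(0, 0)),
                          activation = "rectifier", output = "softmax"))),
    class = "cytofp_classifier")
  imp <- gedeon_importance(model, block_channels = c("c1", "c2"))
  # oracle: P_ij = |w1_ij|/sum_i |w1_ij|; Q_j = sum_k |w2_jk|/sum_j |w2_jk|
  P <- abs(W1) %*% diag(1 / colSums(abs(W1)))
  Q <- rowSums(abs(W2) %*% diag(1 / colSums(abs(W2))))
  score <- as.numeric(P %*% Q)
  score <- score / max(score)
  expect_equal(imp$per_variable$score, score, tolerance = 1e-12)
  expect_equal(imp$per_block$score, score, tolerance = 1e-12)  # blocks of 1
})

test_that("zero first-layer weights for a block zero its importance", {
  W1 <- rbind(c(1, 2), c(0.5, 0.1), c(0, 0), c(0, 0), c(0, 0), c(0, 0))
  W2 <- matrix(c(1, 2, 3, 4), 2, 2)
  model <- structure(list(
    algorithm = "DL", labels = c("x", "y"), n_features = 6,
    spec = model_spec("DL"),
    fit = list(net = list(W = list(W1, W2, diag(2)),
                          b = list(c(0, 0), c(0, 0), c(0, 0)),
                          activation = "rectifier", output = "softmax"))),
    class = "cytofp_classifier")
  imp <- gedeon_importance(model,
                           block_channels = c("FSC-A", "SSC-A", "AmCyan-A"))
  expect_equal(imp$per_block$score[2:3], c(0, 0))
  expect_gt(imp$per_block$score[1], 0)
  # non-DL models are unsupported
  ds <- fp_tibble(matrix(rnorm(40), 20, 2), rep(c("a", "b"), 10))
  nb <- train_classifier(model_spec("NB"), ds)
  expect_error(gedeon_importance(nb), class = "cytofp_unsupported_model")
})

test_that("a channel that alone separates classes earns the top block score", {
  # classes differ only in channel 1 (the first block of each vector)
  des_sep <- list(
    class_distribution("LOW", list(
      list(weight = 1, mean = c(200, 400, 400), sd = c(15, 15, 15)))),
    class_distribution("HIGH", list(
      list(weight = 1, mean = c(700, 400, 400), sd = c(15, 15, 15)))))
  dir <- withr::local_tempdir()
  man <- simulate_study(study_design(des_sep, replicates = 2,
                                     timepoints = 2,
                                     events_per_sample = 500, seed = 31),
                        dir)
  ds <- fingerprint_dataset(read_manifest(man), chunk_size = 20)
  m <- train_classifier(model_spec("DL", list(hidden = c(16, 8, 4),
                                              epochs = 20), seed = 3), ds)
  imp <- gedeon_importance(m)
  expect_equal(which.max(imp$per_block$score), 1L)
})

test_that("report tables carry one row per class plus overall", {
  ds <- dplyr::filter(small_ds(), label %in% c("GLUC", "CELL"))
  models <- list(NB = train_classifier(model_spec("NB"), ds),
                 DRF = train_classifier(model_spec("DRF",
                                                   list(ntrees = 50)), ds))
  at <- accuracy_table(models, ds)
  expect_equal(at$putative_group, c("CELL", "GLUC", "Overall"))
  expect_named(at, c("putative_group", "NB", "DRF"))
  auct <- auc_table(models, ds)
  expect_equal(auct$putative_group, c("CELL", "GLUC"))
  expect_true(all(as.matrix(auct[, -1]) >= 0 & as.matrix(auct[, -1]) <= 1))
})
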