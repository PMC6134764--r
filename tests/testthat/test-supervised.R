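small_specs <- function(seed = 2) list(
  GB = model_spec("GB", list(ntrees = 30), seed = seed),
  NB = model_spec("NB", seed = seed),
  DRF = model_spec("DRF", list(ntrees = 80), seed = seed),
  DL = model_spec("DL", list(hidden = c(24, 12, 6), epochs = 15),
                  seed = seed))

test_that("every algorithm fits well-separated classes almost perfectly", {
  ds <- dplyr::filter(small_ds(), label %in% c("GLUC", "PROP"))
  for (spec in small_specs()) {
    m <- train_classifier(spec, ds)
    acc <- accuracy(m, ds)
    expect_gte(acc$overall, 0.99)
  }
})

test_that("predicted probability rows lie on the simplex for all algorithms", {
  ds <- dplyr::filter(small_ds(), label %in% c("CELL", "ACET"))
  test <- head(ds, 30)
  for (spec in small_specs()) {
    m <- train_classifier(spec, ds)
    probs <- as.matrix(predict_proba(m, test))
    expect_true(all(probs >= 0))
    expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-6)
    expect_identical(colnames(probs), sort(unique(ds$label)))
  }
})

test_that("training and prediction are deterministic for a fixed seed", {
  ds <- per_label_head(dplyr::filter(small_ds(),
                                     label %in% c("GLUC", "CELL")), 60)
  for (spec in small_specs(seed = 33)) {
    p1 <- predict_proba(train_classifier(spec, ds), ds)
    p2 <- predict_proba(train_classifier(spec, ds), ds)
    expect_identical(p1, p2)
  }
})

test_that("naive Bayes posteriors equal brute-force Bayes to 1e-9", {
  # tiny Gaussian toy: 2 features, 3 classes, hand-enumerable
  X <- rbind(c(1.0, 2.0), c(1.2, 1.8), c(0.8, 2.2),
             c(5.0, 6.0), c(5.5, 5.5), c(4.5, 6.5),
             c(9.0, 1.0), c(8.5, 1.5), c(9.5, 0.5))
  y <- rep(c("a", "b", "c"), each = 3)
  ds <- fp_tibble(X, y)
  m <- train_classifier(model_spec("NB"), ds)
  probs <- as.matrix(predict_proba(m, ds))
  # independent brute-force computation of p(c|x) with the same
  # variance-floored class Gaussians and empirical priors
  floor_var <- pmax(1e-9 * apply(X, 2, var), 1e-12)
  labs <- sort(unique(y))
  for (r in seq_len(nrow(X))) {
    joint <- vapply(labs, function(l) {
      Xi <- X[y == l, , drop = FALSE]
      mu <- colMeans(Xi)
      v <- pmax(apply(Xi, 2, var), floor_var)
      prod(dnorm(X[r, ], mu, sqrt(v))) * (nrow(Xi) / nrow(X))
    }, numeric(1))
    expect_equal(unname(probs[r, ]), unname(joint / sum(joint)),
                 tolerance = 1e-9)
  }
})

test_that("naive Bayes agrees with an independent library implementation", {
  skip_if_not_installed("e1071")
  X <- matrix(rnorm(60 * 4, rep(c(0, 4), each = 2)), 60, 4, byrow = TRUE)
  y <- rep(c("a", "b"), length.out = 60)
  ds <- fp_tibble(X, y)
  m <- train_classifier(model_spec("NB"), ds)
  ours <- as.matrix(predict_proba(m, ds))
  ref <- e1071::naiveBayes(x = as.data.frame(X), y = factor(y))
  theirs <- predict(ref, as.data.frame(X), type = "raw")
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
})

test_that("naive Bayes survives zero within-class variance via the floor", {
  X <- cbind(rep(c(1, 5), each = 10), rnorm(20))
  ds <- fp_tibble(X, rep(c("a", "b"), each = 10))
  m <- train_classifier(model_spec("NB"), ds)
  probs <- as.matrix(predict_proba(m, ds))
  expect_true(all(is.finite(probs)))
  expect_gte(accuracy(m, ds)$overall, 0.99)
})

test_that("degenerate duplicated features still yield valid simplex rows", {
  X <- matrix(rep(c(1, 2), each = 12), 12, 2)
  ds <- fp_tibble(cbind(X, X), rep(c("a", "b"), 6))
  for (alg in c("GB", "NB", "DRF")) {
    m <- train_classifier(model_spec(alg, list()), ds)
    probs <- as.matrix(predict_proba(m, ds))
    expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-6)
  }
})

test_that("single-label training sets are rejected", {
  ds <- fp_tibble(matrix(rnorm(20), 10, 2), "onlyclass")
  expect_error(train_classifier(model_spec("NB"), ds),
               class = "cytofp_train_error")
})

test_that("accuracy counts argmax hits overall and per class (hand-built case)", {
  # 1-D classifier with known decision boundary at 5: class a ~ N(0),
  # class b ~ N(10); 10 test vectors, 7 on the correct side
  train <- fp_tibble(matrix(c(rnorm(20, 0, .5), rnorm(20, 10, .5))),
                     rep(c("a", "b"), each = 20))
  m <- train_classifier(model_spec("NB"), train)
  test_vals <- c(0.5, 1, 9.5, 0.2, 9, 8.8, 0.1,  9.4, 0.3, 9.9)
  test_labs <- c("a", "a", "b", "a", "b", "b", "a", "a", "b", "a")
  test <- fp_tibble(matrix(test_vals), test_labs)
  acc <- accuracy(m, test)
  expect_equal(acc$overall, 0.7)
  expect_equal(unname(acc$per_class["a"]), 4 / 6)
  expect_equal(unname(acc$per_class["b"]), 3 / 4)
  # perfect predictor case
  acc_perfect <- accuracy(m, train)
  expect_equal(acc_perfect$overall, 1.0)
  expect_equal(unname(acc_perfect$per_class), c(1, 1))
})

test_that("labels unseen at training are counted wrong, with a warning", {
  ds <- fp_tibble(matrix(c(rnorm(10, 0), rnorm(10, 8))),
                  rep(c("a", "b"), each = 10))
  m <- train_classifier(model_spec("NB"), ds)
  test <- fp_tibble(matrix(c(0.1, 8.2, 4)), c("a", "b", "mystery"))
  expect_warning(acc <- accuracy(m, test), "mystery")
  expect_equal(acc$overall, 2 / 3)
  expect_equal(unname(acc$per_class["mystery"]), 0)
})

test_that("per-class decision thresholds produce the thresholded variant", {
  ds <- fp_tibble(matrix(c(rnorm(10, 0), rnorm(10, 8))),
                  rep(c("a", "b"), each = 10))
  m <- train_classifier(model_spec("NB"), ds)
  # an impossible threshold for class a suppresses all its predictions
  acc <- accuracy(m, ds, class_thresholds = c(a = 1.1))
  expect_equal(unname(acc$per_class["a"]), 0)
  expect_equal(unname(acc$per_class["b"]), 1)
})

test_that("classifier checkpoints round trip with identical probabilities", {
  ds <- dplyr::filter(small_ds(), label %in% c("GLUC", "CELL"))
  for (spec in small_specs()) {
    m <- train_classifier(spec, per_label_head(ds, 50))
    p <- withr::local_tempfile(fileext = ".rds")
    save_classifier(m, p)
    m2 <- load_classifier(p)
    expect_equal(predict_proba(m, head(ds, 20)),
                 predict_proba(m2, head(ds, 20)), tolerance = 1e-12)
  }
})
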