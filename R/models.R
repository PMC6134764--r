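#' Supervised model specification
#'
#' One of the four fingerprint classifiers, with its hyperparameters:
#' \describe{
#'   \item{GB}{gradient boosting (multinomial deviance); defaults 200
#'     trees, maximum depth 5, learning rate 0.1.}
#'   \item{DRF}{random forest; defaults 200 trees, maximum depth 20.}
#'   \item{NB}{Gaussian naive Bayes with a per-feature variance floor and
#'     Laplace-smoothed class priors.}
#'   \item{DL}{feed-forward network with three hidden layers; defaults
#'     hidden sizes (2000, 1000, 500), rectifier-with-dropout activation,
#'     input dropout 0.1, hidden dropouts (0.2, 0.2, 0.1), 10 epochs, and
#'     L1 and L2 penalties of 1e-5 each (both applied by default, each
#'     switchable).}
#' }
#' Values in `hyperparameters` override the defaults.
#'
#' @param algorithm `"GB"`, `"NB"`, `"DRF"` or `"DL"`.
#' @param hyperparameters Named list of overrides.
#' @param seed RNG seed (tree sampling / network initialization).
#' @return A `model_spec` object.
#' @examples
#' model_spec("DL", list(hidden = c(64, 32, 16), epochs = 5))
#' @export
model_spec <- function(algorithm = c("GB", "NB", "DRF", "DL"),
                       hyperparameters = list(), seed = 1) {
  algorithm <- match.arg(algorithm)
  hp <- utils::modifyList(default_hyperparameters(algorithm),
                          hyperparameters)
  structure(list(algorithm = algorithm, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' @rdname model_spec
#' @export
default_hyperparameters <- function(algorithm) {
  switch(algorithm,
    GB = list(ntrees = 200, max_depth = 5, learn_rate = 0.1),
    DRF = list(ntrees = 200, max_depth = 20),
    NB = list(laplace = 0, var_floor_frac = 1e-9),
    DL = list(hidden = c(2000, 1000, 500), activation = "rectifier",
              input_dropout = 0.1, hidden_dropout = c(0.2, 0.2, 0.1),
              epochs = 10, l1 = 1e-5, l2 = 1e-5, learning_rate = 1e-3,
              batch_size = 32),
    abort(sprintf("Unknown algorithm '%s'.", algorithm)))
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (seed %d)\n", x$algorithm, x$seed))
  str(x$hyperparameters, give.attr = FALSE)
  invisible(x)
}

# Class order is lexicographic by label string, fixed across all reports.
model_labels <- function(ds) sort(unique(ds$label))

#' Train a fingerprint classifier
#'
#' All four algorithms share this surface and the
#' [predict_proba()]/[accuracy()] contracts, so they are directly
#' swappable in comparisons. Training is deterministic for a fixed spec
#' seed (single-threaded tree growth; seeded network initialization and
#' minibatch order).
#'
#' @param spec A [model_spec()].
#' @param train Labelled fingerprint tibble with at least two classes.
#' @return A `cytofp_classifier`.
#' @export
train_classifier <- function(spec, train) {
  stopifnot(inherits(spec, "model_spec"))
  X <- fp_values(train)
  labels <- model_labels(train)
  assert_that(length(labels) >= 2,
              "Training requires at least two distinct labels.",
              class = "cytofp_train_error")
  y <- factor(train$label, levels = labels)
  hp <- spec$hyperparameters
  fit <- switch(spec$algorithm,
    GB = {
      dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
      params <- list(objective = "multi:softprob",
                     num_class = length(labels),
                     max_depth = hp$max_depth, eta = hp$learn_rate,
                     nthread = 1, seed = spec$seed)
      xgboost::xgb.train(params, dtrain, nrounds = hp$ntrees, verbose = 0)
    },
    DRF = {
      ranger::ranger(x = as.data.frame(X), y = y,
                     num.trees = hp$ntrees, max.depth = hp$max_depth,
                     probability = TRUE, seed = spec$seed,
                     num.threads = 1)
    },
    NB = nb_fit(X, y, laplace = hp$laplace,
                var_floor_frac = hp$var_floor_frac),
    DL = {
      center <- colMeans(X)
      scale <- pmax(apply(X, 2, sd), 1e-8)
      Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
      Y <- matrix(0, nrow(X), length(labels))
      Y[cbind(seq_len(nrow(X)), as.integer(y))] <- 1
      net <- mlp_train(c(ncol(X), hp$hidden, length(labels)), Xs, Y,
                       activation = hp$activation, output = "softmax",
                       loss = "xent", epochs = hp$epochs,
                       batch_size = hp$batch_size, lr = hp$learning_rate,
                       l1 = hp$l1, l2 = hp$l2,
                       input_dropout = hp$input_dropout,
                       hidden_dropout = hp$hidden_dropout,
                       seed = spec$seed)
      list(net = net, center = center, scale = scale)
    })
  structure(list(spec = spec, algorithm = spec$algorithm, fit = fit,
                 labels = labels, n_features = ncol(X)),
            class = "cytofp_classifier")
}

#' @export
print.cytofp_classifier <- function(x, ...) {
  cat(sprintf("<cytofp_classifier> %s over %d features, classes: %s\n",
              x$algorithm, x$n_features, paste(x$labels, collapse = ", ")))
  invisible(x)
}

# ---- Gaussian naive Bayes --------------------------------------------------
# Per class, features are independent Gaussians; per-class variances are
# floored at var_floor_frac * (pooled feature variance) so constant
# within-class features cannot produce a zero standard deviation.
nb_fit <- function(X, y, laplace = 0, var_floor_frac = 1e-9) {
  labels <- levels(y)
  k <- length(labels)
  n <- nrow(X)
  feat_var <- apply(X, 2, var)
  floor_var <- pmax(var_floor_frac * feat_var, 1e-12)
  means <- vars <- matrix(0, k, ncol(X),
                          dimnames = list(labels, colnames(X)))
  prior <- numeric(k)
  for (i in seq_len(k)) {
    rows <- X[y == labels[i], , drop = FALSE]
    means[i, ] <- colMeans(rows)
    v <- if (nrow(rows) > 1) apply(rows, 2, var) else rep(0, ncol(X))
    vars[i, ] <- pmax(v, floor_var)
    prior[i] <- (nrow(rows) + laplace) / (n + k * laplace)
  }
  list(means = means, vars = vars, prior = setNames(prior, labels))
}

nb_posterior <- function(fit, X) {
  k <- length(fit$prior)
  loglik <- matrix(0, nrow(X), k)
  for (i in seq_len(k)) {
    lp <- sweep(sweep(X, 2, fit$means[i, ])^2, 2, 2 * fit$vars[i, ], "/")
    loglik[, i] <- log(fit$prior[i]) -
      0.5 * sum(log(2 * pi * fit$vars[i, ])) - rowSums(lp)
  }
  post <- exp(loglik - apply(loglik, 1, logsumexp))
  colnames(post) <- names(fit$prior)
  post
}

#' Per-class probability predictions
#'
#' @param model A trained `cytofp_classifier`.
#' @param ds Fingerprint tibble (or numeric matrix) whose vector length
#'   matches training.
#' @return A tibble with one probability column per training label, rows
#'   parallel to `ds`, each row on the probability simplex.
#' @export
predict_proba <- function(model, ds) {
  stopifnot(inherits(model, "cytofp_classifier"))
  X <- if (is.data.frame(ds)) fp_values(ds) else as.matrix(ds)
  assert_that(ncol(X) == model$n_features,
              sprintf("Vector length %d does not match training length %d.",
                      ncol(X), model$n_features))
  k <- length(model$labels)
  probs <- switch(model$algorithm,
    GB = {
      p <- predict(model$fit, xgboost::xgb.DMatrix(X))
      if (is.matrix(p)) p else matrix(p, ncol = k, byrow = TRUE)
    },
    DRF = {
      p <- predict(model$fit, data = as.data.frame(X),
                   num.threads = 1)$predictions
      p[, model$labels, drop = FALSE]
    },
    NB = nb_posterior(model$fit, X),
    DL = {
      Xs <- sweep(sweep(X, 2, model$fit$center), 2, model$fit$scale, "/")
      mlp_predict(model$fit$net, Xs, output = "softmax")
    })
  colnames(probs) <- model$labels
  as_tibble(as.data.frame(probs))
}

#' Predicted class labels (argmax of the class probabilities)
#'
#' @inheritParams predict_proba
#' @return Character vector of predicted labels.
#' @export
predict_class <- function(model, ds) {
  probs <- as.matrix(predict_proba(model, ds))
  model$labels[max.col(probs, ties.method = "first")]
}

#' Overall and per-class accuracy
#'
#' Overall accuracy is the fraction of vectors whose argmax-probability
#' class equals the true label; per-class accuracy is the recall of each
#' true label (the layout of a model-comparison table: one value per
#' putative group plus overall). An optional per-class decision threshold
#' reproduces the thresholded variant: a vector counts as correct for its
#' class only if that class's probability also exceeds the threshold.
#'
#' @param model A trained `cytofp_classifier`.
#' @param test Labelled fingerprint tibble.
#' @param class_thresholds Optional named numeric vector of per-class
#'   probability thresholds (default none).
#' @return List with `overall` (fraction) and `per_class` (named vector of
#'   per-true-label recalls).
#' @export
accuracy <- function(model, test, class_thresholds = NULL) {
  assert_that(nrow(test) > 0, "Test set is empty.")
  probs <- as.matrix(predict_proba(model, test))
  pred <- model$labels[max.col(probs, ties.method = "first")]
  if (!is.null(class_thresholds)) {
    pmax_val <- probs[cbind(seq_len(nrow(probs)),
                            match(pred, model$labels))]
    thr <- class_thresholds[pred]
    thr[is.na(thr)] <- 0
    pred[pmax_val <= thr] <- NA_character_
  }
  truth <- test$label
  unseen <- setdiff(unique(truth), model$labels)
  if (length(unseen) > 0) {
    warn(sprintf("Label(s) unseen in training counted as misclassified: %s",
                 paste(unseen, collapse = ", ")))
  }
  correct <- !is.na(pred) & pred == truth
  per_class <- vapply(sort(unique(truth)), function(lab) {
    mean(correct[truth == lab])
  }, numeric(1))
  list(overall = mean(correct), per_class = per_class)
}

#' Save / load a trained classifier
#'
#' Tree ensembles are stored in their library's raw serialized form and
#' network/NB models as named parameter lists; a round trip reproduces
#' predicted probabilities exactly.
#'
#' @param model A `cytofp_classifier`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` / the restored classifier.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "cytofp_classifier"))
  obj <- unclass(model)
  if (model$algorithm == "GB") {
    obj$fit <- list(raw = xgboost::xgb.save.raw(model$fit))
  }
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  if (obj$algorithm == "GB") {
    obj$fit <- xgboost::xgb.load.raw(obj$fit$raw)
  }
  structure(obj, class = "cytofp_classifier")
}
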