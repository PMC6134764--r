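#' Autoencoder configuration
#'
#' A single-hidden-layer autoencoder (input -> `hidden_nodes` -> input)
#' trained to reconstruct fingerprint vectors; anomalous (perturbed)
#' communities are flagged by large reconstruction mean-squared error.
#' The reference configuration uses one hidden layer of 2000 nodes on
#' 3000-long fingerprints; smaller layouts train in seconds on reduced
#' fingerprints.
#'
#' @param hidden_nodes Hidden-layer width (default 2000).
#' @param epochs Training epochs (default 10).
#' @param activation `"tanh"` (default; bounded), `"rectifier"`, or
#'   `"linear"`.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param l1,l2 Penalty strengths.
#' @param standardize Fit a per-feature standardization on the training
#'   data and apply it identically at scoring (default `TRUE`); MSEs are
#'   then in standardized units, comparable across channels.
#' @param seed RNG seed (initialization and minibatch order).
#' @param input_dim Expected fingerprint length; inferred from the
#'   training data when `NULL`.
#' @return An `autoencoder_config` object.
#' @export
autoencoder_config <- function(hidden_nodes = 2000, epochs = 10,
                               activation = c("tanh", "rectifier", "linear"),
                               learning_rate = 1e-3, batch_size = 32,
                               l1 = 0, l2 = 0, standardize = TRUE,
                               seed = 1, input_dim = NULL) {
  activation <- match.arg(activation)
  assert_that(hidden_nodes >= 1, "`hidden_nodes` must be >= 1.")
  assert_that(epochs >= 1, "`epochs` must be >= 1.")
  structure(list(hidden_nodes = as.integer(hidden_nodes),
                 epochs = as.integer(epochs), activation = activation,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), l1 = l1, l2 = l2,
                 standardize = isTRUE(standardize), seed = as.integer(seed),
                 input_dim = input_dim),
            class = "autoencoder_config")
}

#' Train an autoencoder on fingerprint vectors
#'
#' Unsupervised: labels in `train` are ignored. The network learns an
#' approximation of the identity function through the hidden bottleneck;
#' its reconstruction error on new data is the anomaly score.
#'
#' @param train Fingerprint tibble (training vectors).
#' @param cfg An [autoencoder_config()].
#' @return A `cytofp_autoencoder` with the fitted weights, the
#'   standardization parameters and the per-epoch training loss
#'   (`$net$loss_history`).
#' @export
train_autoencoder <- function(train, cfg = autoencoder_config()) {
  stopifnot(inherits(cfg, "autoencoder_config"))
  X <- fp_values(train)
  assert_that(nrow(X) > 0, "Training set is empty.")
  if (!is.null(cfg$input_dim)) {
    assert_that(ncol(X) == cfg$input_dim,
                sprintf("Config expects input_dim = %d but data has %d.",
                        cfg$input_dim, ncol(X)),
                class = "cytofp_config_error")
  }
  if (cfg$standardize) {
    center <- colMeans(X)
    scale <- pmax(apply(X, 2, sd), 1e-8)
  } else {
    center <- rep(0, ncol(X))
    scale <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  net <- mlp_train(c(ncol(X), cfg$hidden_nodes, ncol(X)), Xs, Xs,
                   activation = cfg$activation, output = "linear",
                   loss = "mse", epochs = cfg$epochs,
                   batch_size = cfg$batch_size, lr = cfg$learning_rate,
                   l1 = cfg$l1, l2 = cfg$l2, seed = cfg$seed)
  structure(list(net = net, center = center, scale = scale,
                 input_dim = ncol(X), cfg = cfg),
            class = "cytofp_autoencoder")
}

#' @export
print.cytofp_autoencoder <- function(x, ...) {
  lh <- x$net$loss_history
  cat(sprintf(
    "<cytofp_autoencoder> %d -> %d -> %d (%s); loss %.4g -> %.4g over %d epochs\n",
    x$input_dim, x$cfg$hidden_nodes, x$input_dim, x$cfg$activation,
    lh[1], lh[length(lh)], x$cfg$epochs))
  invisible(x)
}

#' Mean squared reconstruction error
#'
#' `mse_between()` is the plain arithmetic: with `normalize = TRUE`
#' (default) the per-coordinate mean of squared differences,
#' `||x - x'||^2 / p`; with `normalize = FALSE` the raw squared norm
#' `||x - x'||^2`. `reconstruction_mse()` runs vectors through a trained
#' autoencoder (after its standardization) and applies `mse_between()` to
#' input and reconstruction.
#'
#' @param x,xhat Numeric vectors (or matrices, row-wise) of equal length.
#' @param normalize Divide by the dimension (default `TRUE`).
#' @return Nonnegative MSE (one value per row for matrix input).
#' @export
mse_between <- function(x, xhat, normalize = TRUE) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (is.null(dim(xhat))) xhat <- matrix(xhat, 1)
  assert_that(all(dim(x) == dim(xhat)),
              "Input and reconstruction dimensions differ.")
  ss <- rowSums((x - xhat)^2)
  if (normalize) ss / ncol(x) else ss
}

#' @rdname mse_between
#' @param model A trained `cytofp_autoencoder`.
#' @param v A fingerprint vector (length `input_dim`), a numeric matrix of
#'   row vectors, or a fingerprint tibble.
#' @export
reconstruction_mse <- function(model, v, normalize = TRUE) {
  stopifnot(inherits(model, "cytofp_autoencoder"))
  X <- if (is.data.frame(v)) fp_values(v) else if (is.null(dim(v))) {
    matrix(as.numeric(v), 1)
  } else {
    as.matrix(v)
  }
  assert_that(ncol(X) == model$input_dim,
              sprintf("Vector length %d does not match input_dim %d.",
                      ncol(X), model$input_dim))
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  Xhat <- mlp_predict(model$net, Xs, output = "linear")
  mse_between(Xs, Xhat, normalize = normalize)
}

#' Score samples and flag outliers
#'
#' Vector-level reconstruction MSEs are aggregated per `sample_id` by the
#' chosen statistic; a sample is an outlier when its score strictly
#' exceeds the threshold. A sample score exactly at the threshold is not
#' an outlier.
#'
#' @param model A trained `cytofp_autoencoder`.
#' @param ds Fingerprint tibble to score.
#' @param threshold Nonnegative MSE threshold. MSE thresholds are
#'   study-specific (they depend on the data scale and experiment);
#'   see [training_threshold()] for the default 95th-percentile policy.
#' @param aggregate `"mean"` (default), `"median"` or `"max"` over a
#'   sample's vector MSEs.
#' @return An `anomaly_report`: list with `per_sample` (tibble ordered by
#'   `sample_id`: `sample_id, n_vectors, mse, is_outlier`), `threshold`,
#'   `aggregate` and `per_vector` (tibble of vector-level MSEs).
#' @export
score_samples <- function(model, ds, threshold,
                          aggregate = c("mean", "median", "max")) {
  aggregate <- match.arg(aggregate)
  assert_that(nrow(ds) > 0, "Cannot score an empty dataset.")
  assert_that(is.numeric(threshold) && length(threshold) == 1 &&
                threshold >= 0, "`threshold` must be a nonnegative number.")
  agg_fun <- switch(aggregate, mean = mean, median = stats::median,
                    max = max)
  mse <- reconstruction_mse(model, ds)
  per_vector <- tibble(sample_id = ds$sample_id,
                       chunk_index = ds$chunk_index, mse = mse)
  per_sample <- per_vector |>
    group_by(.data$sample_id) |>
    summarise(n_vectors = dplyr::n(), mse = agg_fun(.data$mse),
              .groups = "drop") |>
    arrange(.data$sample_id) |>
    mutate(is_outlier = .data$mse > threshold)
  structure(list(per_sample = per_sample, threshold = threshold,
                 aggregate = aggregate, per_vector = per_vector),
            class = "anomaly_report")
}

#' Threshold from training-sample scores
#'
#' The default outlier-threshold policy: the `q`-quantile (default 95th
#' percentile) of the training samples' aggregated MSE scores, so at most
#' about `1 - q` of in-distribution samples are flagged.
#'
#' @param model A trained `cytofp_autoencoder`.
#' @param train Training fingerprint tibble.
#' @param q Quantile (default 0.95).
#' @param aggregate Sample aggregation statistic, as in [score_samples()].
#' @return Numeric threshold.
#' @export
training_threshold <- function(model, train, q = 0.95,
                               aggregate = c("mean", "median", "max")) {
  aggregate <- match.arg(aggregate)
  rep0 <- score_samples(model, train, threshold = Inf,
                        aggregate = aggregate)
  unname(quantile(rep0$per_sample$mse, q, type = 7))
}

#' @export
print.anomaly_report <- function(x, ...) {
  cat(sprintf(
    "<anomaly_report> %d samples, threshold %.4g (%s aggregation), %d outlier(s)\n",
    nrow(x$per_sample), x$threshold, x$aggregate,
    sum(x$per_sample$is_outlier)))
  print(x$per_sample, ...)
  invisible(x)
}

#' Save / load a trained autoencoder
#'
#' The checkpoint stores the named weight matrices, standardization
#' parameters and config; a load/save round trip reproduces scores
#' bit-for-bit.
#'
#' @param model A `cytofp_autoencoder`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` / the restored model.
#' @export
save_autoencoder <- function(model, path) {
  stopifnot(inherits(model, "cytofp_autoencoder"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_autoencoder
#' @export
load_autoencoder <- function(path) {
  structure(readRDS(path), class = "cytofp_autoencoder")
}

#' Write an anomaly report as CSV
#'
#' @param report An `anomaly_report`.
#' @param path CSV path; columns `sample_id, mse, threshold, is_outlier`.
#' @return `path`, invisibly.
#' @export
write_anomaly_report <- function(report, path) {
  stopifnot(inherits(report, "anomaly_report"))
  out <- mutate(report$per_sample, threshold = report$threshold) |>
    select("sample_id", "mse", "threshold", "is_outlier")
  readr::write_csv(out, path)
  invisible(path)
}
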