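#' Stratified fold assignment
#'
#' Assigns each row a fold index in `1..k`, stratified by label: within
#' each label the (seeded, shuffled) rows are dealt round-robin, so folds
#' are disjoint, cover the data exactly once, and per-label fold sizes
#' differ by at most one.
#'
#' @param labels Character vector of class labels.
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return Integer vector of fold indices, parallel to `labels`.
#' @export
stratified_folds <- function(labels, k, seed = 1) {
  assert_that(k >= 2, "`k` must be >= 2.")
  fold <- integer(length(labels))
  with_seed(seed, {
    for (lab in sort(unique(labels))) {
      rows <- which(labels == lab)
      assert_that(length(rows) >= k,
                  sprintf("Label '%s' has %d vectors; %d folds need >= %d.",
                          lab, length(rows), k, k),
                  class = "cytofp_cv_error")
      fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
    }
  })
  fold
}

# expand a grid: either a named list of atomic vectors (crossed) or an
# explicit list of hyperparameter lists
expand_hp_grid <- function(grid) {
  assert_that(length(grid) > 0, "Hyperparameter grid is empty.",
              class = "cytofp_cv_error")
  if (!is.null(names(grid)) && all(nzchar(names(grid))) &&
      all(vapply(grid, is.atomic, logical(1)))) {
    df <- expand.grid(grid, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  } else {
    grid
  }
}

cv_fold_accuracy <- function(algorithm, hp, ds, fold, holdout, seed) {
  spec <- model_spec(algorithm, hp, seed = seed)
  m <- train_classifier(spec, ds[fold != holdout, , drop = FALSE])
  accuracy(m, ds[fold == holdout, , drop = FALSE])$overall
}

pick_best <- function(means, sds) {
  # best mean accuracy; ties -> smaller sd -> earlier grid order
  order(-means, sds, seq_along(means))[1]
}

new_cv_result <- function(per_fold, best_hp, algorithm) {
  structure(list(per_fold = per_fold,
                 mean = mean(per_fold$accuracy),
                 sd = sd(per_fold$accuracy),
                 best_hyperparameters = best_hp,
                 algorithm = algorithm),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: mean accuracy %.4f (sd %.4f) over %d folds\n",
              x$algorithm, x$mean, x$sd, nrow(x$per_fold)))
  invisible(x)
}

#' Nested cross-validated grid search
#'
#' Hyperparameter selection without selection bias: for each of
#' `outer_folds` stratified outer partitions, an inner `inner_folds`-fold
#' CV over the grid (on the outer-training part only) picks the grid
#' point with the best inner mean accuracy (ties: smaller inner sd, then
#' grid order); that point is refit on the outer-training part and scored
#' on the held-out outer fold, which never touched selection. The
#' reported best hyperparameters are the grid point with the highest mean
#' outer-fold accuracy among its selections (same tie-breaking).
#'
#' @param algorithm `"GB"`, `"NB"`, `"DRF"` or `"DL"`.
#' @param grid Either a named list of atomic vectors (crossed into a
#'   grid) or an explicit list of hyperparameter lists.
#' @param train Labelled fingerprint tibble.
#' @param outer_folds,inner_folds Fold counts (defaults 4 and 3).
#' @param seed RNG seed.
#' @return List with `best_spec` (a [model_spec()]) and `cv` (a
#'   `cv_result` whose `per_fold` tibble holds each outer fold's accuracy
#'   and selected grid point).
#' @export
nested_cv_grid_search <- function(algorithm, grid, train, outer_folds = 4,
                                  inner_folds = 3, seed = 1) {
  assert_that(outer_folds >= 2 && inner_folds >= 2,
              "Fold counts must be >= 2.", class = "cytofp_cv_error")
  points <- expand_hp_grid(grid)
  outer <- stratified_folds(train$label, outer_folds,
                            seed = derive_seed(seed, "outer"))
  fold_acc <- numeric(outer_folds)
  fold_choice <- integer(outer_folds)
  for (of in seq_len(outer_folds)) {
    inner_ds <- train[outer != of, , drop = FALSE]
    inner <- stratified_folds(inner_ds$label, inner_folds,
                              seed = derive_seed(seed, "inner", of))
    means <- sds <- numeric(length(points))
    for (g in seq_along(points)) {
      accs <- vapply(seq_len(inner_folds), function(inf) {
        cv_fold_accuracy(algorithm, points[[g]], inner_ds, inner, inf,
                         seed = derive_seed(seed, "fit", of, inf, g))
      }, numeric(1))
      means[g] <- mean(accs)
      sds[g] <- sd(accs)
    }
    fold_choice[of] <- pick_best(means, sds)
    fold_acc[of] <- cv_fold_accuracy(
      algorithm, points[[fold_choice[of]]], train, outer, of,
      seed = derive_seed(seed, "outer-fit", of))
  }
  cand <- sort(unique(fold_choice))
  cand_mean <- vapply(cand, function(g) mean(fold_acc[fold_choice == g]),
                      numeric(1))
  cand_sd <- vapply(cand, function(g) {
    a <- fold_acc[fold_choice == g]
    if (length(a) > 1) sd(a) else Inf
  }, numeric(1))
  best <- cand[pick_best(cand_mean, cand_sd)]
  per_fold <- tibble(fold = seq_len(outer_folds), accuracy = fold_acc,
                     grid_point = fold_choice)
  list(best_spec = model_spec(algorithm, points[[best]], seed = seed),
       cv = new_cv_result(per_fold, points[[best]], algorithm))
}

#' k-fold stability check
#'
#' Per-fold accuracies over a stratified `k`-fold partition for one fixed
#' model spec — an overfitting check: a stable model's fold accuracies
#' should track its held-out test accuracy.
#'
#' @param spec A [model_spec()].
#' @param ds Labelled fingerprint tibble.
#' @param k Number of folds (default 5).
#' @param seed RNG seed.
#' @return A `cv_result`.
#' @export
kfold_stability <- function(spec, ds, k = 5, seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  fold <- stratified_folds(ds$label, k, seed = derive_seed(seed, "kfold"))
  accs <- vapply(seq_len(k), function(f) {
    cv_fold_accuracy(spec$algorithm, spec$hyperparameters, ds, fold, f,
                     seed = derive_seed(seed, "kfold-fit", f))
  }, numeric(1))
  new_cv_result(tibble(fold = seq_len(k), accuracy = accs),
                spec$hyperparameters, spec$algorithm)
}
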