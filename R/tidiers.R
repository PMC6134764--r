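#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname score_samples
#' @param x An `anomaly_report`.
#' @param ... Unused.
#' @export
tidy.anomaly_report <- function(x, ...) x$per_sample

#' @rdname score_samples
#' @export
glance.anomaly_report <- function(x, ...) {
  tibble(threshold = x$threshold, aggregate = x$aggregate,
         n_samples = nrow(x$per_sample),
         n_outliers = sum(x$per_sample$is_outlier))
}

#' @rdname one_vs_all_roc
#' @param x A `roc_result`.
#' @param ... Unused.
#' @export
tidy.roc_result <- function(x, ...) {
  tibble(class = x$class_label, threshold = x$thresholds, fpr = x$fpr,
         tpr = x$tpr)
}

#' @rdname one_vs_all_roc
#' @export
glance.roc_result <- function(x, ...) {
  tibble(class = x$class_label, auc = x$auc,
         n_thresholds = length(x$thresholds))
}

#' @rdname kfold_stability
#' @param x A `cv_result`.
#' @param ... Unused.
#' @export
tidy.cv_result <- function(x, ...) x$per_fold

#' @rdname kfold_stability
#' @export
glance.cv_result <- function(x, ...) {
  tibble(algorithm = x$algorithm, mean_accuracy = x$mean,
         sd_accuracy = x$sd, n_folds = nrow(x$per_fold))
}

#' @rdname gedeon_importance
#' @param x An `importance_report`.
#' @param ... Unused.
#' @export
tidy.importance_report <- function(x, ...) x$per_variable

#' @rdname gedeon_importance
#' @export
glance.importance_report <- function(x, ...) {
  tidyr::pivot_wider(x$per_block, names_from = "channel",
                     values_from = "score")
}

#' @rdname train_classifier
#' @param x A `cytofp_classifier`.
#' @param ... Unused.
#' @export
glance.cytofp_classifier <- function(x, ...) {
  tibble(algorithm = x$algorithm, n_features = x$n_features,
         n_classes = length(x$labels), seed = x$spec$seed)
}
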