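#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline geom_line
#'   geom_abline geom_col geom_boxplot labs theme_bw facet_wrap
#' @export
ggplot2::autoplot

#' Plot an anomaly report
#'
#' Per-sample reconstruction MSE with the outlier threshold as a
#' horizontal line — the standard anomaly-screen display.
#'
#' @param object An `anomaly_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.anomaly_report <- function(object, ...) {
  ggplot(object$per_sample,
         aes(x = .data$sample_id, y = .data$mse,
             colour = .data$is_outlier)) +
    geom_point(size = 2) +
    geom_hline(yintercept = object$threshold, colour = "red") +
    labs(x = "sample", y = "reconstruction MSE", colour = "outlier") +
    theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a one-vs-all ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$fpr, y = .data$tpr)) +
    geom_line() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey50") +
    labs(title = sprintf("%s vs rest (AUC = %.4f)", object$class_label,
                         object$auc),
         x = "false positive rate", y = "true positive rate") +
    theme_bw()
}

#' Plot variable importance by channel block
#'
#' @param object An `importance_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.importance_report <- function(object, ...) {
  ggplot(object$per_block, aes(x = .data$channel, y = .data$score)) +
    geom_col() +
    labs(x = "channel block", y = "summed importance") +
    theme_bw()
}

#' Box plots of per-class classification probabilities
#'
#' One panel per true class; boxes are the five-number summaries of each
#' class's predicted probability.
#'
#' @param summary Output of [class_probability_summary()].
#' @return A ggplot.
#' @export
plot_class_probabilities <- function(summary) {
  ggplot(summary,
         aes(x = .data$class, ymin = .data$min, lower = .data$q1,
             middle = .data$median, upper = .data$q3, ymax = .data$max)) +
    geom_boxplot(stat = "identity") +
    facet_wrap(~truth) +
    labs(x = "predicted class", y = "classification probability") +
    theme_bw()
}
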