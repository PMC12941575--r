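#' Plot per-epoch learning curves
#'
#' @param history the data frame returned in `train_classifier()$history`.
#' @return A ggplot object.
#' @export
plot_history <- function(history) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_history requires ggplot2", call. = FALSE)
  }
  long <- rbind(
    data.frame(epoch = history$epoch, value = history$train_loss,
               metric = "loss", split = "train"),
    data.frame(epoch = history$epoch, value = history$val_loss,
               metric = "loss", split = "validation"),
    data.frame(epoch = history$epoch, value = history$train_accuracy,
               metric = "accuracy", split = "train"),
    data.frame(epoch = history$epoch, value = history$val_accuracy,
               metric = "accuracy", split = "validation"))
  ggplot2::ggplot(long, ggplot2::aes(x = epoch, y = value,
                                     colour = split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the ROC curve of an evaluation report
#'
#' @param report an [compute_metrics()] result.
#' @return A ggplot object.
#' @export
plot_roc <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_roc requires ggplot2", call. = FALSE)
  }
  ggplot2::ggplot(report$roc_points,
                  ggplot2::aes(x = fpr, y = tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::annotate("text", x = 0.75, y = 0.1,
                      label = sprintf("AUC = %.3f", report$auc)) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}
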