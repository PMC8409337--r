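#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Training curves for a fit
#'
#' Loss per epoch, plus the validation metrics when a validation set was
#' monitored during training.
#'
#' @param object An `ssmfn_fit`.
#' @param metrics Which history columns to draw (default: all present).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ssmfn_fit <- function(object,
                               metrics = c("loss", "acc", "mcc", "auc"),
                               ...) {
  h <- object$history
  if (nrow(h) == 0) {
    rlang::abort("fit has no training history", class = "ssmfn_plot_error")
  }
  keep <- intersect(metrics, names(h))
  long <- tidyr::pivot_longer(h[, c("epoch", keep)], -"epoch",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = paste0("Training history (", object$variant, ")"))
}

#' ROC curve from labels and scores
#'
#' @param truth Binary labels (0/1).
#' @param scores Continuous positive-class scores.
#' @return A ggplot of the ROC curve with the AUC in the subtitle.
#' @export
plot_roc <- function(truth, scores) {
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(truth[ord] == 1)
  fp <- cumsum(truth[ord] == 0)
  d <- tibble::tibble(
    fpr = c(0, fp / max(1, sum(truth == 0))),
    tpr = c(0, tp / max(1, sum(truth == 1)))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = "ROC curve",
                  subtitle = sprintf("AUC = %.4f", roc_auc(truth, scores)))
}

#' Seed-averaged metric comparison across experiment cells
#'
#' @param object An `ssmfn_result`.
#' @param metric One of `"acc"`, `"f1"`, `"sens"`, `"spec"`, `"mcc"`, `"auc"`.
#' @param ... Unused.
#' @return A ggplot of per-model bars faceted by evaluation set.
#' @export
autoplot.ssmfn_result <- function(object, metric = "mcc", ...) {
  agg <- glance(object)
  col <- paste0(metric, "_mean")
  stopifnot(col %in% names(agg))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$model, y = .data[[col]])) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~evaluation_set) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
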