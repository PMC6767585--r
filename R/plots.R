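#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' ROC plot with the line of equality
#'
#' One-vs-rest ROC curves per density state (x = 1 - specificity,
#' y = sensitivity) with the diagonal random-chance line from (0,0) to
#' (1,1); curves below it are non-informative.
#'
#' @param object A `weed_roc` from [roc_ovr()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.weed_roc <- function(object, ...) {
  labs <- object$auc |>
    dplyr::filter(.data$scorable) |>
    dplyr::mutate(lab = sprintf("%s (AUC %.2f)", .data$state, .data$auc))
  curves <- dplyr::left_join(object$curves,
                             labs[, c("state", "lab")],
                             by = c("state"))
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               colour = .data$lab)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - Specificity", y = "Sensitivity",
                  colour = NULL,
                  title = sprintf("Macro AUC %.3f", object$macro_auc)) +
    ggplot2::theme_minimal()
}

#' Per-field out-of-sample AUC plot
#'
#' @param object A `lofo_result` from [run_lofo()].
#' @param ... Unused.
#' @return A ggplot of each field's leave-one-field-out macro AUC.
#' @export
autoplot.lofo_result <- function(object, ...) {
  dat <- dplyr::filter(object, !is.na(.data$macro_auc))
  dat$field_rank <- rank(dat$field_id, ties.method = "first")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$field_rank,
                                    y = .data$macro_auc)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Field", y = "Out-of-sample macro AUC") +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heat map
#'
#' @param cm A confusion matrix (observed rows x predicted columns).
#' @return A ggplot tile map with counts printed in each cell.
#' @export
plot_confusion <- function(cm) {
  df <- as.data.frame(as.table(cm))
  names(df) <- c("observed", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted,
                                   y = .data$observed,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Predicted", y = "Observed") +
    ggplot2::theme_minimal()
}

#' Index-raster image
#'
#' @param object An `index_raster`.
#' @param ... Unused.
#' @return A ggplot raster image of the index values (NA pixels blank).
#' @export
autoplot.index_raster <- function(object, ...) {
  v <- unclass(object)
  df <- tidyr::expand_grid(row = seq_len(nrow(v)),
                           col = seq_len(ncol(v)))
  df$value <- v[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = attr(object, "index"), x = NULL, y = NULL) +
    ggplot2::theme_void()
}
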