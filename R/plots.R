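#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of an intersubject model matrix
#'
#' Subjects are ordered as in the model; sort the cohort by score before
#' building the model to obtain the familiar wedge-shaped AnnaK display.
#'
#' @param object An [isrsa_model].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.isrsa_model <- function(object, ...) {
  n <- length(object$subjects)
  df <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n))
  df$dissimilarity <- object$matrix[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$dissimilarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste("Intersubject model:", object$kind),
                  x = "subject", y = "subject") +
    ggplot2::theme_minimal()
}

#' Axial montage of a searchlight map
#'
#' @param object A `searchlight_map`.
#' @param statistic `"rho"` (default) or `"p"`.
#' @param ... Unused.
#' @return A ggplot faceted by axial slice.
#' @exportS3Method ggplot2::autoplot
autoplot.searchlight_map <- function(object, statistic = c("rho", "p"), ...) {
  statistic <- match.arg(statistic)
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data[[statistic]])) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~z) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "grey90",
                                  high = "red", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste(object$condition, "x", object$model_kind),
                  subtitle = paste0("B = ", object$B)) +
    ggplot2::theme_minimal()
}

#' Cluster-extent overview plot
#'
#' @param object An `isrsa_clusters` tibble.
#' @param ... Unused.
#' @return A ggplot of cluster extents by model and condition.
#' @exportS3Method ggplot2::autoplot
autoplot.isrsa_clusters <- function(object, ...) {
  df <- tibble::as_tibble(object[, setdiff(names(object), "voxels")])
  if (nrow(df) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "No clusters above threshold") +
             ggplot2::theme_minimal())
  }
  df$id <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$id), y = .data$k,
                                   fill = .data$sign,
                                   alpha = .data$survives_fdr)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = attr(object, "thresholds")$k_min,
                        linetype = 2) +
    ggplot2::facet_grid(model ~ condition, scales = "free_x",
                        space = "free_x") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.4)) +
    ggplot2::labs(x = "cluster", y = "extent (voxels)") +
    ggplot2::theme_minimal()
}
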