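# Optional figure conveniences (ggplot2, Suggests). The numerical CSV
# exporters in io.R are the contract; these are viewing aids.

.needGgplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package")
}

#' Heatmap of attributions across instances
#'
#' Instances on the y axis (ordered by the absolute attribution of
#' `orderBy`, largest at the top), features on the x axis, fill = value.
#'
#' @param attrs list of [Attribution-class] objects (one method).
#' @param orderBy feature whose absolute value orders the rows
#'   (default `"11685"`; `NULL` keeps input order).
#' @return A ggplot object.
#' @export
plotAttributionHeatmap <- function(attrs, orderBy = "11685") {
  .needGgplot()
  df <- attributionsAsDataFrame(attrs)
  if (!is.null(orderBy) && orderBy %in% df$feature) {
    key <- df[df$feature == orderBy, c("instance_id", "phi")]
    lv <- key$instance_id[order(abs(key$phi))]
    df$instance_id <- factor(df$instance_id, levels = lv)
  }
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data[["feature"]], y = .data[["instance_id"]],
      fill = .data[["phi"]]
    )
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "firebrick", mid = "white", high = "steelblue", midpoint = 0
    ) +
    ggplot2::labs(
      x = "feature", y = "instance",
      fill = unique(df$method)[1L]
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of one interaction matrix
#'
#' @param mat an [InteractionMatrix-class]; undefined diagonals are left
#'   blank.
#' @return A ggplot object.
#' @export
plotInteractionHeatmap <- function(mat) {
  .needGgplot()
  df <- interactionsAsDataFrame(mat)
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data[["feature_j"]], y = .data[["feature_i"]],
      fill = .data[["value"]]
    )
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "firebrick", mid = "white", high = "steelblue", midpoint = 0
    ) +
    ggplot2::labs(
      x = "feature j", y = "feature i", fill = mat@metric,
      title = paste(mat@metric, "for", mat@instanceId)
    ) +
    ggplot2::theme_minimal()
}
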