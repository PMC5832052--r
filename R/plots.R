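#' Display one axial slice with optional mask overlays
#'
#' @param volume A [ct_volume()].
#' @param slice Slice index.
#' @param masks Named list of [binary_mask()]s to overlay (colour per name).
#' @param window HU display window (default `c(-1000, 100)`).
#' @return A ggplot object.
#' @export
plot_slice <- function(volume, slice, masks = list(),
                       window = c(-1000, 100)) {
  stopifnot(inherits(volume, "ct_volume"))
  img <- volume$voxels[slice, , ]
  df <- tidyr::expand_grid(row = seq_len(nrow(img)),
                           col = seq_len(ncol(img)))
  df$hu <- as.numeric(img[as.matrix(df[, c("row", "col")])])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$hu)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = window, oob = scales_squish) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "HU", title = sprintf("%s, slice %d",
                                               volume$scan_id, slice)) +
    ggplot2::theme_minimal()
  pal <- c("#e41a1c", "#377eb8", "#4daf4a", "#ff7f00")
  k <- 0
  for (nm in names(masks)) {
    k <- k + 1
    mb <- mask_bits(masks[[nm]])[slice, , ]
    idx <- which(mb, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    od <- tibble(row = idx[, 1], col = idx[, 2])
    p <- p + ggplot2::geom_tile(data = od, fill = pal[(k - 1) %% 4 + 1],
                                alpha = 0.35)
  }
  p
}

# minimal squish (avoid a scales dependency for one out-of-bounds rule)
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}

#' ROC curve of a classifier evaluation
#'
#' @param object A `pq_eval` from [evaluate_classifier()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pq_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
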