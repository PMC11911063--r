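# ggplot2 visualisations for the pipeline's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

image_raster_df <- function(image) {
  tibble::tibble(
    x = rep(seq_len(ncol(image)) - 1, each = nrow(image)),
    y = rep(seq_len(nrow(image)) - 1, times = ncol(image)),
    intensity = as.vector(image)
  )
}

#' Plot a phantom case with its truth landmarks
#'
#' @param object A `phantom_case`.
#' @param landmarks Draw the truth landmarks (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot (y axis reversed so cranial is up).
#' @export
autoplot.phantom_case <- function(object, landmarks = TRUE, ...) {
  df <- image_raster_df(object$image)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px, caudal down)")
  if (landmarks) {
    lm_long <- tidyr::pivot_longer(
      object$truth_landmarks,
      cols = dplyr::all_of(landmark_cols()),
      names_to = c("landmark", "axis"), names_sep = "_", values_to = "value"
    ) |>
      tidyr::pivot_wider(names_from = "axis", values_from = "value")
    p <- p + ggplot2::geom_point(
      data = lm_long, ggplot2::aes(colour = .data$landmark), size = 0.8
    ) + ggplot2::labs(colour = "landmark")
  }
  p
}

#' Plot a fitted spinal curve with inlier/outlier centers
#'
#' @param object A `spinal_curve`.
#' @param ... Unused.
#' @return A ggplot of the detected centers, coloured by inlier status, with
#'   the fitted polynomial `x = f(y)` overlaid.
#' @export
autoplot.spinal_curve <- function(object, ...) {
  ctr <- dplyr::mutate(object$centers,
                       status = ifelse(object$inlier_flags, "inlier", "outlier"))
  ys <- seq(min(ctr$y), max(ctr$y), length.out = 200)
  curve_df <- tibble::tibble(y = ys, x = predict(object, ys))
  ggplot2::ggplot(ctr, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(data = curve_df, colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status), size = 2) +
    ggplot2::scale_colour_manual(values = c(inlier = "black", outlier = "red")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px, caudal down)", colour = NULL,
                  title = sprintf("Spinal curve (degree %d), %d/%d inliers",
                                  object$degree, sum(object$inlier_flags),
                                  length(object$inlier_flags)))
}

#' Bland-Altman plot
#'
#' Pair means against differences, with the mean difference (solid) and the
#' limits of agreement (dashed); points shaded by QM status when bins were
#' supplied.
#'
#' @param object A `bland_altman`.
#' @param ... Unused.
#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- object$data
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$mean, .data$diff))
  p <- if (all(is.na(df$bin))) p + ggplot2::geom_point(alpha = 0.5) else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$bin), alpha = 0.7) +
      ggplot2::labs(colour = "QM status")
  p +
    ggplot2::geom_hline(yintercept = object$md, linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = object$loa, linetype = "dashed") +
    ggplot2::labs(
      x = "mean of pair", y = "difference (a - b)",
      title = sprintf("MD = %.4f, LOA = [%.4f, %.4f]",
                      object$md, object$loa[["lower"]], object$loa[["upper"]])
    )
}
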