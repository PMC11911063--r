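# End-to-end orchestration: detect -> curve-filter -> crop -> landmarks ->
# morphometry on a single radiograph.

#' Detect vertebral bodies and reject off-curve false positives
#'
#' Stage 1 of the pipeline: segment the image into instance masks, reduce
#' each to its center of gravity, fit the RANSAC spinal curve to all centers
#' and discard centers deviating from it.
#'
#' @param image Grayscale matrix.
#' @param seg_backend Passed to [segment_vertebrae()].
#' @param threshold,min_area Reference-backend parameters, see
#'   [segment_vertebrae()].
#' @param max_degree,residual_threshold,n_iter,seed Curve-fit parameters,
#'   see [fit_spinal_curve()].
#' @return A `vm_detection` list: `centers` (all centroids), `curve`
#'   (`spinal_curve`, `NULL` when fewer than 2 centers), `retained`
#'   (on-curve centers, cranial to caudal).
#' @export
detect_vertebrae <- function(image, seg_backend = "threshold", threshold = NULL,
                             min_area = 20, max_degree = 4,
                             residual_threshold = NULL, n_iter = 500,
                             seed = 1L) {
  masks <- segment_vertebrae(image, backend = seg_backend,
                             threshold = threshold, min_area = min_area)
  centers <- mask_centroids(masks)
  curve <- NULL
  retained <- centers
  if (nrow(centers) >= 2) {
    curve <- fit_spinal_curve(centers, max_degree = max_degree,
                              residual_threshold = residual_threshold,
                              n_iter = n_iter, seed = seed)
    retained <- filter_centers(centers, curve)
  }
  retained <- dplyr::arrange(retained, .data$y)
  structure(list(centers = centers, curve = curve, retained = retained,
                 masks = masks),
            class = "vm_detection")
}

#' @export
print.vm_detection <- function(x, ...) {
  cat(sprintf("<vm_detection> %d center(s) detected, %d retained on the spinal curve\n",
              nrow(x$centers), nrow(x$retained)))
  invisible(x)
}

#' Measure a radiograph end to end
#'
#' Runs the full two-stage pipeline: detection with spinal-curve filtering,
#' fixed-size crops around each retained center, landmark prediction on each
#' crop, mapping back to image coordinates, and quantitative morphometry.
#'
#' @param image Grayscale matrix.
#' @param lm_backend Landmark backend, see [predict_landmarks()] and
#'   [landmark_backend_oracle()].
#' @param side Crop side in pixels (default 224).
#' @param pad_value Padding intensity for out-of-image crop regions.
#' @param ... Passed to [detect_vertebrae()].
#' @return Landmark + morphometry tibble, one row per retained vertebra,
#'   cranial to caudal, with columns `x`, `y` (detected center), the 12
#'   landmark coordinates (image frame), heights, ratios, `collapse_pct`
#'   and `qm_status`.
#' @export
measure_radiograph <- function(image, lm_backend, side = 224, pad_value = NULL,
                               ...) {
  det <- detect_vertebrae(image, ...)
  if (nrow(det$retained) == 0) {
    return(vertebra_morphometry(
      dplyr::bind_cols(tibble::tibble(x = numeric(0), y = numeric(0),
                                      frame = character(0)),
                       tibble::as_tibble(stats::setNames(
                         rep(list(numeric(0)), 12), landmark_cols())))
    ))
  }
  rows <- purrr::map(seq_len(nrow(det$retained)), function(i) {
    cen <- det$retained[i, ]
    cw <- crop_vertebra(image, cen, side = side, pad_value = pad_value)
    lms <- predict_landmarks(cw$crop, lm_backend, cw$window)
    lms <- to_image_coords(lms, cw$window)
    dplyr::bind_cols(tibble::tibble(x = cen$x, y = cen$y), lms)
  })
  vertebra_morphometry(dplyr::bind_rows(rows))
}

#' Label measured vertebrae from a reference table
#'
#' Assigns each predicted/measured row the identity columns (`case_id`,
#' `image_id`, `level`, `region`) of the reference vertebra whose landmark
#' center is nearest to the row's landmark center. Convenience for pairing
#' phantom-study output with ground truth in [evaluate_pipeline()].
#'
#' @param pred Landmark table (image frame), e.g. from [measure_radiograph()].
#' @param ref Reference landmark table with identity columns.
#' @return `pred` with the reference identity columns prepended.
#' @export
label_by_nearest <- function(pred, ref) {
  check_landmark_tbl(pred, arg = "pred")
  check_landmark_tbl(ref, arg = "ref")
  if (nrow(ref) == 0) abort_validation("`ref` is empty.")
  pc <- landmark_center(pred)
  rc <- landmark_center(ref)
  idx <- vapply(seq_len(nrow(pc)), function(i) {
    which.min((rc$x - pc$x[i])^2 + (rc$y - pc$y[i])^2)
  }, integer(1))
  id_cols <- intersect(c("case_id", "image_id", "level", "region", "evaluator"),
                       names(ref))
  out <- dplyr::bind_cols(ref[idx, id_cols],
                          pred[setdiff(names(pred), id_cols)])
  tibble::as_tibble(out)
}
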