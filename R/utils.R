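# Shared validation helpers and the landmark-table contract.
#
# Coordinate convention used across the whole package: pixel coordinates,
# 0-based, origin at the top-left of the image, x rightward (columns),
# y downward (cranio-caudal rows). A matrix m[r, c] holds the pixel at
# (x = c - 1, y = r - 1). Intensities are doubles in [0, 1].

#' Names of the six vertebral landmarks
#'
#' Order is fixed everywhere: anterior-upper, anterior-lower, central-upper,
#' central-lower, posterior-upper, posterior-lower. Landmarks are always
#' serialized by name, never by position.
#'
#' @return Character vector of length six.
#' @export
landmark_names <- function() c("AU", "AL", "CU", "CL", "PU", "PL")

#' Coordinate column names of a landmark table
#'
#' @return Character vector `AU_x, AU_y, ..., PL_y` (length 12).
#' @export
landmark_cols <- function() {
  as.vector(t(outer(landmark_names(), c("x", "y"), paste, sep = "_")))
}

vm_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "vm_error"), ...)
}

abort_validation <- function(message, ...) {
  vm_abort(message, "vm_validation_error", ...)
}

abort_io <- function(message, ...) {
  vm_abort(message, "vm_io_error", ...)
}

abort_fit <- function(message, ...) {
  vm_abort(message, "vm_fit_error", ...)
}

# A landmark table is the package's tabular backbone: one row per vertebra,
# coordinate columns named by landmark, a `frame` tag, and optional identity
# columns (case_id, image_id, region, level, evaluator).
check_landmark_tbl <- function(tbl, frame = NULL, arg = "landmarks") {
  if (!is.data.frame(tbl)) {
    abort_validation(sprintf("`%s` must be a data frame with landmark columns.", arg))
  }
  missing <- setdiff(landmark_cols(), names(tbl))
  if (length(missing) > 0) {
    abort_validation(sprintf(
      "`%s` is missing landmark column(s): %s.", arg, paste(missing, collapse = ", ")
    ))
  }
  coords <- as.matrix(tbl[landmark_cols()])
  if (nrow(tbl) > 0 && !all(is.finite(coords))) {
    abort_validation(sprintf("`%s` contains non-finite landmark coordinates.", arg))
  }
  if (!is.null(frame)) {
    if (!"frame" %in% names(tbl)) {
      abort_validation(sprintf("`%s` has no `frame` column (expected \"%s\").", arg, frame))
    }
    if (nrow(tbl) > 0 && !all(tbl$frame == frame)) {
      abort_validation(sprintf(
        "`%s` must be in the \"%s\" frame, got: %s.",
        arg, frame, paste(unique(tbl$frame), collapse = ", ")
      ))
    }
  }
  invisible(tbl)
}

check_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort_validation(sprintf("`%s` must be a numeric matrix (grayscale raster).", arg))
  }
  if (!all(is.finite(image))) {
    abort_validation(sprintf("`%s` contains non-finite intensities.", arg))
  }
  invisible(image)
}

check_number <- function(x, arg, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort_validation(sprintf("`%s` must be a single finite number in [%s, %s].",
                             arg, format(lower), format(upper)))
  }
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(x, y) if (is.null(x)) y else x

# Centre of a landmark set: mean of the six points, row-wise.
landmark_center <- function(tbl) {
  xs <- as.matrix(tbl[paste0(landmark_names(), "_x")])
  ys <- as.matrix(tbl[paste0(landmark_names(), "_y")])
  tibble::tibble(x = rowMeans(xs), y = rowMeans(ys))
}

# Vertebral levels covered by the pipeline, cranial to caudal.
#' Thoracolumbar level vocabulary (T4 to L5)
#'
#' @return Character vector of the 14 levels measured by the pipeline.
#' @export
vertebral_levels <- function() c(paste0("T", 4:12), paste0("L", 1:5))

level_region <- function(level) {
  ifelse(substr(level, 1, 1) == "T", "thoracic", "lumbar")
}
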