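# Stage 2: six-landmark placement on vertebral crops and the crop <-> image
# coordinate mapping.
#
# The landmark head is pluggable: any function (crop, window) -> named
# crop-frame coordinates qualifies; a trained keypoint regressor would be
# one such backend. The reference backend is a truth oracle for phantoms
# that returns the ground-truth landmarks perturbed by seeded Gaussian
# noise of configurable SD — the knob used to study how landmark error
# propagates into height ratios and agreement statistics.

#' Predict the six landmarks on a vertebral crop
#'
#' @param crop Square crop matrix (side x side).
#' @param backend Function `(crop, window) -> ` named numeric vector or
#'   one-row data frame with the 12 coordinate fields `AU_x ... PL_y` in the
#'   crop frame. See [landmark_backend_oracle()].
#' @param window The `crop_window` the crop came from (forwarded to the
#'   backend; oracle backends need it to locate the vertebra).
#' @return One-row landmark table with `frame = "crop"`.
#' @export
predict_landmarks <- function(crop, backend, window = NULL) {
  check_image(crop, "crop")
  if (nrow(crop) != ncol(crop)) abort_validation("`crop` must be square.")
  if (!is.function(backend)) abort_validation("`backend` must be a function.")
  raw <- backend(crop, window)
  if (is.data.frame(raw)) raw <- unlist(raw[1, intersect(landmark_cols(), names(raw))])
  if (!all(landmark_cols() %in% names(raw))) {
    vm_abort("Landmark backend did not return all 12 named coordinates.",
             "vm_backend_error")
  }
  vals <- as.numeric(raw[landmark_cols()])
  side <- nrow(crop)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > side - 1)) {
    vm_abort("Landmark backend returned non-finite or out-of-crop coordinates.",
             "vm_backend_error")
  }
  out <- tibble::as_tibble(as.list(stats::setNames(vals, landmark_cols())))
  out$frame <- "crop"
  out
}

#' Truth-oracle landmark backend for phantom studies
#'
#' Builds a backend that looks up the ground-truth landmark set of the
#' vertebra nearest to the crop-window center, maps it into the crop frame,
#' and adds zero-mean Gaussian noise of the given SD to every coordinate
#' (clamped to the crop bounds). Noise is drawn from a per-vertebra seed, so
#' repeated predictions on the same crop are identical and the whole run is
#' reproducible.
#'
#' @param truth Landmark table in the image frame (e.g.
#'   `phantom_case$truth_landmarks`), or a `phantom_case`.
#' @param noise_sd Noise SD in pixels (0 = exact oracle).
#' @param seed Integer seed for the noise stream.
#' @return A backend function for [predict_landmarks()].
#' @export
landmark_backend_oracle <- function(truth, noise_sd = 0, seed = 1L) {
  if (inherits(truth, "phantom_case")) truth <- truth$truth_landmarks
  check_landmark_tbl(truth, frame = "image", arg = "truth")
  check_number(noise_sd, "noise_sd", lower = 0)
  centers <- landmark_center(truth)
  force(seed)
  function(crop, window) {
    if (is.null(window)) {
      abort_validation("The oracle backend needs the crop window.")
    }
    d2 <- (centers$x - window$center[["x"]])^2 +
          (centers$y - window$center[["y"]])^2
    i <- which.min(d2)
    vals <- unlist(truth[i, landmark_cols()])
    off <- image_to_crop_xy(vals[seq(1, 12, 2)], vals[seq(2, 12, 2)], window)
    vals[seq(1, 12, 2)] <- off$x
    vals[seq(2, 12, 2)] <- off$y
    if (noise_sd > 0) {
      vals <- vals + withr::with_seed(as.integer(seed) + 7919L * i,
                                      stats::rnorm(12, 0, noise_sd))
    }
    side <- nrow(crop)
    stats::setNames(clamp(vals, 0, side - 1), landmark_cols())
  }
}

#' Map crop-frame landmarks back to image coordinates
#'
#' @param landmarks Landmark table with `frame = "crop"`.
#' @param window The `crop_window` used to extract the crop.
#' @return The table with all points offset into the image frame and
#'   `frame = "image"`.
#' @export
to_image_coords <- function(landmarks, window) {
  check_landmark_tbl(landmarks, frame = "crop")
  if (!inherits(window, "crop_window")) {
    abort_validation("`window` must be a crop_window.")
  }
  out <- tibble::as_tibble(landmarks)
  for (nm in landmark_names()) {
    out[[paste0(nm, "_x")]] <- out[[paste0(nm, "_x")]] + window$origin[["x"]]
    out[[paste0(nm, "_y")]] <- out[[paste0(nm, "_y")]] + window$origin[["y"]]
  }
  out$frame <- "image"
  out
}

#' Map image-frame landmarks into a crop's frame
#'
#' Inverse of [to_image_coords()].
#'
#' @inheritParams to_image_coords
#' @export
to_crop_coords <- function(landmarks, window) {
  check_landmark_tbl(landmarks, frame = "image")
  if (!inherits(window, "crop_window")) {
    abort_validation("`window` must be a crop_window.")
  }
  out <- tibble::as_tibble(landmarks)
  for (nm in landmark_names()) {
    out[[paste0(nm, "_x")]] <- out[[paste0(nm, "_x")]] - window$origin[["x"]]
    out[[paste0(nm, "_y")]] <- out[[paste0(nm, "_y")]] - window$origin[["y"]]
  }
  out$frame <- "crop"
  out
}
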