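# Stage 1: instance masks of vertebral bodies and their centers of gravity.
#
# The detector backend is pluggable: any function image -> mask table
# qualifies (a trained instance-segmentation model would be one such
# backend). The reference backend shipped here is a deterministic
# intensity-threshold + connected-component labeler, adequate for phantom
# images where bone is brighter than background.

#' Segment vertebral bodies into instance masks
#'
#' @param image Grayscale matrix, intensities in `[0, 1]`.
#' @param backend `"threshold"` for the reference backend, or a function
#'   `image -> tibble(mask, score, label)` for a custom detector.
#' @param threshold Foreground threshold for the reference backend; `NULL`
#'   picks Otsu's threshold on the image histogram.
#' @param min_area Components smaller than this many pixels are dropped
#'   (speckle suppression).
#' @return Tibble with one row per instance: `mask` (list of logical
#'   matrices), `score` (1.0 for the reference backend, which has no
#'   probabilistic output), `area`, `label` (NA; level labeling from image
#'   content is out of scope). Empty tibble when nothing is found.
#' @export
segment_vertebrae <- function(image, backend = "threshold", threshold = NULL,
                              min_area = 20) {
  check_image(image)
  empty <- tibble::tibble(mask = list(), score = numeric(0),
                          area = integer(0), label = character(0))
  if (length(image) == 0) return(empty)
  if (is.function(backend)) {
    out <- tryCatch(backend(image), error = function(e) {
      vm_abort(sprintf("Segmentation backend failed: %s", conditionMessage(e)),
               "vm_backend_error", parent = e)
    })
    return(tibble::as_tibble(out))
  }
  if (!identical(backend, "threshold")) {
    abort_validation(sprintf("Unknown segmentation backend '%s'.", backend))
  }
  if (diff(range(image)) < 1e-8) return(empty)   # flat image: no foreground
  thr <- threshold %||% EBImage::otsu(EBImage::Image(clamp(image, 0, 1)),
                                      range = c(0, 1))
  bin <- image > thr
  if (!any(bin)) return(empty)
  lab <- EBImage::bwlabel(EBImage::Image(bin))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(image), ncol(image))
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  areas <- tabulate(lab, nbins = max(ids))
  keep <- ids[areas[ids] >= min_area]
  if (length(keep) == 0) return(empty)
  tibble::tibble(
    mask = purrr::map(keep, function(k) lab == k),
    score = 1.0,
    area = as.integer(areas[keep]),
    label = NA_character_
  )
}

#' Center of gravity of a binary mask
#'
#' Arithmetic mean of the foreground pixel coordinates (unweighted: the
#' "center of gravity" is taken on the binary segmentation, not on image
#' intensities).
#'
#' @param mask Logical matrix with at least one `TRUE` pixel.
#' @return Named numeric `c(x = , y = )` in 0-based image coordinates.
#' @export
mask_centroid <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort_validation("`mask` must be a logical matrix.")
  }
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) abort_validation("Cannot take the centroid of an empty mask.")
  c(x = mean(idx[, "col"]) - 1, y = mean(idx[, "row"]) - 1)
}

#' Centers of gravity for a mask table
#'
#' @param masks Tibble from [segment_vertebrae()] (list-column `mask`).
#' @return Tibble with `x`, `y` (0-based image coordinates) and
#'   `source_mask_index`.
#' @export
mask_centroids <- function(masks) {
  if (!is.data.frame(masks) || !"mask" %in% names(masks)) {
    abort_validation("`masks` must be a tibble with a `mask` list-column.")
  }
  if (nrow(masks) == 0) {
    return(tibble::tibble(x = numeric(0), y = numeric(0),
                          source_mask_index = integer(0)))
  }
  cen <- purrr::map(masks$mask, mask_centroid)
  tibble::tibble(
    x = purrr::map_dbl(cen, "x"),
    y = purrr::map_dbl(cen, "y"),
    source_mask_index = seq_len(nrow(masks))
  )
}

#' Apply an ordered list of training-style augmentations
#'
#' The five transform kinds used to augment radiographs at training time,
#' exposed as a reusable preprocessing utility:
#' \describe{
#'   \item{edge}{Unsharp-mask edge enhancement:
#'     `img + amount * (img - gaussian_blur(img, sigma))`, clamped.
#'     Parameters `amount` (default 1), `sigma` (default 1).}
#'   \item{noise}{Additive Gaussian noise, parameter `sd`.}
#'   \item{resize}{Parameter `scale` (isotropic factor) or `size = c(rows, cols)`.}
#'   \item{contrast}{Linear gain about a midpoint:
#'     `clamp(gain * (img - midpoint) + midpoint)`. Parameters `gain`,
#'     `midpoint` (default 0.5).}
#'   \item{rotation}{Parameter `angle` in degrees (0 returns the input
#'     unchanged); output expands to hold the rotated frame, background 0.}
#' }
#'
#' @param image Grayscale matrix.
#' @param ops List of transforms, each `list(kind = ..., <parameters>)`,
#'   applied in order.
#' @param seed Optional seed making stochastic transforms reproducible.
#' @return Transformed matrix.
#' @export
augment_image <- function(image, ops, seed = NULL) {
  check_image(image)
  run <- function() {
    img <- image
    for (op in ops) {
      kind <- op$kind %||% "<missing>"
      img <- switch(kind,
        edge = {
          amount <- op$amount %||% 1; sigma <- op$sigma %||% 1
          blur <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma))
          clamp(img + amount * (img - blur), 0, 1)
        },
        noise = {
          sd <- op$sd %||% abort_validation("noise transform needs `sd`.")
          clamp(img + matrix(stats::rnorm(length(img), 0, sd),
                             nrow(img), ncol(img)), 0, 1)
        },
        resize = {
          size <- op$size %||% round(dim(img) * op$scale %||%
            abort_validation("resize transform needs `scale` or `size`."))
          as.matrix(EBImage::resize(EBImage::Image(img), w = size[1], h = size[2]))
        },
        contrast = {
          gain <- op$gain %||% abort_validation("contrast transform needs `gain`.")
          mid <- op$midpoint %||% 0.5
          clamp(gain * (img - mid) + mid, 0, 1)
        },
        rotation = {
          angle <- op$angle %||% abort_validation("rotation transform needs `angle`.")
          if (angle %% 360 == 0) img else
            as.matrix(EBImage::rotate(EBImage::Image(img), angle, bg.col = 0))
        },
        abort_validation(sprintf("Unknown transform kind '%s'.", kind))
      )
    }
    img
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
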