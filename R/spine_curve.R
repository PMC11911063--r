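# RANSAC polynomial fit to detected vertebral centers, outlier rejection,
# and fixed-size crop extraction.
#
# The spinal curve is parameterized as x = f(y): a vertically running spine
# is single-valued in y (cranio-caudal) but not in x. Candidate models of
# each degree d in 1..min(max_degree, n - 1) are fitted from minimal samples
# of d + 1 centers; the model maximizing the inlier count wins, with ties
# broken by lower degree, then lower sum of squared inlier residuals.
# Coefficients are refit by least squares on the consensus inliers.

poly_fit <- function(x, y, degree) {
  V <- outer(y, 0:degree, `^`)
  qr_ <- qr(V)
  if (qr_$rank < degree + 1) return(NULL)     # degenerate (duplicate y etc.)
  as.numeric(qr.coef(qr_, x))
}

#' Fit the spinal curve to detected centers with RANSAC
#'
#' @param centers Data frame with columns `x`, `y` (0-based image pixels),
#'   at least two rows.
#' @param max_degree Maximum polynomial degree (capped at 4 and at `n - 1`).
#' @param residual_threshold Inlier residual bound `|x - f(y)|` in pixels.
#'   Default: half the median nearest-neighbour spacing of the centers, a
#'   scale-free notion of "deviating significantly" that adapts to image
#'   resolution.
#' @param n_iter RANSAC iterations per degree. When the number of minimal
#'   samples of a degree is no larger than `n_iter`, all of them are
#'   enumerated instead (exhaustive, hence deterministic regardless of seed).
#' @param seed Seed for the sampling iterations.
#' @return A `spinal_curve` object: `degree`, `coeffs` (increasing powers of
#'   y), `inlier_flags`, `residuals`, `residual_threshold`, plus the inputs.
#' @examples
#' ctr <- tibble::tibble(y = seq(0, 90, by = 10))
#' ctr$x <- 0.01 * ctr$y^2 + 2
#' fit_spinal_curve(ctr)
#' @export
fit_spinal_curve <- function(centers, max_degree = 4, residual_threshold = NULL,
                             n_iter = 500, seed = 1L) {
  centers <- tibble::as_tibble(centers)
  if (!all(c("x", "y") %in% names(centers))) {
    abort_validation("`centers` needs numeric columns `x` and `y`.")
  }
  n <- nrow(centers)
  if (n < 2) abort_validation("Need at least 2 centers to fit the spinal curve.")
  x <- centers$x; y <- centers$y
  if (is.null(residual_threshold)) {
    d <- as.matrix(stats::dist(cbind(x, y)))
    diag(d) <- Inf
    residual_threshold <- 0.5 * stats::median(apply(d, 1, min))
  }
  check_number(residual_threshold, "residual_threshold", lower = 0)
  degrees <- seq_len(min(max_degree, 4, n - 1))

  better <- function(cand, best) {
    if (is.null(cand)) return(best)
    if (is.null(best) ||
        cand$n_in > best$n_in ||
        (cand$n_in == best$n_in && cand$degree < best$degree) ||
        (cand$n_in == best$n_in && cand$degree == best$degree &&
         cand$sse < best$sse)) cand else best
  }
  evaluate <- function(idx, degree) {
    coeffs <- poly_fit(x[idx], y[idx], degree)
    if (is.null(coeffs)) return(NULL)
    res <- abs(x - polyval_inc(coeffs, y))
    inl <- res <= residual_threshold
    list(degree = degree, coeffs = coeffs, inliers = inl,
         n_in = sum(inl), sse = sum(res[inl]^2))
  }
  # Least-squares refit on a consensus set, re-flagging against the refit
  # model until a fixpoint, so every reported inlier respects the residual
  # bound under the reported coefficients. A minimal-sample model that
  # over-reaches (its LS refit loses part of its consensus) settles to the
  # stable subset it can actually support.
  refit_fixpoint <- function(cand) {
    inl <- cand$inliers
    coeffs <- cand$coeffs
    for (it in 1:25) {
      deg <- min(cand$degree, sum(inl) - 1)
      if (deg < 1) break
      new_coeffs <- poly_fit(x[inl], y[inl], deg)
      if (is.null(new_coeffs)) break
      res <- abs(x - polyval_inc(new_coeffs, y))
      new_inl <- res <= residual_threshold
      if (!any(new_inl)) break
      coeffs <- new_coeffs
      if (identical(new_inl, inl)) { inl <- new_inl; break }
      inl <- new_inl
    }
    res <- abs(x - polyval_inc(coeffs, y))
    list(degree = length(coeffs) - 1, coeffs = coeffs, inliers = inl,
         n_in = sum(inl), sse = sum(res[inl]^2), residuals = res)
  }

  best_by_degree <- vector("list", max(degrees))
  any_valid <- FALSE
  withr::with_seed(seed, {
    for (degree in degrees) {
      m <- degree + 1
      n_comb <- choose(n, m)
      samples <- if (n_comb <= n_iter) {
        utils::combn(n, m, simplify = FALSE)
      } else {
        replicate(n_iter, sample.int(n, m), simplify = FALSE)
      }
      for (idx in samples) {
        cand <- evaluate(idx, degree)
        if (!is.null(cand)) {
          any_valid <- TRUE
          best_by_degree[[degree]] <- better(cand, best_by_degree[[degree]])
        }
      }
    }
  })
  if (!any_valid) {
    abort_fit(paste("All RANSAC samples were degenerate (duplicate y values",
                    "prevent a polynomial fit x = f(y))."))
  }

  # model selection on the refit models: most inliers, then lowest degree,
  # then lowest inlier SSE
  best <- NULL
  for (cand in best_by_degree) {
    if (!is.null(cand)) best <- better(refit_fixpoint(cand), best)
  }

  structure(list(
    degree = best$degree, coeffs = best$coeffs, inlier_flags = best$inliers,
    residuals = best$residuals, residual_threshold = residual_threshold,
    n_iter = n_iter, seed = seed, centers = centers
  ), class = "spinal_curve")
}

#' @export
print.spinal_curve <- function(x, ...) {
  cat(sprintf("<spinal_curve> degree %d, %d/%d inliers, threshold %.2f px\n",
              x$degree, sum(x$inlier_flags), length(x$inlier_flags),
              x$residual_threshold))
  cat("  x = f(y), coefficients (increasing powers):",
      paste(signif(x$coeffs, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Predict the spinal-curve x position at given y
#' @param object A `spinal_curve`.
#' @param y Vector of y coordinates (defaults to the fitted centers').
#' @param ... Unused.
#' @export
predict.spinal_curve <- function(object, y = NULL, ...) {
  y <- y %||% object$centers$y
  polyval_inc(object$coeffs, y)
}

#' Keep only centers on the spinal curve
#'
#' Returns exactly the inlier-flagged centers, original order preserved —
#' detections deviating significantly from the fitted curve are discarded.
#'
#' @param centers The data frame of centers the curve was fitted on.
#' @param curve A `spinal_curve` fitted on those centers.
#' @return The retained subset of `centers`.
#' @export
filter_centers <- function(centers, curve) {
  if (!inherits(curve, "spinal_curve")) {
    abort_validation("`curve` must be a spinal_curve.")
  }
  if (nrow(centers) != length(curve$inlier_flags)) {
    abort_validation(sprintf(
      "Curve was fitted on %d centers but %d were supplied.",
      length(curve$inlier_flags), nrow(centers)
    ))
  }
  tibble::as_tibble(centers)[curve$inlier_flags, , drop = FALSE]
}

#' Extract a fixed-size crop around a vertebral center
#'
#' The crop window is anchored at integer pixels: its origin is
#' `round(center) - side %/% 2`, so for even `side` the (rounded) center
#' lands on the pixel just below-right of the geometric crop middle. Regions
#' outside the image are padded with `pad_value` and recorded per edge.
#'
#' @param image Grayscale matrix.
#' @param center Named vector or one-row data frame with `x`, `y`
#'   (0-based image pixels); must lie inside the image.
#' @param side Crop side in pixels (default 224).
#' @param pad_value Intensity used for out-of-image padding; default the
#'   image median (the background level on a radiograph-like image).
#' @return List with `crop` (side x side matrix) and `window`, a
#'   `crop_window` carrying the affine crop-to-image offset and the padding
#'   applied per edge.
#' @export
crop_vertebra <- function(image, center, side = 224, pad_value = NULL) {
  check_image(image)
  if (is.data.frame(center)) center <- c(x = center$x[1], y = center$y[1])
  cx <- center[["x"]]; cy <- center[["y"]]
  h <- nrow(image); w <- ncol(image)
  if (!is.finite(cx) || !is.finite(cy) || cx < 0 || cx > w - 1 || cy < 0 || cy > h - 1) {
    abort_validation(sprintf("Center (%.1f, %.1f) lies outside the %d x %d image.",
                             cx, cy, h, w))
  }
  check_number(side, "side", lower = 1)
  side <- as.integer(side)
  x0 <- as.integer(round(cx)) - side %/% 2L
  y0 <- as.integer(round(cy)) - side %/% 2L
  pad_value <- pad_value %||% stats::median(image)
  crop <- matrix(pad_value, side, side)
  # overlap between the window [x0, x0+side-1] x [y0, y0+side-1] and the image
  ix0 <- max(x0, 0L); ix1 <- min(x0 + side - 1L, w - 1L)
  iy0 <- max(y0, 0L); iy1 <- min(y0 + side - 1L, h - 1L)
  if (ix1 >= ix0 && iy1 >= iy0) {
    crop[(iy0 - y0 + 1L):(iy1 - y0 + 1L), (ix0 - x0 + 1L):(ix1 - x0 + 1L)] <-
      image[(iy0 + 1L):(iy1 + 1L), (ix0 + 1L):(ix1 + 1L)]
  }
  window <- structure(list(
    center = c(x = cx, y = cy), side = side, origin = c(x = x0, y = y0),
    padding = c(top = max(0L, -y0), left = max(0L, -x0),
                bottom = max(0L, y0 + side - h), right = max(0L, x0 + side - w))
  ), class = "crop_window")
  list(crop = crop, window = window)
}

#' @export
print.crop_window <- function(x, ...) {
  cat(sprintf("<crop_window> %d px at origin (%d, %d), center (%.1f, %.1f)\n",
              x$side, x$origin[["x"]], x$origin[["y"]],
              x$center[["x"]], x$center[["y"]]))
  invisible(x)
}

crop_to_image_xy <- function(x, y, window) {
  list(x = x + window$origin[["x"]], y = y + window$origin[["y"]])
}

image_to_crop_xy <- function(x, y, window) {
  list(x = x - window$origin[["x"]], y = y - window$origin[["y"]])
}
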