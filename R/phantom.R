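# Synthetic lateral spine phantom: a vertically running column of
# vertebra-like bodies whose centers follow a low-degree polynomial curve,
# with exact ground-truth masks, landmarks and deformity severities.
#
# The phantom is deliberately schematic. Each vertebral body is a filled
# hexagon whose boundary passes exactly through its six landmarks, so the
# truth annotations are consistent with the rendered shape by construction.
# Deformity severity s is mapped so that the defining height ratio equals
# 1 - s (wedge: A/P; biconcave: C/P; crush: all heights scaled), which makes
# the requested severity and the measured collapse percent coincide.

#' Specification of a synthetic spine phantom
#'
#' @param image_size Integer `(height, width)` in pixels.
#' @param n_vertebrae Number of vertebral bodies (default 14, levels T4-L5,
#'   cranial to caudal).
#' @param curve_coeffs Polynomial coefficients (increasing powers) of the
#'   spinal midline `x = f(y)`, degree at most 4. Default: a gentle quadratic
#'   bow around the image midline with ~12% of the image width of deflection,
#'   emulating mild sagittal curvature.
#' @param base_width,base_height Width and height in pixels of the most
#'   cranial vertebra.
#' @param size_gradient Per-level multiplicative growth factor toward the
#'   caudal end (default 1.03; lumbar vertebrae are larger than thoracic).
#' @param gap Intervertebral spacing in pixels.
#' @param deformities Data frame with columns `level`, `type`
#'   (`"none"`, `"wedge"`, `"biconcave"`, `"crush"`) and `severity` in
#'   `[0, 1]`. Levels not listed are undeformed.
#' @param bone_intensity,background_intensity Gray levels in `[0, 1]`.
#' @param noise_sd Additive Gaussian noise SD in gray levels (default 0.02,
#'   a mildly grainy radiograph; 0 for a noise-free phantom).
#' @param edge_sigma Gaussian smoothing applied to the rendered structures
#'   before noise, in pixels (0 disables).
#' @param confusers Character vector from `"diaphragm"`, `"airway"`, `"rib"`:
#'   bright curvilinear structures emulating the classic false-positive
#'   sources (diaphragm edge, posterior airway wall, rib crossing a
#'   vertebral margin).
#' @param anterior_side `"left"` or `"right"`: which image side is anterior.
#' @param seed Integer seed; the phantom is bit-reproducible given the spec.
#' @return A `phantom_spec` object (validated list).
#' @export
phantom_spec <- function(image_size = c(512L, 256L),
                         n_vertebrae = 14,
                         curve_coeffs = NULL,
                         base_width = 40,
                         base_height = 22,
                         size_gradient = 1.03,
                         gap = 8,
                         deformities = NULL,
                         bone_intensity = 0.75,
                         background_intensity = 0.25,
                         noise_sd = 0.02,
                         edge_sigma = 0.7,
                         confusers = character(0),
                         anterior_side = c("left", "right"),
                         seed = 1L) {
  anterior_side <- match.arg(anterior_side)
  if (length(image_size) != 2 || any(image_size < 32)) {
    abort_validation("`image_size` must be (height, width), each at least 32 px.")
  }
  check_number(n_vertebrae, "n_vertebrae", lower = 1)
  check_number(base_width, "base_width", lower = 2)
  check_number(base_height, "base_height", lower = 2)
  check_number(size_gradient, "size_gradient", lower = 0.5, upper = 2)
  check_number(gap, "gap", lower = 1)
  check_number(bone_intensity, "bone_intensity", lower = 0, upper = 1)
  check_number(background_intensity, "background_intensity", lower = 0, upper = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(edge_sigma, "edge_sigma", lower = 0)
  if (bone_intensity <= background_intensity) {
    abort_validation("`bone_intensity` must exceed `background_intensity`.")
  }
  h <- as.integer(image_size[1]); w <- as.integer(image_size[2])
  if (is.null(curve_coeffs)) {
    # quadratic bow: f(y) = w/2 + k (y - h/2)^2 with 12% width deflection at the ends
    k <- 0.12 * w / (h / 2)^2
    curve_coeffs <- c(0.5 * w + k * (h / 2)^2, -k * h, k)
  }
  if (length(curve_coeffs) < 1 || length(curve_coeffs) > 5) {
    abort_validation("`curve_coeffs` must have 1 to 5 coefficients (degree <= 4).")
  }
  levels <- if (n_vertebrae == 14) vertebral_levels() else
    paste0("V", seq_len(n_vertebrae))
  if (is.null(deformities)) {
    deformities <- tibble::tibble(level = character(0), type = character(0),
                                  severity = numeric(0))
  }
  deformities <- tibble::as_tibble(deformities)
  if (nrow(deformities) > 0) {
    if (!all(c("level", "type", "severity") %in% names(deformities))) {
      abort_validation("`deformities` needs columns level, type, severity.")
    }
    bad_type <- setdiff(deformities$type, c("none", "wedge", "biconcave", "crush"))
    if (length(bad_type) > 0) {
      abort_validation(sprintf("Unknown deformity type(s): %s.",
                               paste(bad_type, collapse = ", ")))
    }
    if (any(!is.finite(deformities$severity) | deformities$severity < 0 |
            deformities$severity > 1)) {
      abort_validation("Deformity severity must lie in [0, 1].")
    }
    if (any(deformities$type == "crush" & deformities$severity >= 1)) {
      abort_validation("Crush severity must be < 1 (zero-height vertebra).")
    }
    bad_lvl <- setdiff(deformities$level, levels)
    if (length(bad_lvl) > 0) {
      abort_validation(sprintf("Deformity level(s) not in the phantom: %s.",
                               paste(bad_lvl, collapse = ", ")))
    }
  }
  bad_sev <- deformities$type %in% c("wedge", "biconcave") & deformities$severity >= 1
  if (any(bad_sev)) {
    abort_validation("Wedge/biconcave severity must be < 1 (zero-height edge).")
  }
  structure(list(
    image_size = c(h, w), n_vertebrae = as.integer(n_vertebrae),
    levels = levels, curve_coeffs = as.numeric(curve_coeffs),
    base_width = base_width, base_height = base_height,
    size_gradient = size_gradient, gap = gap, deformities = deformities,
    bone_intensity = bone_intensity, background_intensity = background_intensity,
    noise_sd = noise_sd, edge_sigma = edge_sigma, confusers = confusers,
    anterior_side = anterior_side, seed = as.integer(seed)
  ), class = "phantom_spec")
}

polyval_inc <- function(coeffs, y) {
  # coefficients in increasing powers
  drop(outer(y, seq_along(coeffs) - 1, `^`) %*% coeffs)
}

# Landmark geometry of one vertebra: axis-aligned template deformed per type.
phantom_vertebra_landmarks <- function(cx, cy, W, H, type, severity, anterior_side) {
  wh <- W / 2; hh <- H / 2
  ax <- cx - wh; px <- cx + wh          # anterior left by default
  if (anterior_side == "right") { ax <- cx + wh; px <- cx - wh }
  yu <- cy - hh; yl <- cy + hh
  p <- list(
    AU = c(ax, yu), AL = c(ax, yl), CU = c(cx, yu), CL = c(cx, yl),
    PU = c(px, yu), PL = c(px, yl)
  )
  s <- severity
  if (type == "wedge" && s > 0) {
    p$AU[2] <- yl - (1 - s) * H                       # A/P = 1 - s
    p$CU[2] <- (p$AU[2] + p$PU[2]) / 2                # linear superior endplate
  } else if (type == "biconcave" && s > 0) {
    p$CU[2] <- yl - (1 - s) * H                       # C/P = 1 - s
  } else if (type == "crush" && s > 0) {
    for (nm in c("AU", "CU", "PU")) p[[nm]][2] <- cy - (1 - s) * hh
    for (nm in c("AL", "CL", "PL")) p[[nm]][2] <- cy + (1 - s) * hh
  }
  out <- as.list(stats::setNames(
    unlist(p, use.names = FALSE),
    as.vector(vapply(landmark_names(), function(n) paste0(n, c("_x", "_y")), character(2)))
  ))
  tibble::as_tibble(out)
}

# Fill the hexagon bounded above by the piecewise-linear superior endplate
# through (AU, CU, PU) and below by the inferior endplate through (AL, CL, PL).
render_vertebra_mask <- function(lm, image_size) {
  h <- image_size[1]; w <- image_size[2]
  xs_u <- c(lm$AU_x, lm$CU_x, lm$PU_x); ys_u <- c(lm$AU_y, lm$CU_y, lm$PU_y)
  xs_l <- c(lm$AL_x, lm$CL_x, lm$PL_x); ys_l <- c(lm$AL_y, lm$CL_y, lm$PL_y)
  ord <- order(xs_u); xs_u <- xs_u[ord]; ys_u <- ys_u[ord]
  ord <- order(xs_l); xs_l <- xs_l[ord]; ys_l <- ys_l[ord]
  mask <- matrix(FALSE, h, w)
  c0 <- max(1L, floor(min(xs_u)) + 1L); c1 <- min(w, ceiling(max(xs_u)) + 1L)
  for (cc in c0:c1) {
    x <- cc - 1
    if (x < min(xs_u) || x > max(xs_u)) next
    yt <- stats::approx(xs_u, ys_u, xout = x, rule = 2)$y
    yb <- stats::approx(xs_l, ys_l, xout = x, rule = 2)$y
    r0 <- max(1L, as.integer(ceiling(yt - 1e-9)) + 1L)
    r1 <- min(h, as.integer(floor(yb + 1e-9)) + 1L)
    if (r1 >= r0) mask[r0:r1, cc] <- TRUE
  }
  mask
}

# Paint a thick curvilinear bright structure along a sampled path.
draw_path <- function(canvas, xs, ys, thickness, value) {
  h <- nrow(canvas); w <- ncol(canvas)
  r <- thickness / 2
  for (i in seq_along(xs)) {
    cc <- round(xs[i]) + 1; rr <- round(ys[i]) + 1
    ci <- max(1, cc - ceiling(r)):min(w, cc + ceiling(r))
    ri <- max(1, rr - ceiling(r)):min(h, rr + ceiling(r))
    for (c2 in ci) for (r2 in ri) {
      if ((c2 - 1 - xs[i])^2 + (r2 - 1 - ys[i])^2 <= r^2) {
        canvas[r2, c2] <- value
      }
    }
  }
  canvas
}

add_confusers <- function(canvas, spec, centers) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  v <- spec$bone_intensity
  anterior_left <- spec$anterior_side == "left"
  if ("diaphragm" %in% spec$confusers) {
    # dome-shaped edge low in the anterior field, clear of the spine
    x_max <- if (anterior_left) 0.28 * w else w - 1 - 0.28 * w
    xs <- seq(if (anterior_left) 2 else w - 3, x_max, length.out = 200)
    span <- abs(xs - xs[1]) / (0.28 * w)
    ys <- 0.78 * h - 0.12 * h * sin(pi * span)
    canvas <- draw_path(canvas, xs, ys, thickness = 5, value = v)
  }
  if ("airway" %in% spec$confusers) {
    # near-vertical posterior airway wall along the image edge
    ys <- seq(0.05 * h, 0.7 * h, length.out = 300)
    x0 <- if (anterior_left) w - 1 - 0.06 * w else 0.06 * w
    xs <- x0 + 0.015 * w * sin(ys / h * 4 * pi)
    canvas <- draw_path(canvas, xs, ys, thickness = 4, value = v)
  }
  if ("rib" %in% spec$confusers && nrow(centers) >= 3) {
    # thin oblique edge crossing the margin of a mid-thoracic vertebra
    i <- max(2, round(nrow(centers) / 3))
    x0 <- centers$x[i]; y0 <- centers$y[i]
    dx <- if (anterior_left) -1 else 1
    xs <- x0 + dx * seq(0, 0.3 * w, length.out = 150)
    ys <- y0 - 0.06 * h * seq(0, 1, length.out = 150)^1.5
    canvas <- draw_path(canvas, xs, ys, thickness = 2.5, value = v)
  }
  canvas
}

#' Generate a synthetic spine phantom
#'
#' Renders the phantom image and returns it together with its exact ground
#' truth: one binary mask per vertebra, the six true landmarks per vertebra
#' (image frame), and the morphometry recomputed from those landmarks through
#' the same [vertebra_morphometry()] call the rest of the pipeline uses.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_case`: list with `image` (matrix in `[0, 1]`),
#'   `truth_masks` (list of logical matrices), `truth_landmarks` (landmark
#'   table, image frame), `truth_morphometry`, and `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    abort_validation("`spec` must be created by phantom_spec().")
  }
  h <- spec$image_size[1]; w <- spec$image_size[2]
  n <- spec$n_vertebrae
  heights <- spec$base_height * spec$size_gradient^(seq_len(n) - 1)
  widths <- spec$base_width * spec$size_gradient^(seq_len(n) - 1)
  extent <- sum(heights) + spec$gap * (n - 1)
  top <- (h - extent) / 2
  if (top < 2) {
    abort_validation(sprintf(
      "Phantom does not fit: %d vertebrae need %.0f px of height, image has %d.",
      n, extent + 4, h
    ))
  }
  y_tops <- top + cumsum(c(0, heights[-n] + spec$gap))
  cy <- y_tops + heights / 2
  cx <- polyval_inc(spec$curve_coeffs, cy)

  def <- spec$deformities
  lms <- purrr::map(seq_len(n), function(i) {
    row <- def[def$level == spec$levels[i], , drop = FALSE]
    type <- if (nrow(row) > 0) row$type[1] else "none"
    sev <- if (nrow(row) > 0) row$severity[1] else 0
    phantom_vertebra_landmarks(cx[i], cy[i], widths[i], heights[i],
                               type, sev, spec$anterior_side)
  })
  truth <- dplyr::bind_cols(
    tibble::tibble(case_id = "phantom", image_id = "phantom-001",
                   level = spec$levels, region = level_region(spec$levels),
                   evaluator = "truth", frame = "image"),
    dplyr::bind_rows(lms)
  )
  coords <- as.matrix(truth[landmark_cols()])
  xs <- coords[, seq(1, 12, 2)]; ys <- coords[, seq(2, 12, 2)]
  if (any(xs < 0) || any(xs > w - 1) || any(ys < 0) || any(ys > h - 1)) {
    abort_validation("Spec places landmarks outside the image; reduce sizes or curve.")
  }

  masks <- purrr::map(seq_len(n), function(i) render_vertebra_mask(lms[[i]], spec$image_size))
  img <- matrix(spec$background_intensity, h, w)
  for (m in masks) img[m] <- spec$bone_intensity
  img <- add_confusers(img, spec, tibble::tibble(x = cx, y = cy))
  if (spec$edge_sigma > 0) {
    img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = spec$edge_sigma))
  }
  if (spec$noise_sd > 0) {
    img <- withr::with_seed(spec$seed, {
      img + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    })
  }
  img <- clamp(img, 0, 1)

  structure(list(
    image = img,
    truth_masks = masks,
    truth_landmarks = truth,
    truth_morphometry = vertebra_morphometry(truth),
    spec = spec
  ), class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %d x %d px, %d vertebrae (%s..%s), noise SD %.3f\n",
              x$spec$image_size[1], x$spec$image_size[2], x$spec$n_vertebrae,
              x$spec$levels[1], x$spec$levels[x$spec$n_vertebrae], x$spec$noise_sd))
  ndef <- sum(x$spec$deformities$type != "none")
  cat(sprintf("  deformities: %d; confusers: %s\n", ndef,
              if (length(x$spec$confusers)) paste(x$spec$confusers, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Write a phantom's ground truth to disk
#'
#' Writes the image as 16-bit TIFF and the truth landmarks in the annotation
#' JSON schema shared with [read_annotations()], plus a morphometry CSV.
#'
#' @param case A `phantom_case`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_truth <- function(case, dir) {
  if (!inherits(case, "phantom_case")) {
    abort_validation("`case` must be a phantom_case.")
  }
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) abort_io(sprintf("Cannot create output directory '%s'.", dir))
  paths <- list(
    image = file.path(dir, "phantom.tiff"),
    annotations = file.path(dir, "truth_landmarks.json"),
    morphometry = file.path(dir, "truth_morphometry.csv")
  )
  write_image(case$image, paths$image)
  write_annotations(case$truth_landmarks, paths$annotations)
  readr::write_csv(case$truth_morphometry, paths$morphometry)
  invisible(paths)
}
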