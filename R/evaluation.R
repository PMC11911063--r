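# Observer-agreement evaluation suite: detection metrics, normalised
# landmark errors, normality-gated correlation, and Bland-Altman agreement
# with QM-status subgroups and proportional-bias regression.

#' Match predicted centers to reference vertebrae
#'
#' Greedy one-to-one matching in increasing distance order: the closest
#' (prediction, reference) pair is matched first, then the closest among the
#' remaining, and so on. A prediction is a true positive iff it is matched
#' to a reference within `tau`; each reference absorbs at most one
#' prediction.
#'
#' @param pred Data frame of predicted centers with columns `x`, `y`.
#' @param ref Reference standard: either a data frame of centers (`x`, `y`)
#'   or a landmark table, in which case each vertebra's center is the mean
#'   of its six landmarks.
#' @param tau Matching radius in pixels: a single number, or `NULL` (the
#'   default) to use half of each reference vertebra's height — a local,
#'   scale-free criterion (requires `ref` to be a landmark table).
#' @param n_images Number of images the counts cover (for FP per image).
#' @return List with `labels` (the `pred` tibble plus `status` TP/FP,
#'   `matched_ref`, `distance`) and `counts`, a tibble
#'   `(n_reference, TP, FP, n_images)` for [detection_metrics()].
#' @export
match_detections <- function(pred, ref, tau = NULL, n_images = 1L) {
  pred <- tibble::as_tibble(pred)
  ref <- tibble::as_tibble(ref)
  if (!all(c("x", "y") %in% names(pred))) {
    abort_validation("`pred` needs columns `x` and `y`.")
  }
  has_lms <- all(landmark_cols() %in% names(ref))
  ref_centers <- if (has_lms) landmark_center(ref) else ref
  if (!all(c("x", "y") %in% names(ref_centers))) {
    abort_validation("`ref` needs `x`/`y` columns or the 12 landmark columns.")
  }
  if (is.null(tau)) {
    if (!has_lms) {
      abort_validation("Local `tau` needs a reference landmark table; pass `tau` explicitly.")
    }
    tau_j <- 0.5 * vertebra_dimensions(ref)$height
  } else {
    check_number(tau, "tau", lower = 1e-12)
    tau_j <- rep(tau, nrow(ref_centers))
  }
  np <- nrow(pred); nr <- nrow(ref_centers)
  status <- rep("FP", np)
  matched_ref <- rep(NA_integer_, np)
  distance <- rep(NA_real_, np)
  if (np > 0 && nr > 0) {
    dmat <- sqrt(outer(pred$x, ref_centers$x, `-`)^2 +
                 outer(pred$y, ref_centers$y, `-`)^2)
    ord <- order(dmat)
    p_used <- logical(np); r_used <- logical(nr)
    for (k in ord) {
      i <- (k - 1) %% np + 1
      j <- (k - 1) %/% np + 1
      if (p_used[i] || r_used[j]) next
      if (dmat[i, j] > tau_j[j]) next
      p_used[i] <- TRUE; r_used[j] <- TRUE
      status[i] <- "TP"; matched_ref[i] <- j; distance[i] <- dmat[i, j]
    }
  }
  labels <- dplyr::bind_cols(pred, tibble::tibble(
    status = status, matched_ref = matched_ref, distance = distance
  ))
  counts <- tibble::tibble(
    n_reference = nr, TP = sum(status == "TP"), FP = sum(status == "FP"),
    n_images = as.integer(n_images)
  )
  list(labels = labels, counts = counts)
}

#' Detection performance metrics
#'
#' Sensitivity = TP / reference count, precision = TP / (TP + FP), both in
#' percent; false positives per image = FP / image count. Undefined metrics
#' (zero denominator) are reported as `NA` rather than raising an error.
#'
#' @param counts Tibble with `n_reference`, `TP`, `FP`, `n_images` (one or
#'   more rows; rows are summed).
#' @return One-row tibble with `sensitivity_pct`, `precision_pct`,
#'   `fp_per_image` and the aggregated counts.
#' @export
detection_metrics <- function(counts) {
  counts <- tibble::as_tibble(counts)
  need <- c("n_reference", "TP", "FP", "n_images")
  if (!all(need %in% names(counts))) {
    abort_validation("`counts` needs columns n_reference, TP, FP, n_images.")
  }
  s <- dplyr::summarise(counts, dplyr::across(dplyr::all_of(need), sum))
  if (any(unlist(s) < 0) || s$TP > s$n_reference) {
    abort_validation("Invalid counts: need 0 <= TP <= n_reference and FP >= 0.")
  }
  tibble::tibble(
    n_reference = s$n_reference, TP = s$TP, FP = s$FP, n_images = s$n_images,
    sensitivity_pct = if (s$n_reference > 0) 100 * s$TP / s$n_reference else NA_real_,
    precision_pct = if (s$TP + s$FP > 0) 100 * s$TP / (s$TP + s$FP) else NA_real_,
    fp_per_image = if (s$n_images > 0) s$FP / s$n_images else NA_real_
  )
}

#' Reference width and height of vertebral bodies
#'
#' Width is the mean of the upper and lower edge spans (`||PU - AU||`,
#' `||PL - AL||`); height is the mean of the anterior and posterior heights
#' (`||AU - AL||`, `||PU - PL||`). These are the normalisers used for
#' dimension-adjusted landmark errors.
#'
#' @param landmarks Landmark table (one row per vertebra).
#' @return Tibble with `width` and `height` in pixels.
#' @export
vertebra_dimensions <- function(landmarks) {
  check_landmark_tbl(landmarks)
  tbl <- tibble::as_tibble(landmarks)
  d <- function(a, b) {
    sqrt((tbl[[paste0(a, "_x")]] - tbl[[paste0(b, "_x")]])^2 +
         (tbl[[paste0(a, "_y")]] - tbl[[paste0(b, "_y")]])^2)
  }
  width <- (d("PU", "AU") + d("PL", "AL")) / 2
  height <- (d("AU", "AL") + d("PU", "PL")) / 2
  if (nrow(tbl) > 0 && any(width <= 0 | height <= 0)) {
    abort_validation("Degenerate vertebra: zero width or height.")
  }
  tibble::tibble(width = width, height = height)
}

#' Dimension-normalised landmark errors
#'
#' Per landmark and axis, the absolute coordinate difference between
#' prediction and reference expressed as a percentage of the reference
#' vertebra's width (x) or height (y).
#'
#' @param pred,ref Row-aligned landmark tables in the image frame.
#' @return Long tibble: one row per (vertebra, landmark) with `landmark`,
#'   `x_error_pct`, `y_error_pct`, plus any identity columns of `ref`
#'   (`case_id`, `image_id`, `level`, `region`) and `vertebra` (row index).
#' @export
landmark_errors <- function(pred, ref) {
  check_landmark_tbl(pred, frame = "image", arg = "pred")
  check_landmark_tbl(ref, frame = "image", arg = "ref")
  if (nrow(pred) != nrow(ref)) {
    abort_validation("`pred` and `ref` must be row-aligned (same number of rows).")
  }
  dims <- vertebra_dimensions(ref)
  id_cols <- intersect(c("case_id", "image_id", "level", "region"), names(ref))
  purrr::map_dfr(landmark_names(), function(nm) {
    dplyr::bind_cols(
      tibble::as_tibble(ref[id_cols]),
      tibble::tibble(
        vertebra = seq_len(nrow(ref)),
        landmark = nm,
        x_error_pct = 100 * abs(pred[[paste0(nm, "_x")]] - ref[[paste0(nm, "_x")]]) /
          dims$width,
        y_error_pct = 100 * abs(pred[[paste0(nm, "_y")]] - ref[[paste0(nm, "_y")]]) /
          dims$height
      )
    )
  })
}

shapiro_p <- function(x) {
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0) return(NA_real_)
  if (n > 5000) x <- x[round(seq(1, n, length.out = 5000))]  # test's size limit
  stats::shapiro.test(x)$p.value
}

#' Normality-gated correlation between two ratio series
#'
#' Shapiro-Wilk normality is tested on each series; Pearson's correlation is
#' used when both are compatible with normality (p >= alpha on both),
#' otherwise Spearman's rank correlation.
#'
#' @param a,b Numeric vectors of equal length, at least 4.
#' @param alpha Normality-gate significance level (default 0.05).
#' @return A `qm_correlation` object: `method`, `estimate`, `p_value`,
#'   `normality_p` (length 2), `n`. Constant input yields `method = "undefined"`
#'   with `NA` estimate.
#' @export
qm_correlation <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) abort_validation("`a` and `b` must have equal length.")
  if (length(a) < 4) abort_validation("Need at least 4 pairs for correlation.")
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    abort_validation("Inputs must be finite.")
  }
  norm_p <- c(a = shapiro_p(a), b = shapiro_p(b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    res <- list(method = "undefined", estimate = NA_real_, p_value = NA_real_)
  } else {
    method <- if (all(!is.na(norm_p)) && all(norm_p >= alpha)) "pearson" else "spearman"
    ct <- suppressWarnings(stats::cor.test(a, b, method = method))
    res <- list(method = method, estimate = unname(ct$estimate),
                p_value = ct$p.value)
  }
  structure(c(res, list(normality_p = norm_p, n = length(a), alpha = alpha)),
            class = "qm_correlation")
}

#' @export
print.qm_correlation <- function(x, ...) {
  cat(sprintf("<qm_correlation> %s: r = %s, p = %s (n = %d)\n", x$method,
              format(signif(x$estimate, 4)), format(signif(x$p_value, 3)), x$n))
  cat(sprintf("  Shapiro-Wilk p: a = %s, b = %s (gate alpha = %g)\n",
              format(signif(x$normality_p[1], 3)),
              format(signif(x$normality_p[2], 3)), x$alpha))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `a - b` (algorithm minus reference, when `a` is
#' the algorithm). Limits of agreement are the mean difference +/- 1.96
#' sample SDs of the differences — the interval expected to contain 95% of
#' differences under normality. Proportional bias is the simple linear
#' regression of the difference on the pair mean. When QM-status bins are
#' supplied, per-bin rows report n, mean +/- SD of the differences and the
#' percentage of pairs inside the *global* LOA.
#'
#' @param a,b Paired measurement series (e.g. a height ratio from two
#'   observers), equal length >= 2.
#' @param bins Optional per-pair QM status (factor/character, see
#'   [qm_status()]).
#' @param conf_mult LOA multiplier (default 1.96).
#' @return A `bland_altman` object: `md`, `sd_diff`, `loa`, `data` (tibble
#'   with `mean`, `diff`, `within_loa`, `bin`), `trend`
#'   (`slope`, `intercept`, `p_value`, `r_squared`), `subgroups` tibble.
#' @export
bland_altman <- function(a, b, bins = NULL, conf_mult = 1.96) {
  if (length(a) != length(b)) abort_validation("`a` and `b` must have equal length.")
  if (length(a) < 2) abort_validation("Need at least 2 pairs.")
  if (any(!is.finite(a)) || any(!is.finite(b))) abort_validation("Inputs must be finite.")
  if (!is.null(bins) && length(bins) != length(a)) {
    abort_validation("`bins` must match the series length.")
  }
  d <- a - b
  m <- (a + b) / 2
  md <- mean(d)
  sd_diff <- stats::sd(d)
  loa <- c(lower = md - conf_mult * sd_diff, upper = md + conf_mult * sd_diff)
  within <- d >= loa[["lower"]] & d <= loa[["upper"]]
  trend <- if (sd_diff == 0 || stats::sd(m) == 0) {
    list(slope = NA_real_, intercept = NA_real_, p_value = NA_real_,
         r_squared = NA_real_)
  } else {
    fit <- stats::lm(d ~ m)
    sm <- suppressWarnings(summary(fit))   # perfect trend lines are legal input
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         p_value = sm$coefficients[2, 4],
         r_squared = sm$r.squared)
  }
  data <- tibble::tibble(
    mean = m, diff = d, within_loa = within,
    bin = if (is.null(bins)) factor(rep(NA_character_, length(d)), levels = qm_bins())
          else factor(as.character(bins), levels = qm_bins())
  )
  subgroups <- if (is.null(bins)) {
    tibble::tibble(bin = factor(character(0), levels = qm_bins()),
                   n = integer(0), md = numeric(0), sd = numeric(0),
                   within_loa_pct = numeric(0))
  } else {
    data |>
      dplyr::group_by(bin = .data$bin) |>
      dplyr::summarise(
        n = dplyr::n(),
        md = mean(.data$diff),
        sd = stats::sd(.data$diff),
        within_loa_pct = 100 * mean(.data$within_loa),
        .groups = "drop"
      )
  }
  structure(list(md = md, sd_diff = sd_diff, loa = loa, conf_mult = conf_mult,
                 data = data, trend = trend, subgroups = subgroups),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d, MD = %.4f, LOA = [%.4f, %.4f]\n",
              nrow(x$data), x$md, x$loa[["lower"]], x$loa[["upper"]]))
  cat(sprintf("  within LOA: %.1f%%; proportional bias: slope = %s, p = %s, R^2 = %s\n",
              100 * mean(x$data$within_loa), format(signif(x$trend$slope, 4)),
              format(signif(x$trend$p_value, 3)),
              format(signif(x$trend$r_squared, 4))))
  if (nrow(x$subgroups) > 0) {
    cat("  subgroups (global LOA):\n")
    print(as.data.frame(x$subgroups), row.names = FALSE)
  }
  invisible(x)
}

#' Evaluate an algorithm's annotations against a reference standard
#'
#' Orchestrates the full evaluation: detection counts and metrics (via
#' vertebra centers), dimension-normalised landmark errors stratified by
#' region and reference QM status, normality-gated correlations and
#' Bland-Altman agreement for each height ratio, and the list of vertebrae
#' flagged at the discrepancy threshold.
#'
#' Records are paired on `(case_id, image_id, level)`. Reference vertebrae
#' with no matching prediction count as non-detections; predictions with no
#' matching reference count as false positives.
#'
#' @param pred,ref Landmark tables in the image frame with identity columns
#'   `case_id`, `image_id`, `level`.
#' @param tau Matching radius passed to [match_detections()] (`NULL` = half
#'   the local reference vertebral height).
#' @param discrepancy_threshold Inclusive ratio-difference review threshold
#'   (default 0.2).
#' @return A `qm_report` list: `counts`, `detection`, `landmark_errors`,
#'   `landmark_error_summary`, `correlations` (per ratio), `bland_altman`
#'   (per ratio), `discrepancies`, `paired` (the joined morphometry table).
#' @export
evaluate_pipeline <- function(pred, ref, tau = NULL, discrepancy_threshold = 0.2) {
  check_landmark_tbl(pred, frame = "image", arg = "pred")
  check_landmark_tbl(ref, frame = "image", arg = "ref")
  keys <- c("case_id", "image_id", "level")
  for (k in keys) {
    if (!k %in% names(pred) || !k %in% names(ref)) {
      abort_validation(sprintf("Both tables need identity column `%s`.", k))
    }
  }
  images <- unique(ref[c("case_id", "image_id")])
  if (nrow(dplyr::inner_join(unique(pred[c("case_id", "image_id")]), images,
                             by = c("case_id", "image_id"))) == 0) {
    abort_validation("`pred` and `ref` share no (case_id, image_id).")
  }

  # detection: per image, match predicted vs reference centers
  counts <- purrr::map_dfr(seq_len(nrow(images)), function(i) {
    rr <- dplyr::semi_join(ref, images[i, ], by = c("case_id", "image_id"))
    pp <- dplyr::semi_join(pred, images[i, ], by = c("case_id", "image_id"))
    match_detections(landmark_center(pp), rr, tau = tau, n_images = 1L)$counts
  })
  detection <- detection_metrics(counts)

  ref_m <- vertebra_morphometry(ref)
  pred_m <- vertebra_morphometry(pred)
  paired <- dplyr::inner_join(
    pred_m, ref_m, by = keys, suffix = c("_pred", "_ref")
  )
  if (nrow(paired) == 0) abort_validation("No vertebrae could be paired on (case_id, image_id, level).")

  split_lms <- function(suffix) {
    out <- paired[c(keys, paste0(c(landmark_cols(), "frame"), suffix))]
    names(out) <- c(keys, landmark_cols(), "frame")
    if ("region_ref" %in% names(paired)) out$region <- paired$region_ref
    else if ("region" %in% names(paired)) out$region <- paired$region
    out
  }
  lm_err <- landmark_errors(split_lms("_pred"), split_lms("_ref"))
  lm_err$qm_status_ref <- rep(paired$qm_status_ref, times = 6)

  strat <- c(intersect("region", names(lm_err)), "qm_status_ref", "landmark")
  landmark_error_summary <- lm_err |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strat))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_x_error_pct = mean(.data$x_error_pct),
      mean_y_error_pct = mean(.data$y_error_pct),
      .groups = "drop"
    )

  ratios <- c("ratio_CA", "ratio_CP", "ratio_AP")
  correlations <- purrr::map(stats::setNames(ratios, ratios), function(r) {
    qm_correlation(paired[[paste0(r, "_pred")]], paired[[paste0(r, "_ref")]])
  })
  ba <- purrr::map(stats::setNames(ratios, ratios), function(r) {
    bland_altman(paired[[paste0(r, "_pred")]], paired[[paste0(r, "_ref")]],
                 bins = paired$qm_status_ref)
  })

  disc <- flag_discrepancy(
    stats::setNames(paired[paste0(ratios, "_pred")], ratios),
    stats::setNames(paired[paste0(ratios, "_ref")], ratios),
    threshold = discrepancy_threshold
  )
  discrepancies <- dplyr::bind_cols(paired[keys], disc)

  structure(list(
    counts = counts, detection = detection,
    landmark_errors = lm_err, landmark_error_summary = landmark_error_summary,
    correlations = correlations, bland_altman = ba,
    discrepancies = discrepancies, paired = paired
  ), class = "qm_report")
}

#' @export
print.qm_report <- function(x, ...) {
  d <- x$detection
  cat("<qm_report>\n")
  cat(sprintf("  detection: sensitivity %.1f%%, precision %.1f%%, %.3f FP/image (%d images)\n",
              d$sensitivity_pct, d$precision_pct, d$fp_per_image, d$n_images))
  for (r in names(x$correlations)) {
    co <- x$correlations[[r]]; b <- x$bland_altman[[r]]
    cat(sprintf("  %s: %s r = %.3f | MD = %.4f, LOA [%.4f, %.4f]\n", r,
                co$method, co$estimate, b$md, b$loa[["lower"]], b$loa[["upper"]]))
  }
  cat(sprintf("  discrepancies >= threshold: %d of %d vertebrae\n",
              sum(x$discrepancies$flagged), nrow(x$discrepancies)))
  invisible(x)
}
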