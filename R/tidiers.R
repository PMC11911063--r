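# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted spinal curve
#'
#' @param x A `spinal_curve`.
#' @param ... Unused.
#' @return Tibble with one row per polynomial coefficient (`term` = power of
#'   y, `estimate`).
#' @export
tidy.spinal_curve <- function(x, ...) {
  tibble::tibble(
    term = paste0("y^", seq_along(x$coeffs) - 1),
    estimate = x$coeffs
  )
}

#' One-row summary of a fitted spinal curve
#'
#' @param x A `spinal_curve`.
#' @param ... Unused.
#' @export
glance.spinal_curve <- function(x, ...) {
  tibble::tibble(
    degree = x$degree,
    n_centers = length(x$inlier_flags),
    n_inliers = sum(x$inlier_flags),
    residual_threshold = x$residual_threshold,
    max_inlier_residual = if (any(x$inlier_flags))
      max(x$residuals[x$inlier_flags]) else NA_real_
  )
}

#' Tidy a Bland-Altman analysis
#'
#' @param x A `bland_altman`.
#' @param ... Unused.
#' @return The per-QM-bin subgroup table when bins were supplied, otherwise
#'   one overall row: `n`, `md`, `sd`, `within_loa_pct`.
#' @export
tidy.bland_altman <- function(x, ...) {
  if (nrow(x$subgroups) > 0) return(x$subgroups)
  tibble::tibble(
    bin = factor(NA_character_, levels = qm_bins()),
    n = nrow(x$data), md = x$md, sd = x$sd_diff,
    within_loa_pct = 100 * mean(x$data$within_loa)
  )
}

#' One-row summary of a Bland-Altman analysis
#'
#' @param x A `bland_altman`.
#' @param ... Unused.
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$data), md = x$md, sd_diff = x$sd_diff,
    loa_lower = x$loa[["lower"]], loa_upper = x$loa[["upper"]],
    within_loa_pct = 100 * mean(x$data$within_loa),
    trend_slope = x$trend$slope, trend_p = x$trend$p_value,
    trend_r_squared = x$trend$r_squared
  )
}

#' Tidy a normality-gated correlation
#'
#' @param x A `qm_correlation`.
#' @param ... Unused.
#' @export
tidy.qm_correlation <- function(x, ...) {
  tibble::tibble(
    method = x$method, estimate = x$estimate, p_value = x$p_value,
    n = x$n, normality_p_a = x$normality_p[[1]], normality_p_b = x$normality_p[[2]]
  )
}

#' Tidy an evaluation report
#'
#' @param x A `qm_report`.
#' @param ... Unused.
#' @return Long tibble combining, per height ratio, the correlation and
#'   Bland-Altman summaries.
#' @export
tidy.qm_report <- function(x, ...) {
  purrr::map_dfr(names(x$correlations), function(r) {
    dplyr::bind_cols(
      tibble::tibble(ratio = sub("ratio_", "", r)),
      tidy(x$correlations[[r]]),
      dplyr::rename_with(glance(x$bland_altman[[r]]),
                         function(n) paste0("ba_", n))
    )
  })
}

#' One-row summary of an evaluation report
#'
#' @param x A `qm_report`.
#' @param ... Unused.
#' @export
glance.qm_report <- function(x, ...) {
  dplyr::bind_cols(
    x$detection,
    tibble::tibble(
      n_paired = nrow(x$paired),
      n_discrepancies = sum(x$discrepancies$flagged),
      discrepancy_pct = 100 * mean(x$discrepancies$flagged)
    )
  )
}
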