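# Quantitative morphometry: heights, ratios, collapse percent, QM status.

#' Vertebral body heights from the six landmarks
#'
#' Heights are the Euclidean distances between the paired upper and lower
#' landmarks of the anterior (A), central (C) and posterior (P) edges:
#' A = ||AU - AL||, C = ||CU - CL||, P = ||PU - PL||.
#'
#' @param landmarks A one-row landmark table (see [vertebra_morphometry()] for
#'   the vectorised version) or a named list/vector with elements `AU_x`,
#'   `AU_y`, ..., `PL_y`.
#' @return Named numeric vector `c(A = , C = , P = )` in pixels.
#' @examples
#' lm <- tibble::tibble(
#'   AU_x = 0, AU_y = 0, AL_x = 0, AL_y = 10, CU_x = 5, CU_y = 0,
#'   CL_x = 5, CL_y = 10, PU_x = 10, PU_y = 0, PL_x = 10, PL_y = 10
#' )
#' compute_heights(lm) # 10 10 10
#' @export
compute_heights <- function(landmarks) {
  if (!is.data.frame(landmarks)) landmarks <- tibble::as_tibble(as.list(landmarks))
  check_landmark_tbl(landmarks)
  if (nrow(landmarks) != 1) {
    abort_validation("`landmarks` must describe exactly one vertebra (one row).")
  }
  h <- function(p) {
    sqrt((landmarks[[paste0(p, "U_x")]] - landmarks[[paste0(p, "L_x")]])^2 +
         (landmarks[[paste0(p, "U_y")]] - landmarks[[paste0(p, "L_y")]])^2)
  }
  out <- c(A = h("A"), C = h("C"), P = h("P"))
  if (any(out <= 0)) {
    abort_validation(sprintf(
      "Coincident paired landmarks give a zero height (%s).",
      paste(names(out)[out <= 0], collapse = ", ")
    ))
  }
  out
}

#' Vertebral body height ratios C/A, C/P, A/P
#'
#' @param A,C,P Anterior, central and posterior heights (positive; vectorised).
#' @return Tibble with columns `ratio_CA`, `ratio_CP`, `ratio_AP`.
#' @export
compute_ratios <- function(A, C, P) {
  if (any(!is.finite(A) | !is.finite(C) | !is.finite(P)) ||
      any(A <= 0 | C <= 0 | P <= 0)) {
    abort_validation("Heights A, C, P must all be finite and positive.")
  }
  tibble::tibble(ratio_CA = C / A, ratio_CP = C / P, ratio_AP = A / P)
}

#' Collapse percent from height ratios
#'
#' Collapse is defined within one vertebra as `100 * (1 - min(A/P, C/P))`,
#' floored at zero: the worst proportional loss of anterior or central height
#' relative to the posterior edge. Wedge deformity reduces A/P, biconcave
#' deformity reduces C/P; pure crush (uniform loss including the posterior
#' edge) is invisible to within-vertebra ratios and needs an adjacent-level
#' reference (see [vertebra_morphometry()]'s `crush_reference` option).
#'
#' @param ratio_CP,ratio_AP Height ratios (vectorised).
#' @return Collapse percent, `>= 0`.
#' @export
collapse_percent <- function(ratio_CP, ratio_AP) {
  if (any(!is.finite(ratio_CP) | !is.finite(ratio_AP)) ||
      any(ratio_CP <= 0 | ratio_AP <= 0)) {
    abort_validation("Ratios must be finite and positive.")
  }
  pmax(0, 100 * (1 - pmin(ratio_AP, ratio_CP)))
}

#' QM status bin for a collapse percent
#'
#' Bins are half-open: `[0, 20)` maps to `"<20"`, `[20, 25)` to `"20-25"`,
#' `[25, 40)` to `"25-40"` and `[40, Inf)` to `">40"`. The printed bin labels
#' overlap at their boundaries; the half-open convention used here sends a
#' boundary value (exactly 25, exactly 40) to the upper bin.
#'
#' @param collapse_pct Collapse percent, `>= 0` (vectorised).
#' @return Factor with levels `"<20"`, `"20-25"`, `"25-40"`, `">40"`.
#' @export
qm_status <- function(collapse_pct) {
  if (any(!is.finite(collapse_pct)) || any(collapse_pct < 0)) {
    abort_validation("`collapse_pct` must be finite and non-negative.")
  }
  cut(collapse_pct, breaks = c(0, 20, 25, 40, Inf), right = FALSE,
      labels = qm_bins(), include.lowest = TRUE)
}

#' QM status bin labels, in severity order
#' @return Character vector of the four bin labels.
#' @export
qm_bins <- function() c("<20", "20-25", "25-40", ">40")

#' Flag height-ratio discrepancies between two measurements
#'
#' A vertebra is flagged when any of the three ratios differs by at least
#' `threshold` (inclusive) between the two measurements — the review trigger
#' used to surface gross annotation failures such as landmarks placed on an
#' adjacent vertebra or the diaphragm.
#'
#' @param pred,ref Data frames with columns `ratio_CA`, `ratio_CP`,
#'   `ratio_AP`, row-aligned.
#' @param threshold Inclusive absolute-difference threshold (default 0.2).
#' @return Tibble with per-row `flagged` (logical), `max_delta`, and
#'   `offending` (comma-separated ratio names meeting the threshold).
#' @export
flag_discrepancy <- function(pred, ref, threshold = 0.2) {
  check_number(threshold, "threshold", lower = 0)
  cols <- c("ratio_CA", "ratio_CP", "ratio_AP")
  for (nm in cols) {
    if (!nm %in% names(pred) || !nm %in% names(ref)) {
      abort_validation(sprintf("Both inputs need a `%s` column.", nm))
    }
  }
  if (nrow(pred) != nrow(ref)) {
    abort_validation("`pred` and `ref` must have the same number of rows.")
  }
  delta <- abs(as.matrix(pred[cols]) - as.matrix(ref[cols]))
  hit <- delta >= threshold - 1e-9       # inclusive despite float rounding
  tibble::tibble(
    flagged = rowSums(hit) > 0,
    max_delta = if (nrow(pred) > 0) apply(delta, 1, max) else numeric(0),
    offending = apply(hit, 1, function(r) paste(cols[r], collapse = ","))
  )
}

#' Full morphometry for a table of landmark sets
#'
#' The tibble-first workhorse: takes a landmark table (one row per vertebra)
#' and appends heights, the three height ratios, collapse percent and the QM
#' status bin.
#'
#' @param landmarks Landmark table in the image frame.
#' @param crush_reference If `TRUE` and the table is ordered cranial to caudal
#'   for a single image, collapse percent additionally considers posterior
#'   height loss against the mean posterior height of the adjacent vertebrae
#'   (off by default; within-vertebra ratios cannot see a uniform crush).
#' @return The input tibble with columns `A`, `C`, `P`, `ratio_CA`,
#'   `ratio_CP`, `ratio_AP`, `collapse_pct`, `qm_status` appended.
#' @export
vertebra_morphometry <- function(landmarks, crush_reference = FALSE) {
  check_landmark_tbl(landmarks)
  tbl <- tibble::as_tibble(landmarks)
  derived <- c("A", "C", "P", "ratio_CA", "ratio_CP", "ratio_AP",
               "collapse_pct", "qm_status")
  tbl <- tbl[setdiff(names(tbl), derived)]   # recompute, never duplicate
  if (nrow(tbl) == 0) {
    return(dplyr::mutate(tbl, A = numeric(0), C = numeric(0), P = numeric(0),
                         ratio_CA = numeric(0), ratio_CP = numeric(0),
                         ratio_AP = numeric(0), collapse_pct = numeric(0),
                         qm_status = factor(character(0), levels = qm_bins())))
  }
  d2 <- function(p) {
    sqrt((tbl[[paste0(p, "U_x")]] - tbl[[paste0(p, "L_x")]])^2 +
         (tbl[[paste0(p, "U_y")]] - tbl[[paste0(p, "L_y")]])^2)
  }
  A <- d2("A"); C <- d2("C"); P <- d2("P")
  if (any(A <= 0 | C <= 0 | P <= 0)) {
    abort_validation("Coincident paired landmarks give a zero height.")
  }
  ratios <- compute_ratios(A, C, P)
  out <- dplyr::bind_cols(tbl, tibble::tibble(A = A, C = C, P = P), ratios)
  cp <- collapse_percent(out$ratio_CP, out$ratio_AP)
  if (isTRUE(crush_reference) && nrow(out) >= 2) {
    p_adj <- vapply(seq_len(nrow(out)), function(i) {
      nb <- c(i - 1, i + 1)
      mean(out$P[nb[nb >= 1 & nb <= nrow(out)]])
    }, numeric(1))
    cp <- pmax(cp, pmax(0, 100 * (1 - out$P / p_adj)))
  }
  out$collapse_pct <- cp
  out$qm_status <- qm_status(cp)
  out
}
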