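# Image and annotation file I/O.
#
# JSON is the canonical annotation format (nested six-point records with
# evaluator tags); CSV is a flat convenience export. All coordinates are
# stored in image pixels, 0-based, origin top-left. Physical pixel spacing,
# when known, is metadata only: the height ratios are unit-free.

#' Read a grayscale radiograph
#'
#' Supports PNG and TIFF. Multi-channel images are converted to grayscale by
#' channel averaging. DICOM input is not supported; convert to 16-bit
#' PNG/TIFF upstream.
#'
#' @param path File path.
#' @return Numeric matrix with intensities in `[0, 1]` and attribute
#'   `pixel_spacing` (mm/px, `NA` when unknown).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    vm_abort(sprintf("Image file not found: '%s'.", path), "vm_format_error")
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = tryCatch(png::readPNG(path), error = function(e) {
      vm_abort(sprintf("Cannot read PNG '%s': %s", path, conditionMessage(e)),
               "vm_format_error", parent = e)
    }),
    tif = , tiff = tryCatch(tiff::readTIFF(path), error = function(e) {
      vm_abort(sprintf("Cannot read TIFF '%s': %s", path, conditionMessage(e)),
               "vm_format_error", parent = e)
    }),
    dcm = , dicom = vm_abort(
      sprintf("DICOM input is not supported ('%s'); convert to PNG or TIFF.", path),
      "vm_format_error"),
    vm_abort(sprintf("Unsupported image format '.%s' ('%s').", ext, path),
             "vm_format_error")
  )
  if (length(dim(arr)) == 3) arr <- apply(arr, c(1, 2), mean)
  if (!is.matrix(arr)) arr <- as.matrix(arr)
  attr(arr, "pixel_spacing") <- NA_real_
  arr
}

#' Write a grayscale image as 16-bit TIFF or 8-bit PNG
#'
#' @param image Matrix with intensities in `[0, 1]`.
#' @param path Output path; format from the extension (`.tiff`/`.tif`
#'   written at 16 bits per sample, `.png` at 8).
#' @return Invisibly, `path`.
#' @export
write_image <- function(image, path) {
  check_image(image)
  img <- clamp(image, 0, 1)
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    switch(ext,
      png = png::writePNG(img, path),
      tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 16),
      abort_validation(sprintf("Unsupported output format '.%s'.", ext))
    )
    TRUE
  }, error = function(e) {
    if (inherits(e, "vm_error")) rlang::cnd_signal(e)
    abort_io(sprintf("Cannot write image '%s': %s", path, conditionMessage(e)))
  })
  invisible(path)
}

annotation_schema_version <- "1.0"

#' Write a landmark annotation table
#'
#' JSON (canonical, nested by landmark name) or CSV (flat, one column per
#' coordinate), chosen by extension. Coordinates are rounded to 6 decimal
#' places on write; a write/read round-trip is exact at that precision.
#'
#' @param records Landmark table with identity columns (`case_id`,
#'   `image_id`, `level`; `region`, `evaluator`, `frame` optional).
#' @param path Output `.json` or `.csv` path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(records, path) {
  records <- tibble::as_tibble(records)
  if (nrow(records) > 0) check_landmark_tbl(records, arg = "records")
  ext <- tolower(tools::file_ext(path))
  rec_list <- purrr::map(seq_len(nrow(records)), function(i) {
    row <- records[i, ]
    lms <- stats::setNames(purrr::map(landmark_names(), function(nm) {
      list(x = round(row[[paste0(nm, "_x")]], 6), y = round(row[[paste0(nm, "_y")]], 6))
    }), landmark_names())
    extra <- setdiff(names(row), c(landmark_cols()))
    c(as.list(row[extra]), list(landmarks = lms))
  })
  res <- tryCatch({
    if (ext == "json") {
      jsonlite::write_json(
        list(schema_version = annotation_schema_version, records = rec_list),
        path, auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
    } else if (ext == "csv") {
      out <- records
      for (cc in landmark_cols()) out[[cc]] <- round(out[[cc]], 6)
      readr::write_csv(out, path)
    } else {
      abort_validation(sprintf("Unsupported annotation format '.%s'.", ext))
    }
    TRUE
  }, error = function(e) {
    if (inherits(e, "vm_error")) rlang::cnd_signal(e)
    abort_io(sprintf("Cannot write annotations '%s': %s", path, conditionMessage(e)))
  })
  invisible(path)
}

#' Read a landmark annotation file
#'
#' Accepts the JSON schema written by [write_annotations()] or the flat CSV
#' dialect (columns matched by header name, so column order is free).
#' Unknown fields are preserved.
#'
#' @param path `.json` or `.csv` path.
#' @return Landmark table (tibble).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    vm_abort(sprintf("Annotation file not found: '%s'.", path), "vm_format_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    doc <- tryCatch(jsonlite::read_json(path), error = function(e) {
      vm_abort(sprintf("Cannot parse JSON '%s': %s", path, conditionMessage(e)),
               "vm_format_error", parent = e)
    })
    recs <- doc$records %||% list()
    if (length(recs) == 0) {
      return(dplyr::bind_cols(
        tibble::tibble(case_id = character(0), image_id = character(0),
                       level = character(0)),
        tibble::as_tibble(stats::setNames(rep(list(numeric(0)), 12),
                                          landmark_cols()))
      ))
    }
    rows <- purrr::map(recs, function(r) {
      lms <- r$landmarks %||% list()
      missing <- setdiff(landmark_names(), names(lms))
      if (length(missing) > 0) {
        vm_abort(sprintf(
          "Record (image_id = %s, level = %s) is missing landmark(s): %s.",
          r$image_id %||% "?", r$level %||% "?", paste(missing, collapse = ", ")
        ), "vm_schema_error")
      }
      coords <- unlist(purrr::map(landmark_names(), function(nm) {
        stats::setNames(list(lms[[nm]]$x, lms[[nm]]$y),
                        paste0(nm, c("_x", "_y")))
      }), recursive = FALSE)
      extra <- r[setdiff(names(r), "landmarks")]
      tibble::as_tibble(c(extra, coords))
    })
    out <- dplyr::bind_rows(rows)
  } else if (ext == "csv") {
    out <- tryCatch(
      readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
      error = function(e) {
        vm_abort(sprintf("Cannot parse CSV '%s': %s", path, conditionMessage(e)),
                 "vm_format_error", parent = e)
      })
    missing <- setdiff(landmark_cols(), names(out))
    if (length(missing) > 0) {
      vm_abort(sprintf("CSV '%s' is missing column(s): %s.", path,
                       paste(missing, collapse = ", ")), "vm_schema_error")
    }
  } else {
    vm_abort(sprintf("Unsupported annotation format '.%s' ('%s').", ext, path),
             "vm_format_error")
  }
  coords <- as.matrix(out[landmark_cols()])
  if (nrow(out) > 0 && !all(is.finite(coords))) {
    vm_abort(sprintf("Annotation file '%s' contains non-finite coordinates.", path),
             "vm_schema_error")
  }
  tibble::as_tibble(out)
}
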