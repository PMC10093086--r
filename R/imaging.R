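# Coordinate convention used by every function in the package: row-major,
# 0-based, half-open windows [start, start + size).

new_roi <- function(intensities, origin = c(0L, 0L), case_id = NA_character_,
                    exam_index = NA_integer_, laterality = NA_character_,
                    center_source = "unspecified") {
  structure(list(intensities = intensities, origin = as.integer(origin),
                 case_id = case_id, exam_index = exam_index,
                 laterality = laterality, center_source = center_source),
            class = "mt_roi")
}

#' @export
print.mt_roi <- function(x, ...) {
  cat(sprintf("<mt_roi> %d x %d, origin (%d, %d), case %s exam %s %s\n",
              nrow(x$intensities), ncol(x$intensities),
              x$origin[1], x$origin[2], x$case_id, x$exam_index,
              x$laterality))
  invisible(x)
}

new_image <- function(intensities, spacing_mm = c(0.07, 0.07),
                      laterality = NA_character_, view = "CC",
                      exam_date = as.Date(NA)) {
  if (!all(is.finite(intensities))) abort("image intensities must be finite")
  if (any(spacing_mm <= 0)) abort("pixel spacing must be positive")
  structure(list(intensities = intensities, spacing_mm = spacing_mm,
                 laterality = laterality, view = view, exam_date = exam_date),
            class = "mt_image")
}

#' @export
print.mt_image <- function(x, ...) {
  cat(sprintf("<mt_image> %d x %d @ %.3f x %.3f mm, %s %s\n",
              nrow(x$intensities), ncol(x$intensities),
              x$spacing_mm[1], x$spacing_mm[2], x$view, x$laterality))
  invisible(x)
}

#' Read a grayscale mammogram image
#'
#' Supports 8/16-bit PNG and TIFF and uncompressed explicit-VR little-endian
#' DICOM. Integer intensities are recovered losslessly. Pixel spacing is taken
#' from DICOM tags when present, otherwise from the `spacing_mm` argument
#' (e.g. forwarded from a manifest column), with a warning if neither exists.
#'
#' @param path file path; format inferred from the extension unless `format`
#'   is given.
#' @param format one of `"png"`, `"tiff"`, `"dicom"`.
#' @param spacing_mm fallback pixel spacing (mm per pixel, row/col pair).
#' @return An `mt_image`.
#' @export
read_image <- function(path, format = NULL, spacing_mm = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  format <- format %||% switch(tolower(tools::file_ext(path)),
    png = "png", tif = "tiff", tiff = "tiff", dcm = "dicom", dicom = "dicom",
    abort(sprintf("cannot infer image format from '%s'", path))
  )
  if (format == "dicom") {
    d <- read_dicom(path)
    sp <- d$spacing_mm %||% spacing_mm
    if (is.null(sp)) {
      warn("no PixelSpacing in DICOM and no manifest spacing; assuming 0.07 mm")
      sp <- c(0.07, 0.07)
    }
    return(new_image(d$intensities, spacing_mm = sp))
  }
  raw <- switch(format,
    png = {
      v <- png::readPNG(path)
      if (length(dim(v)) == 3L) v <- v[, , 1L]
      # readPNG rescales to [0,1]; recover integers via the IHDR bit depth
      depth <- as.integer(readBin(path, "raw", 25L)[25L])
      round(v * (2^depth - 1))
    },
    tiff = {
      v <- tiff::readTIFF(path, as.is = TRUE)
      if (length(dim(v)) == 3L) v <- v[, , 1L]
      v * 1.0
    },
    abort(sprintf("unsupported format '%s'", format))
  )
  if (is.null(spacing_mm)) {
    warn("no pixel spacing available; assuming 0.07 mm")
    spacing_mm <- c(0.07, 0.07)
  }
  new_image(raw, spacing_mm = spacing_mm)
}

#' Write an image or ROI patch to a 16-bit file
#'
#' TIFF output (`.tif`/`.tiff`) is 16-bit and lossless for integer intensities
#' in `[0, 65535]`. PNG output is 8-bit (the PNG writer available to the
#' package does not emit 16-bit) and therefore requires intensities in
#' `[0, 255]`.
#'
#' @param x an `mt_image`, `mt_roi`, or numeric matrix.
#' @param path output path ending in `.tif`, `.tiff`, or `.png`.
#' @export
write_image <- function(x, path) {
  v <- as_intensity_matrix(x)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (max(v) > 65535 || min(v) < 0) abort("intensities must lie in [0, 65535]")
    tiff::writeTIFF(round(v) / 65535, path, bits.per.sample = 16L,
                    compression = "none")
  } else if (ext == "png") {
    if (max(v) > 255 || min(v) < 0) {
      abort("PNG output is 8-bit; intensities must lie in [0, 255] (use TIFF)")
    }
    png::writePNG(round(v) / 255, path)
  } else {
    abort(sprintf("unsupported output extension '.%s'", ext))
  }
  invisible(path)
}

#' Extract the standard square ROI around a center point
#'
#' Exact crop, no interpolation, no zero-fill: the window must lie fully
#' inside the image. Coordinates are 0-based; the crop covers rows
#' `[center[1] - size/2, center[1] + size/2)` and likewise for columns.
#'
#' @param image an `mt_image` (or numeric matrix).
#' @param center integer pair (row, col), 0-based.
#' @param size ROI side in pixels (default 512).
#' @param case_id,exam_index,laterality,center_source provenance fields.
#' @return An `mt_roi`.
#' @export
extract_roi <- function(image, center, size = 512L,
                        case_id = NA_character_, exam_index = NA_integer_,
                        laterality = NA_character_,
                        center_source = "manual") {
  v <- as_intensity_matrix(image)
  half <- size %/% 2L
  r0 <- as.integer(center[1]) - half
  c0 <- as.integer(center[2]) - half
  if (r0 < 0L || c0 < 0L || r0 + size > nrow(v) || c0 + size > ncol(v)) {
    abort(sprintf(
      "ROI window [%d,%d) x [%d,%d) exceeds image bounds %d x %d",
      r0, r0 + size, c0, c0 + size, nrow(v), ncol(v)))
  }
  lat <- laterality
  if (is.na(lat) && inherits(image, "mt_image")) lat <- image$laterality
  new_roi(v[(r0 + 1L):(r0 + size), (c0 + 1L):(c0 + size)],
          origin = c(r0, c0), case_id = case_id, exam_index = exam_index,
          laterality = lat, center_source = center_source)
}

#' Automated ROI center posterior to the nipple
#'
#' A convenience surrogate for manual ROI placement: the breast foreground is
#' Otsu-thresholded, the center row is the foreground centroid row, and the
#' center column sits half an ROI side posterior (toward the chest-wall edge)
#' to the nipple-side foreground extremum on that row. A manually supplied
#' center always overrides the heuristic and is returned verbatim.
#'
#' @param image an `mt_image` (or matrix).
#' @param size ROI side the center is intended for.
#' @param manual optional integer pair; returned unchanged when provided.
#' @return Integer pair (row, col), 0-based.
#' @export
default_center <- function(image, size = 512L, manual = NULL) {
  if (!is.null(manual)) return(as.integer(manual))
  v <- as_intensity_matrix(image)
  rng <- range(v)
  if (rng[2] <= rng[1]) abort("image has no foreground (constant intensities)")
  u <- (v - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::as.Image(u))
  fg <- u > th
  if (!any(fg)) abort("image has no foreground above the Otsu threshold")
  rows <- row(fg)[fg]; cols <- col(fg)[fg]
  center_row <- round(mean(rows))
  # chest wall = the vertical image edge with more foreground contact
  left_contact <- sum(fg[, 1L]); right_contact <- sum(fg[, ncol(v)])
  row_fg <- which(fg[center_row, ])
  if (length(row_fg) == 0L) row_fg <- round(mean(cols))
  if (left_contact >= right_contact) {
    nipple_col <- max(row_fg)                 # chest wall left, nipple right
    center_col <- nipple_col - size %/% 2L
  } else {
    nipple_col <- min(row_fg)                 # chest wall right, nipple left
    center_col <- nipple_col + size %/% 2L
  }
  c(center_row - 1L, as.integer(center_col) - 1L)   # back to 0-based
}

#' Read a cohort manifest CSV
#'
#' @param path manifest written by [render_cohort()] (or hand-built with the
#'   same columns: `case_id, label, affected_laterality, laterality,
#'   exam_index, exam_date, image_path`; optional `center_row, center_col,
#'   spacing_mm`).
#' @return A tibble sorted by case, laterality and exam date.
#' @export
read_manifest <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("case_id", "label", "affected_laterality", "laterality",
            "exam_index", "exam_date", "image_path")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste("manifest lacks columns:", paste(missing, collapse = ", ")))
  }
  df$exam_date <- as.Date(df$exam_date)
  dplyr::arrange(df, .data$case_id, .data$laterality, .data$exam_date)
}
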