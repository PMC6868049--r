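#' Write an RF frame to disk
#'
#' The frame matrix is written either as flat binary of little-endian 32-bit
#' floats in column-major order (one scan line after another) with extension
#' `.f32`, or as a plain-text matrix (`.txt`, samples in rows, one scan line
#' per column). A JSON sidecar `<stem>.json` carries the acquisition
#' metadata, label and ROI markers.
#'
#' @param frame an `rf_frame`.
#' @param stem path stem (without extension).
#' @param format `"binary"` or `"text"`.
#' @return Invisibly, the paths written.
#' @export
write_rf_frame <- function(frame, stem, format = c("binary", "text")) {
  format <- match.arg(format)
  stopifnot(inherits(frame, "rf_frame"))
  g <- frame$geometry
  data_path <- paste0(stem, if (format == "binary") ".f32" else ".txt")
  if (format == "binary") {
    con <- file(data_path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(frame$samples), con, size = 4L, endian = "little")
  } else {
    utils::write.table(frame$samples, data_path, row.names = FALSE,
                       col.names = FALSE)
  }
  meta <- list(
    sampling_frequency = g$sampling_frequency,
    center_frequency = g$center_frequency,
    n_scanlines = g$n_scanlines,
    samples_per_line = g$samples_per_line,
    pulse_bandwidth = g$pulse_bandwidth,
    sound_speed = g$sound_speed,
    format = format,
    label = if (is.na(frame$label)) NULL else frame$label,
    roi_markers = if (!is.null(frame$lesion_roi)) unname(frame$lesion_roi$markers) else NULL,
    lesion_shape = frame$lesion_shape
  )
  json_path <- paste0(stem, ".json")
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(data = data_path, meta = json_path))
}

#' Read an RF frame written by [write_rf_frame()]
#'
#' @param stem path stem (without extension).
#' @return An `rf_frame`. The ROI is reconstructed from the stored lesion
#'   ellipse if present, otherwise from the stored markers.
#' @export
read_rf_frame <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  geometry <- acquisition_geometry(
    sampling_frequency = meta$sampling_frequency,
    center_frequency = meta$center_frequency,
    n_scanlines = meta$n_scanlines,
    samples_per_line = meta$samples_per_line,
    pulse_bandwidth = if (!is.null(meta$pulse_bandwidth)) meta$pulse_bandwidth else 0.6,
    sound_speed = if (!is.null(meta$sound_speed)) meta$sound_speed else 1540)
  n <- geometry$samples_per_line; nl <- geometry$n_scanlines
  if (identical(meta$format, "text")) {
    x <- as.matrix(utils::read.table(paste0(stem, ".txt")))
    dimnames(x) <- NULL
  } else {
    con <- file(paste0(stem, ".f32"), "rb")
    on.exit(close(con))
    x <- matrix(readBin(con, "numeric", n * nl, size = 4L, endian = "little"), n, nl)
  }
  if (!all(dim(x) == c(n, nl))) stop("frame dimensions do not match sidecar metadata")
  roi <- NULL
  if (!is.null(meta$lesion_shape)) {
    mask <- .ellipse_mask(n, nl, as.list(meta$lesion_shape))
    roi <- .roi_from_ellipse(mask, as.list(meta$lesion_shape))
  } else if (!is.null(meta$roi_markers)) {
    roi <- roi_from_markers(matrix(unlist(meta$roi_markers), ncol = 2), c(n, nl))
  }
  structure(list(samples = x, geometry = geometry,
                 label = if (is.null(meta$label)) NA_integer_ else as.integer(meta$label),
                 lesion_roi = roi,
                 lesion_shape = if (is.null(meta$lesion_shape)) NULL else as.list(meta$lesion_shape),
                 background = NULL, lesion = NULL, seed = NA_integer_),
            class = "rf_frame")
}

#' Write an 8-bit grayscale image as PNG
#'
#' @param image integer matrix with values in 0..255.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_gray_png <- function(image, path) {
  stopifnot(is.matrix(image), all(image >= 0), all(image <= 255))
  png::writePNG(image / 255, path)
  invisible(path)
}
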