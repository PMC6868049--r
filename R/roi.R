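#' ROI from four corner markers
#'
#' Builds the lesion region of interest from four marker points placed in
#' scan-line coordinates (the clinical convention of marking the tumor with
#' four "fork" points). The markers are ordered by angle about their
#' centroid and the enclosed quadrilateral is filled; a pixel belongs to the
#' ROI when its center lies inside the polygon, with the boundary counting
#' as inside. The mask is therefore invariant to any permutation of the four
#' markers.
#'
#' @param markers 4 x 2 matrix of (row, col) marker points, inside the frame
#'   and not collinear.
#' @param frame_shape integer vector `c(n_rows, n_cols)`.
#' @return An object of class `roi_region`: `markers` (angularly ordered),
#'   `mask` (logical matrix of `frame_shape`), `bounding_box`
#'   (`c(row0, row1, col0, col1)`, half-open).
#' @export
roi_from_markers <- function(markers, frame_shape) {
  markers <- as.matrix(markers)
  if (!all(dim(markers) == c(4L, 2L))) stop("markers must be a 4 x 2 matrix")
  if (any(!is.finite(markers))) stop("markers must be finite")
  nr <- frame_shape[1]; nc <- frame_shape[2]
  if (any(markers[, 1] < 1 | markers[, 1] > nr | markers[, 2] < 1 | markers[, 2] > nc))
    stop("markers out of frame bounds")

  ctr <- colMeans(markers)
  ord <- order(atan2(markers[, 1] - ctr[1], markers[, 2] - ctr[2]))
  poly <- markers[ord, , drop = FALSE]

  # shoelace area; collinear/degenerate markers enclose (almost) nothing
  y <- poly[, 1]; x <- poly[, 2]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  if (area < 1e-9) stop("markers are collinear or degenerate")

  r0 <- floor(min(y)); r1 <- ceiling(max(y))
  c0 <- floor(min(x)); c1 <- ceiling(max(x))
  rows <- r0:r1; cols <- c0:c1
  py <- rep(rows, times = length(cols))
  px <- rep(cols, each = length(rows))
  inside <- .point_in_polygon(px, py, x, y)

  mask <- matrix(FALSE, nr, nc)
  mask[cbind(py[inside], px[inside])] <- TRUE
  if (!any(mask)) stop("ROI mask is empty")
  rr <- range(which(rowSums(mask) > 0)); cc <- range(which(colSums(mask) > 0))
  structure(list(markers = poly, mask = mask,
                 bounding_box = c(row0 = rr[1], row1 = rr[2] + 1L,
                                  col0 = cc[1], col1 = cc[2] + 1L)),
            class = "roi_region")
}

# even-odd rule with an explicit boundary test (boundary counts as inside)
.point_in_polygon <- function(px, py, vx, vy) {
  npt <- length(px)
  nv <- length(vx)
  crossings <- integer(npt)
  on_edge <- logical(npt)
  eps <- 1e-9
  for (k in seq_len(nv)) {
    x1 <- vx[k]; y1 <- vy[k]
    k2 <- if (k == nv) 1L else k + 1L
    x2 <- vx[k2]; y2 <- vy[k2]
    # on-segment test
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    seg_len2 <- (x2 - x1)^2 + (y2 - y1)^2
    within <- (px - pmin(x1, x2) >= -eps) & (pmax(x1, x2) - px >= -eps) &
      (py - pmin(y1, y2) >= -eps) & (pmax(y1, y2) - py >= -eps)
    on_edge <- on_edge | (abs(cross) <= eps * (1 + sqrt(seg_len2)) & within)
    # ray casting (horizontal ray toward +x)
    hit <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    crossings <- crossings + hit
  }
  (crossings %% 2L == 1L) | on_edge
}

#' @export
print.roi_region <- function(x, ...) {
  bb <- x$bounding_box
  cat(sprintf("<roi_region> %d pixels, bbox rows [%d,%d) cols [%d,%d)\n",
              sum(x$mask), bb[1], bb[2], bb[3], bb[4]))
  invisible(x)
}

#' Extract the ROI bounding-box submatrix and mask
#'
#' @param mat matrix in frame coordinates (RF, envelope, or B-mode image).
#' @param roi an `roi_region`.
#' @return List with `values` (submatrix over the ROI bounding box) and
#'   `mask` (logical submatrix of the same shape).
#' @export
crop_roi <- function(mat, roi) {
  stopifnot(inherits(roi, "roi_region"))
  bb <- roi$bounding_box
  rows <- bb["row0"]:(bb["row1"] - 1L)
  cols <- bb["col0"]:(bb["col1"] - 1L)
  list(values = mat[rows, cols, drop = FALSE],
       mask = roi$mask[rows, cols, drop = FALSE])
}
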