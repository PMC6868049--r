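#' Hilbert envelope of RF data
#'
#' Magnitude of the analytic signal, computed per scan line (column) via the
#' FFT one-sided-spectrum construction. This is the standard envelope
#' detection step before log compression in B-mode formation.
#'
#' @param frame an `rf_frame` or a numeric matrix (axial samples x scan
#'   lines) of finite RF values.
#' @return Nonnegative matrix of the same shape.
#' @export
hilbert_envelope <- function(frame) {
  x <- if (inherits(frame, "rf_frame")) frame$samples else frame
  if (!is.matrix(x) || length(x) == 0) stop("frame must be a nonempty matrix")
  if (any(!is.finite(x))) stop("frame contains non-finite values")
  n <- nrow(x)
  if (n == 1L) return(abs(x))
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n)
}

#' Logarithmic compression to an 8-bit B-mode image
#'
#' Maps the envelope to decibels relative to its maximum, clips to
#' `[-dynamic_range_db, 0]`, and rescales affinely to 0..255 so the maximum
#' maps to 255.
#'
#' @param envelope nonnegative matrix (from [hilbert_envelope()]).
#' @param dynamic_range_db display dynamic range in dB (`> 0`).
#' @return Integer matrix with values in 0..255.
#' @export
log_compress <- function(envelope, dynamic_range_db = 60) {
  if (!is.matrix(envelope) || length(envelope) == 0) stop("envelope must be a nonempty matrix")
  if (any(envelope < 0)) stop("envelope must be nonnegative")
  if (dynamic_range_db <= 0) stop("dynamic_range_db must be > 0")
  mx <- max(envelope)
  if (mx == 0) stop("all-zero envelope: reference level undefined")
  db <- 20 * log10(envelope / mx)
  db <- pmax(db, -dynamic_range_db)
  px <- .round_half_up(255 * (1 + db / dynamic_range_db))
  matrix(as.integer(px), nrow(envelope), ncol(envelope))
}

.round_half_up <- function(x) floor(x + 0.5)

#' B-mode image of an RF frame
#'
#' Envelope detection, optional time-gain compensation, and log compression.
#' Clinical grayscale images are displayed after the scanner's time-gain
#' compensation (TGC) flattens the bulk depth decay; `tgc = TRUE` emulates
#' this by dividing each depth row of the envelope by its lateral mean
#' smoothed along depth, so the grayscale control image carries speckle
#' texture but not the raw attenuation trend (which stays available to the
#' RF-domain maps).
#'
#' @inheritParams hilbert_envelope
#' @inheritParams log_compress
#' @param tgc apply adaptive time-gain compensation before compression.
#' @return Integer matrix with values in 0..255.
#' @export
bmode_image <- function(frame, dynamic_range_db = 60, tgc = TRUE) {
  env <- hilbert_envelope(frame)
  if (tgc) env <- tgc_compensate(env)
  log_compress(env, dynamic_range_db)
}

#' Display-grade grayscale image of an RF frame
#'
#' Emulates the scanner's displayed grayscale image: envelope detection,
#' adaptive time-gain compensation, log compression, axial decimation to a
#' display-scale pixel grid (block averaging; RF is sampled far more densely
#' than the display raster), and a 3x3 smoothing pass standing in for
#' speckle-reduction / display interpolation. This is the "conventional
#' grayscale image" control: post-processing discards part of the raw
#' signal information that the RF-domain parametric maps retain.
#'
#' @inheritParams hilbert_envelope
#' @inheritParams log_compress
#' @param axial_decim axial block-averaging factor to the display grid.
#' @param smooth size of the square smoothing kernel (odd; 1 = none).
#' @return Integer matrix in 0..255 with `floor(n_samples / axial_decim)`
#'   rows.
#' @export
display_bmode <- function(frame, dynamic_range_db = 60, axial_decim = 4L,
                          smooth = 3L) {
  env <- tgc_compensate(hilbert_envelope(frame))
  bm <- log_compress(env, dynamic_range_db)
  dd <- .block_decimate(bm, axial_decim)
  if (smooth > 1L) dd <- .boxcar2(dd, as.integer(smooth))
  matrix(as.integer(.round_half_up(dd)), nrow(dd), ncol(dd))
}

.block_decimate <- function(x, k) {
  k <- as.integer(k)
  if (k <= 1L) return(x)
  nr <- (nrow(x) %/% k) * k
  matrix(colMeans(matrix(x[seq_len(nr), , drop = FALSE], k)), nr %/% k, ncol(x))
}

# edge-replicated square moving average
.boxcar2 <- function(x, k) {
  if (k %% 2L == 0L) k <- k + 1L
  h <- (k - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  ri <- pmin(pmax(seq(1 - h, nr + h), 1), nr)
  ci <- pmin(pmax(seq(1 - h, nc + h), 1), nc)
  p <- x[ri, ci, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (dr in 0:(k - 1)) for (dc in 0:(k - 1))
    out <- out + p[dr + seq_len(nr), dc + seq_len(nc), drop = FALSE]
  out / k^2
}

#' Decimate a logical mask to the display grid
#'
#' Axial block majority (ties count as inside), matching [display_bmode()].
#'
#' @param mask logical matrix.
#' @param axial_decim block factor.
#' @return Logical matrix with `floor(nrow / axial_decim)` rows.
#' @export
decimate_mask <- function(mask, axial_decim = 4L) {
  k <- as.integer(axial_decim)
  if (k <= 1L) return(mask)
  nr <- (nrow(mask) %/% k) * k
  matrix(colMeans(matrix(mask[seq_len(nr), , drop = FALSE], k)) >= 0.5,
         nr %/% k, ncol(mask))
}

#' Per-ROI intensity normalization of a grayscale image
#'
#' Z-scores the image against the mean and standard deviation of the masked
#' pixels, clips at `clip` standard deviations, and rescales to 0..255.
#' Standard practice before texture discretization when image brightness is
#' operator- or machine-dependent (as displayed ultrasound grayscale is).
#'
#' @param image numeric matrix.
#' @param mask logical matrix of the same shape; statistics use masked
#'   pixels only.
#' @param clip symmetric clipping point in standard deviations.
#' @return Integer matrix in 0..255 (constant input maps to 128).
#' @export
znormalize_image <- function(image, mask = NULL, clip = 3) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  mu <- mean(image[mask])
  sd <- stats::sd(image[mask])
  if (!is.finite(sd) || sd == 0) return(matrix(128L, nrow(image), ncol(image)))
  z <- pmin(pmax((image - mu) / sd, -clip), clip)
  matrix(as.integer(.round_half_up(255 * (z + clip) / (2 * clip))),
         nrow(image), ncol(image))
}

#' Adaptive time-gain compensation of an envelope
#'
#' Divides each depth row by the frame's lateral mean envelope at that
#' depth, smoothed along depth with a moving average, emulating the
#' scanner's gain curve.
#'
#' @param envelope nonnegative matrix (depth x lines).
#' @param smooth_samples length of the axial moving-average window.
#' @return Compensated envelope of the same shape.
#' @export
tgc_compensate <- function(envelope, smooth_samples = 129L) {
  prof <- rowMeans(envelope)
  k <- min(as.integer(smooth_samples), nrow(envelope))
  if (k %% 2 == 0) k <- k - 1L
  if (k >= 3) {
    half <- (k - 1L) %/% 2L
    padded <- c(rep(prof[1], half), prof, rep(prof[length(prof)], half))
    prof <- stats::filter(padded, rep(1 / k, k), sides = 2)[(half + 1):(half + length(prof))]
  }
  gain <- ifelse(prof > 0, 1 / prof, 0)
  envelope * gain
}
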