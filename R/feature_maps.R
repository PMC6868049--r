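#' Sliding-window specification for parametric maps
#'
#' Defaults follow common quantitative-ultrasound practice: axial windows of
#' 128 samples (roughly ten pulse lengths at the default geometry), 8 scan
#' lines wide, with 50% overlap on both axes.
#'
#' @param axial_len window length in axial samples (`>= 8`).
#' @param lateral_len window width in scan lines (`>= 2`).
#' @param axial_step,lateral_step window steps (`>= 1`).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(axial_len = 128L, lateral_len = 8L,
                        axial_step = 64L, lateral_step = 4L) {
  axial_len <- as.integer(axial_len); lateral_len <- as.integer(lateral_len)
  axial_step <- as.integer(axial_step); lateral_step <- as.integer(lateral_step)
  if (axial_len < 8L) stop("axial_len must be >= 8")
  if (lateral_len < 2L) stop("lateral_len must be >= 2")
  if (axial_step < 1L || lateral_step < 1L) stop("steps must be >= 1")
  structure(list(axial_len = axial_len, lateral_len = lateral_len,
                 axial_step = axial_step, lateral_step = lateral_step),
            class = "window_spec")
}

#' Sliding-window grid start positions
#'
#' @param n_rows,n_cols dimensions of the data the windows slide over.
#' @param window a [window_spec()].
#' @return List with integer vectors `ax` and `lat` of window start indices.
#' @export
window_grid <- function(n_rows, n_cols, window) {
  if (n_rows < window$axial_len || n_cols < window$lateral_len)
    stop("data smaller than one window")
  list(ax = seq(1L, n_rows - window$axial_len + 1L, by = window$axial_step),
       lat = seq(1L, n_cols - window$lateral_len + 1L, by = window$lateral_step))
}

.new_feature_map <- function(kind, values, window, extra = list()) {
  n_missing <- sum(is.na(values))
  imputed <- values
  if (n_missing > 0) {
    fill <- mean(values, na.rm = TRUE)
    if (!is.finite(fill)) fill <- 0
    imputed[is.na(imputed)] <- fill
  }
  structure(c(list(kind = kind, values = values, values_imputed = imputed,
                   window = window, n_missing = n_missing), extra),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map %s> %d x %d windows, %d missing (mean-imputed)\n",
              x$kind, nrow(x$values), ncol(x$values), x$n_missing))
  invisible(x)
}

# 2-D summed-area table padded with a leading zero row/col
.integral2 <- function(x) {
  cs <- apply(x, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  rbind(0, cbind(0, cs))
}
.rect_sum <- function(I, r0, r1, c0, c1) {
  I[cbind(r1 + 1, c1 + 1)] - I[cbind(r0, c1 + 1)] -
    I[cbind(r1 + 1, c0)] + I[cbind(r0, c0)]
}

#' Direct energy attenuation (DEA) map
#'
#' Per window, the least-squares slope (dB/cm) of the windowed log-energy
#' depth profile: the window is split into eight axial sub-windows, the mean
#' squared RF of each sub-window (over all lines in the window) is expressed
#' in dB, and regressed on the sub-window center depth. Negative values mean
#' energy loss with depth; for tissue with attenuation coefficient `alpha`
#' (dB cm^-1 MHz^-1) the expected value is `-alpha * fc` (fc in MHz).
#'
#' Windows with non-positive energy in any sub-window are recorded as
#' missing and mean-imputed from the rest of the map (`n_missing` reports
#' the count).
#'
#' @param roi_rf RF matrix restricted to the ROI bounding box.
#' @param window a [window_spec()].
#' @param fs sampling frequency in Hz.
#' @param sound_speed assumed sound speed in m/s (pulse-echo depth scale).
#' @return A `feature_map` with `kind = "DEA"`.
#' @export
dea_map <- function(roi_rf, window = window_spec(), fs,
                    sound_speed = 1540) {
  grid <- window_grid(nrow(roi_rf), ncol(roi_rf), window)
  nsub <- 8L
  sub_len <- window$axial_len %/% nsub
  I2 <- .integral2(roi_rf^2)
  dz_cm <- sound_speed / (2 * fs) * 100

  vals <- matrix(NA_real_, length(grid$ax), length(grid$lat))
  sub_off <- (seq_len(nsub) - 1L) * sub_len
  for (ii in seq_along(grid$ax)) {
    r <- grid$ax[ii]
    r0s <- r + sub_off
    r1s <- r0s + sub_len - 1L
    z <- (r0s + r1s) / 2 * dz_cm
    for (jj in seq_along(grid$lat)) {
      c0 <- grid$lat[jj]; c1 <- c0 + window$lateral_len - 1L
      e <- .rect_sum(I2, r0s, r1s, rep(c0, nsub), rep(c1, nsub)) /
        (sub_len * window$lateral_len)
      if (any(e <= 0)) next
      y <- 10 * log10(e)
      vals[ii, jj] <- stats::cov(z, y) / stats::var(z)
    }
  }
  .new_feature_map("DEA", vals, window)
}

#' Standard deviation of spectrum difference (SDSD) map
#'
#' Per window, the magnitude spectrum of each Hann-tapered scan-line segment
#' is averaged over the window's lines, expressed in dB, and restricted to
#' the -20 dB pulse band. The map value is the standard deviation, over the
#' band frequencies, of the difference between the window spectrum and a
#' reference spectrum; the reference is the mean spectrum of the shallowest
#' window row of the same ROI, which keeps the map self-contained.
#'
#' @inheritParams dea_map
#' @param band analysis band `c(lo, hi)` in Hz, typically [pulse_band()].
#' @return A `feature_map` with `kind = "SDSD"`.
#' @export
sdsd_map <- function(roi_rf, window = window_spec(), fs, band) {
  grid <- window_grid(nrow(roi_rf), ncol(roi_rf), window)
  nfft <- window$axial_len
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  bins <- which(freqs >= band[1] & freqs <= band[2] & freqs <= fs / 2)
  if (length(bins) < 3) stop("analysis band holds fewer than 3 FFT bins")
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nfft) - 1) / (nfft - 1))

  nlat <- length(grid$lat); nax <- length(grid$ax)
  # per axial row of windows: line spectra over the full ROI width, then
  # average magnitude over each window's lines
  spec_db <- array(NA_real_, c(length(bins), nax, nlat))
  for (ii in seq_len(nax)) {
    r <- grid$ax[ii]
    seg <- roi_rf[r:(r + nfft - 1L), , drop = FALSE] * hann
    mag <- Mod(stats::mvfft(seg))[bins, , drop = FALSE]
    for (jj in seq_len(nlat)) {
      c0 <- grid$lat[jj]
      m <- rowMeans(mag[, c0:(c0 + window$lateral_len - 1L), drop = FALSE])
      if (all(m > 0)) spec_db[, ii, jj] <- 20 * log10(m)
    }
  }
  ref <- rowMeans(spec_db[, 1L, , drop = FALSE], na.rm = TRUE)
  if (all(is.na(ref))) stop("reference window row has no usable spectra")
  vals <- matrix(NA_real_, nax, nlat)
  for (ii in seq_len(nax)) for (jj in seq_len(nlat)) {
    s <- spec_db[, ii, jj]
    if (!any(is.na(s))) vals[ii, jj] <- stats::sd(s - ref)
  }
  .new_feature_map("SDSD", vals, window)
}

#' Nakagami scale (OND) map
#'
#' Per window, moment estimates of the Nakagami parameters on the envelope
#' `R`: the map value is `omega_hat = mean(R^2)` (the mean envelope power);
#' the shape `m_hat = mean(R^2)^2 / var(R^2)` is kept as a diagnostic layer
#' (`m_hat` is `NA` in zero-variance windows; `omega_hat` is still emitted).
#'
#' @param roi_envelope envelope matrix (nonnegative) over the ROI bounding box.
#' @param window a [window_spec()]; each window must hold at least 64 samples.
#' @return A `feature_map` with `kind = "OND"` and an extra `m_hat` matrix.
#' @export
ond_map <- function(roi_envelope, window = window_spec()) {
  if (any(roi_envelope < 0)) stop("envelope must be nonnegative")
  if (window$axial_len * window$lateral_len < 64L)
    stop("each window must hold at least 64 samples")
  grid <- window_grid(nrow(roi_envelope), ncol(roi_envelope), window)
  e2 <- roi_envelope^2
  I2 <- .integral2(e2)
  I4 <- .integral2(e2^2)
  nwin <- window$axial_len * window$lateral_len

  omega <- matrix(NA_real_, length(grid$ax), length(grid$lat))
  mhat <- omega
  for (ii in seq_along(grid$ax)) {
    r0 <- grid$ax[ii]; r1 <- r0 + window$axial_len - 1L
    for (jj in seq_along(grid$lat)) {
      c0 <- grid$lat[jj]; c1 <- c0 + window$lateral_len - 1L
      s2 <- .rect_sum(I2, r0, r1, c0, c1)
      s4 <- .rect_sum(I4, r0, r1, c0, c1)
      om <- s2 / nwin
      v <- s4 / nwin - om^2
      omega[ii, jj] <- om
      if (v > 0) mhat[ii, jj] <- om^2 / v
    }
  }
  .new_feature_map("OND", omega, window, extra = list(m_hat = mhat))
}

#' Render a feature map to an 8-bit image
#'
#' Affine normalization of the (imputed) map values to 0..255 with
#' round-half-up. By default the map's own min-max range is used; a constant
#' map renders as mid-gray 128 (division-by-zero guard). Supplying
#' `value_range` renders on a fixed physical scale (like a fixed colormap),
#' clipping values outside it, so renderings are comparable across lesions.
#' The value range used is attached, making the rendering invertible up to
#' quantization (and clipping).
#'
#' @param map a `feature_map`.
#' @param value_range optional fixed `c(lo, hi)` rendering range.
#' @return Integer matrix in 0..255 with attribute `value_range`.
#' @export
render_map <- function(map, value_range = NULL) {
  stopifnot(inherits(map, "feature_map"))
  v <- map$values_imputed
  if (any(!is.finite(v))) stop("map contains non-finite values after imputation")
  rng <- if (is.null(value_range)) range(v) else as.numeric(value_range)
  if (rng[1] >= rng[2]) {
    img <- matrix(128L, nrow(v), ncol(v))
  } else {
    v <- pmin(pmax(v, rng[1]), rng[2])
    img <- matrix(as.integer(.round_half_up(255 * (v - rng[1]) / (rng[2] - rng[1]))),
                  nrow(v), ncol(v))
  }
  attr(img, "value_range") <- rng
  img
}

#' Window-grid mask for a feature map
#'
#' Marks the windows whose center pixel lies inside the ROI mask, mapping
#' the pixel-level ROI onto the map grid.
#'
#' @param roi_mask logical matrix over the ROI bounding box.
#' @param window a [window_spec()].
#' @return Logical matrix over the window grid. If no window center falls
#'   inside the ROI, all windows are kept.
#' @export
map_grid_mask <- function(roi_mask, window) {
  grid <- window_grid(nrow(roi_mask), ncol(roi_mask), window)
  ctr_r <- grid$ax + window$axial_len %/% 2L
  ctr_c <- grid$lat + window$lateral_len %/% 2L
  ctr_r <- pmin(ctr_r, nrow(roi_mask))
  ctr_c <- pmin(ctr_c, ncol(roi_mask))
  m <- roi_mask[ctr_r, ctr_c, drop = FALSE]
  if (!any(m)) m[] <- TRUE
  m
}

#' All parametric maps and images for one lesion
#'
#' Runs the first feature extraction for a frame: crops the ROI bounding
#' box, computes the DEA, OND and SDSD maps on the ROI RF/envelope, renders
#' them to 8-bit, and extracts the B-mode ROI image. The returned images and
#' masks feed the texture battery.
#'
#' @param frame an `rf_frame` with a lesion ROI (or `roi` supplied).
#' @param window a [window_spec()].
#' @param roi optional `roi_region` overriding the frame's own.
#' @param dynamic_range_db B-mode display dynamic range.
#' @param render_ranges fixed physical rendering ranges for the three maps
#'   (DEA in dB/cm, OND in envelope-power units, SDSD in dB), so the 8-bit
#'   maps are comparable across lesions; any element set to `NULL` falls
#'   back to per-map min-max.
#' @param axial_decim display decimation of the grayscale control image
#'   (see [display_bmode()]).
#' @return List with `maps` (feature_map objects `dea`, `ond`, `sdsd`),
#'   `images` (8-bit images + masks for `gm`, `dea`, `ond`, `sdsd`; the `gm`
#'   entry lives on the decimated display grid) and `parameter_means`
#'   (per-lesion mean DEA/OND/SDSD over the map mask).
#' @export
lesion_feature_maps <- function(frame, window = window_spec(), roi = NULL,
                                dynamic_range_db = 60,
                                render_ranges = list(dea = c(-8, 2),
                                                     ond = c(0, 1),
                                                     sdsd = c(0, 8)),
                                axial_decim = 4L) {
  stopifnot(inherits(frame, "rf_frame"))
  roi <- if (is.null(roi)) frame$lesion_roi else roi
  if (is.null(roi)) stop("frame has no ROI")
  env <- hilbert_envelope(frame)
  rf_c <- crop_roi(frame$samples, roi)
  env_c <- crop_roi(env, roi)

  # display-grade grayscale control image, ROI on the display grid;
  # grayscale brightness is operator- and machine-dependent, so the ROI is
  # intensity-normalized per lesion before texture analysis (the parametric
  # maps, by contrast, are physical quantities rendered on fixed scales)
  disp <- display_bmode(frame, dynamic_range_db, axial_decim)
  dmask <- decimate_mask(roi$mask, axial_decim)
  drows <- range(which(rowSums(dmask) > 0))
  dcols <- range(which(colSums(dmask) > 0))
  gm_mask <- dmask[drows[1]:drows[2], dcols[1]:dcols[2], drop = FALSE]
  gm_img <- znormalize_image(disp[drows[1]:drows[2], dcols[1]:dcols[2],
                                  drop = FALSE], gm_mask)

  fs <- frame$geometry$sampling_frequency
  dea <- dea_map(rf_c$values, window, fs, frame$geometry$sound_speed)
  ond <- ond_map(env_c$values, window)
  sdsd <- sdsd_map(rf_c$values, window, fs, pulse_band(frame$geometry))
  gmask <- map_grid_mask(rf_c$mask, window)

  pm <- c(dea = mean(dea$values_imputed[gmask]),
          ond = mean(ond$values_imputed[gmask]),
          sdsd = mean(sdsd$values_imputed[gmask]))
  list(
    maps = list(dea = dea, ond = ond, sdsd = sdsd),
    images = list(
      gm = list(image = gm_img, mask = gm_mask),
      dea = list(image = render_map(dea, render_ranges$dea), mask = gmask),
      ond = list(image = render_map(ond, render_ranges$ond), mask = gmask),
      sdsd = list(image = render_map(sdsd, render_ranges$sdsd), mask = gmask)),
    parameter_means = pm)
}

#' Per-lesion mean map parameters for a cohort
#'
#' @param cohort an `rf_cohort`.
#' @param window a [window_spec()].
#' @return data.frame with columns `label`, `dea`, `ond`, `sdsd`.
#' @export
cohort_parameter_means <- function(cohort, window = window_spec()) {
  rows <- lapply(cohort, function(f) {
    pm <- lesion_feature_maps(f, window)$parameter_means
    data.frame(label = f$label, dea = pm["dea"], ond = pm["ond"],
               sdsd = pm["sdsd"], row.names = NULL)
  })
  do.call(rbind, rows)
}
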