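#' Simulate one RF frame with an embedded elliptical lesion
#'
#' Generates a scan-line RF frame by convolving a random scatterer
#' reflectivity train with a Gaussian-modulated pulse, imposing the tissue's
#' Nakagami envelope statistics, and applying depth-dependent attenuation.
#'
#' Per scan line the reflectivity is a complex random train (dense Gaussian
#' at the default scatterer density, Bernoulli-thinned when sparse) convolved
#' with the analytic pulse. Local spectral heterogeneity is produced by
#' perturbing the pulse center frequency independently per scan line and
#' depth block (fractional SD `spectral_jitter_sd` of the enclosing tissue).
#' The envelope marginal is then mapped exactly onto Nakagami(m, omega) of
#' the enclosing tissue through the probability integral transform of the
#' (Rayleigh) speckle envelope, which preserves the speckle phase and
#' correlation structure. Finally the signal is multiplied by the cumulative
#' one-way amplitude attenuation `10^(-fc * integral(alpha) / 20)` with
#' `alpha` in dB cm^-1 MHz^-1 and depth in cm, so the local slope of the
#' log-power depth profile equals `-alpha * fc` (dB/cm) of the local tissue.
#'
#' @param geometry an [acquisition_geometry()].
#' @param background [tissue_class_params()] of the surrounding tissue.
#' @param lesion [tissue_class_params()] of the lesion, or `NULL` for a
#'   homogeneous frame.
#' @param lesion_shape list with `center_row`, `center_col`, `semi_axial`
#'   (samples), `semi_lateral` (lines) describing the lesion ellipse;
#'   required when `lesion` is given. The ellipse must fit inside the frame.
#' @param seed integer seed; the same seed and parameters give a
#'   bit-identical frame.
#' @param label optional binary class label stored on the frame.
#' @param jitter_block axial block length (samples) over which the local
#'   pulse center frequency is held constant.
#' @return An object of class `rf_frame`: list with `samples`
#'   (samples x scan lines matrix), `geometry`, `label`, `lesion_roi`
#'   (an `roi_region` or `NULL`), `lesion_shape`, and the tissue parameters.
#' @export
simulate_rf_frame <- function(geometry, background, lesion = NULL,
                              lesion_shape = NULL, seed = 1L,
                              label = NA_integer_, jitter_block = 256L) {
  stopifnot(inherits(geometry, "acq_geometry"), inherits(background, "tissue_params"))
  n <- geometry$samples_per_line
  nl <- geometry$n_scanlines

  lesion_mask <- NULL
  if (!is.null(lesion)) {
    stopifnot(inherits(lesion, "tissue_params"))
    if (is.null(lesion_shape)) stop("lesion_shape required when a lesion class is given")
    lesion_mask <- .ellipse_mask(n, nl, lesion_shape)
  }

  # per-pixel tissue parameter maps
  pick <- function(field) {
    v <- matrix(background[[field]], n, nl)
    if (!is.null(lesion_mask)) v[lesion_mask] <- lesion[[field]]
    v
  }
  m_map <- pick("nakagami_m")
  o_map <- pick("nakagami_omega")
  a_map <- pick("attenuation_db_per_cm_mhz")

  pul <- .gauss_pulse(geometry)
  np <- length(pul$p)
  cell_samples <- max(1, 2 * sqrt(2 * log(2)) * pul$sigma_t * geometry$sampling_frequency)

  withr::local_seed(seed)

  # analytic speckle, blockwise to allow local center-frequency jitter
  g <- matrix(0i, n + np - 1, nl)
  starts <- seq(1L, n, by = as.integer(jitter_block))
  fc <- geometry$center_frequency
  for (s in starts) {
    blen <- min(jitter_block, n - s + 1L)
    lfft <- blen + np - 1L
    dens <- pick("scatterer_density")[s:(s + blen - 1L), , drop = FALSE] / cell_samples
    w <- matrix(stats::rnorm(blen * nl), blen, nl) +
      1i * matrix(stats::rnorm(blen * nl), blen, nl)
    w <- w / sqrt(2)
    if (any(dens < 1)) {
      keep <- matrix(stats::runif(blen * nl), blen, nl) < pmin(dens, 1)
      w <- w * ifelse(dens < 1, keep / sqrt(pmin(dens, 1)), 1) * sqrt(dens)
    } else {
      w <- w * sqrt(dens)
    }
    mid <- min(n, s + blen %/% 2L)
    jsd <- if (!is.null(lesion_mask)) {
      ifelse(lesion_mask[mid, ], lesion$spectral_jitter_sd, background$spectral_jitter_sd)
    } else rep(background$spectral_jitter_sd, nl)
    fj <- fc * (1 + stats::rnorm(nl, 0, 1) * jsd)
    pm <- pul$env * exp(2i * pi * outer(pul$tt, fj))
    W <- stats::mvfft(rbind(w, matrix(0i, np - 1L, nl)))
    P <- stats::mvfft(rbind(pm, matrix(0i, blen - 1L, nl)))
    seg <- stats::mvfft(W * P, inverse = TRUE) / lfft
    g[s:(s + lfft - 1L), ] <- g[s:(s + lfft - 1L), ] + seg
  }
  off <- (np - 1L) %/% 2L
  g <- g[(off + 1L):(off + n), , drop = FALSE]

  # impose the Nakagami envelope marginal via the probability integral
  # transform of the complex-Gaussian speckle envelope
  dens_full <- pick("scatterer_density") / cell_samples
  sig2 <- sum(Mod(pul$p)^2) * dens_full # E|g|^2 per sample
  u <- stats::pgamma(Mod(g)^2, shape = 1, rate = 1 / sig2)
  u <- pmin(pmax(u, 1e-15), 1 - 1e-15)
  env <- sqrt(stats::qgamma(u, shape = m_map, rate = m_map / o_map))
  rf <- env * cos(Arg(g))

  # cumulative one-way attenuation at the pulse center frequency
  dz_cm <- geometry$axial_step_mm / 10
  cum_db <- apply(a_map, 2, cumsum) * dz_cm * (fc / 1e6)
  rf <- rf * 10^(-cum_db / 20)

  roi <- if (!is.null(lesion_mask)) .roi_from_ellipse(lesion_mask, lesion_shape) else NULL
  structure(list(samples = rf, geometry = geometry, label = label,
                 lesion_roi = roi, lesion_shape = lesion_shape,
                 background = background, lesion = lesion, seed = seed),
            class = "rf_frame")
}

.ellipse_mask <- function(n, nl, shape) {
  need <- c("center_row", "center_col", "semi_axial", "semi_lateral")
  if (!all(need %in% names(shape))) stop("lesion_shape needs ", paste(need, collapse = ", "))
  r0 <- shape$center_row; c0 <- shape$center_col
  a <- shape$semi_axial; b <- shape$semi_lateral
  if (a < 1 || b < 1) stop("lesion semi-axes must be >= 1")
  if (r0 - a < 1 || r0 + a > n || c0 - b < 1 || c0 + b > nl)
    stop("lesion ellipse does not fit inside the frame")
  rr <- matrix(seq_len(n), n, nl)
  cc <- matrix(seq_len(nl), n, nl, byrow = TRUE)
  ((rr - r0) / a)^2 + ((cc - c0) / b)^2 <= 1
}

.roi_from_ellipse <- function(mask, shape) {
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  markers <- cbind(row = c(rows[1], shape$center_row, rows[2], shape$center_row),
                   col = c(shape$center_col, cols[2], shape$center_col, cols[1]))
  structure(list(markers = markers, mask = mask,
                 bounding_box = c(row0 = rows[1], row1 = rows[2] + 1L,
                                  col0 = cols[1], col1 = cols[2] + 1L)),
            class = "roi_region")
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("<rf_frame> %d x %d, label=%s, lesion=%s, seed=%d\n",
              nrow(x$samples), ncol(x$samples),
              ifelse(is.na(x$label), "NA", x$label),
              ifelse(is.null(x$lesion_roi), "none", "ellipse"), x$seed))
  invisible(x)
}

#' Generate a labeled synthetic cohort
#'
#' Simulates `n_pos + n_neg` RF frames whose lesions follow two tissue
#' classes. Per-frame acoustic parameters are jittered around the class
#' means so within-class variability exists, and the lesion ellipse position
#' and size vary from frame to frame. All randomness flows from one seeded
#' generator, so a fixed seed reproduces the cohort exactly.
#'
#' @param n_pos,n_neg number of positive / negative lesions (`>= 1`).
#' @param pos_params,neg_params class-mean [tissue_class_params()]; defaults
#'   from [mvi_class_defaults()].
#' @param geometry an [acquisition_geometry()].
#' @param seed integer cohort seed.
#' @param param_jitter SDs of the per-frame parameter jitter: absolute for
#'   `attenuation` (dB cm^-1 MHz^-1), `nakagami_m` and `spectral_jitter`;
#'   log-scale for `nakagami_omega`.
#' @param lesion_base lesion ellipse layout as fractions of the frame:
#'   center position, semi-axes, and their relative jitter.
#' @return A list of [simulate_rf_frame()] frames (class `rf_cohort`),
#'   positives first, each carrying `label` 1 or 0 and its `lesion_roi`.
#' @export
make_cohort <- function(n_pos = 21L, n_neg = 21L,
                        pos_params = mvi_class_defaults()$pos,
                        neg_params = mvi_class_defaults()$neg,
                        geometry = acquisition_geometry(),
                        seed = 1L,
                        param_jitter = list(attenuation = 0.05, nakagami_m = 0.05,
                                            nakagami_omega = 0.05, spectral_jitter = 0.01),
                        lesion_base = list(center_row_frac = 0.55, center_col_frac = 0.5,
                                           semi_axial_frac = 0.16, semi_lateral_frac = 0.22,
                                           pos_jitter_frac = 0.04, size_jitter = 0.15)) {
  if (n_pos < 1L || n_neg < 1L) stop("n_pos and n_neg must be >= 1")
  stopifnot(inherits(geometry, "acq_geometry"))
  n <- geometry$samples_per_line; nl <- geometry$n_scanlines

  withr::local_seed(seed)
  ntot <- n_pos + n_neg
  labels <- rep(c(1L, 0L), c(n_pos, n_neg))
  frame_seeds <- sample.int(.Machine$integer.max - 1L, ntot)

  jit <- function(mean, sd, lo) max(lo, mean + stats::rnorm(1, 0, sd))
  frames <- vector("list", ntot)
  for (i in seq_len(ntot)) {
    cls <- if (labels[i] == 1L) pos_params else neg_params
    par_i <- tissue_class_params(
      attenuation_db_per_cm_mhz = jit(cls$attenuation_db_per_cm_mhz,
                                      param_jitter$attenuation, 0.01),
      nakagami_m = jit(cls$nakagami_m, param_jitter$nakagami_m, 0.1),
      nakagami_omega = cls$nakagami_omega *
        exp(stats::rnorm(1, 0, param_jitter$nakagami_omega)),
      scatterer_density = cls$scatterer_density,
      spectral_jitter_sd = jit(cls$spectral_jitter_sd, param_jitter$spectral_jitter, 0))
    bg_i <- tissue_class_params(
      attenuation_db_per_cm_mhz = neg_params$attenuation_db_per_cm_mhz,
      nakagami_m = neg_params$nakagami_m,
      nakagami_omega = neg_params$nakagami_omega,
      scatterer_density = neg_params$scatterer_density,
      spectral_jitter_sd = neg_params$spectral_jitter_sd)

    sz <- function(frac, total) round(total * frac *
                                        stats::runif(1, 1 - lesion_base$size_jitter,
                                                     1 + lesion_base$size_jitter))
    a <- max(8, sz(lesion_base$semi_axial_frac, n))
    b <- max(3, sz(lesion_base$semi_lateral_frac, nl))
    r0 <- round(n * (lesion_base$center_row_frac +
                       stats::runif(1, -lesion_base$pos_jitter_frac,
                                    lesion_base$pos_jitter_frac)))
    c0 <- round(nl * (lesion_base$center_col_frac +
                        stats::runif(1, -lesion_base$pos_jitter_frac,
                                     lesion_base$pos_jitter_frac)))
    r0 <- min(max(r0, a + 1), n - a)
    c0 <- min(max(c0, b + 1), nl - b)

    frames[[i]] <- simulate_rf_frame(
      geometry, background = bg_i, lesion = par_i,
      lesion_shape = list(center_row = r0, center_col = c0,
                          semi_axial = a, semi_lateral = b),
      seed = frame_seeds[i], label = labels[i])
    frames[[i]]$true_params <- par_i
  }
  structure(frames, class = "rf_cohort")
}

#' @export
print.rf_cohort <- function(x, ...) {
  lab <- vapply(x, function(f) f$label, integer(1))
  cat(sprintf("<rf_cohort> %d frames (%d positive, %d negative)\n",
              length(x), sum(lab == 1L), sum(lab == 0L)))
  invisible(x)
}

#' Per-frame class labels of a cohort
#' @param cohort an `rf_cohort`.
#' @return Integer vector of 0/1 labels.
#' @export
cohort_labels <- function(cohort) vapply(cohort, function(f) f$label, integer(1))
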