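test_that("frame simulation is deterministic and respects geometry", {
  geo <- tiny_geometry()
  cls <- mvi_class_defaults()
  sh <- tiny_shape()
  f1 <- simulate_rf_frame(geo, cls$neg, cls$pos, sh, seed = 42, label = 1L)
  f2 <- simulate_rf_frame(geo, cls$neg, cls$pos, sh, seed = 42, label = 1L)
  f3 <- simulate_rf_frame(geo, cls$neg, cls$pos, sh, seed = 43, label = 1L)
  expect_identical(f1$samples, f2$samples)
  expect_false(identical(f1$samples, f3$samples))
  expect_equal(dim(f1$samples), c(geo$samples_per_line, geo$n_scanlines))
  expect_true(all(is.finite(f1$samples)))
  expect_s3_class(f1$lesion_roi, "roi_region")
  expect_true(any(f1$lesion_roi$mask))
})

test_that("invalid lesion geometry and tissue parameters are rejected", {
  geo <- tiny_geometry()
  cls <- mvi_class_defaults()
  bad <- list(center_row = 10, center_col = 24, semi_axial = 50, semi_lateral = 5)
  expect_error(simulate_rf_frame(geo, cls$neg, cls$pos, bad, seed = 1),
               "does not fit")
  expect_error(tissue_class_params(0.5, nakagami_m = -1), "m")
  expect_error(tissue_class_params(0.5, 1, nakagami_omega = 0), "omega")
  expect_error(tissue_class_params(-0.1, 1), "attenuation")
  expect_error(acquisition_geometry(sampling_frequency = 10e6,
                                    center_frequency = 3e6), "4x")
})

test_that("attenuation produces the closed-form log-power decay", {
  geo <- tiny_geometry()
  fc_mhz <- geo$center_frequency / 1e6
  dz_cm <- geo$axial_step_mm / 10
  slope_of <- function(frame) {
    rf2 <- frame$samples^2
    wlen <- 64L
    starts <- seq(1L, nrow(rf2) - wlen + 1L, by = wlen)
    lp <- vapply(starts, function(s) 10 * log10(mean(rf2[s:(s + wlen - 1L), ])),
                 numeric(1))
    z <- (starts + wlen / 2) * dz_cm
    stats::cov(z, lp) / stats::var(z)
  }
  # alpha = 1 dB/cm/MHz at 3 MHz: expect -3 dB/cm, within 15% seed-averaged
  tis <- tissue_class_params(1.0, nakagami_m = 1, nakagami_omega = 1)
  slopes <- vapply(1:6, function(s)
    slope_of(simulate_rf_frame(geo, tis, seed = s)), numeric(1))
  expect_lt(abs(mean(slopes) - (-1.0 * fc_mhz)) / (1.0 * fc_mhz), 0.15)
  # alpha = 0: depth-stationary, slope near zero
  tis0 <- tissue_class_params(0, nakagami_m = 1, nakagami_omega = 1)
  slopes0 <- vapply(1:6, function(s)
    slope_of(simulate_rf_frame(geo, tis0, seed = s)), numeric(1))
  expect_lt(abs(mean(slopes0)), 0.3)
})

test_that("envelope in homogeneous tissue follows the generating Nakagami law", {
  geo <- acquisition_geometry()   # full-size frame for 1e4 decorrelated samples
  tis <- tissue_class_params(0, nakagami_m = 0.8, nakagami_omega = 1.5)
  f <- simulate_rf_frame(geo, tis, seed = 9)
  env <- hilbert_envelope(f)
  sub <- as.vector(env[seq(60, nrow(env) - 60, by = 20), ])
  sub <- sub[seq_len(min(1e4, length(sub)))]
  ks <- stats::ks.test(sub, function(q) pnaka(q, 0.8, 1.5))
  expect_gt(ks$p.value, 0.01)
  # moment estimates recover the generating parameters
  expect_lt(abs(mean(sub^2) - 1.5) / 1.5, 0.05)
})

test_that("cohorts carry labels, per-frame jitter, and are seed-reproducible", {
  co <- tiny_cohort(4, 3, seed = 2)
  expect_length(co, 7)
  expect_equal(sum(cohort_labels(co) == 1L), 4)
  expect_equal(sum(cohort_labels(co) == 0L), 3)
  # per-frame params are jittered around class means
  alphas <- vapply(co, function(f) f$true_params$attenuation_db_per_cm_mhz,
                   numeric(1))
  expect_gt(stats::sd(alphas[cohort_labels(co) == 1L]), 0)
  co2 <- make_cohort(4, 3, geometry = tiny_geometry(), seed = 2)
  expect_identical(co[[3]]$samples, co2[[3]]$samples)
  expect_error(make_cohort(0, 5), "n_pos")
})

test_that("zero parameter jitter leaves only the scatterer realization random", {
  zero_j <- list(attenuation = 0, nakagami_m = 0, nakagami_omega = 0,
                 spectral_jitter = 0)
  cls <- mvi_class_defaults()
  co <- make_cohort(1, 1, geometry = tiny_geometry(), seed = 3,
                    param_jitter = zero_j)
  expect_equal(co[[1]]$true_params$attenuation_db_per_cm_mhz,
               cls$pos$attenuation_db_per_cm_mhz)
  expect_equal(co[[2]]$true_params$nakagami_m, cls$neg$nakagami_m)
  expect_false(identical(co[[1]]$samples, co[[2]]$samples))
})

test_that("a null cohort (identical classes) gives chance-level discrimination", {
  cls <- tissue_class_params(0.6, 1.0, 1, 12, 0.05)
  aucs <- vapply(1:3, function(s) {
    co <- make_cohort(8, 8, pos_params = cls, neg_params = cls,
                      geometry = tiny_geometry(), seed = 100 + s)
    pm <- cohort_parameter_means(co, tiny_window())
    pr <- loocv_predict(as.matrix(pm[, c("dea", "ond", "sdsd")]), pm$label)
    auc_trapezoid(pr$score, pm$label)
  }, numeric(1))
  expect_gt(mean(aucs), 0.25)
  expect_lt(mean(aucs), 0.75)
})
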