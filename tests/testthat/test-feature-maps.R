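test_that("window grid matches the closed-form sliding-window count", {
  for (dims in list(c(128, 16), c(300, 47), c(64, 8))) {
    ws <- window_spec(64, 4, 32, 2)
    g <- window_grid(dims[1], dims[2], ws)
    expect_length(g$ax, (dims[1] - 64) %/% 32 + 1)
    expect_length(g$lat, (dims[2] - 4) %/% 2 + 1)
  }
  expect_error(window_grid(32, 8, window_spec(64, 4)), "smaller")
  expect_error(window_spec(4, 4), "axial_len")
  expect_error(window_spec(64, 1), "lateral_len")
})

test_that("DEA map recovers the generating attenuation slope", {
  geo <- tiny_geometry()
  ws <- tiny_window()
  # alpha * fc = 3 dB/cm: map mean within 15 percent, seed-averaged
  tis <- tissue_class_params(1.0, 1, 1)
  means <- vapply(1:5, function(s) {
    f <- simulate_rf_frame(geo, tis, seed = 20 + s)
    mean(dea_map(f$samples, ws, geo$sampling_frequency)$values_imputed)
  }, numeric(1))
  expect_lt(abs(mean(means) + 3) / 3, 0.15)
  # no attenuation: map mean near zero
  tis0 <- tissue_class_params(0, 1, 1)
  means0 <- vapply(1:5, function(s) {
    f <- simulate_rf_frame(geo, tis0, seed = 30 + s)
    mean(dea_map(f$samples, ws, geo$sampling_frequency)$values_imputed)
  }, numeric(1))
  expect_lt(abs(mean(means0)), 0.3)
})

test_that("stronger attenuation gives larger absolute DEA inside the lesion", {
  fpos <- tiny_frame(seed = 7, pos = TRUE)    # higher-attenuation class
  fneg <- tiny_frame(seed = 7, pos = FALSE)
  ws <- tiny_window()
  dpos <- lesion_feature_maps(fpos, ws)$parameter_means["dea"]
  dneg <- lesion_feature_maps(fneg, ws)$parameter_means["dea"]
  expect_gt(abs(dpos), abs(dneg))
})

test_that("SDSD is zero against its own reference and orders by jitter", {
  geo <- tiny_geometry()
  ws <- tiny_window()
  f <- tiny_frame()
  # ROI exactly one window: the reference is the window itself
  one <- f$samples[1:ws$axial_len, 1:ws$lateral_len]
  m <- sdsd_map(one, ws, geo$sampling_frequency, pulse_band(geo))
  expect_equal(dim(m$values), c(1, 1))
  expect_equal(m$values[1, 1], 0)
  # frames differing only in spectral jitter: jittered class scores higher
  hi <- tissue_class_params(0, 1, 1, 12, spectral_jitter_sd = 0.08)
  lo <- tissue_class_params(0, 1, 1, 12, spectral_jitter_sd = 0)
  wins <- vapply(1:5, function(s) {
    fh <- simulate_rf_frame(geo, hi, seed = 40 + s)
    fl <- simulate_rf_frame(geo, lo, seed = 40 + s)
    mh <- mean(sdsd_map(fh$samples, ws, geo$sampling_frequency,
                        pulse_band(geo))$values_imputed)
    ml <- mean(sdsd_map(fl$samples, ws, geo$sampling_frequency,
                        pulse_band(geo))$values_imputed)
    mh > ml
  }, logical(1))
  expect_gte(sum(wins), 4)
})

test_that("OND moment estimators satisfy their identities", {
  ws <- window_spec(16, 8, 16, 8)
  # constant envelope: omega = c^2 exactly, m undefined
  cm <- matrix(3, 32, 16)
  m <- ond_map(cm, ws)
  expect_equal(unique(as.vector(m$values)), 9)
  expect_true(all(is.na(m$m_hat)))
  # large-sample recovery from Nakagami draws
  withr::with_seed(8, {
    r <- matrix(rnaka(400 * 256, m = 1, omega = 2), 400, 256)
  })
  big <- ond_map(r, window_spec(400, 256, 400, 256))
  expect_lt(abs(big$values[1, 1] - 2) / 2, 0.02)
  expect_lt(abs(big$m_hat[1, 1] - 1), 0.05)
  # scaling the envelope by k scales omega by k^2
  m2 <- ond_map(3 * r[1:64, 1:8], ws)
  m1 <- ond_map(r[1:64, 1:8], ws)
  expect_equal(m2$values, 9 * m1$values)
  expect_error(ond_map(r[1:16, 1:2, drop = FALSE], window_spec(16, 2, 8, 1)),
               "64 samples")
})

test_that("map rendering follows the normalization contract", {
  fm <- function(v) structure(list(kind = "DEA", values = v, values_imputed = v,
                                   window = NULL, n_missing = 0),
                              class = "feature_map")
  expect_equal(as.vector(render_map(fm(matrix(c(0, 1), 1)))), c(0L, 255L))
  expect_equal(as.vector(render_map(fm(matrix(c(0, 0.5, 1), 1)))),
               c(0L, 128L, 255L))
  expect_true(all(render_map(fm(matrix(5, 3, 3))) == 128L))
  # fixed physical range: values clip and scale against the range
  px <- render_map(fm(matrix(c(-10, -8, -3, 2, 5), 1)), value_range = c(-8, 2))
  expect_equal(as.vector(px), c(0L, 0L, 128L, 255L, 255L))
})

test_that("amplitude invariance: scaling RF leaves DEA and SDSD, squares OND", {
  f <- tiny_frame()
  geo <- f$geometry
  ws <- tiny_window()
  rf <- crop_roi(f$samples, f$lesion_roi)$values
  k <- 3.7
  d1 <- dea_map(rf, ws, geo$sampling_frequency)
  d2 <- dea_map(k * rf, ws, geo$sampling_frequency)
  expect_equal(d1$values, d2$values, tolerance = 1e-10)
  s1 <- sdsd_map(rf, ws, geo$sampling_frequency, pulse_band(geo))
  s2 <- sdsd_map(k * rf, ws, geo$sampling_frequency, pulse_band(geo))
  expect_equal(s1$values, s2$values, tolerance = 1e-10)
  env <- hilbert_envelope(rf)
  o1 <- ond_map(env, ws); o2 <- ond_map(k * env, ws)
  expect_equal(o2$values, k^2 * o1$values, tolerance = 1e-10)
})

test_that("zero-energy windows are recorded missing and mean-imputed", {
  geo <- tiny_geometry()
  ws <- tiny_window()
  f <- tiny_frame()
  rf <- crop_roi(f$samples, f$lesion_roi)$values
  rf[1:ws$axial_len, 1:ws$lateral_len] <- 0
  d <- dea_map(rf, ws, geo$sampling_frequency)
  expect_gt(d$n_missing, 0)
  expect_true(all(is.finite(d$values_imputed)))
  expect_equal(mean(d$values_imputed[is.na(d$values)]),
               mean(d$values, na.rm = TRUE))
})

test_that("lesion maps expose the grid mask and per-lesion parameter means", {
  f <- tiny_frame()
  lf <- lesion_feature_maps(f, tiny_window())
  expect_named(lf$maps, c("dea", "ond", "sdsd"))
  expect_named(lf$images, c("gm", "dea", "ond", "sdsd"))
  expect_equal(dim(lf$images$dea$image), dim(lf$maps$dea$values))
  expect_true(all(dim(lf$images$dea$mask) == dim(lf$images$dea$image)))
  expect_true(all(is.finite(lf$parameter_means)))
  expect_lt(lf$parameter_means["dea"], 0)   # energy decays with depth
})
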