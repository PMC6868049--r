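# small, fast fixtures shared across test files; cached so each is built once
.fixture_env <- new.env(parent = emptyenv())

tiny_geometry <- function() {
  acquisition_geometry(n_scanlines = 48L, samples_per_line = 768L)
}

tiny_window <- function() window_spec(64L, 6L, 32L, 3L)

tiny_shape <- function(geo = tiny_geometry()) {
  list(center_row = round(geo$samples_per_line * 0.55),
       center_col = round(geo$n_scanlines / 2),
       semi_axial = round(geo$samples_per_line * 0.22),
       semi_lateral = round(geo$n_scanlines * 0.3))
}

tiny_frame <- function(seed = 5, pos = TRUE) {
  key <- paste0("frame", seed, pos)
  if (is.null(.fixture_env[[key]])) {
    cls <- mvi_class_defaults()
    les <- if (pos) cls$pos else cls$neg
    .fixture_env[[key]] <- simulate_rf_frame(
      tiny_geometry(), background = cls$neg, lesion = les,
      lesion_shape = tiny_shape(), seed = seed, label = as.integer(pos))
  }
  .fixture_env[[key]]
}

tiny_cohort <- function(n_pos = 6, n_neg = 6, seed = 5) {
  key <- paste0("cohort", n_pos, "_", n_neg, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- make_cohort(n_pos, n_neg, geometry = tiny_geometry(),
                                       seed = seed)
  .fixture_env[[key]]
}

# full-size default cohorts, shared by the acceptance checks
default_cohort <- function(seed) {
  key <- paste0("default", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- make_cohort(seed = seed)
  .fixture_env[[key]]
}
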