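#' Pipeline configuration
#'
#' One resolved configuration object drives the whole pipeline; every run
#' writes its resolved configuration beside its results so any output tree
#' can be reproduced from the seed alone.
#'
#' @param geometry an [acquisition_geometry()].
#' @param pos_params,neg_params class [tissue_class_params()].
#' @param n_pos,n_neg cohort sizes.
#' @param window a [window_spec()].
#' @param levels texture quantization levels.
#' @param sr iterative SR settings (`n_iter`, `subsample_fraction`,
#'   `lambda`, `tal`).
#' @param svm an [svm_config()].
#' @param k_max top-k sweep limit.
#' @param models model layouts to evaluate.
#' @param mode `"pooled"` (selection on all samples, classifier LOOCV) or
#'   `"nested"`.
#' @param seed master seed for cohort simulation and selection.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(geometry = acquisition_geometry(),
                            pos_params = mvi_class_defaults()$pos,
                            neg_params = mvi_class_defaults()$neg,
                            n_pos = 21L, n_neg = 21L,
                            window = window_spec(), levels = 32L,
                            sr = list(n_iter = 100L, subsample_fraction = 0.8,
                                      lambda = "auto", tal = 0.004),
                            svm = svm_config(), k_max = 50L,
                            models = c("GM", "DM", "DOM", "DOSM"),
                            mode = "pooled", seed = 1L) {
  if (n_pos < 1L || n_neg < 1L) stop("n_pos and n_neg must be >= 1")
  stopifnot(inherits(geometry, "acq_geometry"), inherits(window, "window_spec"),
            inherits(pos_params, "tissue_params"), inherits(neg_params, "tissue_params"))
  structure(list(geometry = geometry, pos_params = pos_params,
                 neg_params = neg_params, n_pos = as.integer(n_pos),
                 n_neg = as.integer(n_neg), window = window,
                 levels = as.integer(levels), sr = sr, svm = svm,
                 k_max = as.integer(k_max), models = models, mode = mode,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline and write the artifact tree
#'
#' Simulate (or accept) a cohort, compute per-lesion maps, texture tables,
#' sparse-representation selection and the LOOCV evaluation, and write all
#' tables plus the resolved configuration under `out_dir`. Identical
#' configuration and seed produce byte-identical tables.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` writes nothing.
#' @param cohort optional pre-built `rf_cohort` (otherwise simulated from
#'   the configuration).
#' @param write_maps also write the per-lesion map renderings as PNG.
#' @return Invisibly, a list with `cohort`, `parameter_means`, `group_tests`,
#'   and the [run_models()] output (`results`, `selection`, `summary`).
#' @export
run_all <- function(config = pipeline_config(), out_dir = NULL, cohort = NULL,
                    write_maps = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort))
    cohort <- make_cohort(config$n_pos, config$n_neg, config$pos_params,
                          config$neg_params, config$geometry, seed = config$seed)
  pm <- cohort_parameter_means(cohort, config$window)
  gt <- compare_parameter_groups(pm, pm$label)
  rm_out <- run_models(cohort, config$models, config$window, config$levels,
                       config$sr, config$svm, config$k_max, config$mode,
                       seed = config$seed)
  out <- list(cohort = cohort, parameter_means = pm, group_tests = gt,
              results = rm_out$results, selection = rm_out$selection,
              summary = rm_out$summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(pm, file.path(out_dir, "parameter_means.csv"), row.names = FALSE)
    utils::write.csv(out$group_tests$anova, file.path(out_dir, "parameter_anova.csv"),
                     row.names = FALSE)
    utils::write.csv(out$summary, file.path(out_dir, "model_summary.csv"),
                     row.names = FALSE)
    for (mdl in names(out$results)) {
      ev <- out$results[[mdl]]
      utils::write.csv(ev$per_k, file.path(out_dir, paste0("per_k_", mdl, ".csv")),
                       row.names = FALSE)
      utils::write.csv(ev$curves$roc, file.path(out_dir, paste0("roc_", mdl, ".csv")),
                       row.names = FALSE)
      utils::write.csv(ev$curves$prc, file.path(out_dir, paste0("prc_", mdl, ".csv")),
                       row.names = FALSE)
      utils::write.csv(ev$curves$dca, file.path(out_dir, paste0("dca_", mdl, ".csv")),
                       row.names = FALSE)
    }
    for (mdl in names(out$selection))
      write_selection_json(out$selection[[mdl]],
                           file.path(out_dir, paste0("selection_", mdl, ".json")))
    if (write_maps) {
      mp_dir <- file.path(out_dir, "maps")
      dir.create(mp_dir, showWarnings = FALSE)
      for (i in seq_along(cohort)) {
        lf <- lesion_feature_maps(cohort[[i]], config$window)
        for (nm in c("gm", "dea", "ond", "sdsd"))
          write_gray_png(lf$images[[nm]]$image,
                         file.path(mp_dir, sprintf("lesion%02d_%s.png", i, nm)))
      }
    }
    jsonlite::write_json(.config_json(config), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}

.config_json <- function(config) {
  g <- config$geometry
  list(
    geometry = g[c("sampling_frequency", "center_frequency", "n_scanlines",
                   "samples_per_line", "pulse_bandwidth", "sound_speed")],
    pos_params = unclass(config$pos_params),
    neg_params = unclass(config$neg_params),
    n_pos = config$n_pos, n_neg = config$n_neg,
    window = unclass(config$window), levels = config$levels,
    sr = config$sr, svm = unclass(config$svm), k_max = config$k_max,
    models = config$models, mode = config$mode, seed = config$seed)
}
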