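#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic RF cohort.
#
# Generates the default 21 + 21 lesion cohort (two tissue classes that differ
# in attenuation and spectral heterogeneity), writes a few example frames in
# the portable float32 + JSON-sidecar format, and saves the cohort object for
# the later stages.

suppressPackageStartupMessages(library(rfradiomics))

out <- "results"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1L

cohort <- make_cohort(seed = seed)
print(cohort)

# persist the cohort for stages 2-5
saveRDS(cohort, file.path(out, "cohort.rds"))

# a positive and a negative example frame in the on-disk RF format
labs <- cohort_labels(cohort)
write_rf_frame(cohort[[which(labs == 1)[1]]],
               file.path(out, "example_frame_pos"))
write_rf_frame(cohort[[which(labs == 0)[1]]],
               file.path(out, "example_frame_neg"))

# and their display B-mode images
for (nm in c("pos", "neg")) {
  f <- cohort[[which(labs == as.integer(nm == "pos"))[1]]]
  write_gray_png(display_bmode(f), file.path(out, paste0("bmode_", nm, ".png")))
}
cat("wrote", file.path(out, "cohort.rds"), "and example frames/B-modes\n")
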