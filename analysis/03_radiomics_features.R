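#!/usr/bin/env Rscript
# Stage 3: radiomics feature extraction.
#
# Builds the per-lesion feature tables for the four model layouts: GM
# (grayscale control, 350 features), DM (DEA map, 350), DOM (DEA + OND, 700)
# and DOSM (DEA + OND + SDSD, 1050). Each map contributes 70 texture features
# on the original image and on the four one-level Haar sub-bands.

suppressPackageStartupMessages(library(rfradiomics))

out <- "results"
cohort <- readRDS(file.path(out, "cohort.rds"))

# compute per-lesion images once and share them across layouts
images <- lapply(cohort, function(f) lesion_feature_maps(f)$images)

tables <- list()
for (mdl in c("GM", "DM", "DOM", "DOSM")) {
  tab <- cohort_feature_table(cohort, mdl, per_lesion_images = images)
  tables[[mdl]] <- tab
  df <- data.frame(label = tab$y, tab$X, check.names = FALSE)
  write.csv(df, file.path(out, sprintf("features_%s.csv", mdl)),
            row.names = FALSE)
  cat(sprintf("%-5s %4d features x %d lesions\n", mdl, ncol(tab$X), nrow(tab$X)))
}
saveRDS(tables, file.path(out, "feature_tables.rds"))
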