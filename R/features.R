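.families <- c("hist", "glcm", "glrlm", "glszm", "ngtdm")
.bands <- c("orig", "LL", "LH", "HL", "HH")

#' The 70-feature texture battery on one image band
#'
#' Concatenates the five families on a single 8-bit image: 16 histogram
#' features, 23 GLCM, 13 GLRLM, 13 GLSZM and 5 NGTDM features (70 in all),
#' the matrix families computed on the `levels`-level quantized image.
#'
#' @param image integer matrix with values in 0..255.
#' @param mask logical matrix of the same shape (`NULL` = whole image).
#' @param levels quantization levels for the matrix-based families.
#' @return Named numeric vector of length 70 with names `<family>__<feature>`.
#' @export
texture_70 <- function(image, mask = NULL, levels = 32L) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  q <- quantize(image, levels)
  v <- c(histogram_features(image, mask),
         glcm_features(q, mask, levels),
         glrlm_features(q, mask, levels),
         glszm_features(q, mask, levels),
         ngtdm_features(q, mask, levels))
  fam <- rep(.families, c(16L, 23L, 13L, 13L, 5L))
  names(v) <- paste0(fam, "__", names(v))
  v
}

#' 350 texture features per image: original plus wavelet sub-bands
#'
#' Runs the 70-feature battery on the original image and on each of the four
#' one-level Haar sub-bands (another 280 features), giving 350 features per
#' image in a fixed name order `<band>__<family>__<feature>` with bands
#' `orig, LL, LH, HL, HH`.
#'
#' @inheritParams texture_70
#' @return Named numeric vector of length 350.
#' @export
extract_350 <- function(image, mask = NULL, levels = 32L) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  sb <- wavelet_subbands(image, mask)
  blocks <- c(list(orig = list(image = image, mask = mask)),
              lapply(sb, function(b) list(image = b$image, mask = b$mask)))
  out <- unlist(lapply(names(blocks), function(bn) {
    v <- texture_70(blocks[[bn]]$image, blocks[[bn]]$mask, levels)
    names(v) <- paste0(bn, "__", names(v))
    v
  }))
  stopifnot(length(out) == 350L)
  out
}

.model_maps <- list(GM = "gm", DM = "dea", DOM = c("dea", "ond"),
                    DOSM = c("dea", "ond", "sdsd"))

#' Assemble the feature vector of a prediction model
#'
#' The four models differ in which images feed the texture battery: `GM`
#' uses the grayscale B-mode ROI (350 features), `DM` the DEA map (350),
#' `DOM` the DEA and OND maps (700), `DOSM` the DEA, OND and SDSD maps
#' (1050). Maps are always concatenated in the fixed order DEA, OND, SDSD.
#'
#' @param images named list with entries among `gm`, `dea`, `ond`, `sdsd`,
#'   each a list with `image` (8-bit matrix) and `mask` (logical matrix).
#' @param model one of `"GM"`, `"DM"`, `"DOM"`, `"DOSM"`.
#' @param levels quantization levels.
#' @return Named numeric vector with names `<map>__<band>__<family>__<feature>`.
#' @export
assemble_model_vector <- function(images, model = c("GM", "DM", "DOM", "DOSM"),
                                  levels = 32L) {
  model <- match.arg(model)
  need <- .model_maps[[model]]
  missing <- setdiff(need, names(images))
  if (length(missing)) stop("missing required map(s): ", paste(missing, collapse = ", "))
  out <- unlist(lapply(need, function(mp) {
    v <- extract_350(images[[mp]]$image, images[[mp]]$mask, levels)
    names(v) <- paste0(mp, "__", names(v))
    v
  }))
  out
}

#' Feature-name manifest for a model layout
#'
#' The frozen feature order of each model; all downstream selection and
#' ranking refer to these names, never to positions.
#'
#' @param model one of `"GM"`, `"DM"`, `"DOM"`, `"DOSM"`.
#' @return Character vector of feature names (350, 350, 700 or 1050).
#' @export
feature_manifest <- function(model = c("GM", "DM", "DOM", "DOSM")) {
  model <- match.arg(model)
  fam_feats <- list(
    hist = names(histogram_features(matrix(0:3, 2, 2))),
    glcm = names(glcm_features(matrix(c(1L, 2L, 1L, 2L), 2, 2), levels = 2L)),
    glrlm = .glrlm_names,
    glszm = .glszm_names,
    ngtdm = c("coarseness", "contrast", "busyness", "complexity", "strength"))
  per_band <- unlist(lapply(.families, function(f) paste0(f, "__", fam_feats[[f]])))
  per_image <- unlist(lapply(.bands, function(b) paste0(b, "__", per_band)))
  unlist(lapply(.model_maps[[model]], function(mp) paste0(mp, "__", per_image)))
}

#' Cohort feature table for one model
#'
#' Computes the per-lesion images of a cohort and assembles the model's
#' feature matrix (lesions x features) together with the label vector.
#' When `per_lesion_images` is supplied (precomputed by
#' [lesion_feature_maps()]) the images are reused across models.
#'
#' @param cohort an `rf_cohort`.
#' @param model model layout.
#' @param window a [window_spec()].
#' @param levels quantization levels.
#' @param per_lesion_images optional list of `images` lists, one per frame.
#' @return List with `X` (numeric matrix with feature-name columns) and `y`
#'   (integer labels).
#' @export
cohort_feature_table <- function(cohort, model = "DOSM", window = window_spec(),
                                 levels = 32L, per_lesion_images = NULL) {
  if (is.null(per_lesion_images))
    per_lesion_images <- lapply(cohort, function(f) lesion_feature_maps(f, window)$images)
  rows <- lapply(per_lesion_images, assemble_model_vector, model = model,
                 levels = levels)
  X <- do.call(rbind, rows)
  list(X = X, y = cohort_labels(cohort))
}
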