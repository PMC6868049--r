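#' One-level 2-D Haar wavelet sub-bands
#'
#' Single-level orthonormal Haar (db1) decomposition into the LL, LH, HL and
#' HH coefficient sub-bands, the standard way of splitting an image into one
#' low-pass and three high-pass detail channels for sub-band texture
#' analysis. Odd dimensions are handled by edge replication, so each
#' sub-band has `ceiling(dim / 2)` rows/columns. For texture extraction the
#' raw coefficient bands are min-max rescaled to 8 bits over the masked
#' sub-band pixels (values outside clipped; constant bands map to mid-gray
#' 128), and the pixel mask is downsampled to the sub-band grid by 2x2
#' majority with ties counting as inside — so masked features depend only
#' on the image near the mask.
#'
#' @param image numeric matrix (at least 2x2); typically an 8-bit image.
#' @param mask optional logical matrix of the same shape.
#' @return A list of four sub-bands (`LL`, `LH`, `HL`, `HH`), each a list
#'   with `coefficients` (raw), `image` (8-bit rescaled) and `mask`.
#' @export
wavelet_subbands <- function(image, mask = NULL) {
  if (nrow(image) < 2 || ncol(image) < 2) stop("image must be at least 2x2")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  x <- .pad_even(image)
  mk <- .pad_even(mask)
  io <- seq(1, nrow(x), by = 2); ie <- io + 1
  jo <- seq(1, ncol(x), by = 2); je <- jo + 1
  a <- x[io, jo, drop = FALSE]; b <- x[io, je, drop = FALSE]
  cc <- x[ie, jo, drop = FALSE]; d <- x[ie, je, drop = FALSE]
  bands <- list(LL = (a + b + cc + d) / 2,
                LH = (a - b + cc - d) / 2,
                HL = (a + b - cc - d) / 2,
                HH = (a - b - cc + d) / 2)
  sub_mask <- (mk[io, jo, drop = FALSE] + mk[io, je, drop = FALSE] +
                 mk[ie, jo, drop = FALSE] + mk[ie, je, drop = FALSE]) >= 2
  lapply(bands, function(v) list(coefficients = v,
                                 image = .rescale8(v, sub_mask),
                                 mask = sub_mask))
}

.pad_even <- function(x) {
  if (nrow(x) %% 2 == 1) x <- rbind(x, x[nrow(x), , drop = FALSE])
  if (ncol(x) %% 2 == 1) x <- cbind(x, x[, ncol(x), drop = FALSE])
  x
}

.rescale8 <- function(v, mask = NULL) {
  rng <- if (is.null(mask) || !any(mask)) range(v) else range(v[mask])
  if (rng[1] == rng[2]) return(matrix(128L, nrow(v), ncol(v)))
  v <- pmin(pmax(v, rng[1]), rng[2])
  matrix(as.integer(.round_half_up(255 * (v - rng[1]) / (rng[2] - rng[1]))),
         nrow(v), ncol(v))
}
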