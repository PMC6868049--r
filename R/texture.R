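#' Gray-level quantization
#'
#' Equal-width binning of the 8-bit range 0..255 into `levels` bins,
#' returning integer levels 1..`levels`. `levels = 256` is the identity (up
#' to the +1 offset).
#'
#' @param image matrix with values in 0..255.
#' @param levels number of gray levels (`>= 2`).
#' @return Integer matrix with values in `1..levels`.
#' @export
quantize <- function(image, levels = 32L) {
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2")
  if (any(image < 0 | image > 255)) stop("image values must lie in [0, 255]")
  q <- pmin(floor(image * levels / 256), levels - 1L) + 1L
  matrix(as.integer(q), nrow(image), ncol(image))
}

.entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' First-order histogram features
#'
#' Sixteen first-order statistics of the masked intensities, in fixed order:
#' mean, variance, sd, skewness, kurtosis, energy, entropy, min, max, range,
#' median, p10, p90, iqr, mean_abs_dev, uniformity. Variance and the
#' standardized moments use the population (1/n) convention; skewness and
#' kurtosis of a constant image are 0; entropy and uniformity are computed
#' on the 256-bin intensity histogram; energy is the sum of squared
#' intensities.
#'
#' @param image matrix with integer values in 0..255.
#' @param mask logical matrix of the same shape; must select >= 1 pixel.
#' @return Named numeric vector of length 16.
#' @export
histogram_features <- function(image, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  x <- as.numeric(image[mask])
  if (length(x) == 0) stop("empty mask")
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  p <- tabulate(as.integer(x) + 1L, nbins = 256L) / n
  qs <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  c(mean = mu,
    variance = m2,
    sd = sqrt(m2),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    energy = sum(x^2),
    entropy = .entropy2(p),
    min = min(x),
    max = max(x),
    range = max(x) - min(x),
    median = qs[3],
    p10 = qs[1],
    p90 = qs[5],
    iqr = qs[4] - qs[2],
    mean_abs_dev = mean(abs(x - mu)),
    uniformity = sum(p^2))
}

# the four distance-1 direction offsets (drow, dcol): 0, 45, 90, 135 degrees
.tex_offsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                     `90` = c(-1L, 0L), `135` = c(-1L, -1L))

# co-occurrence counts for one offset, masked pixels only, symmetric
.glcm_one <- function(q, mask, off, levels) {
  nr <- nrow(q); nc <- ncol(q)
  r <- seq_len(nr); c <- seq_len(nc)
  r1 <- r[r + off[1] >= 1 & r + off[1] <= nr]
  c1 <- c[c + off[2] >= 1 & c + off[2] <= nc]
  if (length(r1) == 0 || length(c1) == 0) return(matrix(0, levels, levels))
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
  ok <- mask[r1, c1, drop = FALSE] & mask[r1 + off[1], c1 + off[2], drop = FALSE]
  if (!any(ok)) return(matrix(0, levels, levels))
  idx <- (b[ok] - 1L) * levels + a[ok]
  cnt <- matrix(tabulate(idx, nbins = levels * levels), levels, levels)
  cnt + t(cnt)
}

#' Gray-level co-occurrence matrix features
#'
#' Symmetric distance-1 co-occurrence matrices are computed in the four
#' directions (0, 45, 90, 135 degrees) over masked pixel pairs, normalized,
#' averaged, and summarized by 23 Haralick-style features in fixed order:
#' autocorrelation, joint_average, cluster_prominence, cluster_shade,
#' cluster_tendency, contrast, correlation, difference_average,
#' difference_entropy, difference_variance, joint_energy, joint_entropy,
#' imc1, imc2, inverse_difference, inverse_difference_normalized,
#' inverse_difference_moment, inverse_difference_moment_normalized,
#' inverse_variance, maximum_probability, sum_average, sum_entropy,
#' sum_variance. Logs are base 2. A single-level (or pair-free) mask yields
#' the degenerate values contrast 0, joint_energy 1, correlation 0.
#'
#' @param quantized integer matrix of gray levels `1..levels`.
#' @param mask logical matrix, same shape.
#' @param levels number of gray levels used in the quantization.
#' @return Named numeric vector of length 23.
#' @export
glcm_features <- function(quantized, mask = NULL, levels = max(quantized)) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(quantized), ncol(quantized))
  mats <- lapply(.tex_offsets, function(off) .glcm_one(quantized, mask, off, levels))
  tots <- vapply(mats, sum, numeric(1))
  if (all(tots == 0)) {
    P <- matrix(0, levels, levels)
    lv <- unique(quantized[mask])
    P[lv[1], lv[1]] <- 1
  } else {
    used <- tots > 0
    P <- Reduce(`+`, Map(function(m, s) if (s > 0) m / s else m * 0, mats, tots)) /
      sum(used)
  }
  .glcm_stats(P, levels)
}

.glcm_stats <- function(P, L) {
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(L) * px); muy <- sum(seq_len(L) * py)
  sx <- sqrt(sum((seq_len(L) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(L) - muy)^2 * py))

  # p_{x+y}(k), k = 2..2L ; p_{x-y}(k), k = 0..L-1
  sums <- as.vector(i + j); difs <- as.vector(abs(i - j)); pv <- as.vector(P)
  pxy_s <- vapply(2:(2 * L), function(k) sum(pv[sums == k]), numeric(1))
  pxy_d <- vapply(0:(L - 1), function(k) sum(pv[difs == k]), numeric(1))
  ks <- 2:(2 * L); kd <- 0:(L - 1)

  autoc <- sum(i * j * P)
  contrast <- sum((i - j)^2 * P)
  corr <- if (sx > 0 && sy > 0) (autoc - mux * muy) / (sx * sy) else 0
  da <- sum(kd * pxy_d)
  hxy <- .entropy2(P)
  hx <- .entropy2(px); hy <- .entropy2(py)
  pxpy <- outer(px, py)
  pos <- P > 0 & pxpy > 0
  hxy1 <- -sum(P[pos] * log2(pxpy[pos]))
  hxy2 <- .entropy2(pxpy)
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  sa <- sum(ks * pxy_s)
  offd <- i != j

  c(autocorrelation = autoc,
    joint_average = sum(i * P),
    cluster_prominence = sum((i + j - mux - muy)^4 * P),
    cluster_shade = sum((i + j - mux - muy)^3 * P),
    cluster_tendency = sum((i + j - mux - muy)^2 * P),
    contrast = contrast,
    correlation = corr,
    difference_average = da,
    difference_entropy = .entropy2(pxy_d),
    difference_variance = sum((kd - da)^2 * pxy_d),
    joint_energy = sum(P^2),
    joint_entropy = hxy,
    imc1 = imc1,
    imc2 = imc2,
    inverse_difference = sum(P / (1 + abs(i - j))),
    inverse_difference_normalized = sum(P / (1 + abs(i - j) / L)),
    inverse_difference_moment = sum(P / (1 + (i - j)^2)),
    inverse_difference_moment_normalized = sum(P / (1 + (i - j)^2 / L^2)),
    inverse_variance = sum(P[offd] / (i[offd] - j[offd])^2),
    maximum_probability = max(P),
    sum_average = sa,
    sum_entropy = .entropy2(pxy_s),
    sum_variance = sum((ks - sa)^2 * pxy_s))
}

# run-length counts (gray level, run length) for one direction; runs are
# broken by out-of-mask pixels. Pixels are ordered so that consecutive
# positions within a line index are adjacent along the direction.
.glrlm_one <- function(q, mask, direction) {
  qm <- q
  qm[!mask] <- NA_integer_
  rr <- as.vector(row(qm)); cc <- as.vector(col(qm))
  key <- switch(direction,
    `0`   = list(d = rr, t = cc),
    `90`  = list(d = cc, t = rr),
    `45`  = list(d = rr + cc, t = cc),
    `135` = list(d = cc - rr, t = cc),
    stop("unknown direction"))
  ord <- order(key$d, key$t)
  v <- as.vector(qm)[ord]
  d <- key$d[ord]
  n <- length(v)
  if (n == 1L) {
    if (is.na(v)) return(list(g = integer(0), len = integer(0)))
    return(list(g = v, len = 1L))
  }
  brk <- v[-1] != v[-n]
  brk[is.na(brk)] <- TRUE            # out-of-mask pixels break runs
  brk <- brk | (d[-1] != d[-n])      # line boundaries break runs
  ends <- c(which(brk), n)
  lens <- diff(c(0L, ends))
  vals <- v[ends]
  keep <- !is.na(vals)
  list(g = vals[keep], len = lens[keep])
}

.rl_stats <- function(R, np, feature_names) {
  # R: levels x max-size count matrix (possibly non-integer after averaging)
  nr_tot <- sum(R)
  if (nr_tot == 0) stop("no runs/zones found in mask")
  gi <- matrix(seq_len(nrow(R)), nrow(R), ncol(R))
  rj <- matrix(seq_len(ncol(R)), nrow(R), ncol(R), byrow = TRUE)
  p <- R / nr_tot
  rg <- rowSums(R); rr <- colSums(R)
  mu_g <- sum(gi * p); mu_r <- sum(rj * p)
  out <- c(
    sum(rr / (seq_along(rr))^2) / nr_tot,            # short emphasis
    sum(rr * (seq_along(rr))^2) / nr_tot,            # long emphasis
    sum(rg^2) / nr_tot,                              # gray-level non-uniformity
    sum(rr^2) / nr_tot,                              # size non-uniformity
    nr_tot / np,                                     # percentage
    sum(rg / (seq_along(rg))^2) / nr_tot,            # low gray-level
    sum(rg * (seq_along(rg))^2) / nr_tot,            # high gray-level
    sum(R / (gi^2 * rj^2)) / nr_tot,                 # short + low
    sum(R * gi^2 / rj^2) / nr_tot,                   # short + high
    sum(R * rj^2 / gi^2) / nr_tot,                   # long + low
    sum(R * gi^2 * rj^2) / nr_tot,                   # long + high
    sum(p * (gi - mu_g)^2),                          # gray-level variance
    sum(p * (rj - mu_r)^2))                          # size variance
  names(out) <- feature_names
  out
}

.glrlm_names <- c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
                  "srlge", "srhge", "lrlge", "lrhge", "glv", "rlv")
.glszm_names <- c("sze", "lze", "gln", "szn", "zp", "lgze", "hgze",
                  "szlge", "szhge", "lzlge", "lzhge", "glv", "zsv")

#' Gray-level run-length matrix features
#'
#' Run-length matrices are computed in the four directions (runs broken by
#' the mask), zero-padded to a common maximum run length, averaged, and
#' summarized by the 13 classical features in fixed order: SRE, LRE, GLN,
#' RLN, RP, LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE, GLV, RLV.
#'
#' @inheritParams glcm_features
#' @param directions subset of `c("0", "45", "90", "135")` to average over.
#' @return Named numeric vector of length 13.
#' @export
glrlm_features <- function(quantized, mask = NULL, levels = max(quantized),
                           directions = c("0", "45", "90", "135")) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(quantized), ncol(quantized))
  np <- sum(mask)
  if (np == 0) stop("empty mask")
  runs <- lapply(directions, function(d) .glrlm_one(quantized, mask, d))
  maxlen <- max(1L, vapply(runs, function(r) if (length(r$len)) max(r$len) else 0L,
                           integer(1)))
  mats <- lapply(runs, function(r) {
    if (!length(r$g)) return(matrix(0, levels, maxlen))
    matrix(tabulate((r$len - 1L) * levels + r$g, nbins = levels * maxlen),
           levels, maxlen)
  })
  R <- Reduce(`+`, mats) / length(mats)
  .rl_stats(R, np, .glrlm_names)
}

# 8-connected same-level zones: adjacency edges between equal-level masked
# pixels, connected components in one pass
.glszm_zones <- function(q, mask) {
  nr <- nrow(q); nc <- ncol(q)
  qm <- q
  qm[!mask] <- NA_integer_
  idx <- matrix(seq_len(nr * nc), nr, nc)
  edge_pairs <- function(dr, dc) {
    rs <- seq_len(nr - max(dr, 0L)); rs <- rs[rs + dr >= 1L]
    cs <- seq_len(nc - max(dc, 0L)); cs <- cs[cs + dc >= 1L]
    a <- as.vector(idx[rs, cs, drop = FALSE])
    b <- as.vector(idx[rs + dr, cs + dc, drop = FALSE])
    ok <- !is.na(qm[a]) & !is.na(qm[b]) & qm[a] == qm[b]
    cbind(a[ok], b[ok])
  }
  # 4 of the 8 offsets suffice (undirected edges)
  ed <- rbind(edge_pairs(0L, 1L), edge_pairs(1L, 0L),
              edge_pairs(1L, 1L), edge_pairs(-1L, 1L))
  keep <- which(!is.na(qm))
  remap <- integer(nr * nc)
  remap[keep] <- seq_along(keep)
  g <- igraph::graph_from_edgelist(matrix(remap[ed], ncol = 2), directed = FALSE)
  if (igraph::vcount(g) < length(keep))
    g <- igraph::add_vertices(g, length(keep) - igraph::vcount(g))
  memb <- igraph::components(g)$membership
  sz <- tabulate(memb)
  first <- match(seq_along(sz), memb)
  list(level = as.integer(qm[keep][first]), size = as.integer(sz))
}

#' Gray-level size-zone matrix features
#'
#' Zones are maximal 8-connected regions of equal gray level within the
#' mask. The size-zone matrix is summarized by 13 features mirroring the
#' run-length family with zone size in place of run length: SZE, LZE, GLN,
#' SZN, ZP, LGZE, HGZE, SZLGE, SZHGE, LZLGE, LZHGE, GLV, ZSV.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 13.
#' @export
glszm_features <- function(quantized, mask = NULL, levels = max(quantized)) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(quantized), ncol(quantized))
  np <- sum(mask)
  if (np == 0) stop("empty mask")
  zz <- .glszm_zones(quantized, mask)
  maxsz <- max(zz$size)
  R <- matrix(tabulate((zz$size - 1L) * levels + zz$level, nbins = levels * maxsz),
              levels, maxsz)
  .rl_stats(R, np, .glszm_names)
}

#' Neighborhood gray-tone difference matrix features
#'
#' Amadasun-King features (coarseness, contrast, busyness, complexity,
#' strength) with a 3x3 neighborhood and masked-neighbor averaging: a pixel
#' contributes if it is in the mask and has at least one masked neighbor,
#' and its neighborhood average uses masked neighbors only. Coarseness of a
#' flat region is capped at 1e6.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 5.
#' @export
ngtdm_features <- function(quantized, mask = NULL, levels = max(quantized)) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(quantized), ncol(quantized))
  nr <- nrow(quantized); nc <- ncol(quantized)
  padq <- matrix(0, nr + 2, nc + 2)
  padq[2:(nr + 1), 2:(nc + 1)] <- quantized * mask
  padm <- matrix(0, nr + 2, nc + 2)
  padm[2:(nr + 1), 2:(nc + 1)] <- mask
  nb_sum <- matrix(0, nr, nc); nb_cnt <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb_sum <- nb_sum + padq[2:(nr + 1) + dr, 2:(nc + 1) + dc]
    nb_cnt <- nb_cnt + padm[2:(nr + 1) + dr, 2:(nc + 1) + dc]
  }
  valid <- mask & nb_cnt > 0
  if (!any(valid)) stop("mask has no pixel with a masked neighbor")
  avg <- nb_sum[valid] / nb_cnt[valid]
  gval <- quantized[valid]
  N <- sum(valid)
  s_i <- vapply(seq_len(levels), function(g) sum(abs(gval[gval == g] - avg[gval == g])),
                numeric(1))
  n_i <- tabulate(gval, nbins = levels)
  p_i <- n_i / N
  pres <- which(p_i > 0)
  ng <- length(pres)

  den_coarse <- sum(p_i * s_i)
  coarseness <- if (den_coarse > 0) min(1 / den_coarse, 1e6) else 1e6

  contrast <- if (ng > 1) {
    (sum(outer(p_i[pres], p_i[pres]) * outer(pres, pres, "-")^2) /
       (ng * (ng - 1))) * (sum(s_i) / N)
  } else 0

  busy_den <- sum(abs(outer(pres * p_i[pres], pres * p_i[pres], "-")))
  busyness <- if (busy_den > 0) den_coarse / busy_den else 0

  cm <- outer(pres, pres, function(a, b) abs(a - b)) *
    outer(p_i[pres] * s_i[pres], p_i[pres] * s_i[pres], "+") /
    outer(p_i[pres], p_i[pres], "+")
  complexity <- sum(cm) / N

  str_num <- sum(outer(p_i[pres], p_i[pres], "+") * outer(pres, pres, "-")^2)
  strength <- if (sum(s_i) > 0) str_num / sum(s_i) else 0

  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}
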