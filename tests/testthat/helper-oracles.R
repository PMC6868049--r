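# Independent brute-force oracles. These deliberately use plain scalar
# loops and their own bookkeeping so they share no code path with the
# package implementations they check.

oracle_hist <- function(image, mask) {
  x <- as.numeric(image[mask])
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  cnt <- numeric(256)
  for (v in x) cnt[v + 1] <- cnt[v + 1] + 1
  p <- cnt / n
  ent <- 0
  for (pi in p) if (pi > 0) ent <- ent - pi * log2(pi)
  qs <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  c(mean = mu, variance = m2, sd = sqrt(m2),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    energy = sum(x^2), entropy = ent, min = min(x), max = max(x),
    range = max(x) - min(x), median = qs[3], p10 = qs[1], p90 = qs[5],
    iqr = qs[4] - qs[2], mean_abs_dev = sum(abs(x - mu)) / n,
    uniformity = sum(p^2))
}

oracle_glcm_avg <- function(q, mask, levels) {
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  mats <- list()
  for (o in offs) {
    M <- matrix(0, levels, levels)
    for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
      r2 <- r + o[1]; c2 <- cc + o[2]
      if (r2 < 1 || r2 > nrow(q) || c2 < 1 || c2 > ncol(q)) next
      if (!mask[r, cc] || !mask[r2, c2]) next
      M[q[r, cc], q[r2, c2]] <- M[q[r, cc], q[r2, c2]] + 1
      M[q[r2, c2], q[r, cc]] <- M[q[r2, c2], q[r, cc]] + 1
    }
    mats[[length(mats) + 1]] <- M
  }
  used <- 0
  P <- matrix(0, levels, levels)
  for (M in mats) if (sum(M) > 0) { P <- P + M / sum(M); used <- used + 1 }
  if (used == 0) stop("no co-occurring pairs")
  P / used
}

oracle_glcm <- function(q, mask, levels) {
  P <- oracle_glcm_avg(q, mask, levels)
  L <- levels
  ent2 <- function(v) { s <- 0; for (p in v) if (p > 0) s <- s - p * log2(p); s }
  px <- numeric(L); py <- numeric(L)
  for (i in 1:L) for (j in 1:L) { px[i] <- px[i] + P[i, j]; py[j] <- py[j] + P[i, j] }
  mux <- 0; muy <- 0
  for (i in 1:L) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sx <- sqrt(sum((1:L - mux)^2 * px)); sy <- sqrt(sum((1:L - muy)^2 * py))
  psum <- numeric(2 * L); pdif <- numeric(L)
  for (i in 1:L) for (j in 1:L) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + P[i, j]
  }
  autoc <- 0; javg <- 0; cp <- 0; cs <- 0; ct <- 0; con <- 0; je <- 0
  idn <- 0; idmn <- 0; idf <- 0; idm <- 0; iv <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    autoc <- autoc + i * j * p
    javg <- javg + i * p
    cp <- cp + (i + j - mux - muy)^4 * p
    cs <- cs + (i + j - mux - muy)^3 * p
    ct <- ct + (i + j - mux - muy)^2 * p
    con <- con + (i - j)^2 * p
    je <- je + p^2
    idf <- idf + p / (1 + abs(i - j))
    idn <- idn + p / (1 + abs(i - j) / L)
    idm <- idm + p / (1 + (i - j)^2)
    idmn <- idmn + p / (1 + (i - j)^2 / L^2)
    if (i != j) iv <- iv + p / (i - j)^2
  }
  da <- sum((0:(L - 1)) * pdif)
  dvar <- sum(((0:(L - 1)) - da)^2 * pdif)
  sa <- sum((2:(2 * L)) * psum[2:(2 * L)])
  svar <- sum(((2:(2 * L)) - sa)^2 * psum[2:(2 * L)])
  hxy <- ent2(as.vector(P)); hx <- ent2(px); hy <- ent2(py)
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:L) for (j in 1:L) {
    pp <- px[i] * py[j]
    if (pp > 0) {
      hxy2 <- hxy2 - pp * log2(pp)
      if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log2(pp)
    }
  }
  corr <- if (sx > 0 && sy > 0) (autoc - mux * muy) / (sx * sy) else 0
  c(autocorrelation = autoc, joint_average = javg, cluster_prominence = cp,
    cluster_shade = cs, cluster_tendency = ct, contrast = con,
    correlation = corr, difference_average = da,
    difference_entropy = ent2(pdif), difference_variance = dvar,
    joint_energy = je, joint_entropy = hxy,
    imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    inverse_difference = idf, inverse_difference_normalized = idn,
    inverse_difference_moment = idm,
    inverse_difference_moment_normalized = idmn,
    inverse_variance = iv, maximum_probability = max(P),
    sum_average = sa, sum_entropy = ent2(psum), sum_variance = svar)
}

# enumerate runs by walking each line of a direction pixel by pixel
oracle_glrlm_runs <- function(q, mask, direction) {
  nr <- nrow(q); nc <- ncol(q)
  step <- switch(direction, `0` = c(0, 1), `90` = c(1, 0),
                 `45` = c(-1, 1), `135` = c(1, 1))
  starts <- list()
  for (r in 1:nr) for (cc in 1:nc) {
    pr <- r - step[1]; pc <- cc - step[2]
    if (pr < 1 || pr > nr || pc < 1 || pc > nc)
      starts[[length(starts) + 1]] <- c(r, cc)
  }
  g <- integer(0); len <- integer(0)
  for (s in starts) {
    r <- s[1]; cc <- s[2]
    cur <- NA_integer_; curlen <- 0L
    while (r >= 1 && r <= nr && cc >= 1 && cc <= nc) {
      v <- if (mask[r, cc]) q[r, cc] else NA_integer_
      if (!is.na(v) && !is.na(cur) && v == cur) {
        curlen <- curlen + 1L
      } else {
        if (!is.na(cur)) { g <- c(g, cur); len <- c(len, curlen) }
        cur <- v; curlen <- 1L
      }
      r <- r + step[1]; cc <- cc + step[2]
    }
    if (!is.na(cur)) { g <- c(g, cur); len <- c(len, curlen) }
  }
  list(g = g, len = len)
}

oracle_rl_features <- function(R, np) {
  L <- nrow(R); K <- ncol(R)
  nr_tot <- sum(R)
  sre <- lre <- gln <- rln <- lgre <- hgre <- 0
  srlge <- srhge <- lrlge <- lrhge <- 0
  for (g in 1:L) for (k in 1:K) {
    v <- R[g, k]
    sre <- sre + v / k^2; lre <- lre + v * k^2
    lgre <- lgre + v / g^2; hgre <- hgre + v * g^2
    srlge <- srlge + v / (g^2 * k^2); srhge <- srhge + v * g^2 / k^2
    lrlge <- lrlge + v * k^2 / g^2; lrhge <- lrhge + v * g^2 * k^2
  }
  for (g in 1:L) gln <- gln + sum(R[g, ])^2
  for (k in 1:K) rln <- rln + sum(R[, k])^2
  mu_g <- 0; mu_r <- 0
  for (g in 1:L) for (k in 1:K) { mu_g <- mu_g + g * R[g, k] / nr_tot
                                  mu_r <- mu_r + k * R[g, k] / nr_tot }
  glv <- 0; rlv <- 0
  for (g in 1:L) for (k in 1:K) {
    glv <- glv + (g - mu_g)^2 * R[g, k] / nr_tot
    rlv <- rlv + (k - mu_r)^2 * R[g, k] / nr_tot
  }
  c(sre, lre, gln, rln, nr_tot / np, lgre, hgre,
    srlge, srhge, lrlge, lrhge, glv, rlv) /
    c(nr_tot, nr_tot, nr_tot, nr_tot, 1, nr_tot, nr_tot,
      nr_tot, nr_tot, nr_tot, nr_tot, 1, 1)
}

oracle_glrlm <- function(q, mask, levels, directions = c("0", "45", "90", "135")) {
  rr <- lapply(directions, function(d) oracle_glrlm_runs(q, mask, d))
  maxlen <- max(1L, unlist(lapply(rr, function(r) r$len)))
  Rsum <- matrix(0, levels, maxlen)
  for (r in rr) {
    R <- matrix(0, levels, maxlen)
    for (k in seq_along(r$g)) R[r$g[k], r$len[k]] <- R[r$g[k], r$len[k]] + 1
    Rsum <- Rsum + R
  }
  v <- oracle_rl_features(Rsum / length(directions), sum(mask))
  names(v) <- c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
                "srlge", "srhge", "lrlge", "lrhge", "glv", "rlv")
  v
}

# 8-connected flood fill with an explicit queue
oracle_glszm_zones <- function(q, mask) {
  nr <- nrow(q); nc <- ncol(q)
  seen <- matrix(FALSE, nr, nc)
  level <- integer(0); size <- integer(0)
  for (r0 in 1:nr) for (c0 in 1:nc) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    g <- q[r0, c0]
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE; sz <- 0L
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      sz <- sz + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r <- p[1] + dr; cc <- p[2] + dc
        if (r < 1 || r > nr || cc < 1 || cc > nc) next
        if (!mask[r, cc] || seen[r, cc] || q[r, cc] != g) next
        seen[r, cc] <- TRUE
        queue[[length(queue) + 1]] <- c(r, cc)
      }
    }
    level <- c(level, g); size <- c(size, sz)
  }
  list(level = level, size = size)
}

oracle_glszm <- function(q, mask, levels) {
  zz <- oracle_glszm_zones(q, mask)
  R <- matrix(0, levels, max(zz$size))
  for (k in seq_along(zz$size)) R[zz$level[k], zz$size[k]] <- R[zz$level[k], zz$size[k]] + 1
  v <- oracle_rl_features(R, sum(mask))
  names(v) <- c("sze", "lze", "gln", "szn", "zp", "lgze", "hgze",
                "szlge", "szhge", "lzlge", "lzhge", "glv", "zsv")
  v
}

oracle_ngtdm <- function(q, mask, levels) {
  nr <- nrow(q); nc <- ncol(q)
  s_i <- numeric(levels); n_i <- numeric(levels)
  N <- 0
  for (r in 1:nr) for (cc in 1:nc) {
    if (!mask[r, cc]) next
    tot <- 0; cnt <- 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- cc + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (mask[r2, c2]) { tot <- tot + q[r2, c2]; cnt <- cnt + 1 }
    }
    if (cnt == 0) next
    g <- q[r, cc]
    s_i[g] <- s_i[g] + abs(g - tot / cnt)
    n_i[g] <- n_i[g] + 1
    N <- N + 1
  }
  p_i <- n_i / N
  pres <- which(p_i > 0); ng <- length(pres)
  den <- sum(p_i * s_i)
  coars <- if (den > 0) min(1 / den, 1e6) else 1e6
  con <- 0
  if (ng > 1) {
    for (i in pres) for (j in pres) con <- con + p_i[i] * p_i[j] * (i - j)^2
    con <- con / (ng * (ng - 1)) * sum(s_i) / N
  }
  bden <- 0
  for (i in pres) for (j in pres) bden <- bden + abs(i * p_i[i] - j * p_i[j])
  busy <- if (bden > 0) den / bden else 0
  cmpl <- 0
  for (i in pres) for (j in pres)
    cmpl <- cmpl + abs(i - j) * (p_i[i] * s_i[i] + p_i[j] * s_i[j]) /
      (p_i[i] + p_i[j])
  cmpl <- cmpl / N
  strn <- 0
  for (i in pres) for (j in pres) strn <- strn + (p_i[i] + p_i[j]) * (i - j)^2
  strn <- if (sum(s_i) > 0) strn / sum(s_i) else 0
  c(coarseness = coars, contrast = con, busyness = busy,
    complexity = cmpl, strength = strn)
}

# plain coordinate-descent lasso on standardized X:
# min (1/2n) ||y - b0 - X b||^2 + lambda ||b||_1
oracle_lasso_cd <- function(X, y, lambda, iters = 5000, tol = 1e-12) {
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X); sd <- apply(X, 2, stats::sd)
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sd, "/")
  b0 <- mean(y)
  b <- numeric(p)
  r <- y - b0 - Xs %*% b
  for (it in seq_len(iters)) {
    bold <- b
    for (j in seq_len(p)) {
      r <- r + Xs[, j] * b[j]
      z <- sum(Xs[, j] * r) / n
      bj <- sign(z) * max(0, abs(z) - lambda) / (sum(Xs[, j]^2) / n)
      b[j] <- bj
      r <- r - Xs[, j] * b[j]
    }
    if (max(abs(b - bold)) < tol) break
  }
  b
}

# AUC as the normalized Mann-Whitney U: fraction of concordant
# positive-negative pairs, ties counted half
oracle_auc_mw <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

rand_quantized <- function(nr = 8, nc = 8, levels = 4) {
  matrix(sample.int(levels, nr * nc, replace = TRUE), nr, nc)
}
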