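test_that("quantization bins the 8-bit range into equal-width levels", {
  img <- matrix(c(0, 127, 128, 255), 2, 2)
  expect_equal(as.vector(quantize(img, 2)), c(1L, 1L, 2L, 2L))
  expect_equal(as.vector(quantize(img, 256)), as.vector(img) + 1L)
  expect_true(all(quantize(matrix(77, 3, 3), 8) == 3L))
  expect_error(quantize(img, 1), "levels")
  expect_error(quantize(matrix(300, 2, 2), 4), "0, 255")
})

test_that("histogram features match closed forms and the brute-force oracle", {
  # constant image
  h <- histogram_features(matrix(9L, 4, 4))
  expect_equal(unname(h[c("mean", "variance", "entropy", "uniformity")]),
               c(9, 0, 0, 1))
  expect_equal(unname(h["energy"]), 16 * 81)
  # two-atom distribution: 1 bit of entropy, uniformity 1/2
  h2 <- histogram_features(matrix(c(0L, 255L), 4, 4))
  expect_equal(unname(h2["entropy"]), 1)
  expect_equal(unname(h2["uniformity"]), 0.5)
  # 4x4 ramp against the oracle
  ramp <- matrix(0:15, 4, 4)
  expect_equal(histogram_features(ramp), oracle_hist(ramp, matrix(TRUE, 4, 4)),
               tolerance = 1e-12)
  expect_error(histogram_features(ramp, matrix(FALSE, 4, 4)), "empty")
})

test_that("GLCM handles the checkerboard and degenerate cases", {
  cb <- matrix(rep_len(c(1L, 2L), 36), 6, 6)
  cb <- (row(cb) + col(cb)) %% 2L + 1L
  # horizontal direction: only 1-2 transitions, unit contrast
  P <- rfradiomics:::.glcm_one(cb, matrix(TRUE, 6, 6), c(0L, 1L), 2L)
  P <- P / sum(P)
  expect_equal(P[1, 1] + P[2, 2], 0)
  expect_equal(sum(P * (row(P) - col(P))^2), 1)
  # constant image: degenerate values
  g <- glcm_features(matrix(1L, 4, 4), levels = 4L)
  expect_equal(unname(g["joint_energy"]), 1)
  expect_equal(unname(g["contrast"]), 0)
  expect_equal(unname(g["correlation"]), 0)
})

test_that("GLRLM matches hand counts on canonical patterns", {
  # constant 4x4, horizontal runs only: one run of length 4 per row
  v <- glrlm_features(matrix(2L, 4, 4), levels = 4L, directions = "0")
  expect_equal(unname(v["rp"]), 4 / 16)
  expect_equal(unname(v["lre"]), 16)
  # strictly alternating line: all runs length 1
  alt <- matrix(rep_len(c(1L, 2L), 8), 1, 8)
  v2 <- glrlm_features(alt, levels = 2L, directions = "0")
  expect_equal(unname(v2["sre"]), 1)
  expect_equal(unname(v2["rp"]), 1)
})

test_that("GLSZM zones match the flood-fill picture", {
  # constant image: a single zone covering everything
  v <- glszm_features(matrix(3L, 4, 4), levels = 4L)
  expect_equal(unname(v["zp"]), 1 / 16)
  # two disjoint same-level blobs of sizes 3 and 5
  q <- matrix(1L, 5, 8)
  q[1, 1:3] <- 2L                       # blob of 3
  q[4:5, 6:7] <- 2L; q[5, 8] <- 2L      # blob of 5 (8-connected)
  zz <- rfradiomics:::.glszm_zones(q, matrix(TRUE, 5, 8))
  sizes2 <- sort(zz$size[zz$level == 2L])
  expect_equal(sizes2, c(3L, 5L))
})

test_that("NGTDM matches closed forms on flat and single-spike images", {
  v <- ngtdm_features(matrix(2L, 5, 5), levels = 4L)
  expect_equal(unname(v["coarseness"]), 1e6)   # flat field hits the cap
  expect_equal(unname(v["contrast"]), 0)
  # single bright pixel on a flat 5x5 field: equals the direct-formula oracle
  q <- matrix(1L, 5, 5); q[3, 3] <- 4L
  expect_equal(ngtdm_features(q, levels = 4L),
               oracle_ngtdm(q, matrix(TRUE, 5, 5), 4L), tolerance = 1e-12)
  expect_error(ngtdm_features(matrix(1L, 3, 3), matrix(FALSE, 3, 3)), "mask")
})

test_that("all five families equal their brute-force oracles on random images", {
  withr::with_seed(31, {
    for (i in 1:25) {
      q <- rand_quantized(8, 8, 4)
      mask <- matrix(stats::runif(64) > 0.2, 8, 8)
      if (sum(mask) < 8) mask[] <- TRUE
      img <- (q - 1L) * 60L   # an 8-bit image hitting the same 4 levels
      expect_equal(histogram_features(img, mask), oracle_hist(img, mask),
                   tolerance = 1e-9)
      expect_equal(glcm_features(q, mask, 4L), oracle_glcm(q, mask, 4L),
                   tolerance = 1e-9)
      expect_equal(glrlm_features(q, mask, 4L), oracle_glrlm(q, mask, 4L),
                   tolerance = 1e-9)
      expect_equal(glszm_features(q, mask, 4L), oracle_glszm(q, mask, 4L),
                   tolerance = 1e-9)
      expect_equal(ngtdm_features(q, mask, 4L), oracle_ngtdm(q, mask, 4L),
                   tolerance = 1e-9)
    }
  })
})

test_that("masked features ignore pixels outside the mask", {
  withr::with_seed(5, {
    img <- matrix(sample(0:255, 144, replace = TRUE), 12, 12)
  })
  mask <- matrix(FALSE, 12, 12); mask[4:9, 4:9] <- TRUE
  base <- texture_70(img, mask)
  img2 <- img
  img2[!mask] <- 255L - img2[!mask]
  expect_equal(texture_70(img2, mask), base, tolerance = 1e-12)
})

test_that("Haar sub-bands follow the closed-form butterflies", {
  # constant image: LL = 2c, details vanish
  sb <- wavelet_subbands(matrix(5, 4, 4))
  expect_true(all(sb$LL$coefficients == 10))
  expect_true(all(sb$LH$coefficients == 0))
  expect_true(all(sb$HL$coefficients == 0))
  expect_true(all(sb$HH$coefficients == 0))
  # 2x2 closed form
  m <- matrix(c(a <- 1, c <- 7, b <- 2, d <- 4), 2, 2)
  sb2 <- wavelet_subbands(m)
  expect_equal(sb2$LL$coefficients[1, 1], (a + b + c + d) / 2)
  expect_equal(sb2$LH$coefficients[1, 1], (a - b + c - d) / 2)
  expect_equal(sb2$HL$coefficients[1, 1], (a + b - c - d) / 2)
  expect_equal(sb2$HH$coefficients[1, 1], (a - b - c + d) / 2)
  # odd dimensions pad by edge replication: ceil(n/2) sub-band size
  sb3 <- wavelet_subbands(matrix(1:35, 5, 7))
  expect_equal(dim(sb3$LL$coefficients), c(3, 4))
  # mask downsampling: 2x2 majority with ties inside
  mk <- matrix(FALSE, 4, 4); mk[1:2, 1] <- TRUE    # 2 of 4 in top-left block
  sb4 <- wavelet_subbands(matrix(0, 4, 4), mk)
  expect_true(sb4$LL$mask[1, 1])
  expect_false(sb4$LL$mask[2, 2])
})

test_that("feature vectors have the frozen counts and layout", {
  withr::with_seed(9, {
    img <- matrix(sample(0:255, 16 * 14, replace = TRUE), 16, 14)
  })
  v70 <- texture_70(img, levels = 8L)
  expect_length(v70, 70)
  expect_equal(as.integer(table(sub("__.*", "", names(v70)))[
    c("hist", "glcm", "glrlm", "glszm", "ngtdm")]),
    c(16L, 23L, 13L, 13L, 5L))
  v350 <- extract_350(img, levels = 8L)
  expect_length(v350, 350)
  expect_false(any(duplicated(names(v350))))
  expect_true(all(is.finite(v350)))
  # original-band block equals the direct family calls
  expect_equal(unname(v350[1:70]), unname(v70))
  # wavelet block holds the other 280
  expect_equal(sum(grepl("^(LL|LH|HL|HH)__", names(v350))), 280)
})

test_that("model layouts assemble 350/700/1050 features in fixed map order", {
  withr::with_seed(10, {
    mkimg <- function() list(image = matrix(sample(0:255, 120, TRUE), 12, 10),
                             mask = matrix(TRUE, 12, 10))
    images <- list(gm = mkimg(), dea = mkimg(), ond = mkimg(), sdsd = mkimg())
  })
  gm <- assemble_model_vector(images, "GM", levels = 8L)
  dm <- assemble_model_vector(images, "DM", levels = 8L)
  dom <- assemble_model_vector(images, "DOM", levels = 8L)
  dosm <- assemble_model_vector(images, "DOSM", levels = 8L)
  expect_length(gm, 350); expect_length(dm, 350)
  expect_length(dom, 700); expect_length(dosm, 1050)
  expect_equal(dm, dosm[1:350])          # DM equals the DEA block of DOSM
  expect_identical(names(dosm), feature_manifest("DOSM"))
  expect_error(assemble_model_vector(images[c("gm", "dea")], "DOSM"), "missing")
})
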