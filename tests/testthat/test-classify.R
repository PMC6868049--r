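sep_toy <- function(n = 16, gap = 10, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(1, 0), each = n / 2)
    mu <- ifelse(y == 1, gap, -gap)
    X <- cbind(rnorm(n, mu, 0.5), rnorm(n, mu, 0.5))
  })
  list(X = X, y = y)
}

test_that("a widely separated toy problem is classified perfectly", {
  d <- sep_toy()
  pr <- loocv_predict(d$X, d$y)
  expect_equal(pr$label, d$y)
  expect_equal(auc_trapezoid(pr$score, d$y), 1)
})

test_that("LOOCV folds never see the held-out sample", {
  d <- sep_toy(n = 12, gap = 2, seed = 3)
  pr <- loocv_predict(d$X, d$y)
  # refit fold i by hand: standardize on the others, train, predict i
  for (i in c(1, 5, 12)) {
    tr <- setdiff(seq_len(12), i)
    mu <- colMeans(d$X[tr, ]); sd <- apply(d$X[tr, ], 2, stats::sd)
    Xtr <- sweep(sweep(d$X[tr, ], 2, mu, "-"), 2, sd, "/")
    yf <- factor(ifelse(d$y[tr] == 1, "pos", "neg"), levels = c("neg", "pos"))
    gam <- 1 / (2 * mean(apply(Xtr, 2, stats::var)))
    fit <- e1071::svm(Xtr, yf, kernel = "radial", cost = 1, gamma = gam,
                      scale = FALSE)
    p <- predict(fit, matrix((d$X[i, ] - mu) / sd, 1), decision.values = TRUE)
    dv <- attr(p, "decision.values")
    s <- if (startsWith(colnames(dv)[1], "pos")) dv[1] else -dv[1]
    expect_equal(unname(s), pr$score[i], tolerance = 1e-10)
  }
  # perturbing the held-out sample leaves every other fold's score unchanged
  X2 <- d$X; X2[1, ] <- X2[1, ] + 100
  pr2 <- loocv_predict(X2, d$y)
  # fold 1's model is untouched, so fold 1 differs only through its input;
  # folds that trained on sample 1 change - but the protocol is per-fold
  expect_false(isTRUE(all.equal(pr2$score[1], pr$score[1])))
})

test_that("shuffled labels yield chance-level AUC on average", {
  withr::with_seed(5, {
    y <- rep(c(1, 0), each = 21)
    X <- cbind(rnorm(42, ifelse(y == 1, 3, -3), 1), rnorm(42))
  })
  aucs <- vapply(1:20, function(s) {
    ys <- withr::with_seed(100 + s, sample(y))
    pr <- loocv_predict(X, ys)
    auc_trapezoid(pr$score, ys)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.12)
})

test_that("duplicating feature columns leaves predictions unchanged", {
  d <- sep_toy(n = 12, gap = 2, seed = 7)
  pr1 <- loocv_predict(d$X, d$y, svm_config(gamma = 0.5))
  pr2 <- loocv_predict(cbind(d$X, d$X), d$y, svm_config(gamma = 0.25))
  expect_equal(pr1$score, pr2$score, tolerance = 1e-8)
})

test_that("AUC equals the hand-counted concordant-pair fraction", {
  scores <- c(0.9, 0.8, 0.7, 0.6)
  y <- c(1, 0, 1, 0)
  expect_equal(auc_trapezoid(scores, y), 0.75)   # 3 of 4 pairs concordant
  expect_equal(oracle_auc_mw(scores, y), 0.75)
})

test_that("trapezoidal AUC equals the normalized Mann-Whitney statistic", {
  withr::with_seed(21, {
    for (i in 1:10) {
      n <- sample(6:20, 1)
      y <- c(1, 0, rbinom(n - 2, 1, 0.5))
      scores <- round(rnorm(n), 2)   # rounding forces ties
      expect_equal(auc_trapezoid(scores, y), oracle_auc_mw(scores, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("curve computation satisfies its boundary identities", {
  y <- c(1, 1, 1, 0, 0, 0)
  perfect <- c(3, 2.5, 2, -1, -2, -3)
  cv <- roc_prc_dca(perfect, y)
  expect_equal(cv$auc, 1)
  expect_true(all(cv$prc$precision == 1))          # precision 1 at all recalls
  expect_true(all(cv$roc$tpr >= 0 & cv$roc$tpr <= 1))
  expect_equal(cv$auc_ci[2], 1)
  # net benefit is 0 wherever nobody is predicted positive: overlapping
  # scores keep the Platt probabilities away from 1
  over <- c(0.3, 0.2, 0.35, 0.25, 0.1, 0.15)
  cv2 <- roc_prc_dca(over, y)
  pmax_prob <- max(stats::fitted(suppressWarnings(
    stats::glm(y ~ over, family = stats::binomial()))))
  hi_pt <- cv2$dca[cv2$dca$pt > pmax_prob, ]
  expect_gt(nrow(hi_pt), 0)
  expect_true(all(hi_pt$net_benefit == 0))
  # constant scores are flagged and give AUC 1/2
  cv3 <- roc_prc_dca(rep(1, 6), y)
  expect_equal(cv3$auc, 0.5)
  expect_true(cv3$constant_scores)
  expect_true(all(is.na(cv3$auc_ci)))
})

test_that("the DeLong interval brackets the point AUC", {
  withr::with_seed(30, {
    y <- rep(c(1, 0), each = 15)
    scores <- rnorm(30, mean = y)
  })
  cv <- roc_prc_dca(scores, y)
  expect_lte(cv$auc_ci[1], cv$auc)
  expect_gte(cv$auc_ci[2], cv$auc)
  expect_gt(cv$auc_ci[1], 0)
})

test_that("sweep_k evaluates nested feature sets and breaks ties at small k", {
  withr::with_seed(9, {
    y <- rep(c(1, 0), each = 10)
    X <- cbind(y * 8 + rnorm(20), matrix(rnorm(20 * 4), 20, 4))
  })
  ev <- sweep_k(X, y, k_max = 5)
  expect_equal(nrow(ev$per_k), 5)
  expect_equal(ev$per_k$k, 1:5)
  # the first column separates perfectly, so accuracy 1 at k = 1 and the
  # smallest-k tie-break selects k = 1
  expect_equal(ev$best_k, 1)
  expect_equal(ev$best$accuracy, 1)
  # reported sensitivity/specificity equal a recomputation from predictions
  pr <- loocv_predict(X[, 1, drop = FALSE], y)
  tp <- sum(pr$label == 1 & y == 1); fn <- sum(pr$label == 0 & y == 1)
  tn <- sum(pr$label == 0 & y == 0); fp <- sum(pr$label == 1 & y == 0)
  expect_equal(ev$per_k$sensitivity[1], tp / (tp + fn))
  expect_equal(ev$per_k$specificity[1], tn / (tn + fp))
  ev1 <- sweep_k(X, y, k_max = 1)
  expect_equal(nrow(ev1$per_k), 1)
})

test_that("loocv_predict guards its preconditions", {
  expect_error(loocv_predict(matrix(rnorm(6), 3, 2), c(1, 0, 1)), "4 samples")
  expect_error(loocv_predict(matrix(rnorm(10), 5, 2), rep(1, 5)), "class")
})
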