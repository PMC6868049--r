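#' SVM configuration
#'
#' Gaussian RBF kernel with cost 1 by default; the kernel bandwidth
#' defaults to `1 / (n_features * mean feature variance)` computed on the
#' training fold (the "scale" convention).
#'
#' @param kernel e1071 kernel name.
#' @param cost soft-margin cost parameter.
#' @param gamma kernel bandwidth, or `NULL` for the scale convention.
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(kernel = "radial", cost = 1, gamma = NULL) {
  structure(list(kernel = kernel, cost = cost, gamma = gamma),
            class = "svm_config")
}

.fit_svm <- function(Xtr, ytr, config) {
  gam <- config$gamma
  if (is.null(gam)) {
    v <- mean(apply(Xtr, 2, stats::var))
    gam <- if (is.finite(v) && v > 0) 1 / (ncol(Xtr) * v) else 1 / ncol(Xtr)
  }
  yf <- factor(ifelse(ytr == 1, "pos", "neg"), levels = c("neg", "pos"))
  e1071::svm(Xtr, yf, kernel = config$kernel, cost = config$cost,
             gamma = gam, scale = FALSE)
}

.svm_scores <- function(fit, Xte) {
  pr <- stats::predict(fit, Xte, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  s <- as.numeric(dv[, 1])
  # orient the score so larger means more likely positive
  if (!startsWith(colnames(dv)[1], "pos")) s <- -s
  list(score = s, label = as.integer(pr == "pos"))
}

#' Leave-one-out cross-validated SVM predictions
#'
#' For each sample, an SVM is trained on the remaining `N - 1` samples
#' (features standardized on those `N - 1` only, the same transform then
#' applied to the held-out sample) and the held-out decision score and hard
#' label are recorded. The positive class is the MVI-positive label 1, and
#' the hard-label threshold is the SVM decision boundary (score 0).
#'
#' @param X samples x features matrix.
#' @param y binary labels (1 = positive class).
#' @param config an [svm_config()].
#' @return List with numeric `score` and integer `label` per sample.
#' @export
loocv_predict <- function(X, y, config = svm_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 samples")
  y <- as.integer(.pm1(y) > 0)
  if (length(unique(y)) < 2) stop("both classes must be present")
  score <- numeric(n); label <- integer(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    mu <- colMeans(X[tr, , drop = FALSE])
    sd <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sd[!is.finite(sd) | sd == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu, "-"), 2, sd, "/")
    Xte <- matrix((X[i, ] - mu) / sd, 1)
    fit <- .fit_svm(Xtr, y[tr], config)
    out <- .svm_scores(fit, Xte)
    score[i] <- out$score
    label[i] <- out$label
  }
  list(score = score, label = label)
}

.binary_metrics <- function(pred_label, y) {
  tp <- sum(pred_label == 1 & y == 1); tn <- sum(pred_label == 0 & y == 0)
  fp <- sum(pred_label == 1 & y == 0); fn <- sum(pred_label == 0 & y == 1)
  c(accuracy = (tp + tn) / length(y),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Trapezoidal AUC from scores
#'
#' @param scores decision scores (larger = more positive).
#' @param y binary labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(scores, y) {
  r <- .roc_points(scores, y)
  sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
}

.roc_points <- function(scores, y) {
  y <- as.integer(.pm1(y) > 0)
  thr <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / npos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / nneg, numeric(1))
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' ROC, precision-recall and decision curves with AUC confidence interval
#'
#' ROC by score-threshold sweep with trapezoidal AUC and a DeLong 95% CI;
#' precision-recall points over the same thresholds; decision-curve net
#' benefit `NB(pt) = TP/N - (FP/N) pt/(1-pt)` over a threshold-probability
#' grid, with predicted probabilities obtained from a logistic (Platt) link
#' fitted on the decision scores.
#'
#' @param scores decision scores.
#' @param y binary labels (1 = positive).
#' @param threshold_grid threshold probabilities for the decision curve,
#'   strictly inside (0, 1).
#' @return List with `roc` (data.frame), `auc`, `auc_ci` (95% DeLong, `NA`
#'   when the scores are constant), `prc` (data.frame recall/precision),
#'   `dca` (data.frame pt/net_benefit/nb_all/nb_none).
#' @export
roc_prc_dca <- function(scores, y, threshold_grid = seq(0.01, 0.99, by = 0.01)) {
  y <- as.integer(.pm1(y) > 0)
  if (length(unique(y)) < 2) stop("both classes must be present")
  n <- length(y)
  constant <- length(unique(scores)) == 1

  roc <- .roc_points(scores, y)
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  auc_ci <- c(NA_real_, NA_real_)
  if (!constant) {
    r <- pROC::roc(response = y, predictor = scores, levels = c(0, 1),
                   direction = "<", quiet = TRUE)
    auc_ci <- suppressWarnings(
      as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)])
  }

  thr <- sort(unique(scores), decreasing = TRUE)
  prc <- do.call(rbind, lapply(thr, function(t) {
    tp <- sum(scores >= t & y == 1); fp <- sum(scores >= t & y == 0)
    data.frame(recall = tp / sum(y == 1),
               precision = if (tp + fp > 0) tp / (tp + fp) else 1)
  }))
  # stop at the first threshold achieving full recall; later thresholds
  # only dilute precision
  full <- which(prc$recall == 1)
  if (length(full)) prc <- prc[seq_len(full[1]), , drop = FALSE]

  # Platt link; perfect separation just saturates the probabilities
  prob <- if (constant) rep(mean(y), n) else {
    fit <- suppressWarnings(stats::glm(y ~ scores, family = stats::binomial()))
    as.numeric(stats::fitted(fit))
  }
  prev <- mean(y)
  dca <- do.call(rbind, lapply(threshold_grid, function(pt) {
    pos <- prob >= pt
    tp <- sum(pos & y == 1); fp <- sum(pos & y == 0)
    data.frame(pt = pt,
               net_benefit = tp / n - fp / n * pt / (1 - pt),
               nb_all = prev - (1 - prev) * pt / (1 - pt),
               nb_none = 0)
  }))
  list(roc = roc, auc = auc, auc_ci = auc_ci, prc = prc, dca = dca,
       constant_scores = constant)
}

#' Incremental top-k feature sweep with LOOCV
#'
#' Starting from the single best-ranked feature, evaluates the SVM under
#' LOOCV on the top-k features for `k = 1..k_max` (identical fold structure
#' at every k), and selects `best_k` by maximum accuracy, ties broken by
#' maximum AUC, then by the smallest k.
#'
#' @param X_ranked samples x features matrix whose columns are already in
#'   ranking order (best feature first).
#' @param y binary labels.
#' @param k_max largest feature count to evaluate (clipped to `ncol`).
#' @param config an [svm_config()].
#' @param model_name label stored on the result.
#' @return An object of class `eval_result`: `per_k` (data.frame with k,
#'   auc, accuracy, sensitivity, specificity), `best_k`, `best` (metrics
#'   row), `curves` ([roc_prc_dca()] output at `best_k`), `scores_best_k`.
#' @export
sweep_k <- function(X_ranked, y, k_max = 50L, config = svm_config(),
                    model_name = NA_character_) {
  X_ranked <- as.matrix(X_ranked)
  k_max <- min(as.integer(k_max), ncol(X_ranked))
  y <- as.integer(.pm1(y) > 0)
  rows <- vector("list", k_max)
  preds <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    pr <- loocv_predict(X_ranked[, seq_len(k), drop = FALSE], y, config)
    m <- .binary_metrics(pr$label, y)
    rows[[k]] <- data.frame(k = k, auc = auc_trapezoid(pr$score, y),
                            accuracy = m["accuracy"], sensitivity = m["sensitivity"],
                            specificity = m["specificity"], row.names = NULL)
    preds[[k]] <- pr
  }
  per_k <- do.call(rbind, rows)
  ord <- order(-per_k$accuracy, -per_k$auc, per_k$k)
  best_k <- per_k$k[ord[1]]
  curves <- roc_prc_dca(preds[[best_k]]$score, y)
  structure(list(per_k = per_k, best_k = best_k,
                 best = per_k[per_k$k == best_k, ],
                 curves = curves, scores_best_k = preds[[best_k]]$score,
                 model_name = model_name),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  b <- x$best
  cat(sprintf("<eval_result %s> best k=%d: AUC=%.3f acc=%.3f sens=%.3f spec=%.3f\n",
              ifelse(is.na(x$model_name), "", x$model_name), x$best_k,
              b$auc, b$accuracy, b$sensitivity, b$specificity))
  invisible(x)
}

#' End-to-end evaluation of the four prediction models
#'
#' Runs the full pipeline on a cohort: per-lesion images (B-mode ROI and the
#' three parametric maps), texture feature tables, iterative
#' sparse-representation ranking, and the incremental top-k LOOCV sweep, for
#' each requested model layout.
#'
#' In mode `"pooled"` feature selection is run once on all samples and only
#' the classifier is cross-validated — the protocol of the study this
#' pipeline mirrors, which leaks selection information across folds; mode
#' `"nested"` re-runs selection inside every training fold and is the
#' unbiased variant (slower).
#'
#' @param cohort an `rf_cohort`.
#' @param models character subset of `c("GM","DM","DOM","DOSM")`.
#' @param window a [window_spec()].
#' @param levels quantization levels for the texture battery.
#' @param sr list of [iterative_sr()] settings (`n_iter`,
#'   `subsample_fraction`, `lambda`, `tal`).
#' @param svm an [svm_config()].
#' @param k_max top-k sweep limit.
#' @param mode `"pooled"` or `"nested"`.
#' @param seed seed for the selection subsampling.
#' @return List with `results` (named list of `eval_result`), `selection`
#'   (named list of `selection_result`, mode `"pooled"` only), `summary`
#'   (data.frame: model, n_features, n_survivors, best_k and metrics).
#' @export
run_models <- function(cohort, models = c("GM", "DM", "DOM", "DOSM"),
                       window = window_spec(), levels = 32L,
                       sr = list(n_iter = 100L, subsample_fraction = 0.8,
                                 lambda = "auto", tal = 0.004),
                       svm = svm_config(), k_max = 50L,
                       mode = c("pooled", "nested"), seed = 1L) {
  mode <- match.arg(mode)
  if (length(cohort) == 0) stop("empty cohort")
  models <- match.arg(models, several.ok = TRUE)
  per_lesion_images <- lapply(cohort, function(f) lesion_feature_maps(f, window)$images)
  y <- cohort_labels(cohort)

  results <- list(); selections <- list(); summary_rows <- list()
  for (mdl in models) {
    tab <- cohort_feature_table(cohort, mdl, window, levels, per_lesion_images)
    X <- tab$X
    if (mode == "pooled") {
      sel <- iterative_sr(X, y, n_iter = sr$n_iter,
                          subsample_fraction = sr$subsample_fraction,
                          lambda = sr$lambda, tal = sr$tal, seed = seed)
      ev <- sweep_k(X[, sel$ranking, drop = FALSE], y, k_max, svm, mdl)
      selections[[mdl]] <- sel
      n_surv <- length(sel$survivors)
    } else {
      ev <- .nested_sweep(X, y, sr, svm, k_max, mdl, seed)
      n_surv <- NA_integer_
    }
    results[[mdl]] <- ev
    summary_rows[[mdl]] <- data.frame(
      model = mdl, n_features = ncol(X), n_survivors = n_surv,
      best_k = ev$best_k, auc = ev$best$auc, accuracy = ev$best$accuracy,
      sensitivity = ev$best$sensitivity, specificity = ev$best$specificity,
      row.names = NULL)
  }
  list(results = results, selection = selections,
       summary = do.call(rbind, summary_rows))
}

# nested mode: selection re-run on each LOOCV training fold
.nested_sweep <- function(X, y, sr, svm, k_max, model_name, seed) {
  n <- nrow(X)
  k_max <- min(as.integer(k_max), ncol(X))
  scores <- matrix(NA_real_, n, k_max)
  labels <- matrix(NA_integer_, n, k_max)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    sel <- iterative_sr(X[tr, , drop = FALSE], y[tr], n_iter = sr$n_iter,
                        subsample_fraction = sr$subsample_fraction,
                        lambda = sr$lambda, tal = sr$tal, seed = seed + i)
    for (k in seq_len(k_max)) {
      cols <- sel$ranking[seq_len(k)]
      mu <- colMeans(X[tr, cols, drop = FALSE])
      sd <- apply(X[tr, cols, drop = FALSE], 2, stats::sd)
      sd[!is.finite(sd) | sd == 0] <- 1
      Xtr <- sweep(sweep(X[tr, cols, drop = FALSE], 2, mu, "-"), 2, sd, "/")
      Xte <- matrix((X[i, cols] - mu) / sd, 1)
      fit <- .fit_svm(Xtr, y[tr], svm)
      out <- .svm_scores(fit, Xte)
      scores[i, k] <- out$score
      labels[i, k] <- out$label
    }
  }
  rows <- lapply(seq_len(k_max), function(k) {
    m <- .binary_metrics(labels[, k], y)
    data.frame(k = k, auc = auc_trapezoid(scores[, k], y),
               accuracy = m["accuracy"], sensitivity = m["sensitivity"],
               specificity = m["specificity"], row.names = NULL)
  })
  per_k <- do.call(rbind, rows)
  ord <- order(-per_k$accuracy, -per_k$auc, per_k$k)
  best_k <- per_k$k[ord[1]]
  structure(list(per_k = per_k, best_k = best_k,
                 best = per_k[per_k$k == best_k, ],
                 curves = roc_prc_dca(scores[, best_k], y),
                 scores_best_k = scores[, best_k],
                 model_name = model_name),
            class = "eval_result")
}
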