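#' Single sparse-representation fit
#'
#' Represents the label vector over the feature dictionary by L1-penalized
#' least squares: coefficients of `min (1/2n)||y - b0 - X b||^2 + lambda ||b||_1`
#' with the feature columns standardized on the supplied subset. Most
#' coefficients are exactly zero at adequate `lambda`.
#'
#' @param X_sub samples x features matrix (a subsample; standardization is
#'   computed on it, never on held-out data).
#' @param y_sub labels coded -1/+1 (0/1 accepted and recoded).
#' @param lambda L1 penalty.
#' @return Numeric vector of per-feature coefficients (on the standardized
#'   scale), named by the columns of `X_sub`.
#' @export
sr_fit_once <- function(X_sub, y_sub, lambda) {
  y <- .pm1(y_sub)
  if (length(unique(y)) < 2) stop("subset contains a single class")
  if (min(table(y)) < 2) stop("need at least 2 samples per class in the subset")
  Xs <- .standardize(X_sub)
  keep <- attr(Xs, "keep")
  beta <- numeric(ncol(X_sub))
  if (any(keep)) {
    n <- nrow(Xs)
    lam_max <- max(abs(crossprod(Xs[, keep, drop = FALSE], y - mean(y)))) / n
    if (lambda >= lam_max) {
      # at or beyond the null penalty every coefficient is zero
      beta[] <- 0
    } else if (sum(keep) == 1L) {
      # univariate soft-threshold solution
      x1 <- Xs[, keep]
      yc <- y - mean(y)
      z <- sum(x1 * yc) / n
      beta[keep] <- sign(z) * max(0, abs(z) - lambda) / (sum(x1^2) / n)
    } else {
      lams <- exp(seq(log(lam_max), log(lambda), length.out = 40L))
      fit <- glmnet::glmnet(Xs[, keep, drop = FALSE], y, family = "gaussian",
                            lambda = lams, standardize = FALSE,
                            intercept = TRUE, thresh = 1e-13, maxit = 1e7)
      beta[keep] <- as.numeric(stats::coef(fit, s = lambda))[-1]
    }
  }
  names(beta) <- colnames(X_sub)
  beta
}

.pm1 <- function(y) {
  y <- as.numeric(y)
  u <- sort(unique(y))
  if (length(u) > 2) stop("labels must be binary")
  ifelse(y == max(u), 1, -1)
}

.standardize <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  keep <- is.finite(sd) & sd > 0
  Xs <- sweep(X, 2, mu, "-")
  Xs[, keep] <- sweep(Xs[, keep, drop = FALSE], 2, sd[keep], "/")
  Xs[, !keep] <- 0
  attr(Xs, "keep") <- keep
  Xs
}

#' Iterative sparse-representation feature ranking
#'
#' Repeats [sr_fit_once()] on class-stratified subsamples, averages the
#' coefficients over iterations, ranks features by the absolute averaged
#' coefficient (ties broken lexicographically by name, so builds are
#' deterministic), and keeps the features whose `|coefficient| >= tal`.
#'
#' When `lambda = "auto"` the penalty is chosen once, before the iterations,
#' from a small grid (fractions of the null penalty on the full data) by
#' maximizing the mean pairwise Jaccard overlap of the top-20 features
#' across probe subsamples — a stability criterion.
#'
#' @param X samples x features matrix with column names.
#' @param y binary labels.
#' @param n_iter number of subsample iterations (`>= 1`).
#' @param subsample_fraction fraction of each class drawn per iteration,
#'   in (0, 1).
#' @param lambda L1 penalty, or `"auto"`.
#' @param tal survivor threshold on the absolute averaged coefficient.
#' @param seed integer seed; fixed seed reproduces the selection exactly.
#' @return An object of class `selection_result`: `coefficients` (named,
#'   averaged), `ranking` (feature names, decreasing `|coefficient|`),
#'   `survivors`, `tal`, `n_iter`, `subsample_fraction`, `lambda`, `seed`.
#' @export
iterative_sr <- function(X, y, n_iter = 100L, subsample_fraction = 0.8,
                         lambda = "auto", tal = 0.004, seed = 1L) {
  if (n_iter < 1L) stop("n_iter must be >= 1")
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stop("subsample_fraction must be in (0, 1]")
  if (is.null(colnames(X))) stop("X must have column names (feature identity)")
  if (any(!is.finite(X))) stop("X must be finite")
  yb <- .pm1(y)

  withr::local_seed(seed)
  if (identical(lambda, "auto")) lambda <- .choose_lambda(X, yb, subsample_fraction)

  idx_pos <- which(yb > 0); idx_neg <- which(yb < 0)
  n_take <- function(idx) max(2L, ceiling(subsample_fraction * length(idx)))
  acc <- numeric(ncol(X))
  for (it in seq_len(n_iter)) {
    sub <- c(sample(idx_pos, min(n_take(idx_pos), length(idx_pos))),
             sample(idx_neg, min(n_take(idx_neg), length(idx_neg))))
    acc <- acc + sr_fit_once(X[sub, , drop = FALSE], yb[sub], lambda)
  }
  coefs <- acc / n_iter
  names(coefs) <- colnames(X)
  ord <- order(-abs(coefs), names(coefs), method = "radix")
  ranking <- colnames(X)[ord]
  survivors <- ranking[abs(coefs[ord]) >= tal]
  structure(list(coefficients = coefs, ranking = ranking, survivors = survivors,
                 tal = tal, n_iter = n_iter,
                 subsample_fraction = subsample_fraction,
                 lambda = lambda, seed = seed),
            class = "selection_result")
}

.choose_lambda <- function(X, yb, subsample_fraction,
                           fractions = c(0.5, 0.2, 0.1, 0.05),
                           n_probe = 8L, top = 20L) {
  Xs <- .standardize(X)
  n <- nrow(X)
  lam_max <- max(abs(crossprod(Xs, yb - mean(yb)))) / n
  idx_pos <- which(yb > 0); idx_neg <- which(yb < 0)
  n_take <- function(idx) max(2L, ceiling(subsample_fraction * length(idx)))
  best <- fractions[1] * lam_max; best_score <- -Inf
  for (f in fractions) {
    lam <- f * lam_max
    tops <- lapply(seq_len(n_probe), function(i) {
      sub <- c(sample(idx_pos, min(n_take(idx_pos), length(idx_pos))),
               sample(idx_neg, min(n_take(idx_neg), length(idx_neg))))
      b <- sr_fit_once(X[sub, , drop = FALSE], yb[sub], lam)
      nz <- names(b)[b != 0]
      utils::head(nz[order(-abs(b[b != 0]))], top)
    })
    pairs <- utils::combn(n_probe, 2)
    jac <- mean(apply(pairs, 2, function(p) {
      a <- tops[[p[1]]]; b <- tops[[p[2]]]
      if (length(a) == 0 && length(b) == 0) return(0)
      length(intersect(a, b)) / length(union(a, b))
    }))
    if (jac > best_score) { best_score <- jac; best <- lam }
  }
  best
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d features, %d survivors at tal=%g (lambda=%.4g, %d iterations)\n",
              length(x$coefficients), length(x$survivors), x$tal, x$lambda, x$n_iter))
  invisible(x)
}

#' Serialize a selection result to JSON
#'
#' @param sel a `selection_result`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_selection_json <- function(sel, path) {
  jsonlite::write_json(
    list(coefficients = as.list(sel$coefficients), ranking = sel$ranking,
         survivors = sel$survivors, tal = sel$tal, n_iter = sel$n_iter,
         subsample_fraction = sel$subsample_fraction, lambda = sel$lambda,
         seed = sel$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Group comparison of the per-lesion map parameters
#'
#' One-way ANOVA per ultrasound parameter (DEA, OND, SDSD) between the two
#' lesion groups, plus Tukey HSD pairwise comparisons among the
#' parameter-by-group cells (each parameter standardized to unit pooled
#' scale so the three parameters are comparable).
#'
#' @param per_lesion_means data.frame with columns `dea`, `ond`, `sdsd`.
#' @param labels binary group labels, `>= 2` lesions per group.
#' @return List with `anova` (data.frame: parameter, F, p) and `tukey`
#'   (the Tukey HSD table over parameter x group cells).
#' @export
compare_parameter_groups <- function(per_lesion_means, labels) {
  params <- c("dea", "ond", "sdsd")
  stopifnot(all(params %in% names(per_lesion_means)))
  g <- factor(labels)
  if (nlevels(g) < 2 || min(table(g)) < 2) stop("need >= 2 lesions per group")
  res <- lapply(params, function(p) {
    v <- per_lesion_means[[p]]
    if (stats::var(v) == 0) stop("degenerate (zero-variance) parameter: ", p)
    a <- stats::anova(stats::aov(v ~ g))
    data.frame(parameter = p, F = a$`F value`[1], p = a$`Pr(>F)`[1])
  })
  long <- do.call(rbind, lapply(params, function(p) {
    v <- per_lesion_means[[p]]
    data.frame(value = (v - mean(v)) / stats::sd(v),
               cell = interaction(p, g, sep = ":"))
  }))
  tk <- stats::TukeyHSD(stats::aov(value ~ cell, data = long))$cell
  list(anova = do.call(rbind, res), tukey = tk)
}
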