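#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 logL + 2k + 2k(k + 1) / (n - k - 1).
#'
#' @param log_likelihood maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size; must exceed k + 1 or the correction is undefined.
#' @return scalar AICc.
#' @export
aicc <- function(log_likelihood, k, n) {
  if (n <= k + 1) stop("AICc undefined: need n > k + 1")
  -2 * log_likelihood + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Compare candidate RSF models by AICc
#'
#' Ranks models by AICc on the same data; the best-supported model is
#' decisive when its margin over the runner-up exceeds 2, and every model
#' within 2 of the best is flagged parsimonious.
#'
#' @param fits named list of `rsf_fit` objects fitted to the same used-point
#'   set, or a data.frame with columns `model`, `log_likelihood`, `k`, `n`
#'   (or a pre-computed `aicc` column).
#' @return a `model_comparison` data.frame sorted by AICc with columns
#'   `model`, `k`, `n`, `log_likelihood`, `aicc`, `delta`, `parsimonious`,
#'   plus attributes `best` and `decisive`.
#' @export
compare_models <- function(fits) {
  if (is.data.frame(fits)) {
    tab <- fits
    if (is.null(tab$aicc)) {
      tab$aicc <- mapply(aicc, tab$log_likelihood, tab$k, tab$n)
    }
  } else {
    n <- vapply(fits, function(f) f$n_used + f$n_available, 0)
    n_used <- vapply(fits, function(f) f$n_used, 0)
    if (length(unique(n_used)) > 1L || length(unique(n)) > 1L) {
      stop("models were fitted to different data (n differs)")
    }
    tab <- data.frame(
      model = names(fits) %||% paste0("m", seq_along(fits)),
      k = vapply(fits, function(f) f$k, 0),
      n = n,
      log_likelihood = vapply(fits, function(f) f$log_likelihood, 0)
    )
    tab$aicc <- mapply(aicc, tab$log_likelihood, tab$k, tab$n)
  }
  tab <- tab[order(tab$aicc), , drop = FALSE]
  tab$delta <- tab$aicc - tab$aicc[1]
  tab$parsimonious <- tab$delta <= 2
  rownames(tab) <- NULL
  attr(tab, "best") <- tab$model[1]
  attr(tab, "decisive") <- nrow(tab) < 2 || tab$delta[2] > 2
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

#' Rank-based AUC (Mann-Whitney estimator)
#'
#' Probability that a randomly chosen positive scores above a randomly
#' chosen negative, ties counted one half — identical to the normalized
#' Mann-Whitney U statistic computed from midranks.
#'
#' @param scores numeric scores.
#' @param labels 0/1 (or logical) class labels.
#' @return scalar AUC in [0, 1].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fivefold cross-validated AUC of a used-available design
#'
#' Rows are partitioned into k folds stratified by case (so each fold keeps
#' the used:available ratio); for each fold the RSF is refitted on the
#' remaining folds and the held-out rows are scored by their linear
#' predictor. AUC per fold is the rank statistic of used vs available
#' scores. Mean AUC is banded per the usual reading: 0.5--0.7 low
#' performance, 0.7--0.9 useful application, > 0.9 high performance.
#'
#' @param design an `rsf_design`.
#' @param k number of folds (default 5).
#' @param seed integer RNG seed for fold assignment.
#' @return a `cv_result`: list with `fold_auc`, `mean_auc`, `sd_auc`, `k`,
#'   `band`.
#' @export
kfold_auc <- function(design, k = 5L, seed = 1L) {
  df <- design$data
  if (design$n_used < k || design$n_available < k) {
    stop("need at least k rows of each class")
  }
  set.seed(seed)
  fold <- integer(nrow(df))
  for (cls in c(0, 1)) {
    i <- which(df$case == cls)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  fml <- design_formula(design)
  fold_auc <- vapply(seq_len(k), function(f) {
    train <- df[fold != f, , drop = FALSE]
    test <- df[fold == f, , drop = FALSE]
    if (length(unique(test$case)) < 2L) {
      stop("a fold contains a single class; change the stratification seed")
    }
    m <- suppressWarnings(
      stats::glm(fml, family = stats::binomial(), data = train)
    )
    eta <- stats::predict(m, newdata = test, type = "link")
    auc_rank(eta, test$case)
  }, 0)
  m <- mean(fold_auc)
  band <- if (m > 0.9) "high" else if (m > 0.7) "useful" else "low"
  structure(list(fold_auc = fold_auc, mean_auc = m,
                 sd_auc = sd(fold_auc), k = k, band = band),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV AUC: %.3f (SD %.4f) — %s\n",
              x$k, x$mean_auc, x$sd_auc, x$band))
  invisible(x)
}

#' Screen continuous covariates for collinearity
#'
#' Computes the pairwise Pearson correlation matrix and drops, from every
#' pair with |r| above the threshold, the covariate that comes later in the
#' priority order (the column order of `x`).
#'
#' @param x data.frame or matrix of continuous covariates (>= 2 columns).
#' @param threshold absolute-correlation cutoff (default 0.7).
#' @return list with `retained`, `dropped`, `correlation` (matrix) and
#'   `flagged` (data.frame of offending pairs with their r).
#' @export
correlation_screen <- function(x, threshold = 0.7) {
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, TRUE)
  x <- x[num]
  if (ncol(x) < 2L) stop("need >= 2 continuous covariates")
  cm <- cor(as.matrix(x), use = "pairwise.complete.obs")
  flagged <- data.frame(a = character(), b = character(), r = numeric())
  dropped <- character()
  nms <- colnames(cm)
  for (i in seq_len(ncol(cm) - 1L)) {
    for (j in (i + 1L):ncol(cm)) {
      if (abs(cm[i, j]) > threshold) {
        flagged <- rbind(flagged,
                         data.frame(a = nms[i], b = nms[j], r = cm[i, j]))
        if (!(nms[i] %in% dropped)) dropped <- union(dropped, nms[j])
      }
    }
  }
  list(retained = setdiff(nms, dropped), dropped = dropped,
       correlation = cm, flagged = flagged)
}

#' Empirical semivariogram of model residuals
#'
#' gamma(h) = mean of (r_i - r_j)^2 / 2 over point pairs whose separation
#' falls in the lag bin around h. A flat curve indicates no residual
#' spatial autocorrelation.
#'
#' @param residuals numeric vector (>= 30 points).
#' @param coords matrix or data.frame of (x, y).
#' @param n_lags number of equal-width lag bins (default 12).
#' @param max_lag largest separation considered; default half the diagonal
#'   of the coordinate bounding box.
#' @return data.frame with `lag` (bin midpoint), `gamma`, `n_pairs`; empty
#'   bins are kept with `n_pairs = 0` and NA gamma.
#' @export
residual_semivariogram <- function(residuals, coords, n_lags = 12L,
                                   max_lag = NULL) {
  coords <- as.matrix(coords)
  n <- length(residuals)
  if (n < 30L) stop("need >= 30 points for a semivariogram")
  if (is.null(max_lag)) {
    max_lag <- sqrt(diff(range(coords[, 1]))^2 +
                      diff(range(coords[, 2]))^2) / 2
  }
  if (max_lag <= 0) stop("max_lag must be > 0")
  d <- as.vector(stats::dist(coords))
  # dist() enumerates (2,1),(3,1),...,(n,1),(3,2),...: i below is the
  # smaller index of each pair in that same order
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n))
  sq <- (residuals[i] - residuals[j])^2 / 2
  keep <- d <= max_lag & d > 0
  breaks <- seq(0, max_lag, length.out = n_lags + 1L)
  bin <- cut(d[keep], breaks = breaks, include.lowest = TRUE, labels = FALSE)
  gamma <- tapply(sq[keep], factor(bin, levels = seq_len(n_lags)), mean)
  npairs <- tapply(rep(1, sum(keep)), factor(bin, levels = seq_len(n_lags)),
                   sum)
  npairs[is.na(npairs)] <- 0
  data.frame(lag = (breaks[-1] + breaks[-length(breaks)]) / 2,
             gamma = as.numeric(gamma),
             n_pairs = as.integer(npairs))
}
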