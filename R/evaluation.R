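## Test statistics, empirical and binormal AUC, bootstrap uncertainty,
## and test-statistic SNR.

#' Bundle scores and labels
#'
#' @param scores Numeric test statistics, one per image.
#' @param labels Binary hypothesis indicator (0 = signal absent,
#'   1 = signal present).
#' @return A `score_set` object.
#' @export
score_set <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)),
            all(is.finite(scores)))
  structure(list(scores = as.numeric(scores), labels = as.numeric(labels)),
            class = "score_set")
}

#' Apply an observer to images
#'
#' Computes the linear test statistic `t(g) = w' g` for a
#' `linear_observer`, or `t(v) = w_v' T g` (projection through the
#' channels first) for a `channelized_observer`.
#'
#' @param observer A `linear_observer` or `channelized_observer`.
#' @param images Matrix of flattened images, one per row.
#' @param labels Optional binary labels; when given, a `score_set` is
#'   returned instead of a bare score vector.
#' @return Numeric scores, or a `score_set` when `labels` is supplied.
#' @export
apply_observer <- function(observer, images, labels = NULL) {
  if (is.null(dim(images))) images <- matrix(images, nrow = 1)
  if (inherits(observer, "linear_observer")) {
    stopifnot(ncol(images) == length(observer$template))
    sc <- drop(images %*% observer$template)
  } else if (inherits(observer, "channelized_observer")) {
    sc <- drop(channelize(observer$channels, images) %*% observer$w_v)
  } else {
    stop("unsupported observer type")
  }
  if (is.null(labels)) sc else score_set(sc, labels)
}

## Convenience: score a paired dataset (absent first, then present).
score_dataset <- function(observer, dataset) {
  s <- stack_pairs(dataset)
  apply_observer(observer, s$images, s$labels)
}

#' Empirical (Mann-Whitney) AUC
#'
#' Fraction of (signal-present, signal-absent) score pairs in which the
#' present score exceeds the absent score, ties counting one half.
#' Computed from ranks in `O(n log n)`.
#'
#' @param scores A `score_set` with both classes represented.
#' @return AUC in `[0, 1]`.
#' @examples
#' empirical_auc(score_set(c(0, 2, 1, 3), c(0, 0, 1, 1)))  # 0.75
#' @export
empirical_auc <- function(scores) {
  stopifnot(inherits(scores, "score_set"))
  n1 <- sum(scores$labels == 1)
  n0 <- sum(scores$labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores$scores, ties.method = "average")
  (sum(r[scores$labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Test-statistic signal-to-noise ratio
#'
#' `SNR = (mean_1 - mean_0) / sqrt(var_0 / 2 + var_1 / 2)` with
#' population (divisor n) class variances.
#'
#' @param scores A `score_set` with at least two scores per class.
#' @return The SNR value.
#' @export
snr <- function(scores) {
  stopifnot(inherits(scores, "score_set"))
  s0 <- scores$scores[scores$labels == 0]
  s1 <- scores$scores[scores$labels == 1]
  stopifnot(length(s0) >= 2, length(s1) >= 2)
  v0 <- mean((s0 - mean(s0))^2)
  v1 <- mean((s1 - mean(s1))^2)
  pooled <- (v0 + v1) / 2
  if (pooled == 0) stop("zero pooled score variance")
  (mean(s1) - mean(s0)) / sqrt(pooled)
}

#' Binormal ROC fit with bootstrap uncertainty
#'
#' Fits the binormal ROC model and reports the fitted AUC together with
#' the empirical AUC and a seeded nonparametric case-bootstrap standard
#' deviation of the fitted AUC.
#'
#' Two estimators are provided.  The default, `"latent"`, is the
#' classical rank-based binormal ROC model: it assumes some (unknown)
#' monotone transform of the scores is Gaussian within each class, fits
#' `qnorm(TPR) = a + b * qnorm(FPR)` to the empirical ROC points by least
#' squares, and reports `AUC = pnorm(a / sqrt(1 + b^2))`.  Being
#' rank-based, it is invariant to monotone transforms of the scores and
#' tracks the empirical AUC even for skewed score distributions.
#' `"moment"` instead fits Gaussians to the raw scores by (population)
#' moments, for which `AUC = pnorm((mu1 - mu0) / sqrt(s0^2 + s1^2))`
#' holds in closed form; it is exact when the raw scores really are
#' Gaussian but biased for skewed scores.
#'
#' @param scores A `score_set` with at least two scores per class.
#' @param bootstrap_reps Number of bootstrap resamples for `auc_sd`
#'   (0 skips the bootstrap).
#' @param seed Optional integer seed for the bootstrap.
#' @param method `"latent"` (rank-based, default) or `"moment"`.
#' @return A `roc_summary`: list with `auc_binormal`, `auc_empirical`,
#'   the binormal intercept/slope (`a`, `b`), raw-score moments (`mu0`,
#'   `mu1`, `sd0`, `sd1`), `auc_sd`, `method` and a `degenerate` flag.
#' @export
binormal_fit <- function(scores, bootstrap_reps = 1000, seed = NULL,
                         method = c("latent", "moment")) {
  method <- match.arg(method)
  stopifnot(inherits(scores, "score_set"))
  s0 <- scores$scores[scores$labels == 0]
  s1 <- scores$scores[scores$labels == 1]
  stopifnot(length(s0) >= 2, length(s1) >= 2)
  fit_fun <- if (method == "latent") latent_binormal else moment_binormal
  fit <- fit_fun(s0, s1)
  mom <- moment_binormal(s0, s1)
  auc_sd <- NA_real_
  if (bootstrap_reps > 0) {
    if (!is.null(seed)) set.seed(seed)
    reps <- vapply(seq_len(bootstrap_reps), function(i) {
      b0 <- s0[sample.int(length(s0), replace = TRUE)]
      b1 <- s1[sample.int(length(s1), replace = TRUE)]
      fit_fun(b0, b1)$auc
    }, numeric(1))
    auc_sd <- stats::sd(reps)
  }
  structure(list(auc_binormal = fit$auc,
                 auc_empirical = empirical_auc(scores),
                 mu0 = mom$mu0, mu1 = mom$mu1, sd0 = mom$sd0, sd1 = mom$sd1,
                 a = fit$a, b = fit$b, auc_sd = auc_sd, method = method,
                 degenerate = fit$degenerate),
            class = "roc_summary")
}

moment_binormal <- function(s0, s1) {
  mu0 <- mean(s0); mu1 <- mean(s1)
  # population (divisor n) moments, consistent with the SNR definition
  sd0 <- sqrt(mean((s0 - mu0)^2))
  sd1 <- sqrt(mean((s1 - mu1)^2))
  pooled <- sqrt(sd0^2 + sd1^2)
  degenerate <- FALSE
  if (pooled == 0) {
    degenerate <- TRUE
    auc <- 0.5
    a <- NA_real_; b <- NA_real_
  } else {
    auc <- stats::pnorm((mu1 - mu0) / pooled)
    a <- if (sd1 > 0) (mu1 - mu0) / sd1 else Inf
    b <- if (sd1 > 0) sd0 / sd1 else Inf
  }
  list(auc = auc, mu0 = mu0, mu1 = mu1, sd0 = sd0, sd1 = sd1,
       a = a, b = b, degenerate = degenerate)
}

## Rank-based (latent) binormal fit: probit-linear least squares through
## the interior empirical ROC points.  Falls back to the moment fit when
## the ROC has too few interior points (e.g. perfect separation).
latent_binormal <- function(s0, s1) {
  n0 <- length(s0); n1 <- length(s1)
  th <- sort(unique(c(s0, s1)))
  ss0 <- sort(s0); ss1 <- sort(s1)
  # P(s >= t): count of scores < t via findInterval on the open left
  fpr <- 1 - findInterval(th, ss0, left.open = TRUE) / n0
  tpr <- 1 - findInterval(th, ss1, left.open = TRUE) / n1
  keep <- fpr > 0 & fpr < 1 & tpr > 0 & tpr < 1
  zf <- stats::qnorm(fpr[keep])
  zt <- stats::qnorm(tpr[keep])
  if (length(unique(zf)) < 2) {
    out <- moment_binormal(s0, s1)
    out$degenerate <- TRUE
    return(out)
  }
  cf <- stats::coef(stats::lm.fit(cbind(1, zf), zt))
  a <- cf[[1]]; b <- cf[[2]]
  list(auc = stats::pnorm(a / sqrt(1 + b^2)), a = a, b = b,
       degenerate = FALSE)
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("roc_summary: AUC (binormal) = %.4f, AUC (empirical) = %.4f",
              x$auc_binormal, x$auc_empirical))
  if (is.finite(x$auc_sd)) cat(sprintf(" +/- %.4f", x$auc_sd))
  cat("\n")
  invisible(x)
}

#' Evaluate an observer on a paired test dataset
#'
#' Scores the test set and summarizes performance.
#'
#' @param observer A `linear_observer` or `channelized_observer`.
#' @param dataset A `paired_images` test split.
#' @param bootstrap_reps,seed,method Passed to [binormal_fit()].
#' @return A `roc_summary` (with `snr` attached).
#' @export
evaluate_observer <- function(observer, dataset, bootstrap_reps = 1000,
                              seed = NULL, method = "latent") {
  sc <- score_dataset(observer, dataset)
  out <- binormal_fit(sc, bootstrap_reps = bootstrap_reps, seed = seed,
                      method = method)
  out$snr <- snr(sc)
  out
}
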