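## Image-space Hotelling observers: first/second-order statistics,
## regularized pseudoinversion, HO-Direct and HO-CMD.

#' Estimate the mean signal difference
#'
#' Computes `delta_g = mean(present) - mean(absent)` over all pairs of a
#' dataset -- the empirical difference of the class-conditional means.
#'
#' @param dataset A `paired_images` object.
#' @return A `mean_signal` object: list with `delta_g` (length-N vector),
#'   `source` and `n_pairs_used`.
#' @export
estimate_mean_signal <- function(dataset) {
  stopifnot(inherits(dataset, "paired_images"), n_pairs(dataset) >= 1)
  dg <- colMeans(dataset$present) - colMeans(dataset$absent)
  structure(list(delta_g = dg, source = "estimated_from_subset",
                 n_pairs_used = n_pairs(dataset), grid = dataset$grid),
            class = "mean_signal")
}

#' Wrap a known signal image as a mean-signal estimate
#'
#' Used for the fixed-signal study variant, where the mean signal is
#' provided (e.g. estimated once at the maximum dataset size) rather than
#' re-estimated from each training subset.
#'
#' @param delta_g Length-N signal vector (or image matrix).
#' @param grid Grid as `c(rows, cols)`.
#' @return A `mean_signal` object with `source = "provided_fixed"`.
#' @export
fixed_mean_signal <- function(delta_g, grid = NULL) {
  if (is.matrix(delta_g)) {
    grid <- dim(delta_g)
    delta_g <- as.vector(delta_g)
  }
  stopifnot(all(is.finite(delta_g)))
  structure(list(delta_g = delta_g, source = "provided_fixed",
                 n_pairs_used = NA_integer_, grid = grid),
            class = "mean_signal")
}

#' Per-hypothesis empirical covariances
#'
#' Computes the empirical covariance of each class (divisor `n`, matching
#' the expectation definition) and their average `k_avg = (K0 + K1) / 2`.
#'
#' @param dataset A `paired_images` object with at least two pairs.
#' @return A `covariance_model`: list with `k0`, `k1`, `k_avg`.
#' @export
estimate_covariances <- function(dataset) {
  stopifnot(inherits(dataset, "paired_images"), n_pairs(dataset) >= 2)
  k0 <- class_covariance(dataset$absent)
  k1 <- class_covariance(dataset$present)
  structure(list(k0 = k0, k1 = k1, k_avg = (k0 + k1) / 2),
            class = "covariance_model")
}

## Empirical covariance with divisor n.
class_covariance <- function(x) {
  n <- nrow(x)
  xc <- sweep(x, 2, colMeans(x))
  crossprod(xc) / n
}

## Average-covariance fast path: accumulate one centered class at a
## time, never materializing K0/K1 or both centered copies at once.
average_covariance <- function(dataset) {
  n <- n_pairs(dataset)
  x <- sweep(dataset$absent, 2, colMeans(dataset$absent))
  k <- crossprod(x)
  x <- sweep(dataset$present, 2, colMeans(dataset$present))
  k <- k + crossprod(x)
  k / (2 * n)
}

#' Regularized Moore-Penrose pseudoinverse
#'
#' SVD-based pseudoinverse that discards singular values below
#' `rel_tol` times the largest singular value.
#'
#' @param m Square symmetric numeric matrix.
#' @param rel_tol Relative singular-value cutoff (default `1e-6`).
#' @return The pseudoinverse matrix.
#' @examples
#' regularized_pinv(diag(c(1, 1e-7)))  # second mode truncated
#' @export
regularized_pinv <- function(m, rel_tol = 1e-6) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), all(is.finite(m)))
  s <- svd(m)
  keep <- s$d > rel_tol * max(s$d)
  if (!any(keep)) {
    warning("all singular values truncated; returning zero pseudoinverse")
    return(matrix(0, nrow(m), ncol(m)))
  }
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

## Solve pinv(M) %*% b for symmetric M via eigendecomposition, truncating
## eigenvalues below rel_tol * max|eigenvalue|.  Avoids forming the N x N
## pseudoinverse for large covariance matrices.
pinv_solve_sym <- function(m, b, rel_tol = 1e-6) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  keep <- abs(e$values) > rel_tol * max(abs(e$values))
  if (!any(keep)) {
    warning("all eigenvalues truncated; returning zero solution")
    return(numeric(length(b)))
  }
  u <- e$vectors[, keep, drop = FALSE]
  drop(u %*% (crossprod(u, b) / e$values[keep]))
}

#' Directly estimated Hotelling observer
#'
#' Builds the image-space Hotelling template
#' `w = pinv((K0 + K1) / 2) %*% delta_g` from the empirical class
#' covariances of a dataset, using the truncated-SVD regularized
#' pseudoinverse.
#'
#' @param dataset A `paired_images` object providing the covariance
#'   estimate.
#' @param signal Optional `mean_signal`; estimated from `dataset` when
#'   omitted.
#' @param rel_tol Relative spectrum cutoff for the pseudoinverse.
#' @return A `linear_observer`: list with `template` and `method`.
#' @export
ho_direct <- function(dataset, signal = NULL, rel_tol = 1e-6) {
  stopifnot(inherits(dataset, "paired_images"), n_pairs(dataset) >= 2)
  if (is.null(signal)) signal <- estimate_mean_signal(dataset)
  k <- average_covariance(dataset)
  w <- pinv_solve_sym(k, signal$delta_g, rel_tol)
  structure(list(template = w, method = "ho_direct", grid = dataset$grid),
            class = "linear_observer")
}

#' Hotelling observer via covariance-matrix decomposition
#'
#' When noiseless imaged backgrounds are available and the measurement
#' noise covariance is known (i.i.d. Gaussian, `sd^2 * I`), the average
#' data covariance decomposes as `K_background + sd^2 * I`, and the
#' Hotelling template follows without estimating the noisy-image
#' covariance.  Only the Gaussian noise model is supported: the mixed
#' Poisson/Gaussian model (with its per-image rescaling) has no
#' closed-form noise covariance.
#'
#' @param noiseless_backgrounds Matrix of flattened noiseless background
#'   images (one per row).
#' @param noise A [noise_model()] of kind `"gaussian"`.
#' @param signal A `mean_signal` object.
#' @param rel_tol Relative spectrum cutoff for the pseudoinverse.
#' @return A `linear_observer` with `method = "ho_cmd"`.
#' @export
ho_cmd <- function(noiseless_backgrounds, noise, signal, rel_tol = 1e-6) {
  stopifnot(is.matrix(noiseless_backgrounds),
            inherits(noise, "noise_model"), inherits(signal, "mean_signal"))
  if (noise$kind != "gaussian")
    stop("ho_cmd requires the Gaussian noise model (known noise covariance)")
  kb <- class_covariance(noiseless_backgrounds)
  diag(kb) <- diag(kb) + noise$sd^2
  w <- pinv_solve_sym(kb, signal$delta_g, rel_tol)
  structure(list(template = w, method = "ho_cmd", grid = NULL),
            class = "linear_observer")
}

#' @export
print.linear_observer <- function(x, ...) {
  cat("linear_observer (", x$method, "), template length ",
      length(x$template), "\n", sep = "")
  invisible(x)
}
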