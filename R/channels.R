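## Reference channel families (Laguerre-Gauss, convolutional LG, PLS),
## the nonprewhitening matched filter, and CHO construction.

new_channel_matrix <- function(basis, method, params = list()) {
  stopifnot(is.matrix(basis), all(is.finite(basis)))
  if (any(colSums(abs(basis)) == 0)) stop("channel matrix has a zero column")
  structure(list(basis = basis, method = method, params = params),
            class = "channel_matrix")
}

#' @export
print.channel_matrix <- function(x, ...) {
  cat("channel_matrix (", x$method, "): ", ncol(x$basis), " channels of ",
      nrow(x$basis), " pixels\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.channel_matrix <- function(x, ...) x$basis

## Laguerre polynomials L_0..L_{k} at x, by the three-term recurrence.
laguerre_eval <- function(x, k_max) {
  out <- matrix(0, length(x), k_max + 1)
  out[, 1] <- 1
  if (k_max >= 1) out[, 2] <- 1 - x
  if (k_max >= 2) {
    for (k in 1:(k_max - 1)) {
      out[, k + 2] <- ((2 * k + 1 - x) * out[, k + 1] - k * out[, k]) / (k + 1)
    }
  }
  out
}

#' Laguerre-Gauss channels
#'
#' Rotationally symmetric channels
#' `u_j(r) = exp(-pi r^2 / a^2) * L_j(2 pi r^2 / a^2)` evaluated on the
#' pixel grid about `center` and normalized to unit Euclidean norm, where
#' `L_j` is the j-th Laguerre polynomial.
#'
#' @param n_channels Number of channels (1..20 in study configurations).
#' @param width Gaussian width parameter `a` in pixels.
#' @param grid Grid as `c(rows, cols)`.
#' @param center Channel centre in pixel coordinates (x, y).
#' @return A `channel_matrix` whose columns are the channels.
#' @examples
#' ch <- lg_channels(5, width = 25)
#' dim(as.matrix(ch))
#' @export
lg_channels <- function(n_channels, width, grid = c(64, 64),
                        center = c(32, 32)) {
  stopifnot(n_channels >= 1, n_channels <= prod(grid), width > 0)
  xs <- seq_len(grid[2]) - 1
  ys <- seq_len(grid[1]) - 1
  r2 <- outer((ys - center[2])^2, (xs - center[1])^2, "+")
  z <- 2 * pi * as.vector(r2) / width^2
  basis <- exp(-z / 2) * laguerre_eval(z, n_channels - 1)
  nrm <- sqrt(colSums(basis^2))
  if (any(nrm < 1e-12))
    stop("LG width too small: channels alias to near-zero vectors")
  basis <- sweep(basis, 2, nrm, "/")
  new_channel_matrix(basis, "lg",
                     list(width = width, grid = grid, center = center))
}

## 2-D 'same'-size linear convolution via zero-padded FFT.  The output is
## anchored so that a kernel consisting of a unit impulse at (0-based)
## index floor(dim/2) acts as the identity.
conv2_same <- function(x, k) {
  nr <- nrow(x) + nrow(k) - 1
  nc <- ncol(x) + ncol(k) - 1
  xp <- matrix(0, nr, nc); xp[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  kp <- matrix(0, nr, nc); kp[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  full <- Re(stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE)) /
    (nr * nc)
  r0 <- floor(nrow(k) / 2)
  c0 <- floor(ncol(k) / 2)
  full[r0 + seq_len(nrow(x)), c0 + seq_len(ncol(x))]
}

#' Convolutional Laguerre-Gauss (filtered channel observer) channels
#'
#' Convolves each baseline LG channel with the (estimated) mean-signal
#' image ('same'-size 2-D convolution) and renormalizes to unit norm,
#' yielding signal-adapted channels.
#'
#' @param base A `channel_matrix` of LG channels.
#' @param signal A `mean_signal` whose `delta_g` reshapes to the channel
#'   grid.
#' @return A `channel_matrix` with `method = "conv_lg"`.
#' @export
conv_lg_channels <- function(base, signal) {
  stopifnot(inherits(base, "channel_matrix"), inherits(signal, "mean_signal"))
  grid <- base$params$grid
  stopifnot(length(signal$delta_g) == prod(grid))
  sig <- matrix(signal$delta_g, grid[1], grid[2])
  if (all(sig == 0)) stop("zero signal image yields degenerate channels")
  basis <- apply(base$basis, 2, function(u)
    as.vector(conv2_same(matrix(u, grid[1], grid[2]), sig)))
  nrm <- sqrt(colSums(basis^2))
  if (any(nrm < 1e-12)) stop("degenerate convolved channel")
  basis <- sweep(basis, 2, nrm, "/")
  new_channel_matrix(basis, "conv_lg", base$params)
}

#' Partial-least-squares channels
#'
#' NIPALS-style PLS on column-centred images `X` and the centred binary
#' label vector: each component's weight vector is `X' y` (normalized),
#' after which `X` is deflated by the regression on the component scores.
#' The label vector is not deflated; both variants share the first
#' component.  The unit-norm weight vectors are returned as channels.
#'
#' @param images Matrix of flattened images, one per row.
#' @param labels Binary (0/1) label per image.
#' @param n_channels Number of latent components (capped at 20 in study
#'   configurations).
#' @return A `channel_matrix` with `method = "pls"`.
#' @export
pls_channels <- function(images, labels, n_channels) {
  stopifnot(is.matrix(images), length(labels) == nrow(images),
            all(labels %in% c(0, 1)), n_channels >= 1)
  x <- sweep(images, 2, colMeans(images))
  y <- labels - mean(labels)
  if (all(x == 0) || all(y == 0)) stop("zero-variance input")
  basis <- matrix(0, ncol(images), n_channels)
  for (k in seq_len(n_channels)) {
    w <- drop(crossprod(x, y))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("PLS deflation exhausted the label covariance at ",
                         k - 1, " components")
    w <- w / nw
    tt <- drop(x %*% w)
    p <- drop(crossprod(x, tt)) / sum(tt^2)
    x <- x - tcrossprod(tt, p)
    basis[, k] <- w
  }
  new_channel_matrix(basis, "pls", list(n_channels = n_channels))
}

#' Nonprewhitening matched filter
#'
#' The linear observer whose template is the mean signal difference
#' itself, with no covariance whitening.
#'
#' @param signal A `mean_signal` object with non-zero `delta_g`.
#' @return A `linear_observer` with `method = "npwmf"`.
#' @export
npwmf_observer <- function(signal) {
  stopifnot(inherits(signal, "mean_signal"))
  if (all(signal$delta_g == 0)) stop("zero mean signal")
  structure(list(template = signal$delta_g, method = "npwmf",
                 grid = signal$grid),
            class = "linear_observer")
}

#' Project images into channel space
#'
#' Computes `v = T g` for every image, where the rows of `T` are the
#' transposed channel columns; with images stored one per row this is
#' `images %*% basis`, giving an `n x M` matrix of channel outputs.
#'
#' @param channels A `channel_matrix`.
#' @param images Matrix of flattened images (one per row) or a single
#'   image vector.
#' @return `n x M` matrix of channelized data.
#' @export
channelize <- function(channels, images) {
  stopifnot(inherits(channels, "channel_matrix"))
  if (is.null(dim(images))) images <- matrix(images, nrow = 1)
  if (ncol(images) != nrow(channels$basis))
    stop("image length does not match channel dimension")
  images %*% channels$basis
}

#' Build a channelized Hotelling observer
#'
#' Channelizes the covariance dataset, forms the channel-space average
#' covariance `Kv = (Kv0 + Kv1) / 2` (divisor n) and mean signal
#' `delta_v = T delta_g`, and solves `Kv w_v = delta_v` directly, falling
#' back to the regularized pseudoinverse when `Kv` is ill-conditioned.
#'
#' @param channels A `channel_matrix`.
#' @param covariance_dataset A `paired_images` object held out for the
#'   channel-covariance estimate (disjoint from channel training data in
#'   the study protocol).
#' @param signal A `mean_signal` object.
#' @param cond_tol Condition-number threshold beyond which the
#'   pseudoinverse fallback is used.
#' @param pinv_fallback Allow the pseudoinverse fallback (error when
#'   disabled and `Kv` is singular).
#' @return A `channelized_observer`: list with `channels`, `w_v`, `k_v`,
#'   `delta_v`.
#' @export
cho_build <- function(channels, covariance_dataset, signal,
                      cond_tol = 1e12, pinv_fallback = TRUE) {
  stopifnot(inherits(channels, "channel_matrix"),
            inherits(covariance_dataset, "paired_images"),
            inherits(signal, "mean_signal"))
  v0 <- channelize(channels, covariance_dataset$absent)
  v1 <- channelize(channels, covariance_dataset$present)
  kv <- (class_covariance(v0) + class_covariance(v1)) / 2
  delta_v <- drop(crossprod(channels$basis, signal$delta_g))
  rc <- tryCatch(rcond(kv), error = function(e) 0)
  if (is.finite(rc) && rc > 1 / cond_tol) {
    w_v <- drop(solve(kv, delta_v))
  } else if (pinv_fallback) {
    w_v <- pinv_solve_sym(kv, delta_v)
  } else {
    stop("singular channel covariance and pseudoinverse fallback disabled")
  }
  structure(list(channels = channels, w_v = w_v, k_v = kv,
                 delta_v = delta_v),
            class = "channelized_observer")
}

#' @export
print.channelized_observer <- function(x, ...) {
  cat("channelized_observer:", ncol(x$channels$basis), "channels (",
      x$channels$method, ")\n")
  invisible(x)
}

#' Grid-search a convolutional-LG observer
#'
#' Builds LG bases over a grid of widths, convolves each with the mean
#' signal, and selects the LG width and channel count (nested prefixes of
#' the basis) that maximize empirical AUC on the validation set; the
#' returned observer uses the held-out covariance split.
#'
#' @param train_signal A `mean_signal` (estimated from training data).
#' @param validation_dataset,covariance_dataset `paired_images` splits.
#' @param widths Candidate LG widths in pixels.
#' @param max_channels Maximum channel count (capped at 20).
#' @param center Channel centre (defaults to the signal centre
#'   convention, pixel (32, 32) on a 64 x 64 grid).
#' @return List with the selected `observer`, `width`, `n_channels`, and
#'   the search `leaderboard` data frame.
#' @export
conv_lg_search <- function(train_signal, validation_dataset,
                           covariance_dataset,
                           widths = c(10, 15, 20, 25, 30, 40, 50),
                           max_channels = 10, center = c(32, 32)) {
  stopifnot(max_channels >= 1, max_channels <= 20)
  grid <- validation_dataset$grid
  sv <- stack_pairs(validation_dataset)
  best <- NULL
  rows <- list()
  for (a in widths) {
    base <- lg_channels(max_channels, a, grid, center)
    ch <- conv_lg_channels(base, train_signal)
    vv <- channelize(ch, sv$images)
    for (m in seq_len(max_channels)) {
      chm <- new_channel_matrix(ch$basis[, seq_len(m), drop = FALSE],
                                "conv_lg", c(ch$params, n_channels = m))
      obs <- cho_build(chm, covariance_dataset, train_signal)
      sc <- drop(vv[, seq_len(m), drop = FALSE] %*% obs$w_v)
      auc <- empirical_auc(score_set(sc, sv$labels))
      rows[[length(rows) + 1]] <-
        data.frame(width = a, n_channels = m, val_auc = auc)
      if (is.null(best) || auc > best$val_auc)
        best <- list(observer = obs, width = a, n_channels = m, val_auc = auc)
    }
  }
  best$leaderboard <- do.call(rbind, rows)
  best
}
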