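# Small in-code fixtures shared across the unit tests.

# Wrap raw image matrices as a paired_images object.
wrap_pairs <- function(absent, present, grid = NULL, angles = NULL) {
  if (is.null(grid)) grid <- c(1, ncol(absent))
  structure(list(absent = absent, present = present,
                 grid = as.integer(grid),
                 angles = if (is.null(angles)) rep(NA_real_, nrow(absent))
                 else angles,
                 params = list(), seed = NULL, source = NULL,
                 noiseless_backgrounds = NULL),
            class = "paired_images")
}

# Correlated multivariate-normal toy pairs: absent ~ N(0, K),
# present ~ N(delta, K).
gauss_pairs <- function(n, delta, k_chol, seed = 1) {
  set.seed(seed)
  N <- length(delta)
  z0 <- matrix(rnorm(n * N), n, N) %*% k_chol
  z1 <- matrix(rnorm(n * N), n, N) %*% k_chol
  wrap_pairs(z0, sweep(z1, 2, delta, "+"))
}

# A random symmetric positive-definite matrix.
random_spd <- function(N, seed = 1) {
  set.seed(seed)
  a <- matrix(rnorm(N * N), N, N)
  crossprod(a) / N + diag(N)
}

# Tiny lumpy-task dataset on a small grid (fast unit-test scale).
tiny_lumpy_dataset <- function(n, width = 1, grid = c(16, 16), seed = 1,
                               noise = noise_model("gaussian", sd = 2),
                               signal = elliptical_signal(
                                 amplitude = 0.2, width_x = 2, width_y = 1,
                                 center = c(8, 8))) {
  generate_paired_dataset(n, lumpy_background(mean_lumps = 3, width = 3),
                          signal, imaging_system(40, width, grid), noise,
                          seed = seed)
}
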