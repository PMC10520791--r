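test_that("constructors reject invalid parameters", {
  expect_error(lumpy_background(mean_lumps = -1))
  expect_error(lumpy_background(amplitude = 0))
  expect_error(imaging_system(width = 0))
  expect_error(elliptical_signal(amplitude = -0.2))
  expect_error(noise_model("gaussian", sd = -1))
  expect_error(noise_model("gaussian", rescale = TRUE))
})

test_that("lump count is Poisson with the configured mean", {
  bg0 <- lumpy_background(mean_lumps = 0)
  set.seed(1)
  for (i in 1:5)
    expect_equal(nrow(sample_lumpy_scene(bg0)$components), 0)

  set.seed(42)
  counts <- replicate(10000, nrow(sample_lumpy_scene(lumpy_background())$components))
  expect_lt(abs(mean(counts) - 5), 3 * sqrt(5 / 10000))

  # chi-square goodness of fit against the Poisson(5) pmf
  set.seed(7)
  counts <- replicate(20000, nrow(sample_lumpy_scene(lumpy_background())$components))
  breaks <- 0:12
  obs <- tabulate(pmin(counts, 12) + 1, nbins = 13)
  p <- dpois(breaks, 5); p[13] <- 1 - ppois(11, 5)
  stat <- sum((obs - 20000 * p)^2 / (20000 * p))
  expect_lt(stat, qchisq(0.99, df = 12))

  # centers fall in the continuous field of view
  set.seed(3)
  sc <- sample_lumpy_scene(lumpy_background(mean_lumps = 50), grid = c(16, 32))
  expect_true(all(sc$components$x >= 0 & sc$components$x < 32))
  expect_true(all(sc$components$y >= 0 & sc$components$y < 16))
})

# Object-space evaluation of a Gaussian-mixture scene (test oracle).
eval_scene <- function(scene, xs, ys) {
  out <- matrix(0, length(ys), length(xs))
  for (l in seq_len(nrow(scene$components))) {
    cm <- scene$components[l, ]
    S <- matrix(c(cm$cov_xx, cm$cov_xy, cm$cov_xy, cm$cov_yy), 2, 2)
    Q <- solve(S)
    dx <- xs - cm$x; dy <- ys - cm$y
    out <- out + cm$amplitude *
      exp(-0.5 * (outer(dy^2 * Q[2, 2], dx^2 * Q[1, 1], "+") +
                    2 * Q[1, 2] * outer(dy, dx)))
  }
  out
}

test_that("rotated signal component matches the direct rotated-Gaussian formula", {
  sig <- elliptical_signal(angles = c(0, 45, 90, 135))
  xs <- 0:63; ys <- 0:63
  # direct evaluation of A * exp(-(R d)' D^-1 (R d)) at 45 degrees
  th <- 45 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Dinv <- diag(1 / (2 * c(sig$width_x^2, sig$width_y^2)))
  direct <- outer(ys, xs, Vectorize(function(y, x) {
    d <- R %*% (c(x, y) - sig$center)
    sig$amplitude * exp(-drop(t(d) %*% Dinv %*% d))
  }))
  comp <- signal_component(sig, 45)
  expect_equal(eval_scene(comp, xs, ys), direct, tolerance = 1e-12)
  # peak value at the centre is the amplitude
  expect_equal(eval_scene(comp, sig$center[1], sig$center[2])[1, 1],
               sig$amplitude, tolerance = 1e-12)
})

test_that("90-degree rotation exchanges the signal axis widths", {
  sys <- imaging_system(40, 0.5)
  a <- apply_imaging_operator(
    signal_component(elliptical_signal(angles = 90), 90), sys)
  b <- apply_imaging_operator(
    signal_component(elliptical_signal(width_x = 1.5, width_y = 5), 0), sys)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("imaging operator matches the Gaussian-Gaussian closed form and quadrature", {
  sys <- imaging_system(40, 0.5)
  centred <- structure(list(components = data.frame(
    x = 32, y = 32, amplitude = 1, cov_xx = 49, cov_xy = 0, cov_yy = 49,
    tag = "background"), grid = c(64L, 64L)), class = "object_scene")
  # peak pixel value a * h * s^2 / (s^2 + w^2)
  expect_equal(max(apply_imaging_operator(centred, sys)), 40 * 49 / 49.25,
               tolerance = 1e-12)
  lump <- structure(list(components = data.frame(
    x = 31.3, y = 33.7, amplitude = 1, cov_xx = 49, cov_xy = 0, cov_yy = 49,
    tag = "background"), grid = c(64L, 64L)), class = "object_scene")
  img <- apply_imaging_operator(lump, sys)
  skip_if_not_installed("pracma")
  psf <- function(x, y, mx, my) sys$height / (2 * pi * sys$width^2) *
    exp(-((x - mx)^2 + (y - my)^2) / (2 * sys$width^2))
  obj <- function(x, y) exp(-((x - 31.3)^2 + (y - 33.7)^2) / (2 * 49))
  for (px in list(c(31, 34), c(20, 40))) {
    # the narrow PSF confines the integrand to a small window about the
    # pixel; 96-node Gauss-Legendre resolves it to machine accuracy
    q <- pracma::quad2d(function(x, y) psf(x, y, px[1], px[2]) * obj(x, y),
                        px[1] - 8, px[1] + 8, px[2] - 8, px[2] + 8, n = 96)
    expect_equal(img[px[2] + 1, px[1] + 1], q, tolerance = 1e-6)
  }
})

test_that("imaging is linear and the empty scene maps to zero", {
  sys <- imaging_system(40, 1)
  empty <- structure(list(components = taskobs:::empty_components(),
                          grid = c(64L, 64L)), class = "object_scene")
  expect_equal(apply_imaging_operator(empty, sys), matrix(0, 64, 64))
  set.seed(5)
  s1 <- sample_lumpy_scene(lumpy_background())
  s2 <- sample_lumpy_scene(lumpy_background())
  both <- combine_scenes(s1, s2)
  expect_equal(apply_imaging_operator(both, sys),
               apply_imaging_operator(s1, sys) + apply_imaging_operator(s2, sys),
               tolerance = 1e-12)
})

test_that("closed-form blur agrees with discrete FFT convolution of a rasterized scene", {
  sys <- imaging_system(40, 2)
  set.seed(11)
  scene <- sample_lumpy_scene(lumpy_background(mean_lumps = 8))
  closed <- apply_imaging_operator(scene, sys)
  # rasterize object and PSF on a 4x-oversampled periodic grid
  os <- 4
  n <- 64 * os
  coords <- (0:(n - 1)) / os
  obj <- eval_scene(scene, coords, coords)
  d <- pmin(coords, 64 - coords)  # circular distance for the kernel
  psf <- sys$height / (2 * pi * sys$width^2) *
    exp(-outer(d^2, d^2, "+") / (2 * sys$width^2)) / os^2
  conv <- Re(fft(fft(obj) * fft(psf), inverse = TRUE)) / n^2
  disc <- conv[seq(1, n, by = os), seq(1, n, by = os)]
  interior <- 17:48
  expect_lt(max(abs((disc - closed) / closed)[interior, interior]), 1e-3)
})

test_that("noise models have the stated moments and ranges", {
  img <- matrix(rnorm(64), 4, 16)
  expect_identical(add_noise(img, noise_model("gaussian", sd = 0)), img)

  # mixed model: Var[Poisson(c) + N(0,1)] = c + 1
  cval <- 30
  const <- matrix(cval, 25, 4096)
  noisy <- add_noise(const, noise_model("poisson_gaussian", rescale = FALSE),
                     seed = 2)
  expect_lt(abs(var(as.vector(noisy)) / (cval + 1) - 1), 0.05)

  scaled <- add_noise(const + matrix(rnorm(25 * 4096), 25),
                      noise_model("poisson_gaussian"), seed = 3)
  expect_equal(apply(scaled, 1, min), rep(0, 25))
  expect_equal(apply(scaled, 1, max), rep(1, 25))
})

test_that("paired dataset generation honours its contracts", {
  bg <- lumpy_background(); sys <- imaging_system(40, 0.5)
  sks <- elliptical_signal(angles = c(0, 45, 90, 135))
  ds <- generate_paired_dataset(10, bg, sks, sys, noise_model("gaussian"),
                                seed = 9)
  expect_equal(dim(ds$absent), c(10, 4096))
  expect_equal(dim(ds$present), c(10, 4096))
  expect_true(all(ds$angles %in% c(0, 45, 90, 135)))

  # identical seeds give bit-identical datasets
  ds2 <- generate_paired_dataset(10, bg, sks, sys, noise_model("gaussian"),
                                 seed = 9)
  expect_identical(ds, ds2)

  # with noise disabled and the background scenes mirrored across the two
  # hypotheses, the class-mean difference is exactly the mean noiseless
  # imaged signal over the realized angles (linearity of the mean)
  set.seed(10)
  half <- replicate(20, sample_lumpy_scene(bg), simplify = FALSE)
  clean <- generate_paired_dataset(20, bg, sks, sys,
                                   noise_model("gaussian", sd = 0), seed = 10,
                                   scenes = c(half, half))
  expected <- Reduce(`+`, lapply(clean$angles, function(a)
    as.vector(apply_imaging_operator(signal_component(sks, a), sys)))) / 20
  expect_equal(colMeans(clean$present) - colMeans(clean$absent), expected,
               tolerance = 1e-10)
})

test_that("amalgamation draws evenly and without replacement", {
  mk <- function(seed) tiny_lumpy_dataset(12, seed = seed)
  sets <- list(mk(1), mk(2), mk(3))
  am <- amalgamate(sets, 30, seed = 4)
  expect_equal(n_pairs(am), 30)
  expect_equal(as.vector(table(am$source)), c(10, 10, 10))
  # no pair appears twice (exact row scan)
  key <- apply(cbind(am$absent, am$present), 1, paste, collapse = ",")
  expect_equal(anyDuplicated(key), 0L)
  # a single source yields a without-replacement subsample
  one <- amalgamate(sets[1], 8, seed = 5)
  expect_equal(n_pairs(one), 8)
  in_src <- apply(one$absent, 1, function(r)
    any(colSums(abs(t(sets[[1]]$absent) - r)) == 0))
  expect_true(all(in_src))
  expect_error(amalgamate(sets, 60))
})
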