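## Coordinate convention used throughout:
##   * images are R x C matrices; pixel (i, j) sits at continuous
##     coordinates (x = j - 1, y = i - 1), i.e. pixel centres lie on the
##     integer lattice 0..C-1 x 0..R-1;
##   * lump centres are sampled uniformly over the continuous rectangle
##     [0, C) x [0, R) (no wrap-around; lumps near the border are simply
##     truncated by the field of view);
##   * flattened images are column-major (R's native as.vector order) and
##     datasets store one flattened image per row.

#' Lumpy background parameters
#'
#' Parameters of the stochastic lumpy object model: a Poisson-distributed
#' number of isotropic Gaussian blobs ("lumps") dropped uniformly at random
#' over the field of view.
#'
#' @param mean_lumps Expected number of lumps per scene (Poisson mean).
#' @param amplitude Peak amplitude of each lump (intensity units).
#' @param width Lump width `s` in pixels; each lump is
#'   `amplitude * exp(-|r - r_n|^2 / (2 * width^2))`.
#' @return An object of class `lumpy_background`.
#' @examples
#' bg <- lumpy_background()
#' bg$mean_lumps
#' @export
lumpy_background <- function(mean_lumps = 5, amplitude = 1, width = 7) {
  stopifnot(is.finite(mean_lumps), mean_lumps >= 0,
            is.finite(amplitude), amplitude > 0,
            is.finite(width), width > 0)
  structure(list(mean_lumps = mean_lumps, amplitude = amplitude,
                 width = width),
            class = "lumpy_background")
}

#' Stylized imaging system
#'
#' An idealized parallel-hole-collimator system whose point response at
#' pixel `m` is `h / (2 pi w^2) * exp(-|r - r_m|^2 / (2 w^2))`, a
#' continuous-to-discrete Gaussian blur with gain `height` and width
#' `width` (pixels).
#'
#' @param height PSF gain `h`.
#' @param width PSF width `w` in pixels.
#' @param grid Image grid as `c(rows, cols)`.
#' @return An object of class `imaging_system`.
#' @examples
#' sys <- imaging_system(height = 40, width = 0.5)
#' @export
imaging_system <- function(height = 40, width = 0.5, grid = c(64, 64)) {
  stopifnot(is.finite(height), height > 0, is.finite(width), width > 0,
            length(grid) == 2, all(grid >= 1))
  structure(list(height = height, width = width, grid = as.integer(grid)),
            class = "imaging_system")
}

#' Elliptical Gaussian signal parameters
#'
#' A rotated anisotropic Gaussian signal
#' `f_s(r) = A exp(-(R_theta (r - r_c))' D^-1 (R_theta (r - r_c)))` with
#' `D = diag(2 sx^2, 2 sy^2)`, so the per-axis standard deviations in the
#' rotated frame are `width_x` and `width_y`.
#'
#' @param amplitude Peak amplitude `A`.
#' @param width_x,width_y Axis widths `sx`, `sy` in pixels.
#' @param angles Rotation angles in degrees that the signal may take.  A
#'   single angle gives a location-known task; several (e.g.
#'   `c(0, 45, 90, 135)`) give a fixed-centroid signal-known-statistically
#'   task with the angle drawn uniformly per signal-present image.
#' @param center Signal centre `r_c` in pixel coordinates (x, y).
#' @return An object of class `elliptical_signal`.
#' @examples
#' sig <- elliptical_signal()
#' sks <- elliptical_signal(angles = c(0, 45, 90, 135))
#' @export
elliptical_signal <- function(amplitude = 0.2, width_x = 5, width_y = 1.5,
                              angles = 0, center = c(32, 32)) {
  stopifnot(is.finite(amplitude), amplitude > 0,
            is.finite(width_x), width_x > 0, is.finite(width_y), width_y > 0,
            length(angles) >= 1, all(is.finite(angles)),
            length(center) == 2, all(is.finite(center)))
  structure(list(amplitude = amplitude, width_x = width_x, width_y = width_y,
                 angles = angles, center = center),
            class = "elliptical_signal")
}

#' Measurement noise model
#'
#' Either i.i.d. Gaussian noise of standard deviation `sd` per pixel, or a
#' mixed Poisson/Gaussian model in which each pixel value `g_m` is replaced
#' by `Poisson(g_m) + N(0, sd^2)` (with `sd = 1` by default), optionally
#' followed by a per-image affine rescaling to `[0, 1]`.
#'
#' @param kind `"gaussian"` or `"poisson_gaussian"`.
#' @param sd Standard deviation of the Gaussian component.  Defaults to 20
#'   for the pure Gaussian model and to 1 for the mixed model.
#' @param rescale Rescale each noisy image to `[0, 1]` (min-max, per
#'   image).  Only available for the mixed model, where it is the default.
#' @return An object of class `noise_model`.
#' @examples
#' noise_model("gaussian")
#' noise_model("poisson_gaussian")
#' @export
noise_model <- function(kind = c("gaussian", "poisson_gaussian"),
                        sd = NULL, rescale = NULL) {
  kind <- match.arg(kind)
  if (is.null(sd)) sd <- if (kind == "gaussian") 20 else 1
  if (is.null(rescale)) rescale <- kind == "poisson_gaussian"
  stopifnot(is.finite(sd), sd >= 0)
  if (rescale && kind != "poisson_gaussian")
    stop("rescaling to [0, 1] is defined only for the mixed Poisson/Gaussian model")
  structure(list(kind = kind, sd = sd, rescale = rescale),
            class = "noise_model")
}

new_object_scene <- function(components, grid) {
  structure(list(components = components, grid = as.integer(grid)),
            class = "object_scene")
}

empty_components <- function() {
  data.frame(x = numeric(0), y = numeric(0), amplitude = numeric(0),
             cov_xx = numeric(0), cov_xy = numeric(0), cov_yy = numeric(0),
             tag = character(0), stringsAsFactors = FALSE)
}

#' Sample a lumpy background scene
#'
#' Draws the number of lumps from `Poisson(mean_lumps)` and their centres
#' i.i.d. uniformly over the continuous field of view.  Each lump is an
#' isotropic Gaussian component with the configured amplitude and
#' covariance `width^2 * I`.
#'
#' Uses R's global random number generator; call [set.seed()] (or pass
#' `seed`) for reproducibility.
#'
#' @param background A [lumpy_background()] object.
#' @param grid Field-of-view grid as `c(rows, cols)`.
#' @param seed Optional integer seed applied before sampling.
#' @return An `object_scene`: a list with a `components` data frame
#'   (columns `x`, `y`, `amplitude`, `cov_xx`, `cov_xy`, `cov_yy`, `tag`)
#'   and the `grid`.
#' @examples
#' scene <- sample_lumpy_scene(lumpy_background(), seed = 1)
#' nrow(scene$components)
#' @export
sample_lumpy_scene <- function(background, grid = c(64, 64), seed = NULL) {
  stopifnot(inherits(background, "lumpy_background"))
  if (!is.null(seed)) set.seed(seed)
  n_lumps <- stats::rpois(1, background$mean_lumps)
  if (n_lumps == 0) return(new_object_scene(empty_components(), grid))
  # x spans columns, y spans rows
  x <- stats::runif(n_lumps, 0, grid[2])
  y <- stats::runif(n_lumps, 0, grid[1])
  comps <- data.frame(x = x, y = y, amplitude = background$amplitude,
                      cov_xx = background$width^2, cov_xy = 0,
                      cov_yy = background$width^2, tag = "background",
                      stringsAsFactors = FALSE)
  new_object_scene(comps, grid)
}

#' Elliptical signal as a Gaussian scene component
#'
#' Converts the rotated elliptical signal at a given angle into a single
#' anisotropic Gaussian component with peak amplitude `A` and covariance
#' `R_theta' diag(sx^2, sy^2) R_theta`.
#'
#' @param signal An [elliptical_signal()] object.
#' @param angle Rotation angle in degrees; must be one of `signal$angles`.
#' @param grid Grid as `c(rows, cols)`.
#' @return An `object_scene` holding the single signal component.
#' @examples
#' comp <- signal_component(elliptical_signal(), angle = 0)
#' @export
signal_component <- function(signal, angle = signal$angles[1],
                             grid = c(64, 64)) {
  stopifnot(inherits(signal, "elliptical_signal"))
  if (!any(abs(angle - signal$angles) < 1e-12))
    stop("angle must be one of the configured signal angles")
  th <- angle * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)  # R_theta
  S <- t(R) %*% diag(c(signal$width_x^2, signal$width_y^2)) %*% R
  comps <- data.frame(x = signal$center[1], y = signal$center[2],
                      amplitude = signal$amplitude,
                      cov_xx = S[1, 1], cov_xy = S[1, 2], cov_yy = S[2, 2],
                      tag = "signal", stringsAsFactors = FALSE)
  new_object_scene(comps, grid)
}

#' Combine two scenes
#'
#' @param scene,other `object_scene`s on the same grid.
#' @return An `object_scene` with the concatenated components.
#' @export
combine_scenes <- function(scene, other) {
  stopifnot(inherits(scene, "object_scene"), inherits(other, "object_scene"),
            all(scene$grid == other$grid))
  new_object_scene(rbind(scene$components, other$components), scene$grid)
}

#' Image a scene through the stylized system
#'
#' Evaluates the continuous-to-discrete Gaussian-blur imaging operator in
#' closed form.  A Gaussian component with amplitude `a` and covariance
#' `S` contributes, at pixel location `r_m`,
#' `a * h * sqrt(det S / det(S + w^2 I)) * exp(-(r_m - r_n)' (S + w^2 I)^-1
#' (r_m - r_n) / 2)` -- the Gaussian-Gaussian convolution integral of the
#' point response against the component.
#'
#' @param scene An `object_scene`.
#' @param system An [imaging_system()] whose grid matches the scene's.
#' @return The noiseless image as a `rows x cols` numeric matrix.
#' @examples
#' img <- apply_imaging_operator(signal_component(elliptical_signal()),
#'                               imaging_system())
#' max(img)
#' @export
apply_imaging_operator <- function(scene, system) {
  stopifnot(inherits(scene, "object_scene"), inherits(system, "imaging_system"),
            all(scene$grid == system$grid))
  comps <- scene$components
  if (!all(is.finite(as.matrix(comps[, 1:6]))))
    stop("scene contains non-finite components")
  render_components(comps, system)
}

## Closed-form rendering of Gaussian components; diagonal-covariance
## components are rendered with separable 1-D factors and a single BLAS
## call, general components individually.
render_components <- function(comps, system) {
  rows <- system$grid[1]; cols <- system$grid[2]
  img <- matrix(0, rows, cols)
  if (nrow(comps) == 0) return(img)
  xs <- seq_len(cols) - 1
  ys <- seq_len(rows) - 1
  w2 <- system$width^2
  h <- system$height
  diag_idx <- comps$cov_xy == 0
  if (any(diag_idx)) {
    d <- comps[diag_idx, , drop = FALSE]
    bxx <- d$cov_xx + w2
    byy <- d$cov_yy + w2
    amp <- d$amplitude * h * sqrt(d$cov_xx * d$cov_yy / (bxx * byy))
    # Ex[l, j] = exp(-(xs[j] - x_l)^2 / (2 bxx_l)); image += t(Ey)' Ex
    Ex <- exp(-(outer(d$x, xs, "-"))^2 / (2 * bxx))
    Ey <- exp(-(outer(d$y, ys, "-"))^2 / (2 * byy)) * amp
    img <- img + crossprod(Ey, Ex)
  }
  if (any(!diag_idx)) {
    g <- comps[!diag_idx, , drop = FALSE]
    for (l in seq_len(nrow(g))) {
      S <- matrix(c(g$cov_xx[l], g$cov_xy[l], g$cov_xy[l], g$cov_yy[l]), 2, 2)
      B <- S + w2 * diag(2)
      Q <- solve(B)
      amp <- g$amplitude[l] * h * sqrt(det(S) / det(B))
      dx <- xs - g$x[l]
      dy <- ys - g$y[l]
      quad <- outer(dy^2 * Q[2, 2], dx^2 * Q[1, 1], "+") +
        2 * Q[1, 2] * outer(dy, dx)
      img <- img + amp * exp(-0.5 * quad)
    }
  }
  img
}

#' Add measurement noise to images
#'
#' For the Gaussian model, adds i.i.d. `N(0, sd^2)` noise per pixel.  For
#' the mixed model, each pixel `g_m` (clamped at zero) is replaced by a
#' `Poisson(g_m)` draw plus `N(0, sd^2)` noise, and each image is then
#' optionally min-max rescaled to `[0, 1]`.
#'
#' @param images Numeric matrix with one flattened image per row (a single
#'   image may be passed as a vector).
#' @param noise A [noise_model()] object.
#' @param seed Optional integer seed.
#' @return Noisy images, same shape as the input.
#' @examples
#' img <- matrix(10, 2, 16)
#' noisy <- add_noise(img, noise_model("gaussian", sd = 1), seed = 1)
#' @export
add_noise <- function(images, noise, seed = NULL) {
  stopifnot(inherits(noise, "noise_model"))
  if (!is.null(seed)) set.seed(seed)
  vec_in <- is.null(dim(images))
  x <- if (vec_in) matrix(images, nrow = 1) else images
  x <- t(noise_cols(t(x), noise))
  if (vec_in) drop(x) else x
}

## Noise core on column-per-image matrices (pixels x images).
noise_cols <- function(x, noise) {
  if (noise$kind == "gaussian") {
    if (noise$sd > 0)
      x <- x + matrix(stats::rnorm(length(x), sd = noise$sd),
                      nrow(x), ncol(x))
  } else {
    x <- matrix(as.numeric(stats::rpois(length(x), pmax(x, 0))),
                nrow(x), ncol(x))
    if (noise$sd > 0)
      x <- x + matrix(stats::rnorm(length(x), sd = noise$sd),
                      nrow(x), ncol(x))
    if (noise$rescale) {
      r <- apply(x, 2, range)
      span <- r[2, ] - r[1, ]
      span[span == 0] <- 1
      x <- (x - rep(r[1, ], each = nrow(x))) / rep(span, each = nrow(x))
    }
  }
  x
}

#' Generate a paired signal-present/signal-absent dataset
#'
#' Draws `2 * n_pairs` independent lumpy background scenes, images them
#' through the system, adds the noiseless imaged signal to half of them
#' (the signal angle is drawn uniformly from `signal$angles` per
#' signal-present image), and finally applies measurement noise to every
#' image.  The signal is added before noise, consistent with
#' `g = H(f_b + f_s) + n`.
#'
#' @param n_pairs Number of image pairs.
#' @param background A [lumpy_background()].
#' @param signal An [elliptical_signal()], or `NULL` for background-only
#'   pairs.
#' @param system An [imaging_system()].
#' @param noise A [noise_model()].
#' @param seed Optional integer seed governing scenes, angles and noise.
#' @param scenes Optional list of `2 * n_pairs` pre-sampled background
#'   scenes (used, e.g., to share backgrounds across imaging systems in
#'   domain-shift studies).  Scenes `1..n_pairs` become the signal-absent
#'   images, the rest the signal-present ones.
#' @param angles Optional vector of per-pair signal angles (overrides the
#'   uniform draw).
#' @param keep_noiseless Also store the `2 * n_pairs x N` noiseless imaged
#'   backgrounds (needed by the covariance-matrix-decomposition Hotelling
#'   estimate).
#' @return A `paired_images` object: list with `absent` and `present`
#'   (`n_pairs x N` matrices of flattened images), `grid`, `angles`,
#'   parameter records and the seed.
#' @examples
#' ds <- generate_paired_dataset(5, lumpy_background(), elliptical_signal(),
#'                               imaging_system(), noise_model("gaussian"),
#'                               seed = 1)
#' dim(ds$absent)
#' @export
generate_paired_dataset <- function(n_pairs, background, signal, system,
                                    noise, seed = NULL, scenes = NULL,
                                    angles = NULL, keep_noiseless = FALSE) {
  stopifnot(n_pairs >= 1)
  if (!is.null(seed)) set.seed(seed)
  grid <- system$grid
  N <- prod(grid)
  if (is.null(scenes)) {
    scenes <- replicate(2 * n_pairs, sample_lumpy_scene(background, grid),
                        simplify = FALSE)
  } else {
    stopifnot(length(scenes) == 2 * n_pairs)
  }
  # render into an N x 2n buffer (contiguous column writes), transpose once
  timgs <- matrix(0, N, 2 * n_pairs)
  for (i in seq_along(scenes))
    timgs[, i] <- render_components(scenes[[i]]$components, system)
  noiseless <- if (keep_noiseless) t(timgs) else NULL
  if (!is.null(signal)) {
    if (is.null(angles)) {
      angles <- if (length(signal$angles) == 1L)
        rep(signal$angles, n_pairs)
      else
        sample(signal$angles, n_pairs, replace = TRUE)
    }
    stopifnot(length(angles) == n_pairs)
    uang <- unique(angles)
    for (a in uang) {
      sig_img <- as.vector(apply_imaging_operator(
        signal_component(signal, a, grid), system))
      sel <- n_pairs + which(angles == a)
      timgs[, sel] <- timgs[, sel, drop = FALSE] + sig_img
    }
  } else {
    angles <- rep(NA_real_, n_pairs)
  }
  # apply noise in column blocks to bound temporary allocations
  block <- 512L
  for (start in seq(1L, 2L * n_pairs, by = block)) {
    idx <- start:min(start + block - 1L, 2L * n_pairs)
    timgs[, idx] <- noise_cols(timgs[, idx, drop = FALSE], noise)
  }
  absent <- t(timgs[, seq_len(n_pairs), drop = FALSE])
  present <- t(timgs[, n_pairs + seq_len(n_pairs), drop = FALSE])
  rm(timgs)
  structure(list(absent = absent,
                 present = present,
                 grid = grid, angles = angles,
                 params = list(background = background, signal = signal,
                               system = system, noise = noise),
                 seed = seed, source = NULL,
                 noiseless_backgrounds = noiseless),
            class = "paired_images")
}

#' @export
print.paired_images <- function(x, ...) {
  cat("paired_images:", nrow(x$absent), "pairs of",
      paste(x$grid, collapse = "x"), "images\n")
  if (!is.null(x$params$noise))
    cat("  noise:", x$params$noise$kind,
        if (x$params$noise$rescale) "(rescaled to [0,1])" else "", "\n")
  invisible(x)
}

#' Number of image pairs in a dataset
#' @param dataset A `paired_images` object.
#' @return Integer pair count.
#' @export
n_pairs <- function(dataset) nrow(dataset$absent)

#' Subset a paired dataset by pair index
#'
#' @param dataset A `paired_images` object.
#' @param idx Pair indices to keep.
#' @return A `paired_images` object with the selected pairs.
#' @export
subset_pairs <- function(dataset, idx) {
  stopifnot(all(idx >= 1), all(idx <= n_pairs(dataset)))
  out <- dataset
  out$absent <- dataset$absent[idx, , drop = FALSE]
  out$present <- dataset$present[idx, , drop = FALSE]
  out$angles <- dataset$angles[idx]
  if (!is.null(dataset$source)) out$source <- dataset$source[idx]
  out
}

#' Stack a paired dataset into images and labels
#'
#' @param dataset A `paired_images` object.
#' @return List with `images` (absent rows first, then present) and
#'   binary `labels` (0 = absent, 1 = present).
#' @export
stack_pairs <- function(dataset) {
  list(images = rbind(dataset$absent, dataset$present),
       labels = rep(c(0, 1), each = n_pairs(dataset)))
}

#' Amalgamate several paired datasets
#'
#' Draws an equal number of pairs from each source dataset without
#' replacement and concatenates them, recording the source index of every
#' pair.  Used to build the amalgamated source of the generalization
#' studies; train/validation/test separation is preserved by amalgamating
#' each split separately.
#'
#' @param datasets List of `paired_images` objects on a common grid.
#' @param n_pairs_out Total number of pairs to draw (must be divisible by
#'   the number of sources).
#' @param seed Optional integer seed for the without-replacement draws.
#' @return A `paired_images` object with a `source` vector.
#' @export
amalgamate <- function(datasets, n_pairs_out, seed = NULL) {
  stopifnot(length(datasets) >= 1, n_pairs_out >= 1)
  k <- length(datasets)
  if (n_pairs_out %% k != 0)
    stop("n_pairs_out must be divisible by the number of source datasets")
  per <- n_pairs_out %/% k
  grid <- datasets[[1]]$grid
  for (d in datasets) {
    stopifnot(all(d$grid == grid))
    if (n_pairs(d) < per)
      stop("a source dataset has fewer than ", per, " pairs")
  }
  if (!is.null(seed)) set.seed(seed)
  picks <- lapply(datasets, function(d) sort(sample.int(n_pairs(d), per)))
  absent <- do.call(rbind, Map(function(d, ix) d$absent[ix, , drop = FALSE],
                               datasets, picks))
  present <- do.call(rbind, Map(function(d, ix) d$present[ix, , drop = FALSE],
                                datasets, picks))
  angles <- unlist(Map(function(d, ix) d$angles[ix], datasets, picks))
  structure(list(absent = absent, present = present, grid = grid,
                 angles = angles,
                 params = list(sources = lapply(datasets, `[[`, "params")),
                 seed = seed,
                 source = rep(seq_len(k), each = per)),
            class = "paired_images")
}
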