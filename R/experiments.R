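## Config-driven study runners: dataset-size sweeps (standard and
## fixed-signal variants), the domain-shift and amalgamation
## generalization studies.

#' Study configuration
#'
#' Collects the dataset sizes, object/system/noise models, method list
#' and hyperparameter grids for a study run.  Defaults reproduce the
#' lumpy-background study conditions; pass smaller sizes for desk-scale
#' runs.
#'
#' @param kind One of `"size_sweep"`, `"domain_shift"`.
#' @param n_train,n_validation,n_cov,n_test Split sizes in pairs.  The
#'   channel-covariance split is dedicated (the lumpy protocol); in the
#'   domain-shift study the validation split doubles as the covariance
#'   split when `n_cov` is 0.
#' @param sizes Training-subset sizes for size sweeps.
#' @param methods Subset of `c("ho_direct", "ho_cmd", "conv_lg", "pls",
#'   "npwmf", "ae_task", "ae_conventional")`.
#' @param background,signal,noise Object models (see
#'   [lumpy_background()], [elliptical_signal()], [noise_model()]).
#' @param system_height PSF gain.
#' @param system_width PSF width for size sweeps.
#' @param widths Source-system PSF widths for the domain-shift study.
#' @param fixed_signal Use a single mean-signal estimate from the
#'   maximum-size training + validation data for every subset size
#'   (the fixed-signal study variant).
#' @param lg Conv-LG grid: list with `widths`, `max_channels`.
#' @param ae AE grid: list with `channel_counts`, `learning_rates`,
#'   `epochs`, `batch_size`, `train_pairs` (optional cap on pairs used
#'   for AE training), `burn_in`.
#' @param pls_max_channels Channel-count cap for the PLS sweep.
#' @param bootstrap_reps Bootstrap replicates for test-set AUC errors.
#' @param seed Master seed; all per-stage seeds derive from it.
#' @return A `study_config` object.
#' @export
study_config <- function(kind = c("size_sweep", "domain_shift"),
                         n_train = 30000, n_validation = 5000,
                         n_cov = 5000, n_test = 5000,
                         sizes = NULL,
                         methods = c("ho_direct", "conv_lg", "pls",
                                     "npwmf", "ae_task"),
                         background = lumpy_background(),
                         signal = elliptical_signal(),
                         noise = NULL,
                         system_height = 40,
                         system_width = 0.5,
                         widths = c(1, 2, 4),
                         fixed_signal = FALSE,
                         lg = list(widths = c(10, 15, 20, 25, 30, 40, 50),
                                   max_channels = 10),
                         ae = list(channel_counts = c(10, 20),
                                   learning_rates = NULL,
                                   epochs = 500, batch_size = 250,
                                   train_pairs = NULL, burn_in = FALSE),
                         pls_max_channels = 20,
                         bootstrap_reps = 200,
                         seed = 1) {
  kind <- match.arg(kind)
  if (is.null(noise))
    noise <- if (kind == "domain_shift") noise_model("poisson_gaussian")
    else noise_model("gaussian")
  if (is.null(sizes)) sizes <- n_train
  stopifnot(all(sizes >= 1), max(sizes) <= n_train, length(methods) >= 1)
  structure(list(kind = kind, n_train = n_train,
                 n_validation = n_validation, n_cov = n_cov,
                 n_test = n_test, sizes = sizes, methods = methods,
                 background = background, signal = signal, noise = noise,
                 system_height = system_height, system_width = system_width,
                 widths = widths, fixed_signal = fixed_signal,
                 lg = lg, ae = ae, pls_max_channels = pls_max_channels,
                 bootstrap_reps = bootstrap_reps, seed = seed),
            class = "study_config")
}

## Derived seeds stay well below 2^31 (double arithmetic avoids integer
## overflow for large master seeds).
derive_seed <- function(seed, k)
  as.integer((as.numeric(seed) * 1009 + as.numeric(k)) %% 2000000011)

make_scenes <- function(n_images, background, grid, seed) {
  set.seed(seed)
  replicate(n_images, sample_lumpy_scene(background, grid), simplify = FALSE)
}

default_ae_lr <- function(noise) {
  ## Empirically stated study rate for the Gaussian-noise lumpy study;
  ## unit-rescaled images train at the larger rate used for unit-scaled
  ## data, with the grid spanning both regimes.
  if (noise$kind == "gaussian" && !noise$rescale) 1e-5 else 5e-3
}

## Train one method on a source (train/validation/cov splits + signal)
## and return an observer.
fit_method <- function(method, splits, signal, config) {
  ae_cfg <- config$ae
  if (is.null(ae_cfg$learning_rates))
    ae_cfg$learning_rates <- default_ae_lr(config$noise)
  cov_split <- if (!is.null(splits$cov)) splits$cov else splits$validation
  switch(method,
    ho_direct = ho_direct(splits$train, signal),
    ho_cmd = {
      if (is.null(splits$noiseless_backgrounds))
        stop("ho_cmd requires noiseless background images")
      ho_cmd(splits$noiseless_backgrounds, config$noise, signal)
    },
    npwmf = npwmf_observer(signal),
    conv_lg = conv_lg_search(signal, splits$validation, cov_split,
                             widths = config$lg$widths,
                             max_channels = config$lg$max_channels,
                             center = config$signal$center)$observer,
    pls = {
      st <- stack_pairs(splits$train)
      ch <- pls_channels(st$images, st$labels, config$pls_max_channels)
      sv <- stack_pairs(splits$validation)
      vv <- channelize(ch, sv$images)
      best <- NULL
      for (m in seq_len(config$pls_max_channels)) {
        chm <- new_channel_matrix(ch$basis[, seq_len(m), drop = FALSE], "pls")
        obs <- cho_build(chm, cov_split, signal)
        auc <- empirical_auc(score_set(
          drop(vv[, seq_len(m), drop = FALSE] %*% obs$w_v), sv$labels))
        if (is.null(best) || auc > best$auc) best <- list(obs = obs, auc = auc)
      }
      best$obs
    },
    ae_task = ,
    ae_conventional = {
      loss_kind <- if (method == "ae_task") "task" else "conventional"
      tr <- splits$train
      if (!is.null(ae_cfg$train_pairs) && ae_cfg$train_pairs < n_pairs(tr)) {
        # random subset keeps amalgamated sources evenly mixed
        set.seed(derive_seed(config$seed, 778L))
        tr <- subset_pairs(tr, sort(sample.int(n_pairs(tr),
                                               ae_cfg$train_pairs)))
      }
      cfg <- ae_train_config(learning_rate = ae_cfg$learning_rates[1],
                             epochs = ae_cfg$epochs,
                             batch_size = ae_cfg$batch_size,
                             burn_in = isTRUE(ae_cfg$burn_in),
                             seed = derive_seed(config$seed, 777L))
      ae_grid_search(tr, splits$validation, cov_split, signal,
                     channel_counts = ae_cfg$channel_counts,
                     learning_rates = ae_cfg$learning_rates,
                     loss_kind = loss_kind, config = cfg)$observer
    },
    stop("unknown method: ", method)
  )
}

#' Run a dataset-size sweep
#'
#' For each training-subset size, estimates the mean signal (from the
#' subset, or fixed from the maximum-size estimate in the fixed-signal
#' variant), fits every configured method, and evaluates test-set AUC.
#' The channel covariance always comes from the dedicated held-out split.
#'
#' @param config A [study_config()] of kind `"size_sweep"`.
#' @return List with `results` (one row per method x size) and the
#'   fitted `observers`.
#' @export
run_size_sweep <- function(config) {
  stopifnot(inherits(config, "study_config"), config$kind == "size_sweep")
  grid <- c(64, 64)
  sys <- imaging_system(config$system_height, config$system_width, grid)
  keep_clean <- "ho_cmd" %in% config$methods
  gen <- function(n, k) generate_paired_dataset(
    n, config$background, config$signal, sys, config$noise,
    seed = derive_seed(config$seed, k), keep_noiseless = keep_clean)
  train_full <- gen(config$n_train, 1L)
  validation <- gen(config$n_validation, 2L)
  cov_split <- gen(config$n_cov, 3L)
  test <- gen(config$n_test, 4L)
  fixed_sig <- NULL
  if (config$fixed_signal) {
    dg <- (colMeans(train_full$present) * n_pairs(train_full) +
             colMeans(validation$present) * n_pairs(validation) -
             colMeans(train_full$absent) * n_pairs(train_full) -
             colMeans(validation$absent) * n_pairs(validation)) /
      (n_pairs(train_full) + n_pairs(validation))
    fixed_sig <- fixed_mean_signal(dg, grid)
  }
  rows <- list()
  observers <- list()
  for (k in config$sizes) {
    tr <- subset_pairs(train_full, seq_len(k))
    signal <- if (config$fixed_signal) fixed_sig else estimate_mean_signal(tr)
    splits <- list(train = tr, validation = validation, cov = cov_split)
    if (keep_clean)
      splits$noiseless_backgrounds <-
        rbind(train_full$noiseless_backgrounds, validation$noiseless_backgrounds)
    for (method in config$methods) {
      obs <- fit_method(method, splits, signal, config)
      res <- evaluate_observer(obs, test,
                               bootstrap_reps = config$bootstrap_reps,
                               seed = derive_seed(config$seed, 90L))
      rows[[length(rows) + 1]] <- data.frame(
        method = method, n_pairs = k,
        auc_binormal = res$auc_binormal, auc_empirical = res$auc_empirical,
        auc_sd = res$auc_sd, snr = res$snr)
      observers[[paste(method, k, sep = "_")]] <- obs
    }
  }
  list(results = do.call(rbind, rows), observers = observers,
       config = config)
}

#' Run the domain-shift and amalgamation study
#'
#' Builds one dataset per source-system PSF width over a shared stream of
#' background scenes (the same background scenes feed every width), plus
#' an amalgamated source evenly sampled without replacement from the
#' width datasets split-by-split.  Every configured method is trained on
#' every source and each trained observer is evaluated, frozen, on every
#' target width's test split.
#'
#' @param config A [study_config()] of kind `"domain_shift"`.
#' @param cells Optional data frame with columns `source` and `method`
#'   restricting which (source, method) observers are fitted; defaults to
#'   the full grid.  Sources are `as.character(width)` or `"amalg"`.
#' @param targets Target widths to evaluate on (default: all).
#' @param include_amalg Build and use the amalgamated source.
#' @param lean Free each source's training images as soon as its
#'   observers are fitted (the amalgamated source is then assembled from
#'   pre-drawn even contributions).  Keeps the peak memory footprint to
#'   roughly one training split; the returned `datasets` then hold only
#'   validation and test splits.
#' @return List with `results` (one row per source x method x target),
#'   `observers`, `signals` (per-source mean-signal estimates) and
#'   `datasets` (per-width splits, for reuse).
#' @export
run_domain_shift <- function(config, cells = NULL, targets = NULL,
                             include_amalg = TRUE, lean = FALSE) {
  stopifnot(inherits(config, "study_config"), config$kind == "domain_shift")
  grid <- c(64, 64)
  widths <- config$widths
  k <- length(widths)
  if (is.null(targets)) targets <- widths
  sources <- c(as.character(widths), if (include_amalg) "amalg")
  if (is.null(cells))
    cells <- expand.grid(source = sources, method = config$methods,
                         stringsAsFactors = FALSE)
  cells$source <- as.character(cells$source)
  cells$method <- as.character(cells$method)
  stopifnot(all(cells$source %in% sources))

  scen_train <- make_scenes(2 * config$n_train, config$background, grid,
                            derive_seed(config$seed, 11L))
  scen_val <- make_scenes(2 * config$n_validation, config$background, grid,
                          derive_seed(config$seed, 12L))
  scen_test <- make_scenes(2 * config$n_test, config$background, grid,
                           derive_seed(config$seed, 13L))

  observers <- list()
  datasets <- list()
  signals <- list()
  amalg_parts <- list()
  n_amalg <- config$n_train - config$n_train %% k

  fit_source <- function(src, splits) {
    want <- cells$method[cells$source == src]
    if (length(want) == 0) return()
    signal <- estimate_mean_signal(splits$train)
    signals[[src]] <<- signal
    for (method in want) {
      obs <- fit_method(method, splits, signal, config)
      observers[[paste(src, method, sep = "_")]] <<- obs
    }
  }

  for (i in seq_along(widths)) {
    w <- widths[i]
    wk <- as.character(w)
    sys <- imaging_system(config$system_height, w, grid)
    splits <- list(
      train = generate_paired_dataset(
        config$n_train, config$background, config$signal, sys, config$noise,
        seed = derive_seed(config$seed, 20L + i), scenes = scen_train),
      validation = generate_paired_dataset(
        config$n_validation, config$background, config$signal, sys,
        config$noise, seed = derive_seed(config$seed, 40L + i),
        scenes = scen_val),
      test = generate_paired_dataset(
        config$n_test, config$background, config$signal, sys, config$noise,
        seed = derive_seed(config$seed, 60L + i), scenes = scen_test))
    fit_source(wk, splits)
    if (include_amalg) {
      # even without-replacement contribution to the amalgamated source
      set.seed(derive_seed(config$seed, 70L + i))
      amalg_parts[[wk]] <- subset_pairs(
        splits$train, sort(sample.int(config$n_train, n_amalg %/% k)))
    }
    if (lean) splits$train <- NULL
    datasets[[wk]] <- splits
    rm(splits)
    if (lean) gc(FALSE)
  }

  if (include_amalg) {
    amalg <- list(
      train = amalgamate(amalg_parts, n_amalg,
                         seed = derive_seed(config$seed, 81L)),
      validation = amalgamate(lapply(datasets, `[[`, "validation"),
                              config$n_validation -
                                config$n_validation %% k,
                              seed = derive_seed(config$seed, 82L)),
      test = amalgamate(lapply(datasets, `[[`, "test"),
                        config$n_test - config$n_test %% k,
                        seed = derive_seed(config$seed, 83L)))
    rm(amalg_parts)
    fit_source("amalg", amalg)
    if (lean) amalg$train <- NULL
    datasets$amalg <- amalg
    if (lean) gc(FALSE)
  }

  rows <- list()
  for (r in seq_len(nrow(cells))) {
    src <- cells$source[r]
    method <- cells$method[r]
    obs <- observers[[paste(src, method, sep = "_")]]
    for (tw in targets) {
      res <- evaluate_observer(obs, datasets[[as.character(tw)]]$test,
                               bootstrap_reps = config$bootstrap_reps,
                               seed = derive_seed(config$seed, 91L))
      rows[[length(rows) + 1]] <- data.frame(
        source = src, method = method, target = tw,
        n_pairs = config$n_train,
        auc_binormal = res$auc_binormal, auc_empirical = res$auc_empirical,
        auc_sd = res$auc_sd, snr = res$snr)
    }
  }
  list(results = do.call(rbind, rows), observers = observers,
       signals = signals, datasets = datasets, config = config)
}

#' Audit that study splits are disjoint
#'
#' Checks that no image row is duplicated across the given datasets
#' (up to exact equality), as the train / covariance / test protocol
#' requires.
#'
#' @param datasets List of `paired_images` objects.
#' @return `TRUE` invisibly; errors if an overlap is found.
#' @export
audit_disjoint <- function(datasets) {
  keys <- unlist(lapply(datasets, function(d) {
    apply(cbind(d$absent[, 1:4, drop = FALSE], d$present[, 1:4, drop = FALSE]),
          1, paste, collapse = ",")
  }))
  if (anyDuplicated(keys))
    stop("split audit failed: identical image pairs found in two splits")
  invisible(TRUE)
}
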