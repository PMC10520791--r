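## Tied-weight linear autoencoder channel learning: conventional and
## task-informed losses, Adam trainer, model selection, channel ablation.

#' Autoencoder training configuration
#'
#' Hyperparameters of the tied-weight linear autoencoder trainer.  The
#' defaults follow the study protocol: Adam with a small learning rate,
#' 500 epochs, balanced mini-batches of 250 images, and a truncated-normal
#' weight initializer with standard deviation `5e-6` (truncated at plus or
#' minus two standard deviations).
#'
#' @param learning_rate Adam step size (`1e-5` in the Gaussian-noise lumpy
#'   study; `5e-3` for unit-scaled images).
#' @param epochs Number of passes over the training data.
#' @param batch_size Mini-batch size; each batch holds `batch_size / 2`
#'   signal-present and `batch_size / 2` signal-absent images.
#' @param init_sd Standard deviation of the truncated-normal initializer.
#' @param burn_in Optionally pre-train on a fixed 500-image subset for
#'   `burn_in_epochs` before the main phase (Adam moments are reset when
#'   the main phase starts).
#' @param burn_in_images,burn_in_epochs Burn-in subset size and length.
#' @param beta1,beta2,epsilon Adam moment decays and stabilizer.
#' @param seed Integer seed; the trainer is fully deterministic given the
#'   seed, configuration and data.
#' @return An `ae_train_config` object.
#' @export
ae_train_config <- function(learning_rate = 1e-5, epochs = 500,
                            batch_size = 250, init_sd = 5e-6,
                            burn_in = FALSE, burn_in_images = 500,
                            burn_in_epochs = 500,
                            beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                            seed = 1) {
  stopifnot(learning_rate > 0, epochs >= 0, batch_size >= 2,
            batch_size %% 2 == 0, init_sd > 0)
  structure(list(learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, init_sd = init_sd,
                 burn_in = burn_in, burn_in_images = burn_in_images,
                 burn_in_epochs = burn_in_epochs,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 seed = seed),
            class = "ae_train_config")
}

#' Autoencoder loss specification
#'
#' The conventional loss reconstructs the input image; the task-informed
#' loss replaces the reconstruction target with `I(signal present) *
#' delta_g`, so the embedding spends its entire capacity on
#' signal-relevant structure.
#'
#' @param kind `"task"` or `"conventional"`.
#' @param signal A `mean_signal` (required, and non-zero, for the task
#'   loss).
#' @return An `ae_loss_spec` object.
#' @export
ae_loss_spec <- function(kind = c("task", "conventional"), signal = NULL) {
  kind <- match.arg(kind)
  if (kind == "task") {
    if (is.null(signal) || all(signal$delta_g == 0))
      stop("the task-informed loss requires a non-zero mean-signal target")
  }
  structure(list(kind = kind, signal = signal), class = "ae_loss_spec")
}

## Truncated normal (+/- 2 sd) initializer via inverse-CDF sampling.
truncnorm_init <- function(n_pixels, n_channels, sd) {
  lo <- stats::pnorm(-2); hi <- stats::pnorm(2)
  u <- stats::runif(n_pixels * n_channels, lo, hi)
  matrix(stats::qnorm(u) * sd, n_pixels, n_channels)
}

## Batch targets for a weight-free loss/gradient evaluation.
ae_targets <- function(images, labels, loss) {
  if (loss$kind == "conventional") images
  else outer(labels, loss$signal$delta_g)
}

#' Autoencoder reconstruction loss
#'
#' Mean over the batch of the squared Euclidean error between the tied
#' reconstruction `W W' g` and the target (`g` for the conventional loss,
#' `I(g) * delta_g` for the task-informed loss).
#'
#' @param weights `N x M` weight matrix `W` (or a `tied_linear_ae`).
#' @param images Batch of flattened images, one per row.
#' @param labels Binary labels of the batch.
#' @param loss An [ae_loss_spec()].
#' @return Scalar loss value.
#' @export
ae_loss <- function(weights, images, labels, loss) {
  if (inherits(weights, "tied_linear_ae")) weights <- weights$weights
  if (is.null(dim(images))) images <- matrix(images, nrow = 1)
  stopifnot(ncol(images) == nrow(weights), length(labels) == nrow(images))
  tt <- ae_targets(images, labels, loss)
  v <- images %*% weights
  r <- tcrossprod(v, weights) - tt
  sum(r^2) / nrow(images)
}

## Analytic loss and gradient of the tied reconstruction objective
## (reference form, used as the oracle for the fast trainer path).
## d/dW (1/P) sum_i ||g_i W W' - t_i||^2 = (2/P) (G' R W + R' G W).
ae_loss_grad <- function(weights, images, targets) {
  p <- nrow(images)
  v <- images %*% weights
  r <- tcrossprod(v, weights) - targets
  grad <- (crossprod(images, r %*% weights) + crossprod(r, v)) * (2 / p)
  list(loss = sum(r^2) / p, grad = grad)
}

## Fast batch step on column-major batches (images as N x P).  Expanding
## the residual R = V W' - T keeps every intermediate N x M or smaller:
##   grad = (2/P) [ (G V) (W'W) + W (V'V) - (G'T)' terms ],
## where for the conventional loss T = G' (so G'T W = G V), and for the
## task loss T = y delta_g' is rank one.  Verified against ae_loss_grad.
ae_batch_grad <- function(weights, g_cols, labels, delta_g = NULL) {
  p <- ncol(g_cols)
  v <- crossprod(g_cols, weights)        # P x M scores
  gv <- g_cols %*% v                     # N x M
  wtw <- crossprod(weights)
  vtv <- crossprod(v)
  if (is.null(delta_g)) {                # conventional: target is the input
    grad <- (gv %*% wtw + weights %*% vtv - 2 * gv) * (2 / p)
    loss <- (sum(wtw * vtv) - 2 * sum(diag(vtv)) + sum(g_cols^2)) / p
  } else {                               # task: target y * delta_g'
    pres <- labels == 1
    a <- rowSums(g_cols[, pres, drop = FALSE])   # G y
    bw <- drop(crossprod(weights, delta_g))      # W' delta_g
    yv <- colSums(v[pres, , drop = FALSE])       # V' y
    grad <- (gv %*% wtw + weights %*% vtv -
               tcrossprod(a, bw) - tcrossprod(delta_g, yv)) * (2 / p)
    loss <- (sum(wtw * vtv) - 2 * sum(bw * yv) +
               sum(pres) * sum(delta_g^2)) / p
  }
  list(loss = loss, grad = grad)
}

#' Train a tied-weight linear autoencoder
#'
#' Minimizes the conventional or task-informed reconstruction loss with
#' Adam over balanced mini-batches (equal numbers of signal-present and
#' signal-absent images per batch, re-shuffled each epoch).  Weights are
#' initialized truncated-normal and the per-epoch mean training loss is
#' recorded.  Fully deterministic given `config$seed`.
#'
#' @param train_dataset A `paired_images` training split.
#' @param n_channels Embedding dimension `M` (the channel count).
#' @param loss An [ae_loss_spec()].
#' @param config An [ae_train_config()].
#' @param backend `"compiled"` runs the mini-batch loop in C++;
#'   `"reference"` runs the pure-R path.  Both share the analytic
#'   gradient and agree at numerical tolerance (a tested property); the
#'   compiled path is the default.
#' @return A `tied_linear_ae`: list with `weights` (`N x M`), `config`,
#'   `loss_spec` kind, `n_channels` and `loss_trace`.
#' @export
train_ae <- function(train_dataset, n_channels, loss, config,
                     backend = c("compiled", "reference")) {
  backend <- match.arg(backend)
  stopifnot(inherits(train_dataset, "paired_images"),
            inherits(loss, "ae_loss_spec"),
            inherits(config, "ae_train_config"),
            n_channels >= 1)
  n <- n_pairs(train_dataset)
  half <- config$batch_size / 2
  if (n < half) stop("dataset too small for one balanced mini-batch")
  set.seed(config$seed)
  N <- ncol(train_dataset$absent)
  w <- truncnorm_init(N, n_channels, config$init_sd)
  if (config$epochs == 0) {
    return(structure(list(weights = w, config = config,
                          loss_spec = loss$kind, n_channels = n_channels,
                          loss_trace = numeric(0)),
                     class = "tied_linear_ae"))
  }
  dg <- if (loss$kind == "task") loss$signal$delta_g else NULL
  # column-major image stores make the per-batch gathers contiguous
  tabs <- t(train_dataset$absent)
  tpres <- t(train_dataset$present)
  batch_labels <- rep(c(0, 1), each = half)
  run_phase <- function(w, tabs, tpres, epochs) {
    np <- ncol(tabs)
    if (backend == "compiled") {
      # epoch permutations come from R's RNG, drawn in the same
      # interleaved order as the reference loop
      perms <- lapply(seq_len(epochs), function(i)
        list(sample.int(np), sample.int(np)))
      p0 <- vapply(perms, `[[`, integer(np), 1)
      p1 <- vapply(perms, `[[`, integer(np), 2)
      out <- .ae_train_loop(tabs, tpres, w, p0, p1,
                            if (is.null(dg)) numeric(0) else dg,
                            as.integer(half), config$learning_rate,
                            config$beta1, config$beta2, config$epsilon)
      return(list(weights = out$weights, trace = drop(out$trace)))
    }
    nb <- np %/% half
    m <- matrix(0, N, n_channels)
    v <- matrix(0, N, n_channels)
    step <- 0
    trace <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      p0 <- sample.int(np)
      p1 <- sample.int(np)
      ep_loss <- 0
      for (b in seq_len(nb)) {
        i0 <- p0[(b - 1) * half + seq_len(half)]
        i1 <- p1[(b - 1) * half + seq_len(half)]
        gb <- cbind(tabs[, i0, drop = FALSE], tpres[, i1, drop = FALSE])
        lg <- ae_batch_grad(w, gb, batch_labels, dg)
        if (!is.finite(lg$loss))
          stop("training diverged (non-finite loss) at epoch ", ep)
        step <- step + 1
        m <- config$beta1 * m + (1 - config$beta1) * lg$grad
        v <- config$beta2 * v + (1 - config$beta2) * lg$grad^2
        mhat <- m / (1 - config$beta1^step)
        vhat <- v / (1 - config$beta2^step)
        w <- w - config$learning_rate * mhat / (sqrt(vhat) + config$epsilon)
        ep_loss <- ep_loss + lg$loss
      }
      trace[ep] <- ep_loss / nb
    }
    list(weights = w, trace = trace)
  }
  burn_trace <- numeric(0)
  if (config$burn_in && 2 * n > config$burn_in_images) {
    bp <- max(half, min(n, config$burn_in_images %/% 2))
    sel <- sample.int(n, bp)
    ph <- run_phase(w, tabs[, sel, drop = FALSE], tpres[, sel, drop = FALSE],
                    config$burn_in_epochs)
    w <- ph$weights
    burn_trace <- ph$trace
  }
  ph <- run_phase(w, tabs, tpres, config$epochs)
  structure(list(weights = ph$weights, config = config,
                 loss_spec = loss$kind, n_channels = n_channels,
                 loss_trace = ph$trace, burn_in_trace = burn_trace),
            class = "tied_linear_ae")
}

#' @export
print.tied_linear_ae <- function(x, ...) {
  cat("tied_linear_ae:", x$n_channels, "channels,", x$loss_spec, "loss")
  if (length(x$loss_trace))
    cat(sprintf(", final loss %.4g", x$loss_trace[length(x$loss_trace)]))
  cat("\n")
  invisible(x)
}

#' Extract the encoder as a channel matrix
#'
#' The tied weights double as CHO channels: the channel matrix is
#' `T = W'`, so the columns of `W` are the channels.
#'
#' @param ae A `tied_linear_ae`.
#' @return A `channel_matrix` with `method = "ae"`.
#' @export
ae_channels <- function(ae) {
  stopifnot(inherits(ae, "tied_linear_ae"))
  new_channel_matrix(ae$weights, "ae",
                     list(loss = ae$loss_spec, n_channels = ae$n_channels))
}

#' Select the best autoencoder observer by validation AUC
#'
#' Converts each candidate's encoder into channels, builds a CHO with the
#' held-out covariance split, evaluates empirical AUC on the validation
#' split, and returns the argmax observer with the full leaderboard.
#'
#' @param candidates List of `tied_linear_ae` objects.
#' @param validation_dataset,covariance_dataset `paired_images` splits.
#' @param signal A `mean_signal`.
#' @return List with `observer`, `ae`, `index` and `leaderboard`.
#' @export
select_ae_model <- function(candidates, validation_dataset,
                            covariance_dataset, signal) {
  stopifnot(length(candidates) >= 1)
  sv <- stack_pairs(validation_dataset)
  rows <- list()
  best <- NULL
  for (i in seq_along(candidates)) {
    ae <- candidates[[i]]
    obs <- cho_build(ae_channels(ae), covariance_dataset, signal)
    auc <- empirical_auc(apply_observer(obs, sv$images, sv$labels))
    rows[[i]] <- data.frame(index = i, n_channels = ae$n_channels,
                            learning_rate = ae$config$learning_rate,
                            loss = ae$loss_spec, val_auc = auc)
    if (is.null(best) || auc > best$val_auc)
      best <- list(observer = obs, ae = ae, index = i, val_auc = auc)
  }
  best$leaderboard <- do.call(rbind, rows)
  best
}

#' Train autoencoders over a hyperparameter grid and select by AUC
#'
#' Trains one tied-weight AE per (channel count, learning rate) cell --
#' each cell also acts as an independent random initialization -- and
#' selects the best observer by validation AUC.
#'
#' @param train_dataset,validation_dataset,covariance_dataset
#'   `paired_images` splits.
#' @param signal A `mean_signal` (also the task-loss target).
#' @param channel_counts,learning_rates Grid values (channel counts are
#'   capped at 20).
#' @param loss_kind `"task"` or `"conventional"`.
#' @param config Base [ae_train_config()]; each cell reuses it with its
#'   own learning rate and a derived seed.
#' @return As [select_ae_model()], plus the trained `candidates`.
#' @export
ae_grid_search <- function(train_dataset, validation_dataset,
                           covariance_dataset, signal,
                           channel_counts = c(10, 20),
                           learning_rates = 5e-3,
                           loss_kind = "task",
                           config = ae_train_config()) {
  stopifnot(all(channel_counts >= 1), all(channel_counts <= 20))
  loss <- ae_loss_spec(loss_kind, signal)
  candidates <- list()
  cell <- 0
  for (lr in learning_rates) {
    for (m in channel_counts) {
      cell <- cell + 1
      cfg <- config
      cfg$learning_rate <- lr
      cfg$seed <- config$seed + cell
      candidates[[cell]] <- train_ae(train_dataset, m, loss, cfg)
    }
  }
  out <- select_ae_model(candidates, validation_dataset,
                         covariance_dataset, signal)
  out$candidates <- candidates
  out
}

#' Greedy backward channel ablation
#'
#' Iteratively removes the channel whose removal yields the highest
#' validation AUC of the rebuilt CHO, producing an importance ranking and
#' the AUC-versus-channel-count curve.
#'
#' @param observer A `channelized_observer` with at least two channels.
#' @param validation_dataset,covariance_dataset `paired_images` splits.
#' @param signal A `mean_signal`.
#' @return List with `elimination_order` (channel indices in removal
#'   order, least important first), `ranking` (most important first) and
#'   `auc_curve` (data frame of channel count vs validation AUC).
#' @export
ablate_channels <- function(observer, validation_dataset,
                            covariance_dataset, signal) {
  stopifnot(inherits(observer, "channelized_observer"))
  basis <- observer$channels$basis
  method <- observer$channels$method
  stopifnot(ncol(basis) >= 2)
  sv <- stack_pairs(validation_dataset)
  auc_for <- function(cols) {
    ch <- new_channel_matrix(basis[, cols, drop = FALSE], method)
    obs <- cho_build(ch, covariance_dataset, signal)
    empirical_auc(apply_observer(obs, sv$images, sv$labels))
  }
  active <- seq_len(ncol(basis))
  elim <- integer(0)
  curve <- data.frame(n_channels = length(active), val_auc = auc_for(active))
  while (length(active) > 1) {
    aucs <- vapply(seq_along(active), function(j)
      auc_for(active[-j]), numeric(1))
    j <- which.max(aucs)
    elim <- c(elim, active[j])
    active <- active[-j]
    curve <- rbind(curve,
                   data.frame(n_channels = length(active), val_auc = aucs[j]))
  }
  list(elimination_order = elim,
       ranking = c(active, rev(elim)),
       auc_curve = curve[order(curve$n_channels), ])
}
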