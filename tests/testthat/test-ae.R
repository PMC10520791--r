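test_that("autoencoder losses match hand-computed values", {
  dg <- c(1, 1)
  sig <- fixed_mean_signal(dg)
  task <- ae_loss_spec("task", sig)

  # W = 0 on a balanced batch: reconstruction is zero, half the targets
  # are delta_g, so the mean loss is ||delta_g||^2 / 2
  imgs <- matrix(rnorm(8), 4, 2)
  labels <- c(0, 0, 1, 1)
  expect_equal(ae_loss(matrix(0, 2, 3), imgs, labels, task),
               sum(dg^2) / 2)

  # conventional loss vanishes for an orthonormal square W
  q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  conv <- ae_loss_spec("conventional")
  expect_equal(ae_loss(q, matrix(rnorm(20), 5, 4), rep(0, 5), conv), 0,
               tolerance = 1e-12)

  # two-pixel toy: ||(3,0) - (1,1)||^2 = 5, checked against direct
  # matrix arithmetic
  w <- matrix(c(1, 0), 2, 1)
  g <- matrix(c(3, 4), 1, 2)
  expect_equal(ae_loss(w, g, 1, task), 5)
  recon <- g %*% w %*% t(w)
  expect_equal(sum((recon - dg)^2), 5)

  expect_error(ae_loss_spec("task"), "non-zero")
})

test_that("fast batch gradient matches the reference and finite differences", {
  set.seed(23)
  N <- 7; P <- 6; M <- 2
  g_cols <- matrix(rnorm(N * P), N, P)
  y <- rep(c(0, 1), each = 3)
  dg <- rnorm(N)
  w <- matrix(rnorm(N * M, sd = 0.5), N, M)
  for (target in list(NULL, dg)) {
    tt <- if (is.null(target)) t(g_cols) else outer(y, dg)
    ref <- taskobs:::ae_loss_grad(w, t(g_cols), tt)
    fast <- taskobs:::ae_batch_grad(w, g_cols, y, target)
    expect_equal(fast$loss, ref$loss, tolerance = 1e-12)
    expect_equal(fast$grad, ref$grad, tolerance = 1e-12)
    # central finite differences on a few coordinates
    eps <- 1e-6
    for (idx in list(c(1, 1), c(4, 2), c(7, 1))) {
      wp <- w; wp[idx[1], idx[2]] <- wp[idx[1], idx[2]] + eps
      wm <- w; wm[idx[1], idx[2]] <- wm[idx[1], idx[2]] - eps
      fd <- (taskobs:::ae_loss_grad(wp, t(g_cols), tt)$loss -
               taskobs:::ae_loss_grad(wm, t(g_cols), tt)$loss) / (2 * eps)
      expect_equal(fast$grad[idx[1], idx[2]], fd, tolerance = 1e-5)
    }
  }
})

make_toy_task <- function(n = 300, N = 16, seed = 24, amp = 0.5) {
  set.seed(seed)
  delta <- c(amp, rep(0, N - 1))
  absent <- matrix(rnorm(n * N), n, N)
  present <- sweep(matrix(rnorm(n * N), n, N), 2, delta, "+")
  list(ds = wrap_pairs(absent, present), delta = delta)
}

test_that("trainer is deterministic and returns the initialization at zero epochs", {
  toy <- make_toy_task()
  sig <- fixed_mean_signal(toy$delta)
  loss <- ae_loss_spec("task", sig)
  cfg0 <- ae_train_config(epochs = 0, batch_size = 20, seed = 5)
  ae0 <- train_ae(toy$ds, 2, loss, cfg0)
  set.seed(5)
  expect_identical(ae0$weights, taskobs:::truncnorm_init(16, 2, 5e-6))
  # truncation bounds: +/- 2 sd
  big <- taskobs:::truncnorm_init(200, 50, 1)
  expect_lt(max(abs(big)), 2 + 1e-12)

  cfg <- ae_train_config(learning_rate = 5e-3, epochs = 30, batch_size = 20,
                         seed = 6)
  a1 <- train_ae(toy$ds, 2, loss, cfg)
  a2 <- train_ae(toy$ds, 2, loss, cfg)
  expect_identical(a1$weights, a2$weights)
})

test_that("single-channel task AE recovers the signal direction", {
  toy <- make_toy_task(n = 400, amp = 1)
  sig <- fixed_mean_signal(toy$delta)
  loss <- ae_loss_spec("task", sig)
  cfg <- ae_train_config(learning_rate = 5e-3, epochs = 300, batch_size = 80,
                         seed = 7)
  ae <- train_ae(toy$ds, 1, loss, cfg)
  w <- drop(ae$weights)
  cos_sig <- sum(w * toy$delta) / sqrt(sum(w^2) * sum(toy$delta^2))
  expect_gt(abs(cos_sig), 0.99)

  # independent numerical minimizer of the same objective over rank-1 W
  st <- stack_pairs(toy$ds)
  obj <- function(v) ae_loss(matrix(v, 16, 1), st$images, st$labels, loss)
  opt <- stats::optim(toy$delta * 0.9, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  vo <- opt$par
  cos_opt <- abs(sum(w * vo)) / sqrt(sum(w^2) * sum(vo^2))
  expect_gt(cos_opt, 0.99)
  # and the trained loss is close to the independent optimum
  expect_lt(ae_loss(ae$weights, st$images, st$labels, loss),
            opt$value * 1.05 + 1e-8)

  # loss trace decreases to a plateau after the Adam transient, with
  # only mini-batch jitter afterwards
  tr <- ae$loss_trace
  burn <- ceiling(length(tr) * 0.1)
  expect_lt(max(diff(tr[burn:length(tr)])), 0.02 * tr[burn])
  expect_lte(mean(utils::tail(tr, 30)), tr[burn] * (1 + 1e-3))
  expect_lt(min(tr), tr[1])
})

test_that("model selection picks the argmax-AUC candidate", {
  toy <- make_toy_task(n = 200, seed = 26)
  val <- make_toy_task(n = 150, seed = 27)$ds
  cov_ds <- make_toy_task(n = 150, seed = 28)$ds
  sig <- fixed_mean_signal(toy$delta)
  loss <- ae_loss_spec("task", sig)
  cands <- lapply(c(5, 40), function(ep)
    train_ae(toy$ds, 2, loss,
             ae_train_config(learning_rate = 5e-3, epochs = ep,
                             batch_size = 20, seed = 9)))
  one <- select_ae_model(cands[1], val, cov_ds, sig)
  expect_equal(one$index, 1)
  sel <- select_ae_model(cands, val, cov_ds, sig)
  # exhaustive re-evaluation oracle
  sv <- stack_pairs(val)
  aucs <- vapply(cands, function(ae) {
    obs <- cho_build(ae_channels(ae), cov_ds, sig)
    empirical_auc(apply_observer(obs, sv$images, sv$labels))
  }, numeric(1))
  expect_equal(sel$index, which.max(aucs))
  expect_equal(sel$leaderboard$val_auc, aucs, tolerance = 1e-12)
})

test_that("greedy ablation matches exhaustive single-removal search", {
  toy <- make_toy_task(n = 300, seed = 30)
  val <- make_toy_task(n = 200, seed = 31)$ds
  cov_ds <- make_toy_task(n = 200, seed = 32)$ds
  sig <- fixed_mean_signal(toy$delta)
  set.seed(33)
  basis <- cbind(toy$delta + rnorm(16, 0, 0.1), rnorm(16), rnorm(16))
  ch <- taskobs:::new_channel_matrix(basis, "test")
  obs <- cho_build(ch, cov_ds, sig)
  ab <- ablate_channels(obs, val, cov_ds, sig)
  expect_equal(sort(c(ab$elimination_order, ab$ranking[1])), 1:3)
  expect_equal(nrow(ab$auc_curve), 3)

  # first greedy elimination equals the exhaustive argmax
  sv <- stack_pairs(val)
  aucs <- vapply(1:3, function(j) {
    chj <- taskobs:::new_channel_matrix(basis[, -j, drop = FALSE], "test")
    empirical_auc(apply_observer(cho_build(chj, cov_ds, sig),
                                 sv$images, sv$labels))
  }, numeric(1))
  expect_equal(ab$elimination_order[1], which.max(aucs))

  # pruning an exact duplicate channel changes the AUC negligibly
  dup <- taskobs:::new_channel_matrix(cbind(basis[, 1:2], basis[, 2]), "dup")
  obs_dup <- cho_build(dup, cov_ds, sig)
  auc_dup <- empirical_auc(apply_observer(obs_dup, sv$images, sv$labels))
  auc_2 <- empirical_auc(apply_observer(
    cho_build(taskobs:::new_channel_matrix(basis[, 1:2], "dup"), cov_ds, sig),
    sv$images, sv$labels))
  expect_lt(abs(auc_dup - auc_2), 1e-6)
})

test_that("CHO scores are invariant to channel rescaling", {
  toy <- make_toy_task(n = 250, seed = 34)
  cov_ds <- make_toy_task(n = 250, seed = 35)$ds
  sig <- fixed_mean_signal(toy$delta)
  set.seed(36)
  basis <- matrix(rnorm(16 * 3), 16, 3)
  scaled <- basis %*% diag(c(10, 0.01, 3))
  s <- stack_pairs(toy$ds)
  s1 <- apply_observer(cho_build(taskobs:::new_channel_matrix(basis, "a"),
                                 cov_ds, sig), s$images)
  s2 <- apply_observer(cho_build(taskobs:::new_channel_matrix(scaled, "a"),
                                 cov_ds, sig), s$images)
  expect_equal(s1, s2, tolerance = 1e-8)
})
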