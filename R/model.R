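# Masked pathway-module VAE internals: parameter initialization, forward
# passes in train and eval mode, analytic backpropagation, and the Adam
# training loop.  Masks are re-applied after every update so that weights
# at masked positions are exactly zero at all times.

.init_params <- function(masks) {
  m <- masks$meta
  N <- m$N; C <- m$n_conditions; H <- m$H; D <- m$D
  glorot <- function(mask) {
    fan_in <- pmax(colSums(mask), 1)
    fan_out <- pmax(rowSums(mask), 1)
    lim <- sqrt(6 / (mean(fan_in) + mean(fan_out)))
    matrix(stats::runif(length(mask), -lim, lim), nrow(mask)) * mask
  }
  params <- list(
    W_e1 = glorot(masks$assignment), b_e1 = numeric(H),
    g_e = rep(1, H), be_e = numeric(H),
    W_mu = glorot(masks$sep_enc), b_mu = numeric(D),
    W_lv = glorot(masks$sep_enc), b_lv = numeric(D),
    W_d1 = glorot(masks$sep_dec), b_d1 = numeric(H),
    g_d = rep(1, H), be_d = numeric(H),
    W_d2 = glorot(masks$out), B_out = masks$module_out * 0
  )
  buffers <- list(rmean_e = numeric(H), rvar_e = rep(1, H),
                  rmean_d = numeric(H), rvar_d = rep(1, H))
  list(params = params, buffers = buffers)
}

.apply_masks <- function(params, masks) {
  params$W_e1 <- params$W_e1 * masks$assignment
  params$W_mu <- params$W_mu * masks$sep_enc
  params$W_lv <- params$W_lv * masks$sep_enc
  params$W_d1 <- params$W_d1 * masks$sep_dec
  params$W_d2 <- params$W_d2 * masks$out
  params$B_out <- params$B_out * masks$module_out
  params
}

.mask_grads <- .apply_masks

# --- eval-mode forward passes (deterministic; BN uses running statistics) ---

.encode_eval <- function(params, buffers, masks, X, Cmat = NULL) {
  inp <- if (is.null(Cmat)) X else cbind(X, Cmat)
  a1 <- sweep(inp %*% params$W_e1, 2, params$b_e1, "+")
  y1 <- .bn_eval(a1, list(gamma = params$g_e, beta = params$be_e,
                          rmean = buffers$rmean_e, rvar = buffers$rvar_e))
  h <- .elu(y1)
  list(mu = sweep(h %*% params$W_mu, 2, params$b_mu, "+"),
       log_var = sweep(h %*% params$W_lv, 2, params$b_lv, "+"),
       h = h, y1 = y1)
}

.decode_eval <- function(params, buffers, masks, Z, Cmat = NULL,
                         per_module = FALSE) {
  din <- if (is.null(Cmat)) Z else cbind(Z, Cmat)
  a2 <- sweep(din %*% params$W_d1, 2, params$b_d1, "+")
  y2 <- .bn_eval(a2, list(gamma = params$g_d, beta = params$be_d,
                          rmean = buffers$rmean_d, rvar = buffers$rvar_d))
  h <- .elu(y2)
  xhat <- h %*% params$W_d2 +
    matrix(colSums(params$B_out), nrow(Z), masks$meta$N, byrow = TRUE)
  res <- list(xhat = xhat, h = h, y2 = y2)
  if (per_module) {
    res$modules <- lapply(seq_along(masks$module_slices), function(j) {
      sl <- masks$module_slices[[j]]
      xm <- matrix(0, nrow(Z), masks$meta$N,
                   dimnames = list(NULL, masks$meta$genes))
      xm[, sl$genes] <- h[, sl$hidden, drop = FALSE] %*%
        params$W_d2[sl$hidden, sl$genes, drop = FALSE] +
        matrix(params$B_out[j, sl$genes], nrow(Z), length(sl$genes),
               byrow = TRUE)
      xm
    })
    names(res$modules) <- masks$meta$modules
  }
  res
}

# --- loss components on a batch (training convention: mean over samples,
#     sum over genes / latent dimensions) ---

.loss_components <- function(X, xhat, mods_resid, mu, lv, masks,
                             z = NULL, Cmat = NULL, weights) {
  B <- nrow(X)
  recon_global <- sum((X - xhat)^2) / B
  N <- masks$meta$N; K <- masks$meta$K
  recon_local <- 0
  for (j in seq_len(K)) {
    sl <- masks$module_slices[[j]]
    recon_local <- recon_local +
      (N / length(sl$genes)) * sum(mods_resid[[j]]^2) / B
  }
  recon_local <- recon_local / K
  kl <- sum(0.5 * (mu^2 + exp(lv) - lv - 1)) / B
  hs <- if (!is.null(Cmat) && weights$hsic_weight > 0)
    .hsic(z, Cmat)$value else 0
  total <- recon_global + weights$kl_weight * kl + recon_local +
    weights$hsic_weight * hs
  list(recon_global = recon_global, recon_local = recon_local,
       kl = kl, hsic = hs, total = total)
}

# --- one training step: forward (train-mode BN), loss, analytic backprop ---

.train_step <- function(params, buffers, masks, X, Cmat, eps, weights) {
  B <- nrow(X); m <- masks$meta
  inp <- if (is.null(Cmat)) X else cbind(X, Cmat)

  a1 <- sweep(inp %*% params$W_e1, 2, params$b_e1, "+")
  bn1 <- .bn_train(a1, list(gamma = params$g_e, beta = params$be_e,
                            rmean = buffers$rmean_e, rvar = buffers$rvar_e))
  buffers$rmean_e <- bn1$bn$rmean; buffers$rvar_e <- bn1$bn$rvar
  h1 <- .elu(bn1$y)
  mu <- sweep(h1 %*% params$W_mu, 2, params$b_mu, "+")
  lv <- sweep(h1 %*% params$W_lv, 2, params$b_lv, "+")
  sd_ <- exp(0.5 * lv)
  z <- mu + sd_ * eps

  din <- if (is.null(Cmat)) z else cbind(z, Cmat)
  a2 <- sweep(din %*% params$W_d1, 2, params$b_d1, "+")
  bn2 <- .bn_train(a2, list(gamma = params$g_d, beta = params$be_d,
                            rmean = buffers$rmean_d, rvar = buffers$rvar_d))
  buffers$rmean_d <- bn2$bn$rmean; buffers$rvar_d <- bn2$bn$rvar
  h2 <- .elu(bn2$y)
  bias_row <- colSums(params$B_out)
  xhat <- h2 %*% params$W_d2 + matrix(bias_row, B, m$N, byrow = TRUE)

  # per-module reconstructions and residuals (support restricted to members)
  K <- m$K; N <- m$N
  mods_resid <- vector("list", K)
  for (j in seq_len(K)) {
    sl <- masks$module_slices[[j]]
    xm <- h2[, sl$hidden, drop = FALSE] %*%
      params$W_d2[sl$hidden, sl$genes, drop = FALSE] +
      matrix(params$B_out[j, sl$genes], B, length(sl$genes), byrow = TRUE)
    mods_resid[[j]] <- xm - X[, sl$genes, drop = FALSE]
  }

  hs <- list(value = 0, dz = NULL)
  if (!is.null(Cmat) && weights$hsic_weight > 0) hs <- .hsic(z, Cmat, grad = TRUE)

  loss <- .loss_components(X, xhat, mods_resid, mu, lv, masks,
                           z = z, Cmat = Cmat, weights = weights)
  if (!is.finite(loss$total)) return(list(loss = loss, diverged = TRUE))

  # ---- backward ----
  d_xhat <- 2 * (xhat - X) / B
  dW_d2 <- crossprod(h2, d_xhat)
  dB_out <- params$B_out * 0
  dh2 <- d_xhat %*% t(params$W_d2)
  cs_glob <- colSums(d_xhat)
  for (j in seq_len(K)) {
    sl <- masks$module_slices[[j]]
    w_p <- (N / length(sl$genes)) / K
    dR <- (2 * w_p / B) * mods_resid[[j]]
    dW_d2[sl$hidden, sl$genes] <- dW_d2[sl$hidden, sl$genes] +
      crossprod(h2[, sl$hidden, drop = FALSE], dR)
    dB_out[j, sl$genes] <- cs_glob[sl$genes] + colSums(dR)
    dh2[, sl$hidden] <- dh2[, sl$hidden, drop = FALSE] +
      dR %*% t(params$W_d2[sl$hidden, sl$genes, drop = FALSE])
  }
  dy2 <- dh2 * .elu_grad(bn2$y)
  bb2 <- .bn_backward(dy2, bn2, params$g_d)
  dW_d1 <- crossprod(din, bb2$da)
  db_d1 <- colSums(bb2$da)
  dz <- bb2$da %*% t(params$W_d1[seq_len(m$D), , drop = FALSE])
  if (!is.null(hs$dz)) dz <- dz + weights$hsic_weight * hs$dz

  dmu <- dz + weights$kl_weight * mu / B
  dlv <- dz * eps * 0.5 * sd_ + weights$kl_weight * 0.5 * (exp(lv) - 1) / B

  dW_mu <- crossprod(h1, dmu); db_mu <- colSums(dmu)
  dW_lv <- crossprod(h1, dlv); db_lv <- colSums(dlv)
  dh1 <- dmu %*% t(params$W_mu) + dlv %*% t(params$W_lv)
  dy1 <- dh1 * .elu_grad(bn1$y)
  bb1 <- .bn_backward(dy1, bn1, params$g_e)
  dW_e1 <- crossprod(inp, bb1$da)
  db_e1 <- colSums(bb1$da)

  grads <- list(W_e1 = dW_e1, b_e1 = db_e1, g_e = bb1$dgamma, be_e = bb1$dbeta,
                W_mu = dW_mu, b_mu = db_mu, W_lv = dW_lv, b_lv = db_lv,
                W_d1 = dW_d1, b_d1 = db_d1, g_d = bb2$dgamma, be_d = bb2$dbeta,
                W_d2 = dW_d2, B_out = dB_out)
  grads$W_e1 <- grads$W_e1 * masks$assignment
  grads$W_mu <- grads$W_mu * masks$sep_enc
  grads$W_lv <- grads$W_lv * masks$sep_enc
  grads$W_d1 <- grads$W_d1 * masks$sep_dec
  grads$W_d2 <- grads$W_d2 * masks$out
  grads$B_out <- grads$B_out * masks$module_out

  list(loss = loss, grads = grads, buffers = buffers, diverged = FALSE)
}

# Recompute batch-normalization population statistics exactly under the
# current weights (one deterministic pass over the data, z = posterior
# mean).  Eval-mode passes then reflect the weights themselves rather
# than lagged running averages, which matters when there are few
# optimizer steps per epoch.
.calibrate_bn <- function(params, buffers, masks, X, Cmat = NULL) {
  n <- nrow(X)
  inp <- if (is.null(Cmat)) X else cbind(X, Cmat)
  a1 <- sweep(inp %*% params$W_e1, 2, params$b_e1, "+")
  m1 <- colMeans(a1)
  v1 <- colMeans(a1^2) - m1^2
  buffers$rmean_e <- m1
  buffers$rvar_e <- pmax(v1, 0) * if (n > 1) n / (n - 1) else 1
  y1 <- .bn_eval(a1, list(gamma = params$g_e, beta = params$be_e,
                          rmean = buffers$rmean_e, rvar = buffers$rvar_e))
  h1 <- .elu(y1)
  mu <- sweep(h1 %*% params$W_mu, 2, params$b_mu, "+")
  din <- if (is.null(Cmat)) mu else cbind(mu, Cmat)
  a2 <- sweep(din %*% params$W_d1, 2, params$b_d1, "+")
  m2 <- colMeans(a2)
  v2 <- colMeans(a2^2) - m2^2
  buffers$rmean_d <- m2
  buffers$rvar_d <- pmax(v2, 0) * if (n > 1) n / (n - 1) else 1
  buffers
}

# Deterministic loss evaluation (eval-mode BN, z = posterior mean).
.eval_losses <- function(params, buffers, masks, X, Cmat, weights,
                         hsic_cap = 2000L) {
  enc <- .encode_eval(params, buffers, masks, X, Cmat)
  dec <- .decode_eval(params, buffers, masks, enc$mu, Cmat)
  B <- nrow(X); K <- masks$meta$K; N <- masks$meta$N
  mods_resid <- lapply(seq_len(K), function(j) {
    sl <- masks$module_slices[[j]]
    dec$h[, sl$hidden, drop = FALSE] %*%
      params$W_d2[sl$hidden, sl$genes, drop = FALSE] +
      matrix(params$B_out[j, sl$genes], B, length(sl$genes), byrow = TRUE) -
      X[, sl$genes, drop = FALSE]
  })
  zc <- enc$mu; Cc <- Cmat
  if (!is.null(Cmat) && nrow(X) > hsic_cap) {
    keep <- seq_len(hsic_cap)
    zc <- zc[keep, , drop = FALSE]; Cc <- Cmat[keep, , drop = FALSE]
  }
  .loss_components(X, dec$xhat, mods_resid, enc$mu, enc$log_var, masks,
                   z = zc, Cmat = Cc, weights = weights)
}

.train_pmvae <- function(params, buffers, masks, X, Cmat, config,
                         verbose = FALSE) {
  n <- nrow(X)
  weights <- list(kl_weight = config$kl_weight,
                  hsic_weight = config$hsic_weight)
  n_val <- max(2L, floor(config$validation_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xv <- X[val_idx, , drop = FALSE]
  Cv <- if (is.null(Cmat)) NULL else Cmat[val_idx, , drop = FALSE]

  state <- .adam_init(params)
  lr <- config$learning_rate
  best <- list(val = Inf, params = params, buffers = buffers, epoch = 0L)
  stall <- 0L
  patience <- config$lr_patience %||% 2L
  val1 <- NA_real_
  started <- FALSE  # plateau schedule arms once learning is underway
  hist <- vector("list", config$max_epochs)
  D <- masks$meta$D

  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample(tr_idx)
    starts <- seq(1L, length(perm), by = config$batch_size)
    acc <- c(recon_global = 0, recon_local = 0, kl = 0, hsic = 0, total = 0)
    nb <- 0L
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1L, length(perm))]
      if (length(idx) < 2L) next
      eps <- matrix(stats::rnorm(length(idx) * D), length(idx), D)
      st <- .train_step(params, buffers, masks,
                        X[idx, , drop = FALSE],
                        if (is.null(Cmat)) NULL else Cmat[idx, , drop = FALSE],
                        eps, weights)
      if (isTRUE(st$diverged))
        .stopf("training diverged (non-finite loss) at epoch %d, step %d",
               epoch, nb + 1L)
      buffers <- st$buffers
      upd <- .adam_step(params, st$grads, state, lr)
      params <- .apply_masks(upd$params, masks)
      state <- upd$state
      acc <- acc + unlist(st$loss)
      nb <- nb + 1L
    }
    acc <- acc / max(nb, 1L)
    cal <- .calibrate_bn(params, buffers, masks,
                         X[tr_idx, , drop = FALSE],
                         if (is.null(Cmat)) NULL
                         else Cmat[tr_idx, , drop = FALSE])
    val <- .eval_losses(params, cal, masks, Xv, Cv, weights)
    hist[[epoch]] <- data.frame(
      epoch = epoch, lr = lr,
      train_total = acc[["total"]], train_recon_global = acc[["recon_global"]],
      train_recon_local = acc[["recon_local"]], train_kl = acc[["kl"]],
      train_hsic = acc[["hsic"]],
      val_total = val$total, val_recon_global = val$recon_global,
      val_recon_local = val$recon_local, val_kl = val$kl, val_hsic = val$hsic)
    if (epoch == 1L) val1 <- val$recon_global
    if (!started && val$recon_global < 0.999 * val1) started <- TRUE
    if (val$recon_global < best$val) {
      best <- list(val = val$recon_global, params = params,
                   buffers = cal, epoch = epoch)
      stall <- 0L
    } else if (started) {
      # no decrease in held-out reconstruction error this epoch
      stall <- stall + 1L
      if (stall >= patience) {
        lr <- max(lr / config$lr_decay_factor, config$lr_floor)
        stall <- 0L
      }
    }
    if (verbose && (epoch %% 10L == 0L || epoch == 1L))
      message(sprintf("epoch %3d  lr %.2g  train %.4f  val recon %.4f",
                      epoch, lr, acc[["total"]], val$recon_global))
  }
  list(params = best$params, buffers = best$buffers,
       history = do.call(rbind, hist), best_epoch = best$epoch,
       val_idx = sort(val_idx))
}
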