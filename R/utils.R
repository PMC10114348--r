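# Internal numerical helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.check_matrix <- function(x, what = "x") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    .stopf("'%s' must be a numeric matrix (samples x genes)", what)
  if (any(!is.finite(x)))
    .stopf("'%s' contains non-finite values", what)
  x
}

# ELU activation and its derivative, evaluated elementwise.
.elu <- function(u) ifelse(u > 0, u, exp(pmin(u, 0)) - 1)
.elu_grad <- function(u) ifelse(u > 0, 1, exp(pmin(u, 0)))

# Batch normalization. Train mode normalizes with batch statistics and
# returns updated running statistics (momentum 0.1, unbiased running var,
# matching the usual BatchNorm1d convention); eval mode is a fixed affine
# map per unit.
.bn_eps <- 1e-5

.bn_train <- function(a, bn, momentum = 0.1) {
  b <- nrow(a)
  m <- colMeans(a)
  v <- colMeans(a^2) - m^2          # biased batch variance
  v <- pmax(v, 0)
  s <- sqrt(v + .bn_eps)
  xhat <- sweep(sweep(a, 2, m, "-"), 2, s, "/")
  y <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
  vu <- if (b > 1) v * b / (b - 1) else v
  bn$rmean <- (1 - momentum) * bn$rmean + momentum * m
  bn$rvar <- (1 - momentum) * bn$rvar + momentum * vu
  list(y = y, xhat = xhat, s = s, bn = bn)
}

# Gradient of BN train-mode output wrt its input, plus parameter grads.
.bn_backward <- function(dy, cache, gamma) {
  b <- nrow(dy)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, gamma, "*")
  t1 <- sweep(dxhat, 2, colSums(dxhat) / b, "-")
  t2 <- sweep(xhat, 2, colSums(dxhat * xhat) / b, "*")
  da <- sweep(t1 - t2, 2, cache$s, "/")
  list(da = da, dgamma = dgamma, dbeta = dbeta)
}

.bn_eval_scale <- function(bn) bn$gamma / sqrt(bn$rvar + .bn_eps)

.bn_eval <- function(a, bn) {
  sc <- .bn_eval_scale(bn)
  sweep(sweep(a, 2, bn$rmean, "-") , 2, sc, "*") +
    matrix(bn$beta, nrow(a), length(bn$beta), byrow = TRUE)
}

# Adam optimizer state over a named list of arrays.
.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Spearman rank correlation shortcut used in examples and vignette.
.spearman <- function(a, b) stats::cor(a, b, method = "spearman")
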