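# Exported loss components.  Training conventions: squared errors are
# summed over genes and averaged over the batch; the KL term is summed
# over latent dimensions and averaged over the batch.

#' Module-weighted local reconstruction loss
#'
#' Computes the pathway-module reconstruction penalty
#' (1/K) * sum_p (N/N_p) * ||xhat^(p) - x^(p)||^2, averaged over the batch,
#' where `xhat^(p)` is module p's partial reconstruction of its member
#' genes and the N/N_p weight stops large pathways from dominating.
#'
#' @param xhat_modules A list of per-module reconstructions.  Each element
#'   may be a samples x N matrix supported on the module's genes, or a
#'   samples x N_p matrix over the member genes only.
#' @param x Observed expression batch (samples x N), columns in model
#'   gene order.
#' @param membership A `pathway_membership` or `pmvae_masks` object
#'   defining the modules.
#' @return The scalar loss value.
#' @export
local_recon_loss <- function(xhat_modules, x, membership) {
  x <- .check_matrix(x, "x")
  slices <- if (inherits(membership, "pmvae_masks"))
    lapply(membership$module_slices, `[[`, "genes")
  else if (inherits(membership, "pathway_membership"))
    apply(membership$M[, , drop = FALSE], 2, function(col) which(col == 1L),
          simplify = FALSE)
  else .stopf("'membership' must be a pathway_membership or pmvae_masks")
  K <- length(slices)
  if (length(xhat_modules) != K)
    .stopf("expected %d per-module reconstructions, got %d",
           K, length(xhat_modules))
  N <- ncol(x)
  B <- nrow(x)
  total <- 0
  for (j in seq_len(K)) {
    g <- slices[[j]]
    xm <- xhat_modules[[j]]
    xm <- if (ncol(xm) == N) xm[, g, drop = FALSE] else xm
    if (ncol(xm) != length(g))
      .stopf("module %d reconstruction has %d columns; expected %d or %d",
             j, ncol(xm), length(g), N)
    total <- total + (N / length(g)) * sum((xm - x[, g, drop = FALSE])^2) / B
  }
  total / K
}

#' KL divergence of diagonal Gaussian posteriors from the standard normal
#'
#' Per-dimension closed form 0.5 * (mu^2 + sigma^2 - log sigma^2 - 1),
#' averaged over samples; the total is the sum over latent dimensions.
#'
#' @param mu Posterior means (samples x D).
#' @param log_var Posterior log-variances (samples x D).
#' @return A list with `total` (scalar) and `per_dim` (length-D vector).
#' @export
kl_term <- function(mu, log_var) {
  mu <- as.matrix(mu); log_var <- as.matrix(log_var)
  stopifnot(all(dim(mu) == dim(log_var)))
  per_dim <- colMeans(0.5 * (mu^2 + exp(log_var) - log_var - 1))
  list(total = sum(per_dim), per_dim = per_dim)
}

#' Draw latent variables with the reparameterization trick
#'
#' z = mu + exp(log_var / 2) * eps with eps ~ N(0, I); deterministic under
#' a fixed seed.
#'
#' @param encoding A list with `mu` and `log_var` (as returned by
#'   [encode()]), or a matrix of means (in which case `log_var` must be
#'   supplied).
#' @param log_var Optional log-variance matrix when `encoding` is a matrix.
#' @param seed Optional integer seed for the standard-normal draws.
#' @return A samples x D matrix of latent draws.
#' @export
reparameterize <- function(encoding, log_var = NULL, seed = NULL) {
  if (is.list(encoding)) {
    mu <- encoding$mu; lv <- encoding$log_var
  } else {
    mu <- encoding; lv <- log_var
  }
  stopifnot(!is.null(lv), all(dim(mu) == dim(lv)))
  if (!is.null(seed)) set.seed(seed)
  eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  mu + exp(0.5 * lv) * eps
}

# One-hot encode condition labels; matrices pass through unchanged.
.condition_matrix <- function(c, levels = NULL) {
  if (is.null(c)) return(NULL)
  if (is.matrix(c)) return(c)
  f <- if (is.factor(c)) c else factor(c)
  if (!is.null(levels)) {
    if (!all(as.character(f) %in% levels))
      .stopf("condition label(s) outside the model's levels: %s",
             paste(setdiff(unique(as.character(f)), levels), collapse = ", "))
    f <- factor(as.character(f), levels = levels)
  }
  Cmat <- matrix(0, length(f), nlevels(f),
                 dimnames = list(NULL, levels(f)))
  Cmat[cbind(seq_along(f), as.integer(f))] <- 1
  Cmat
}

# Internal biased HSIC with Gaussian kernels and median-heuristic
# bandwidths (frozen per batch), with optional analytic gradient in z.
.sq_dists <- function(a) {
  sq <- rowSums(a^2)
  d <- outer(sq, sq, "+") - 2 * tcrossprod(a)
  pmax(d, 0)
}

.median_bw <- function(d2) {
  d <- sqrt(d2[upper.tri(d2)])
  d <- d[d > 0]
  if (length(d) == 0) 1 else stats::median(d)
}

.hsic <- function(z, c, grad = FALSE) {
  z <- as.matrix(z); c <- as.matrix(c)
  n <- nrow(z)
  if (n < 2) .stopf("HSIC requires at least 2 samples")
  Dz <- .sq_dists(z); Dc <- .sq_dists(c)
  sz <- .median_bw(Dz); sc <- .median_bw(Dc)
  Kz <- exp(-Dz / (2 * sz^2))
  L <- exp(-Dc / (2 * sc^2))
  H <- diag(n) - 1 / n
  A <- H %*% L %*% H
  value <- sum(Kz * A) / (n - 1)^2
  out <- list(value = value, dz = NULL)
  if (grad) {
    G <- Kz * A
    out$dz <- (2 / (sz^2 * (n - 1)^2)) * (G %*% z - rowSums(G) * z)
  }
  out
}

#' Hilbert-Schmidt independence criterion penalty
#'
#' Biased empirical HSIC, tr(K H L H) / (n - 1)^2, between the rows of a
#' latent embedding and the rows of a condition/batch label encoding.
#' Both kernels are Gaussian with bandwidths set by the median
#' pairwise-distance heuristic of the batch.  The statistic is zero when
#' either argument is constant and nonnegative up to numerical rounding.
#'
#' @param z Latent embedding (samples x D).
#' @param c Condition labels: a factor/character vector (one-hot encoded
#'   internally) or a numeric matrix.
#' @return Scalar penalty value (>= 0).
#' @export
hsic_penalty <- function(z, c) {
  Cmat <- .condition_matrix(c)
  v <- .hsic(as.matrix(z), Cmat)$value
  max(v, 0)
}

#' Full loss breakdown for a pmVAE model on a batch
#'
#' Deterministic (posterior-mean, eval-mode) evaluation of all loss
#' components: global reconstruction error, module-weighted local
#' reconstruction loss, KL divergence, HSIC penalty, and their weighted
#' total.
#'
#' @param object A fitted or initialized [pmvae] model.
#' @param x Expression batch (samples x genes, model gene order).
#' @param conditions Optional condition labels (required iff the model is
#'   conditional).
#' @return A list of class `pmvae_loss` with components `recon_global`,
#'   `recon_local`, `kl`, `hsic` and `total`.
#' @export
pmvae_loss <- function(object, x, conditions = NULL) {
  stopifnot(inherits(object, "pmvae"))
  x <- .align_genes(object, x)
  Cmat <- .model_conditions(object, conditions, nrow(x))
  weights <- list(kl_weight = object$config$kl_weight,
                  hsic_weight = object$config$hsic_weight)
  out <- .eval_losses(object$params, object$buffers, object$masks, x, Cmat,
                      weights)
  bad <- names(out)[!vapply(out, is.finite, TRUE)]
  if (length(bad)) .stopf("non-finite loss component(s): %s",
                          paste(bad, collapse = ", "))
  structure(out, class = "pmvae_loss")
}

#' @export
print.pmvae_loss <- function(x, ...) {
  cat(sprintf(paste0("pmVAE loss: total %.4f (recon %.4f, local %.4f, ",
                     "KL %.4f, HSIC %.3g)\n"),
              x$total, x$recon_global, x$recon_local, x$kl, x$hsic))
  invisible(x)
}
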