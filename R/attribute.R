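# Path-integral (Aumann-Shapley / integrated-gradient) attributions.
# Reconstruction-loss credit flows to latent pathway nodes; latent-node
# credit flows back to input genes.  The line integral along the straight
# path from a baseline is approximated by a midpoint Riemann sum with
# evenly spaced steps, which is exact when the gradient is affine along
# the path.

#' Midpoint path integral of a scalar function's gradient
#'
#' Approximates, per coordinate, `(v_i - v'_i) * Int_0^1 df/dv_i along the
#' straight path from baseline v' to v` with `n_steps` midpoint
#' evaluations at `alpha_t = (t - 1/2)/n_steps`.  Exact for linear `f` and
#' for any `f` whose gradient is affine in `alpha`; by the completeness
#' property the coordinates sum to approximately `f(v) - f(v')`.
#'
#' @param f Scalar-valued function of a numeric vector.
#' @param v Input vector.
#' @param baseline Baseline vector `v'` (defaults to zeros).
#' @param n_steps Number of quadrature steps (>= 1).
#' @param grad Optional gradient function; when omitted, central finite
#'   differences are used.
#' @return Numeric attribution vector, one entry per coordinate.
#' @export
path_integral <- function(f, v, baseline = NULL, n_steps = 200L,
                          grad = NULL) {
  v <- as.numeric(v)
  baseline <- if (is.null(baseline)) numeric(length(v)) else as.numeric(baseline)
  stopifnot(length(baseline) == length(v), n_steps >= 1)
  if (is.null(grad)) grad <- function(u) .fd_grad(f, u)
  acc <- numeric(length(v))
  for (t in seq_len(n_steps)) {
    alpha <- (t - 0.5) / n_steps
    g <- grad(baseline + alpha * (v - baseline))
    if (any(!is.finite(g)))
      .stopf("non-finite gradient at alpha = %.6f", alpha)
    acc <- acc + g
  }
  (v - baseline) * acc / n_steps
}

.fd_grad <- function(f, u, h = 1e-6) {
  vapply(seq_along(u), function(i) {
    hp <- h * max(1, abs(u[i]))
    up <- u; up[i] <- u[i] + hp
    um <- u; um[i] <- u[i] - hp
    (f(up) - f(um)) / (2 * hp)
  }, 0)
}

#' Reconstruction loss of a sample as a function of the latent vector
#'
#' Returns the differentiable map `l(z) = ||x - g(z)||^2` for a single
#' sample `x` under the model's decoder, with its analytic gradient
#' attached as the `"grad"` attribute (both accept a latent vector).
#'
#' @param object A `pmvae` model (trained or untrained).
#' @param x A single expression sample (vector or 1-row matrix).
#' @param conditions Condition label for conditional models.
#' @return A function of `z`; `attr(, "grad")` is its gradient function.
#' @export
recon_loss_fn <- function(object, x, conditions = NULL) {
  stopifnot(inherits(object, "pmvae"))
  x <- .align_genes(object, matrix(as.numeric(x), nrow = 1,
                                   dimnames = list(NULL, names(x) %||%
                                                     colnames(x))))
  Cmat <- .model_conditions(object, conditions, 1L)
  fn <- function(z) {
    g <- .decoder_loss_grad(object, matrix(z, nrow = 1), x, Cmat)
    as.numeric(g$ell)
  }
  attr(fn, "grad") <- function(z)
    as.numeric(.decoder_loss_grad(object, matrix(z, nrow = 1), x, Cmat)$dz)
  fn
}

# Batched eval-mode value and gradient of ell(z) = ||x - g(z)||^2.
.decoder_loss_grad <- function(object, Z, X, Cmat = NULL) {
  p <- object$params; b <- object$buffers; masks <- object$masks
  dec <- .decode_eval(p, b, masks, Z, Cmat)
  r <- dec$xhat - X
  ell <- rowSums(r^2)
  dh <- (2 * r) %*% t(p$W_d2)
  dy <- dh * .elu_grad(dec$y2)
  sc <- p$g_d / sqrt(b$rvar_d + .bn_eps)
  da <- sweep(dy, 2, sc, "*")
  dz <- da %*% t(p$W_d1[seq_len(masks$meta$D), , drop = FALSE])
  list(ell = ell, dz = dz)
}

# Batched eval-mode gradient of the k-th latent mean wrt the input genes.
.encoder_node_grad <- function(object, X, Cmat = NULL, k) {
  p <- object$params; b <- object$buffers; masks <- object$masks
  enc <- .encode_eval(p, b, masks, X, Cmat)
  dh <- matrix(p$W_mu[, k], nrow(X), masks$meta$H, byrow = TRUE)
  dy <- dh * .elu_grad(enc$y1)
  sc <- p$g_e / sqrt(b$rvar_e + .bn_eps)
  da <- sweep(dy, 2, sc, "*")
  dx <- da %*% t(p$W_e1[seq_len(masks$meta$N), , drop = FALSE])
  list(mu_k = enc$mu[, k], dx = dx)
}

#' Pathway attributions of the reconstruction loss
#'
#' For every sample, allocates the reduction in reconstruction error
#' between a baseline embedding `z'` and the sample's embedding `z` to the
#' latent pathway nodes, as the path integral of the loss gradient along
#' the straight line from `z'` to `z`.  Global attributions are the mean
#' of the local attributions over all samples (no subsampling).  Negative
#' attributions indicate loss *reduction*: the most important pathway has
#' the most negative global attribution.
#'
#' @param object A `pmvae` model.
#' @param x Expression matrix (samples x genes).
#' @param conditions Condition labels for conditional models.
#' @param baseline `"dataset_mean"` (mean embedding over `x`), `"zeros"`,
#'   or a numeric length-D vector.
#' @param latent_source `"posterior_mean"` (deterministic, the default) or
#'   `"posterior_sample"` (one reparameterized draw, seeded).
#' @param n_steps Midpoint quadrature steps (default 200).
#' @param seed Seed for `latent_source = "posterior_sample"`.
#' @return An object of class `pause_attribution`: `local` (samples x D),
#'   `global` (length D, column means of `local`), `pathway_global`
#'   (summed over each module's latent nodes), `baseline`, `ell_z`,
#'   `ell_baseline`, `completeness_gap` (signed, per sample) and
#'   `n_steps`.
#' @export
pathway_attributions <- function(object, x, conditions = NULL,
                                 baseline = c("dataset_mean", "zeros"),
                                 latent_source = c("posterior_mean",
                                                   "posterior_sample"),
                                 n_steps = 200L, seed = NULL) {
  stopifnot(inherits(object, "pmvae"), n_steps >= 1)
  latent_source <- match.arg(latent_source)
  x <- .align_genes(object, x)
  Cmat <- .model_conditions(object, conditions, nrow(x))
  enc <- .encode_eval(object$params, object$buffers, object$masks, x, Cmat)
  Z <- if (latent_source == "posterior_sample")
    reparameterize(list(mu = enc$mu, log_var = enc$log_var), seed = seed)
  else enc$mu
  D <- ncol(Z)
  zp <- if (is.numeric(baseline)) {
    stopifnot(length(baseline) == D)
    as.numeric(baseline)
  } else switch(match.arg(baseline),
                dataset_mean = colMeans(Z),
                zeros = numeric(D))
  Zp <- matrix(zp, nrow(Z), D, byrow = TRUE)
  dZ <- Z - Zp
  if (max(abs(dZ)) < 1e-12)
    .warnf("baseline equals every sample's embedding; attributions are all zero")

  G <- matrix(0, nrow(Z), D)
  for (t in seq_len(n_steps)) {
    alpha <- (t - 0.5) / n_steps
    g <- .decoder_loss_grad(object, Zp + alpha * dZ, x, Cmat)
    if (any(!is.finite(g$dz)))
      .stopf("non-finite gradient at alpha = %.6f", alpha)
    G <- G + g$dz
  }
  local <- dZ * G / n_steps
  colnames(local) <- object$masks$meta$latent_names
  ell_z <- .decoder_loss_grad(object, Z, x, Cmat)$ell
  ell_zp <- .decoder_loss_grad(object, Zp, x, Cmat)$ell
  gap <- rowSums(local) - (ell_z - ell_zp)
  global <- colMeans(local)
  slices <- object$masks$module_slices
  pathway_global <- vapply(slices, function(sl) sum(global[sl$latent]), 0)
  structure(list(local = local, global = global,
                 pathway_global = pathway_global, baseline = zp,
                 latent_source = latent_source, n_steps = as.integer(n_steps),
                 ell_z = ell_z, ell_baseline = ell_zp,
                 completeness_gap = gap),
            class = "pause_attribution")
}

#' @export
print.pause_attribution <- function(x, ...) {
  cat(sprintf("Pathway loss attributions: %d samples x %d latent nodes (n_steps = %d)\n",
              nrow(x$local), ncol(x$local), x$n_steps))
  ord <- order(x$pathway_global, names(x$pathway_global))
  top <- utils::head(ord, 5)
  cat("Top pathways (most negative = most loss explained):\n")
  for (i in top)
    cat(sprintf("  %-30s %10.4f\n", names(x$pathway_global)[i],
                x$pathway_global[i]))
  invisible(x)
}

#' Rank pathways by their loss attributions
#'
#' Importance is the negated global pathway attribution (larger loss
#' reduction = more important); ties break lexicographically by pathway
#' name.
#'
#' @param attribution A [pathway_attributions()] result.
#' @return A `pathway_ranking` object (method `"pause"`).
#' @export
pause_ranking <- function(attribution) {
  stopifnot(inherits(attribution, "pause_attribution"))
  .new_ranking("pause", names(attribution$pathway_global),
               -attribution$pathway_global)
}

#' Summarize the completeness gap of pathway attributions
#'
#' Completeness states that per-sample attributions sum to
#' `l(z) - l(z')`.  The midpoint quadrature leaves a residual gap, which
#' is recorded rather than silently dropped; this reports its magnitude.
#'
#' @param result A [pathway_attributions()] result.
#' @return A list with `max_abs`, `mean_abs`, `max_rel`, `mean_rel`
#'   (relative gaps are `|gap| / |l(z) - l(z')|`) and `n`.
#' @export
completeness_report <- function(result) {
  stopifnot(inherits(result, "pause_attribution"))
  gap <- abs(result$completeness_gap)
  denom <- abs(result$ell_z - result$ell_baseline)
  rel <- gap / pmax(denom, .Machine$double.eps)
  list(max_abs = max(gap), mean_abs = mean(gap),
       max_rel = max(rel), mean_rel = mean(rel), n = length(gap))
}

#' Gene attributions of a latent pathway node
#'
#' Attributes the value of encoder latent node `node` (its posterior mean)
#' to the input genes via the path integral from a baseline expression
#' profile.  Global attributions average the *magnitude* of the local
#' attributions, avoiding cancellation between samples of opposite sign.
#'
#' @param object A `pmvae` model.
#' @param x Expression matrix (samples x genes).
#' @param node Latent node index (1-based, `<= D`) or latent node name.
#' @param conditions Condition labels for conditional models.
#' @param baseline `"dataset_mean"`, `"zeros"`, or a length-N numeric
#'   vector.
#' @param n_steps Midpoint quadrature steps.
#' @return An object of class `gene_attribution`: `node`, `local`
#'   (samples x N), `global` (length N, mean |local|), `baseline`.
#' @export
gene_attributions <- function(object, x, node, conditions = NULL,
                              baseline = c("dataset_mean", "zeros"),
                              n_steps = 200L) {
  stopifnot(inherits(object, "pmvae"), n_steps >= 1)
  x <- .align_genes(object, x)
  Cmat <- .model_conditions(object, conditions, nrow(x))
  nm <- object$masks$meta$latent_names
  if (is.character(node)) node <- match(node, nm)
  stopifnot(length(node) == 1, !is.na(node), node >= 1,
            node <= object$masks$meta$D)
  N <- ncol(x)
  xp <- if (is.numeric(baseline)) {
    stopifnot(length(baseline) == N)
    as.numeric(baseline)
  } else switch(match.arg(baseline),
                dataset_mean = colMeans(x),
                zeros = numeric(N))
  Xp <- matrix(xp, nrow(x), N, byrow = TRUE)
  dX <- x - Xp
  G <- matrix(0, nrow(x), N)
  for (t in seq_len(n_steps)) {
    alpha <- (t - 0.5) / n_steps
    g <- .encoder_node_grad(object, Xp + alpha * dX, Cmat, node)
    if (any(!is.finite(g$dx)))
      .stopf("non-finite gradient at alpha = %.6f", alpha)
    G <- G + g$dx
  }
  local <- dX * G / n_steps
  colnames(local) <- object$masks$meta$genes
  structure(list(node = nm[node], node_index = as.integer(node),
                 local = local, global = colMeans(abs(local)),
                 baseline = xp, n_steps = as.integer(n_steps)),
            class = "gene_attribution")
}

#' @export
print.gene_attribution <- function(x, ...) {
  cat(sprintf("Gene attributions for latent node '%s': %d samples x %d genes\n",
              x$node, nrow(x$local), ncol(x$local)))
  top <- utils::head(order(-x$global), 5)
  for (i in top)
    cat(sprintf("  %-20s %10.4f\n", colnames(x$local)[i], x$global[i]))
  invisible(x)
}

#' Write attribution tables as TSV
#'
#' For pathway attributions, writes (pathway, attribution, importance,
#' rank); for gene attributions, (gene, attribution, rank).
#'
#' @param x A `pause_attribution` or `gene_attribution`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_attribution_tsv <- function(x, path) {
  if (inherits(x, "pause_attribution")) {
    imp <- -x$pathway_global
    ord <- order(-imp, names(imp))
    df <- data.frame(pathway = names(imp), attribution = x$pathway_global,
                     importance = imp, row.names = NULL)[ord, ]
    df$rank <- seq_len(nrow(df))
  } else if (inherits(x, "gene_attribution")) {
    ord <- order(-x$global, names(x$global))
    df <- data.frame(gene = names(x$global), attribution = x$global,
                     row.names = NULL)[ord, ]
    df$rank <- seq_len(nrow(df))
  } else .stopf("unsupported object of class %s", class(x)[1])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
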