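#' Fit a pathway-module variational autoencoder
#'
#' Trains a VAE whose encoder and decoder are partitioned by binary masks
#' into independent per-pathway modules that sum at the output layer.
#' Each module sees only the genes of its pathway (plus any condition
#' indicators), passes them through one hidden layer of `hidden_per_module`
#' units with batch normalization and an ELU activation, and parameterizes
#' a diagonal Gaussian posterior over its `latent_per_module` latent nodes.
#' The training objective is the (weighted) ELBO with Gaussian
#' reconstruction likelihood, plus the module-weighted local reconstruction
#' loss and, for conditional models, an HSIC penalty enforcing independence
#' between the latent embedding and the condition labels.
#'
#' Optimization uses Adam with reduce-on-plateau annealing: after
#' `lr_patience` consecutive epochs in which the held-out global
#' reconstruction error did not reach a new minimum, the learning rate is
#' divided by `lr_decay_factor`; the checkpoint with the lowest
#' validation reconstruction error is returned.  Masks are re-applied
#' after every update, so masked weights are exactly zero at all times.
#'
#' @param x Expression matrix (samples x genes), assumed library-size
#'   normalized and log transformed, with gene names as column names when
#'   `gene_sets` is given.
#' @param gene_sets A `gmt_collection` (filtered internally against
#'   `colnames(x)` with `min_genes`) defining the pathway modules.
#'   Alternatively supply `membership` or `masks` directly.
#' @param membership Optional precomputed [build_membership()] result.
#' @param masks Optional precomputed [build_masks()] result.
#' @param conditions Optional per-sample nuisance labels (factor, character
#'   or indicator matrix).  When given the model is a conditional pmVAE:
#'   the labels are appended to every module's input in the encoder and to
#'   every module's latent block in the decoder, and the HSIC penalty is
#'   switched on.
#' @param min_genes Minimum genes per retained set (see
#'   [filter_gene_sets()]).
#' @param hidden_per_module,latent_per_module Module sizes (defaults 12
#'   hidden units, 1 latent node).
#' @param dense_module If `TRUE`, add an auxiliary module connected to all
#'   genes.
#' @param kl_weight Weight of the KL term (default 1, the plain ELBO).
#' @param hsic_weight Weight of the HSIC penalty; defaults to 1e6 for
#'   conditional models and 0 otherwise.
#' @param learning_rate,max_epochs,batch_size,lr_decay_factor,lr_floor,
#'   validation_fraction Optimization controls.
#' @param lr_patience Consecutive epochs without a new best validation
#'   reconstruction error before the learning rate is divided by
#'   `lr_decay_factor` (default 2; plateau tolerance for small datasets
#'   where per-epoch validation error is noisy).
#' @param seed Integer seed controlling initialization, the validation
#'   split, shuffling and the reparameterization draws; the whole fit is
#'   reproducible given `seed`.
#' @param verbose Print per-epoch progress.
#' @return An object of class `pmvae` with elements `params`, `buffers`,
#'   `masks`, `membership`, `config`, `history` (per-epoch loss
#'   components on training and validation splits), `best_epoch`, and
#'   `condition_levels`.
#' @seealso [pathway_attributions()], [gene_attributions()],
#'   [impute_benchmark()], [simulate_pathway_data()]
#' @export
pmvae <- function(x, gene_sets = NULL, membership = NULL, masks = NULL,
                  conditions = NULL, min_genes = 13L,
                  hidden_per_module = 12L, latent_per_module = 1L,
                  dense_module = FALSE,
                  kl_weight = 1, hsic_weight = NULL,
                  learning_rate = 1e-3, max_epochs = 200L,
                  batch_size = 256L, lr_decay_factor = 10,
                  lr_floor = 1e-7, lr_patience = 2L,
                  validation_fraction = 0.25,
                  seed = 1L, verbose = FALSE) {
  x <- .check_matrix(x, "x")
  stopifnot(validation_fraction > 0, validation_fraction < 1,
            kl_weight >= 0, learning_rate > 0, max_epochs >= 1)

  cond_levels <- NULL
  if (!is.null(conditions) && !is.matrix(conditions)) {
    f <- factor(conditions)
    cond_levels <- levels(f)
    conditions <- .condition_matrix(f)
  }
  n_conditions <- if (is.null(conditions)) 0L else ncol(conditions)
  if (!is.null(conditions) && nrow(conditions) != nrow(x))
    .stopf("'conditions' has %d rows; expected %d", nrow(conditions), nrow(x))

  if (is.null(masks)) {
    if (is.null(membership)) {
      if (is.null(gene_sets))
        .stopf("supply one of 'gene_sets', 'membership' or 'masks'")
      if (is.null(colnames(x)))
        .stopf("'x' must have gene names as column names when 'gene_sets' is used")
      gene_sets <- filter_gene_sets(gene_sets, colnames(x), min_genes)
      membership <- build_membership(gene_sets, colnames(x))
      if (length(membership$unassigned) > 0 && !dense_module)
        message(sprintf("excluding %d genes annotated to no retained pathway",
                        length(membership$unassigned)))
    }
    masks <- build_masks(membership, hidden_per_module, latent_per_module,
                         n_conditions, dense_module)
  }
  m <- masks$meta
  if (m$n_conditions != n_conditions)
    .stopf("masks built for %d conditions but %d supplied",
           m$n_conditions, n_conditions)
  if (!is.null(colnames(x))) {
    if (!all(m$genes %in% colnames(x)))
      .stopf("model genes missing from 'x': %s",
             paste(utils::head(setdiff(m$genes, colnames(x)), 5), collapse = ", "))
    x <- x[, m$genes, drop = FALSE]
  } else if (ncol(x) != m$N) {
    .stopf("'x' has %d columns; model expects %d genes", ncol(x), m$N)
  }

  if (is.null(hsic_weight)) hsic_weight <- if (n_conditions > 0) 1e6 else 0
  stopifnot(hsic_weight >= 0)
  config <- list(hidden_per_module = m$hidden_per_module,
                 latent_per_module = m$latent_per_module,
                 n_conditions = n_conditions, dense_module = m$dense_module,
                 kl_weight = kl_weight, hsic_weight = hsic_weight,
                 learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 lr_decay_factor = lr_decay_factor, lr_floor = lr_floor,
                 lr_patience = as.integer(lr_patience),
                 validation_fraction = validation_fraction,
                 activation = "elu", seed = as.integer(seed))

  set.seed(config$seed)
  init <- .init_params(masks)
  params <- .apply_masks(init$params, masks)
  fit <- .train_pmvae(params, init$buffers, masks, x, conditions, config,
                      verbose = verbose)
  structure(list(
    params = fit$params, buffers = fit$buffers, masks = masks,
    membership = membership, config = config, history = fit$history,
    best_epoch = fit$best_epoch, val_idx = fit$val_idx,
    condition_levels = cond_levels,
    n_train = nrow(x), trained = TRUE, call = match.call()
  ), class = "pmvae")
}

#' Initialize an untrained pathway-module VAE
#'
#' Builds a `pmvae` object with seeded, masked parameter initialization and
#' no training; mainly useful for tests and for inspecting the
#' architecture.
#'
#' @param masks A [build_masks()] result.
#' @param kl_weight,hsic_weight Loss weights stored in the config.
#' @param seed Integer seed for the deterministic initialization.
#' @return An untrained object of class `pmvae`.
#' @export
init_pmvae <- function(masks, kl_weight = 1, hsic_weight = 0, seed = 1L) {
  stopifnot(inherits(masks, "pmvae_masks"))
  set.seed(seed)
  init <- .init_params(masks)
  config <- list(hidden_per_module = masks$meta$hidden_per_module,
                 latent_per_module = masks$meta$latent_per_module,
                 n_conditions = masks$meta$n_conditions,
                 dense_module = masks$meta$dense_module,
                 kl_weight = kl_weight, hsic_weight = hsic_weight,
                 learning_rate = 1e-3, max_epochs = 0L, batch_size = 256L,
                 lr_decay_factor = 10, lr_floor = 1e-7,
                 validation_fraction = 0.25, activation = "elu",
                 seed = as.integer(seed))
  structure(list(params = .apply_masks(init$params, masks),
                 buffers = init$buffers, masks = masks, membership = NULL,
                 config = config, history = NULL, best_epoch = 0L,
                 val_idx = integer(), condition_levels = NULL,
                 n_train = 0L, trained = FALSE, call = match.call()),
            class = "pmvae")
}

# Reorder data columns to the model's gene order when names are available.
.align_genes <- function(object, x) {
  x <- .check_matrix(x, "x")
  genes <- object$masks$meta$genes
  if (!is.null(colnames(x))) {
    if (!all(genes %in% colnames(x)))
      .stopf("data is missing model gene(s): %s",
             paste(utils::head(setdiff(genes, colnames(x)), 5), collapse = ", "))
    x <- x[, genes, drop = FALSE]
  } else if (ncol(x) != length(genes)) {
    .stopf("data has %d columns; model expects %d genes", ncol(x), length(genes))
  }
  x
}

.model_conditions <- function(object, conditions, n) {
  if (object$config$n_conditions == 0L) {
    if (!is.null(conditions))
      .stopf("model is unconditional; 'conditions' must be NULL")
    return(NULL)
  }
  if (is.null(conditions))
    .stopf("model is conditional; supply 'conditions'")
  Cmat <- .condition_matrix(conditions, levels = object$condition_levels)
  if (nrow(Cmat) != n)
    .stopf("'conditions' has %d rows; expected %d", nrow(Cmat), n)
  if (ncol(Cmat) != object$config$n_conditions)
    .stopf("'conditions' encodes %d columns; model expects %d",
           ncol(Cmat), object$config$n_conditions)
  Cmat
}

#' Encode expression into per-module posterior parameters
#'
#' Deterministic eval-mode pass (batch normalization uses running
#' statistics).  Module p's outputs depend only on the genes of pathway p
#' and on the condition labels.
#'
#' @param object A `pmvae` model.
#' @param x Expression batch (samples x genes).
#' @param conditions Condition labels for conditional models.
#' @return A list with `mu` and `log_var` (samples x D matrices, columns
#'   named by latent node).
#' @export
encode <- function(object, x, conditions = NULL) {
  stopifnot(inherits(object, "pmvae"))
  x <- .align_genes(object, x)
  Cmat <- .model_conditions(object, conditions, nrow(x))
  enc <- .encode_eval(object$params, object$buffers, object$masks, x, Cmat)
  nm <- object$masks$meta$latent_names
  colnames(enc$mu) <- nm; colnames(enc$log_var) <- nm
  list(mu = enc$mu, log_var = enc$log_var)
}

#' Decode latent embeddings into reconstructions
#'
#' Deterministic eval-mode pass.  The full reconstruction is the sum of
#' the per-module reconstructions, each supported only on its pathway's
#' genes (the dense module, when present, covers all genes).
#'
#' @param object A `pmvae` model.
#' @param z Latent batch (samples x D).
#' @param conditions Condition labels for conditional models.
#' @param per_module If `TRUE`, also return the list of per-module
#'   reconstructions.
#' @return The reconstruction matrix, or (with `per_module = TRUE`) a list
#'   with `xhat` and `modules`.
#' @export
decode <- function(object, z, conditions = NULL, per_module = FALSE) {
  stopifnot(inherits(object, "pmvae"))
  z <- as.matrix(z)
  if (ncol(z) != object$masks$meta$D)
    .stopf("'z' has %d columns; model latent dimension is %d",
           ncol(z), object$masks$meta$D)
  Cmat <- .model_conditions(object, conditions, nrow(z))
  dec <- .decode_eval(object$params, object$buffers, object$masks, z, Cmat,
                      per_module = per_module)
  colnames(dec$xhat) <- object$masks$meta$genes
  if (per_module) list(xhat = dec$xhat, modules = dec$modules) else dec$xhat
}

#' @export
print.pmvae <- function(x, ...) {
  m <- x$masks$meta
  cat(sprintf("%s pathway-module VAE\n",
              if (m$n_conditions > 0) "Conditional" else "Unconditional"))
  cat(sprintf("  %d genes -> %d modules (%d hidden, %d latent each) -> %d latent nodes\n",
              m$N, m$K, m$hidden_per_module, m$latent_per_module, m$D))
  if (isTRUE(x$trained)) {
    h <- x$history
    cat(sprintf("  trained %d epochs on %d samples; best epoch %d (val recon %.4f)\n",
                nrow(h), x$n_train, x$best_epoch,
                h$val_recon_global[x$best_epoch]))
  } else cat("  untrained (initialized only)\n")
  invisible(x)
}

#' @export
summary.pmvae <- function(object, ...) {
  m <- object$masks$meta
  out <- list(
    modules = m$K, genes = m$N, latent = m$D,
    conditional = m$n_conditions > 0,
    trained = isTRUE(object$trained),
    best_epoch = object$best_epoch,
    config = object$config,
    final = if (!is.null(object$history))
      object$history[nrow(object$history), ] else NULL,
    best = if (!is.null(object$history))
      object$history[object$best_epoch, ] else NULL)
  class(out) <- "summary.pmvae"
  out
}

#' @export
print.summary.pmvae <- function(x, ...) {
  cat(sprintf("pmVAE: %d modules over %d genes, %d latent nodes%s\n",
              x$modules, x$genes, x$latent,
              if (x$conditional) " (conditional + HSIC)" else ""))
  if (x$trained) {
    cat(sprintf("  best epoch %d: val recon %.4f, local %.4f, KL %.4f, HSIC %.3g\n",
                x$best_epoch, x$best$val_recon_global, x$best$val_recon_local,
                x$best$val_kl, x$best$val_hsic))
  }
  invisible(x)
}

#' Predict method for pmVAE models
#'
#' @param object A fitted `pmvae`.
#' @param newdata Expression matrix (samples x genes).
#' @param conditions Condition labels for conditional models.
#' @param type `"reconstruction"` (decode the posterior mean),
#'   `"latent"` (posterior means), `"log_var"` (posterior log-variances)
#'   or `"modules"` (list of per-module reconstructions).
#' @param sample If `TRUE`, decode a reparameterized posterior draw
#'   instead of the mean.
#' @param seed Seed for the posterior draw when `sample = TRUE`.
#' @param ... Unused.
#' @return A matrix (or list for `type = "modules"`).
#' @export
predict.pmvae <- function(object, newdata, conditions = NULL,
                          type = c("reconstruction", "latent", "log_var",
                                   "modules"),
                          sample = FALSE, seed = NULL, ...) {
  type <- match.arg(type)
  enc <- encode(object, newdata, conditions)
  if (type == "latent") return(enc$mu)
  if (type == "log_var") return(enc$log_var)
  z <- if (sample) reparameterize(enc, seed = seed) else enc$mu
  if (type == "modules")
    decode(object, z, conditions, per_module = TRUE)$modules
  else decode(object, z, conditions)
}

#' @export
residuals.pmvae <- function(object, newdata, conditions = NULL, ...) {
  x <- .align_genes(object, newdata)
  x - predict(object, newdata, conditions)
}

#' @export
coef.pmvae <- function(object, ...) object$params

#' Simulate expression from the generative model
#'
#' Draws latent vectors from the standard-normal prior and decodes them,
#' optionally adding Gaussian observation noise.
#'
#' @param object A fitted `pmvae`.
#' @param nsim Number of samples to draw.
#' @param seed Optional seed.
#' @param conditions Condition labels (length `nsim`) for conditional
#'   models.
#' @param noise_sd Observation noise standard deviation (default 0).
#' @param ... Unused.
#' @return An `nsim` x genes matrix.
#' @export
simulate.pmvae <- function(object, nsim = 1, seed = NULL, conditions = NULL,
                           noise_sd = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  D <- object$masks$meta$D
  z <- matrix(stats::rnorm(nsim * D), nsim, D)
  x <- decode(object, z, conditions)
  if (noise_sd > 0) x <- x + matrix(stats::rnorm(length(x), 0, noise_sd),
                                    nrow(x))
  x
}

#' Plot pmVAE training history
#'
#' Training and validation global reconstruction error by epoch, with the
#' best-checkpoint epoch marked.
#'
#' @param x A fitted `pmvae`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.pmvae <- function(x, ...) {
  h <- x$history
  if (is.null(h)) .stopf("model has no training history")
  graphics::matplot(h$epoch, cbind(h$train_recon_global, h$val_recon_global),
                    type = "l", lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "global reconstruction error", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Save and load pmVAE checkpoints
#'
#' A checkpoint is a single-file archive of parameters, masks, orderings,
#' config and package version; loading verifies the stored gene-order
#' hash.
#'
#' @param object A `pmvae`.
#' @param path Checkpoint file path.
#' @return `save_pmvae` returns `path` invisibly; `load_pmvae` the model.
#' @export
save_pmvae <- function(object, path) {
  stopifnot(inherits(object, "pmvae"))
  object$gene_hash <- .gene_hash(object$masks$meta$genes)
  object$pkg_version <- as.character(utils::packageVersion("pmvae"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_pmvae
#' @export
load_pmvae <- function(path) {
  object <- readRDS(path)
  if (!inherits(object, "pmvae")) .stopf("'%s' is not a pmvae checkpoint", path)
  if (!identical(object$gene_hash, .gene_hash(object$masks$meta$genes)))
    .stopf("checkpoint gene-order hash mismatch; file is corrupt")
  object
}

.gene_hash <- function(genes) {
  # order-sensitive polynomial rolling hash; avoids a digest dependency
  s <- paste(genes, collapse = "\r")
  v <- utf8ToInt(s)
  h <- 0
  for (ch in v) h <- (h * 131 + ch) %% 2147483647
  sprintf("%d:%d", length(genes), h)
}
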