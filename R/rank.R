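# Baseline pathway-importance scores and the impute/retrain ablation
# benchmarks that validate a ranking, plus the k-means/ARI batch-mixing
# diagnostic.

.new_ranking <- function(method, pathways, scores, seed = NULL) {
  stopifnot(length(pathways) == length(scores))
  names(scores) <- pathways
  ord <- order(-scores, pathways)      # descending importance, lexicographic ties
  structure(list(method = method, pathways = pathways, scores = scores,
                 order = ord, seed = seed),
            class = "pathway_ranking")
}

#' @export
print.pathway_ranking <- function(x, ...) {
  cat(sprintf("Pathway ranking (%s): %d pathways\n", x$method,
              length(x$pathways)))
  top <- utils::head(x$order, 5)
  for (i in seq_along(top))
    cat(sprintf("  %2d. %-30s %10.4f\n", i, x$pathways[top[i]],
                x$scores[top[i]]))
  invisible(x)
}

#' Latent-node index slices per pathway module
#'
#' @param x A `pmvae` model or `pmvae_masks` object.
#' @return Named list of latent column indices, one per module.
#' @export
module_latent_slices <- function(x) {
  masks <- if (inherits(x, "pmvae")) x$masks else x
  stopifnot(inherits(masks, "pmvae_masks"))
  lapply(masks$module_slices, `[[`, "latent")
}

# Small ridge-penalized logistic regression by IRLS; intercept
# unpenalized.  Used instead of glmnet because the benchmark models have a
# single latent node per pathway and glmnet requires >= 2 predictors.
.ridge_logistic <- function(X, y, lambda = 1, maxit = 50L, tol = 1e-9) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X1 * W, X1) + pen
    g <- crossprod(X1, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

#' Supervised logistic-regression (LR) pathway score
#'
#' For each pathway, the 5-fold stratified cross-validated accuracy of an
#' L2-regularized logistic regression classifying a binary perturbation
#' label from that pathway's latent nodes only.
#'
#' @param latents Latent embedding matrix (samples x D).
#' @param labels Binary labels (two classes required).
#' @param slices Named list of latent column indices per pathway (see
#'   [module_latent_slices()]).
#' @param folds Number of CV folds.
#' @param lambda Ridge penalty (default 1).
#' @param seed Seed for the fold assignment.
#' @return A `pathway_ranking` (method `"lr"`).
#' @export
lr_score <- function(latents, labels, slices, folds = 5L, lambda = 1,
                     seed = 1L) {
  latents <- as.matrix(latents)
  y <- as.integer(factor(labels)) - 1L
  if (length(unique(y)) < 2)
    .stopf("LR score requires two classes in 'labels'")
  stopifnot(length(y) == nrow(latents))
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  acc <- vapply(slices, function(cols) {
    Xp <- latents[, cols, drop = FALSE]
    hits <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f
      beta <- .ridge_logistic(Xp[tr, , drop = FALSE], y[tr], lambda)
      pr <- drop(cbind(1, Xp[!tr, , drop = FALSE]) %*% beta) > 0
      hits <- hits + sum(pr == (y[!tr] == 1L))
    }
    hits / length(y)
  }, 0)
  .new_ranking("lr", names(slices), acc, seed = seed)
}

#' KL-divergence pathway score
#'
#' Mean over samples of the per-dimension KL divergence of the learned
#' posterior from the standard-normal prior, summed over each module's
#' latent nodes.
#'
#' @param mu,log_var Posterior parameters over the dataset (samples x D).
#' @param slices Latent column indices per pathway.
#' @return A `pathway_ranking` (method `"kld"`).
#' @export
kld_score <- function(mu, log_var, slices) {
  if (is.null(log_var))
    .stopf("KLD requires variational posterior (no log-variance available)")
  per_dim <- kl_term(mu, log_var)$per_dim
  s <- vapply(slices, function(cols) sum(per_dim[cols]), 0)
  .new_ranking("kld", names(slices), s)
}

#' Latent-space-scale (LSV) pathway score
#'
#' Default mode follows the learned posterior scale parameter: the mean
#' over samples and module dimensions of `sigma = exp(log_var / 2)`.  The
#' alternative reading, the variance of the posterior means across the
#' dataset, is available as `mode = "variance_of_means"`.
#'
#' @param mu,log_var Posterior parameters over the dataset.
#' @param slices Latent column indices per pathway.
#' @param mode `"scale"` or `"variance_of_means"`.
#' @return A `pathway_ranking` (method `"lsv"`).
#' @export
lsv_score <- function(mu, log_var, slices,
                      mode = c("scale", "variance_of_means")) {
  mode <- match.arg(mode)
  if (mode == "scale" && is.null(log_var))
    .stopf("LSV requires variational posterior (no log-variance available)")
  s <- if (mode == "scale") {
    sig <- exp(0.5 * as.matrix(log_var))
    vapply(slices, function(cols) mean(sig[, cols, drop = FALSE]), 0)
  } else {
    v <- apply(as.matrix(mu), 2, stats::var)
    vapply(slices, function(cols) mean(v[cols]), 0)
  }
  .new_ranking("lsv", names(slices), s)
}

#' Random pathway ranking
#'
#' @param pathways Pathway names (or an integer count).
#' @param seed Seed for the uniform permutation.
#' @return A `pathway_ranking` (method `"random"`).
#' @export
random_score <- function(pathways, seed = 1L) {
  if (is.numeric(pathways) && length(pathways) == 1)
    pathways <- paste0("P", seq_len(pathways))
  set.seed(seed)
  # scores are a random permutation of ranks, so the order is uniform
  s <- sample(length(pathways))
  .new_ranking("random", pathways, as.numeric(s), seed = seed)
}

#' Trapezoidal area under a curve
#'
#' @param xs Strictly increasing x coordinates.
#' @param ys y coordinates (same length).
#' @return The trapezoid-rule area.
#' @export
trapezoid_auc <- function(xs, ys) {
  stopifnot(length(xs) == length(ys), length(xs) >= 2)
  if (any(diff(xs) <= 0)) .stopf("'xs' must be strictly increasing")
  sum(0.5 * (ys[-1] + ys[-length(ys)]) * diff(xs))
}

#' Impute ablation benchmark
#'
#' Progressively replaces the latent nodes of the top-ranked pathways with
#' an uninformative constant (the per-dimension mean embedding over the
#' test data by default), decodes, and records the mean squared
#' reconstruction error after each removal.  Better rankings make the
#' error rise faster, giving a larger AUC.  The k = 0 and k = K endpoints
#' are identical for every ranking.
#'
#' @param object A fitted `pmvae`.
#' @param x Held-out expression matrix.
#' @param ranking A `pathway_ranking` over the model's modules.
#' @param conditions Condition labels for conditional models.
#' @param baseline `"dataset_mean"` or `"zeros"`: the imputation constant.
#' @return An object of class `benchmark_curve` with `xs` (fraction of
#'   pathways removed), `ys` (test MSE per expression entry), `auc` and
#'   `method`.
#' @export
impute_benchmark <- function(object, x, ranking, conditions = NULL,
                             baseline = c("dataset_mean", "zeros")) {
  stopifnot(inherits(object, "pmvae"), inherits(ranking, "pathway_ranking"))
  x <- .align_genes(object, x)
  Cmat <- .model_conditions(object, conditions, nrow(x))
  slices <- module_latent_slices(object)
  if (!setequal(ranking$pathways, names(slices)))
    .stopf("ranking pathways do not match the model's modules")
  Z <- .encode_eval(object$params, object$buffers, object$masks, x, Cmat)$mu
  zbase <- switch(match.arg(baseline),
                  dataset_mean = colMeans(Z),
                  zeros = numeric(ncol(Z)))
  K <- length(slices)
  ord_names <- ranking$pathways[ranking$order]
  ys <- numeric(K + 1)
  Zk <- Z
  for (k in 0:K) {
    if (k > 0) {
      cols <- slices[[ord_names[k]]]
      Zk[, cols] <- matrix(zbase[cols], nrow(Z), length(cols), byrow = TRUE)
    }
    xhat <- .decode_eval(object$params, object$buffers, object$masks, Zk,
                         Cmat)$xhat
    ys[k + 1] <- mean((x - xhat)^2)
  }
  xs <- (0:K) / K
  structure(list(method = ranking$method, xs = xs, ys = ys,
                 auc = trapezoid_auc(xs, ys), baseline = zbase),
            class = "benchmark_curve")
}

#' Retrain ablation benchmark
#'
#' For each k in `schedule`, keeps only the top-k ranked pathways, trains
#' a fresh seeded model on the training split, and records the held-out
#' mean squared error over the full gene space (genes outside the kept
#' pathways are predicted by their training means).  Better rankings
#' decrease the error faster, giving a smaller AUC.
#'
#' @param train_x,test_x Training and held-out expression matrices
#'   (samples x genes, shared gene names).
#' @param ranking A `pathway_ranking`.
#' @param membership The full `pathway_membership` the ranking refers to.
#' @param schedule Increasing integer vector of k values; defaults to
#'   `1:K` when K <= 20 and a geometric subset otherwise (retraining is
#'   the expensive benchmark).
#' @param seed Seed passed to each retrained model.
#' @param ... Further arguments to [pmvae()] (epochs, sizes, ...).
#' @return A `benchmark_curve`; `xs` is the fraction of pathways kept.
#' @export
retrain_benchmark <- function(train_x, test_x, ranking, membership,
                              schedule = NULL, seed = 1L, ...) {
  stopifnot(inherits(ranking, "pathway_ranking"),
            inherits(membership, "pathway_membership"))
  train_x <- .check_matrix(train_x, "train_x")
  test_x <- .check_matrix(test_x, "test_x")
  K <- length(membership$pathways)
  if (is.null(schedule)) {
    schedule <- if (K <= 20) seq_len(K)
    else unique(round(exp(seq(log(1), log(K), length.out = 12))))
  }
  schedule <- as.integer(schedule)
  stopifnot(all(schedule >= 1), all(schedule <= K), !is.unsorted(schedule))
  ord_names <- ranking$pathways[ranking$order]
  gene_means <- colMeans(train_x)
  ys <- numeric(length(schedule))
  for (i in seq_along(schedule)) {
    k <- schedule[i]
    keep <- ord_names[seq_len(k)]
    sub <- .subset_membership(membership, keep)
    if (length(sub$genes) == 0)
      .stopf("top-%d pathways cover zero genes", k)
    fit <- pmvae(train_x[, sub$genes, drop = FALSE], membership = sub,
                 seed = seed, ...)
    pred <- matrix(gene_means, nrow(test_x), ncol(test_x), byrow = TRUE,
                   dimnames = dimnames(test_x))
    pred[, sub$genes] <- predict(fit, test_x[, sub$genes, drop = FALSE])
    ys[i] <- mean((test_x - pred)^2)
  }
  xs <- schedule / K
  structure(list(method = ranking$method, xs = xs, ys = ys,
                 auc = trapezoid_auc(xs, ys), schedule = schedule,
                 seed = seed),
            class = "benchmark_curve")
}

.subset_membership <- function(membership, keep) {
  M <- membership$M[, keep, drop = FALSE]
  genes <- membership$genes[rowSums(M) > 0]
  structure(list(genes = genes, pathways = keep,
                 M = M[genes, , drop = FALSE],
                 sizes = colSums(M[genes, , drop = FALSE]),
                 unassigned = character()),
            class = "pathway_membership")
}

#' @export
print.benchmark_curve <- function(x, ...) {
  cat(sprintf("Benchmark curve (%s): %d points, AUC = %.4f\n",
              x$method, length(x$xs), x$auc))
  invisible(x)
}

#' @export
plot.benchmark_curve <- function(x, ...) {
  graphics::plot(x$xs, x$ys, type = "b", pch = 16,
                 xlab = "fraction of pathways", ylab = "test MSE", ...)
  invisible(x)
}

#' Write a benchmark curve as TSV
#'
#' @param curve A `benchmark_curve`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_curve_tsv <- function(curve, path) {
  utils::write.table(data.frame(x = curve$xs, y = curve$ys),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Batch-mixing diagnostic: k-means + adjusted Rand index
#'
#' Clusters the latent embedding with k-means (k = number of batches, 10
#' seeded restarts) and returns the adjusted Rand index between cluster
#' assignments and batch labels.  Values near 0 indicate a well-mixed
#' embedding; values near 1 indicate clustering by batch.
#'
#' @param latents Latent embedding (samples x D).
#' @param batch Batch labels (>= 2 distinct values).
#' @param seed Seed for the k-means restarts.
#' @param nstart Number of k-means restarts.
#' @return Scalar ARI.
#' @export
batch_ari <- function(latents, batch, seed = 1L, nstart = 10L) {
  batch <- factor(batch)
  k <- nlevels(batch)
  if (k < 2) .stopf("batch ARI requires >= 2 batches")
  set.seed(seed)
  cl <- stats::kmeans(as.matrix(latents), centers = k, nstart = nstart,
                      iter.max = 50L)$cluster
  mclust::adjustedRandIndex(cl, batch)
}

#' Paired Wilcoxon signed-rank comparison of benchmark AUCs
#'
#' Reporting utility for comparing two methods' AUC distributions across
#' train/test splits, using the exact small-sample null.
#'
#' @param auc_a,auc_b Paired AUC vectors.
#' @param alternative Passed to [stats::wilcox.test()].
#' @return The `htest` object.
#' @export
compare_aucs <- function(auc_a, auc_b, alternative = "two.sided") {
  stopifnot(length(auc_a) == length(auc_b))
  stats::wilcox.test(auc_a, auc_b, paired = TRUE, exact = TRUE,
                     alternative = alternative)
}
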