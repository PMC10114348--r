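test_that("initialization is seeded, masked and shaped by the architecture", {
  masks <- build_masks(toy_membership(), 2, 1)
  m1 <- init_pmvae(masks, seed = 9)
  m2 <- init_pmvae(masks, seed = 9)
  expect_identical(m1$params, m2$params)
  expect_true(all(m1$params$W_e1[masks$assignment == 0] == 0))
  expect_true(all(m1$params$W_mu[masks$sep_enc == 0] == 0))
  expect_true(all(m1$params$W_d2[masks$out == 0] == 0))
  expect_identical(masks$meta$D, 2L)  # 2 pathways x 1 latent
})

test_that("encoder respects module separation and shapes", {
  masks <- build_masks(toy_membership(), 2, 1)
  model <- init_pmvae(masks, seed = 1)
  x <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("g1", "g2", "g3")))
  enc <- encode(model, x)
  expect_identical(dim(enc$mu), c(5L, 2L))
  # g3 is not in P1: perturbing it cannot move module 1's posterior
  x2 <- x; x2[, "g3"] <- x2[, "g3"] + 10
  enc2 <- encode(model, x2)
  expect_identical(enc$mu[, 1], enc2$mu[, 1])
  expect_false(all(enc$mu[, 2] == enc2$mu[, 2]))
  expect_error(encode(model, x[, 1:2]), "missing model gene")
})

test_that("conditions reach every module in a conditional model", {
  masks <- build_masks(toy_membership(), 2, 1, n_conditions = 2)
  model <- init_pmvae(masks, seed = 3)
  model$condition_levels <- c("a", "b")
  model$config$n_conditions <- 2L
  x <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("g1", "g2", "g3")))
  e1 <- encode(model, x, conditions = rep("a", 4))
  e2 <- encode(model, x, conditions = rep("b", 4))
  expect_true(all(abs(e1$mu - e2$mu) > 0))
})

test_that("decoder outputs are the sum of masked per-module reconstructions", {
  masks <- build_masks(toy_membership(), 2, 1)
  model <- init_pmvae(masks, seed = 2)
  z <- matrix(rnorm(8), 4, 2)
  dec <- decode(model, z, per_module = TRUE)
  expect_equal(dec$xhat, Reduce(`+`, dec$modules), tolerance = 1e-12)
  expect_true(all(dec$modules[["P1"]][, "g3"] == 0))
  expect_true(all(dec$modules[["P2"]][, "g1"] == 0))
  # zeroing module 2's latent only moves genes of P2 (g2, g3)
  z0 <- z; z0[, 2] <- 0
  d0 <- decode(model, z0)
  expect_identical(dec$xhat[, "g1"], d0[, "g1"])
  expect_false(all(dec$xhat[, "g3"] == d0[, "g3"]))
})

test_that("local reconstruction loss matches the worked module-weighted form", {
  M <- matrix(c(1L, 1L, 0L, 0L,
                0L, 0L, 1L, 0L), 4, 2,
              dimnames = list(paste0("g", 1:4), c("PA", "PB")))
  mem <- structure(list(genes = rownames(M), pathways = colnames(M), M = M,
                        sizes = colSums(M), unassigned = character()),
                   class = "pathway_membership")
  x <- matrix(0, 1, 4)
  mods <- list(matrix(c(1, -1), 1, 2), matrix(2, 1, 1))
  expect_identical(local_recon_loss(mods, x, mem), 10)
  # perfect reconstruction and quadratic homogeneity
  expect_identical(local_recon_loss(list(matrix(0, 1, 2), matrix(0, 1, 1)),
                                    x, mem), 0)
  mods2 <- lapply(mods, function(m) 2 * m)
  expect_identical(local_recon_loss(mods2, x, mem), 40)
})

test_that("KL closed form matches hand values and Monte Carlo", {
  expect_equal(kl_term(matrix(0), matrix(0))$total, 0)
  expect_equal(kl_term(matrix(1), matrix(0))$total, 0.5)
  expect_equal(kl_term(matrix(2), matrix(0))$total, 2.0)

  set.seed(88)
  mu <- runif(1, -2, 2); lv <- runif(1, -1, 1)
  n <- 2e5
  z <- rnorm(n, mu, exp(0.5 * lv))
  logq <- dnorm(z, mu, exp(0.5 * lv), log = TRUE)
  logp <- dnorm(z, 0, 1, log = TRUE)
  mc <- mean(logq - logp)
  se <- sd(logq - logp) / sqrt(n)
  expect_lt(abs(kl_term(matrix(mu), matrix(lv))$total - mc), 3 * se)
})

test_that("reparameterization is deterministic and centered on the mean", {
  enc <- list(mu = matrix(1:6 / 2, 2, 3), log_var = matrix(-60, 2, 3))
  expect_equal(reparameterize(enc, seed = 1), enc$mu, tolerance = 1e-12)
  enc$log_var[] <- 0.4
  z1 <- reparameterize(enc, seed = 5)
  z2 <- reparameterize(enc, seed = 5)
  expect_identical(z1, z2)
  big <- list(mu = matrix(0.7, 1e5, 1), log_var = matrix(0.2, 1e5, 1))
  draws <- reparameterize(big, seed = 2)
  se <- exp(0.1) / sqrt(1e5)
  expect_lt(abs(mean(draws) - 0.7), 4 * se)
})

test_that("HSIC matches its explicit kernel-matrix construction", {
  set.seed(31)
  z <- matrix(rnorm(16), 8, 2)
  cmat <- matrix(rnorm(8), 8, 1)
  # independent oracle: loops over the definition
  gauss <- function(a) {
    n <- nrow(a)
    d <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) d[i, j] <- sum((a[i, ] - a[j, ])^2)
    sigma <- median(sqrt(d[upper.tri(d)][d[upper.tri(d)] > 0]))
    exp(-d / (2 * sigma^2))
  }
  K <- gauss(z); L <- gauss(cmat)
  H <- diag(8) - 1 / 8
  oracle <- sum(diag(K %*% H %*% L %*% H)) / 49
  expect_equal(hsic_penalty(z, cmat), oracle, tolerance = 1e-12)
})

test_that("HSIC behaves like a dependence measure", {
  set.seed(7)
  z <- matrix(rnorm(40), 20, 2)
  expect_equal(hsic_penalty(z, factor(rep("a", 20))), 0)
  expect_gt(hsic_penalty(z, z), 0)
  # invariant to a shared row permutation
  cmat <- matrix(rnorm(20), 20, 1)
  p <- sample(20)
  expect_equal(hsic_penalty(z, cmat), hsic_penalty(z[p, ], cmat[p, , drop = FALSE]),
               tolerance = 1e-12)
  # approaches zero in expectation when c is shuffled independently
  h0 <- hsic_penalty(z, cmat)
  hs <- replicate(100, hsic_penalty(z, cmat[sample(20), , drop = FALSE]))
  expect_lt(mean(hs), h0 + 3 * sd(hs))
  expect_error(hsic_penalty(z[1, , drop = FALSE], cmat[1, , drop = FALSE]),
               "2 samples")
})

test_that("loss breakdown is finite and reduces to the pmVAE loss without HSIC", {
  sim <- small_sim()
  masks <- build_masks(sim$membership, 12, 1)
  model <- init_pmvae(masks, seed = 4)
  lb <- pmvae_loss(model, sim$X)
  expect_true(all(vapply(unclass(lb), is.finite, TRUE)))
  expect_gte(lb$kl, 0)
  expect_identical(lb$hsic, 0)
  expect_equal(lb$total, lb$recon_global + lb$kl + lb$recon_local)
})

test_that("training reduces validation error, keeps masks, and is reproducible", {
  fit <- small_model()
  h <- fit$history
  expect_lt(h$val_recon_global[fit$best_epoch], h$val_recon_global[1])
  masks <- fit$masks
  expect_true(all(fit$params$W_e1[masks$assignment == 0] == 0))
  expect_true(all(fit$params$W_d2[masks$out == 0] == 0))
  expect_true(all(fit$params$W_mu[masks$sep_enc == 0] == 0))

  sim <- small_sim()
  f1 <- pmvae(sim$X, gene_sets = sim$gene_sets, min_genes = 3,
              max_epochs = 5, batch_size = 128, seed = 77)
  f2 <- pmvae(sim$X, gene_sets = sim$gene_sets, min_genes = 3,
              max_epochs = 5, batch_size = 128, seed = 77)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("checkpoints round-trip and verify the gene order", {
  fit <- small_model()
  path <- tempfile(fileext = ".rds")
  save_pmvae(fit, path)
  back <- load_pmvae(path)
  expect_identical(back$params, fit$params)
  obj <- readRDS(path)
  obj$masks$meta$genes <- rev(obj$masks$meta$genes)
  saveRDS(obj, path)
  expect_error(load_pmvae(path), "hash")
})

test_that("prediction interfaces agree with encode/decode", {
  fit <- small_model()
  sim <- small_sim()
  x <- sim$X[1:20, ]
  enc <- encode(fit, x)
  expect_identical(predict(fit, x, type = "latent"), enc$mu)
  expect_identical(predict(fit, x), decode(fit, enc$mu))
  r <- residuals(fit, x)
  expect_equal(r, x - predict(fit, x))
  gen <- simulate(fit, nsim = 7, seed = 3)
  expect_identical(dim(gen), c(7L, ncol(x)))
})
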