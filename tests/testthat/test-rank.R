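test_that("LR score separates informative from uninformative latents", {
  set.seed(21)
  n <- 2000
  y <- rep(0:1, each = n / 2)
  latents <- cbind(sep = y * 4 - 2 + rnorm(n, sd = 0.1),  # separable
                   noise = rnorm(n))                      # label-independent
  slices <- list(sep = 1L, noise = 2L)
  rk <- lr_score(latents, y, slices, seed = 4)
  expect_equal(unname(rk$scores[["sep"]]), 1.0)
  expect_lt(abs(rk$scores[["noise"]] - 0.5), 0.05)
  expect_identical(rk$pathways[rk$order[1]], "sep")

  # identical latents get identical scores
  rk2 <- lr_score(cbind(latents[, 1], latents[, 1]), y,
                  list(a = 1L, b = 2L), seed = 4)
  expect_equal(unname(rk2$scores[["a"]]), unname(rk2$scores[["b"]]))
  expect_error(lr_score(latents, rep(1, n), slices), "two classes")
})

test_that("KLD score sums per-dimension divergences within modules", {
  n <- 50
  slices <- list(A = 1:2, B = 3L)
  mu <- cbind(matrix(0, n, 2), 1)
  lv <- matrix(0, n, 3)
  rk <- kld_score(mu, lv, slices)
  expect_equal(unname(rk$scores), c(0, 0.5))
  mu2 <- cbind(matrix(1, n, 2), 0)
  expect_equal(unname(kld_score(mu2, lv, slices)$scores), c(1.0, 0))
  expect_error(kld_score(mu, NULL, slices), "variational")
})

test_that("LSV score reads the posterior scale, or the variance of means", {
  n <- 40
  slices <- list(A = 1L, B = 2L)
  mu <- matrix(0, n, 2)
  lv <- cbind(rep(0, n), rep(1, n))
  rk <- lsv_score(mu, lv, slices)
  expect_equal(unname(rk$scores), c(1, exp(0.5)))

  set.seed(14)
  mu2 <- cbind(rnorm(1e4, sd = 2), rnorm(1e4, sd = 1))
  rk2 <- lsv_score(mu2, NULL, slices, mode = "variance_of_means")
  expect_lt(abs(rk2$scores[["A"]] / 4 - 1), 0.05)
  expect_error(lsv_score(mu2, NULL, slices), "variational")
})

test_that("random ranking is a seeded uniform permutation", {
  r1 <- random_score(letters[1:6], seed = 9)
  r2 <- random_score(letters[1:6], seed = 9)
  expect_identical(r1$order, r2$order)
  expect_setequal(r1$order, 1:6)
  # mean rank of each pathway over many seeds is uniform
  K <- 5
  ranks <- matrix(0, 2000, K)
  for (s in 1:2000) {
    r <- random_score(paste0("P", 1:K), seed = s)
    ranks[s, ] <- match(seq_len(K), r$order)
  }
  se <- sqrt((K^2 - 1) / 12 / 2000)
  expect_true(all(abs(colMeans(ranks) - (K + 1) / 2) < 3 * se))
})

test_that("trapezoid AUC matches hand values and dense quadrature", {
  expect_equal(trapezoid_auc(c(0, 1), c(1, 1)), 1.0)
  expect_equal(trapezoid_auc(c(0, 1), c(0, 1)), 0.5)
  xs <- seq(0, 1, length.out = 1000)
  f <- function(x) x^3 - 0.5 * x + 2
  expect_equal(trapezoid_auc(xs, f(xs)), 1 / 4 - 1 / 4 + 2, tolerance = 1e-6)
  expect_error(trapezoid_auc(c(0, 0.5, 0.5), c(1, 1, 1)), "increasing")
  # inserting a collinear point changes nothing
  expect_equal(trapezoid_auc(c(0, 0.25, 1), c(0, 0.25, 1)),
               trapezoid_auc(c(0, 1), c(0, 1)))
})

test_that("batch ARI matches the contingency-table formula on separated blobs", {
  set.seed(33)
  xy <- rbind(matrix(rnorm(20, 0, 0.05), 10, 2),
              matrix(rnorm(20, 5, 0.05), 10, 2))
  blob <- rep(1:2, each = 10)
  # batch labels disagree with the blobs for 3 points
  batch <- blob; batch[c(1, 2, 11)] <- 3 - batch[c(1, 2, 11)]
  got <- batch_ari(xy, batch, seed = 1)
  # independent oracle: ARI from the contingency table of (blob, batch)
  tab <- table(blob, batch)
  comb2 <- function(v) sum(choose(v, 2))
  idx <- comb2(as.vector(tab))
  e1 <- comb2(rowSums(tab)); e2 <- comb2(colSums(tab))
  expected <- e1 * e2 / choose(20, 2)
  oracle <- (idx - expected) / ((e1 + e2) / 2 - expected)
  expect_equal(got, oracle, tolerance = 1e-12)
  # perfectly batch-separated blobs
  expect_equal(batch_ari(xy, blob, seed = 1), 1.0)
  # shuffled labels: near zero on average
  set.seed(2)
  aris <- replicate(30, batch_ari(xy, sample(blob), seed = 1))
  expect_lt(abs(mean(aris)), 0.15)
  expect_error(batch_ari(xy, rep(1, 20)), "2 batches")
})

test_that("impute benchmark endpoints are ranking-independent and ordered by information", {
  sim <- memo("rank_sim", simulate_pathway_data(
    600, n_pathways = 3, genes_per_pathway = 10, loadings = "unit",
    activity_scales = sqrt(c(0.8, 0.15, 0.05)), noise_sd = 0,
    seed = 17))
  fit <- memo("rank_fit", pmvae(sim$X, gene_sets = sim$gene_sets,
                                min_genes = 3, max_epochs = 80,
                                batch_size = 64, seed = 5))
  shares <- ground_truth_shares(sim)
  oracle <- pmvae:::.new_ranking("oracle", names(shares), shares)
  reversed <- pmvae:::.new_ranking("reversed", names(shares), -shares)
  co <- impute_benchmark(fit, sim$X, oracle)
  cr <- impute_benchmark(fit, sim$X, reversed)
  expect_identical(co$ys[1], cr$ys[1])
  expect_identical(co$ys[4], cr$ys[4])
  expect_identical(co$xs, c(0, 1, 2, 3) / 3)
  expect_gt(co$auc, cr$auc)
  # k = 0 point is the unmodified test error
  expect_equal(co$ys[1], mean(residuals(fit, sim$X)^2), tolerance = 1e-12)
  expect_equal(co$auc, trapezoid_auc(co$xs, co$ys))
})

test_that("retrain benchmark recovers full-model error and is deterministic", {
  sim <- memo("rank_sim", simulate_pathway_data(
    600, n_pathways = 3, genes_per_pathway = 10, loadings = "unit",
    activity_scales = sqrt(c(0.8, 0.15, 0.05)), noise_sd = 0,
    seed = 17))
  shares <- ground_truth_shares(sim)
  oracle <- pmvae:::.new_ranking("oracle", names(shares), shares)
  tr <- sim$X[1:400, ]; te <- sim$X[401:600, ]
  c1 <- retrain_benchmark(tr, te, oracle, sim$membership,
                          min_genes = 3, max_epochs = 60, batch_size = 64,
                          seed = 3)
  c2 <- retrain_benchmark(tr, te, oracle, sim$membership,
                          min_genes = 3, max_epochs = 60, batch_size = 64,
                          seed = 3)
  expect_identical(c1$ys, c2$ys)
  expect_identical(c1$schedule, 1:3)
  # error falls as informative modules are added (tolerate training noise)
  expect_lt(c1$ys[3], c1$ys[1])
  expect_true(all(diff(c1$ys) < 0.05 * (max(c1$ys) - min(c1$ys) + 1e-9)))
  # full-pathway retrain approaches the directly trained model's error
  full <- pmvae(tr, membership = sim$membership, min_genes = 3,
                max_epochs = 60, batch_size = 64, seed = 3)
  full_err <- mean(residuals(full, te)^2)
  expect_lt(abs(c1$ys[3] - full_err) / full_err, 0.3)
})

test_that("AUC comparison utility uses the exact signed-rank null", {
  a <- c(0.9, 0.85, 0.88, 0.92, 0.87, 0.91)
  b <- a - c(0.051, 0.043, 0.062, 0.034, 0.055, 0.047)
  ht <- compare_aucs(a, b)
  expect_s3_class(ht, "htest")
  expect_match(ht$method, "Wilcoxon")
  expect_equal(ht$p.value, wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value)
})
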