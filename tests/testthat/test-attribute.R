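test_that("path integral is exact for linear functions and 1-D quadratics", {
  f <- function(v) 2 * v[1] + 3 * v[2]
  g <- function(v) c(2, 3)
  expect_identical(path_integral(f, c(1, 1), c(0, 0), n_steps = 200,
                                 grad = g), c(2, 3))
  # finite-difference fallback stays very close on the same toy
  expect_equal(path_integral(f, c(1, 1), c(0, 0), n_steps = 50), c(2, 3),
               tolerance = 1e-8)
  # f(v) = v^2: gradient is affine in alpha, so midpoint quadrature is
  # exact and the attribution equals f(v) - f(v') = 9
  fq <- function(v) v^2
  expect_equal(path_integral(fq, 3, 0, n_steps = 7, grad = function(v) 2 * v),
               9, tolerance = 1e-12)
})

test_that("quadratic decoder losses match the endpoint-average closed form", {
  set.seed(12)
  W <- matrix(rnorm(12), 4, 3)
  x <- rnorm(4)
  ell <- function(z) sum((x - W %*% z)^2)
  grad <- function(z) as.numeric(-2 * t(W) %*% (x - W %*% z))
  z <- rnorm(3); zp <- rnorm(3)
  got <- path_integral(ell, z, zp, n_steps = 200, grad = grad)
  closed <- (z - zp) * (grad(zp) + grad(z)) / 2
  expect_equal(got, closed, tolerance = 1e-6 * max(abs(closed)))
  # and completeness holds exactly for the affine-gradient case
  expect_equal(sum(got), ell(z) - ell(zp), tolerance = 1e-10)
})

test_that("recon_loss_fn is a nonnegative loss with an accurate gradient", {
  fit <- small_model()
  sim <- small_sim()
  fn <- recon_loss_fn(fit, sim$X[5, ])
  gr <- attr(fn, "grad")
  set.seed(3)
  for (i in 1:5) {
    z <- rnorm(3)
    expect_gte(fn(z), 0)
    fd <- vapply(1:3, function(d) {
      h <- 1e-5
      zp <- z; zp[d] <- z[d] + h
      zm <- z; zm[d] <- z[d] - h
      (fn(zp) - fn(zm)) / (2 * h)
    }, 0)
    expect_equal(gr(z), fd, tolerance = 1e-4)
  }
})

test_that("pathway attributions satisfy completeness and vanish at the baseline", {
  fit <- small_model()
  sim <- small_sim()
  x <- sim$X[1:100, ]
  pa <- pathway_attributions(fit, x, n_steps = 200)
  expect_identical(dim(pa$local), c(100L, 3L))
  expect_equal(pa$global, colMeans(pa$local))
  rel <- abs(pa$completeness_gap) / pmax(abs(pa$ell_z - pa$ell_baseline), 1e-12)
  expect_lt(max(rel), 1e-2)
  cr <- completeness_report(pa)
  expect_equal(cr$max_rel, max(rel))

  # baseline equal to the sample's own embedding => exactly zero
  z1 <- predict(fit, sim$X[1, , drop = FALSE], type = "latent")
  expect_warning(
    pa0 <- pathway_attributions(fit, sim$X[1, , drop = FALSE],
                                baseline = as.numeric(z1), n_steps = 10),
    "zero")
  expect_true(all(pa0$local == 0))
})

test_that("completeness gap shrinks as quadrature steps double", {
  fit <- small_model()
  sim <- small_sim()
  x <- sim$X[1:40, ]
  gaps <- vapply(c(25, 50, 100, 200), function(ns)
    completeness_report(pathway_attributions(fit, x, n_steps = ns))$mean_abs,
    0)
  expect_true(all(diff(gaps) < 0))
})

test_that("attributions are independent of how samples are batched", {
  fit <- small_model()
  sim <- small_sim()
  pa_full <- pathway_attributions(fit, sim$X[1:30, ], baseline = "zeros",
                                  n_steps = 50)
  pa_part <- pathway_attributions(fit, sim$X[11:20, ], baseline = "zeros",
                                  n_steps = 50)
  expect_equal(pa_full$local[11:20, ], pa_part$local, tolerance = 1e-12)
})

test_that("attributions are invariant to hidden-unit permutations", {
  fit <- small_model()
  sim <- small_sim()
  perm_model <- fit
  sl <- fit$masks$module_slices[[1]]
  idx <- sl$hidden
  p <- rev(seq_along(idx))
  # permute module 1's hidden units consistently in encoder and decoder
  perm_model$params$W_e1[, idx] <- fit$params$W_e1[, idx[p]]
  for (nm in c("b_e1", "g_e", "be_e"))
    perm_model$params[[nm]][idx] <- fit$params[[nm]][idx[p]]
  for (nm in c("rmean_e", "rvar_e"))
    perm_model$buffers[[nm]][idx] <- fit$buffers[[nm]][idx[p]]
  perm_model$params$W_mu[idx, ] <- fit$params$W_mu[idx[p], ]
  perm_model$params$W_lv[idx, ] <- fit$params$W_lv[idx[p], ]
  perm_model$params$W_d1[, idx] <- fit$params$W_d1[, idx[p]]
  for (nm in c("b_d1", "g_d", "be_d"))
    perm_model$params[[nm]][idx] <- fit$params[[nm]][idx[p]]
  for (nm in c("rmean_d", "rvar_d"))
    perm_model$buffers[[nm]][idx] <- fit$buffers[[nm]][idx[p]]
  perm_model$params$W_d2[idx, ] <- fit$params$W_d2[idx[p], ]

  x <- sim$X[1:50, ]
  pa1 <- pathway_attributions(fit, x, n_steps = 100)
  pa2 <- pathway_attributions(perm_model, x, n_steps = 100)
  expect_equal(pa1$local, pa2$local, tolerance = 1e-6)
})

test_that("exactly symmetric modules receive equal attributions", {
  mem <- block_membership(c(2, 2))
  masks <- build_masks(mem, hidden_per_module = 3, latent_per_module = 1)
  model <- init_pmvae(masks, seed = 6)
  # tie module 2's weights to module 1's
  s1 <- masks$module_slices[[1]]; s2 <- masks$module_slices[[2]]
  model$params$W_e1[s2$genes, s2$hidden] <- model$params$W_e1[s1$genes, s1$hidden]
  model$params$W_mu[s2$hidden, 2] <- model$params$W_mu[s1$hidden, 1]
  model$params$W_lv[s2$hidden, 2] <- model$params$W_lv[s1$hidden, 1]
  model$params$b_lv[2] <- model$params$b_lv[1]
  model$params$W_d1[2, s2$hidden] <- model$params$W_d1[1, s1$hidden]
  model$params$W_d2[s2$hidden, s2$genes] <- model$params$W_d2[s1$hidden, s1$genes]
  model$params$B_out[2, s2$genes] <- model$params$B_out[1, s1$genes]

  set.seed(10)
  half <- matrix(rnorm(40), 20, 2)
  x <- cbind(half, half)
  colnames(x) <- mem$genes
  pa <- pathway_attributions(model, x, n_steps = 50)
  expect_equal(pa$local[, 1], pa$local[, 2], tolerance = 1e-10)
})

test_that("gene attributions are exact for a linearized encoder and masked genes", {
  mem <- toy_membership()
  masks <- build_masks(mem, hidden_per_module = 2, latent_per_module = 1)
  model <- linearize_model(init_pmvae(masks, seed = 8))
  # nonnegative weights keep ELU in its identity range for positive inputs
  model$params$W_e1 <- abs(model$params$W_e1)
  model$params$W_mu <- abs(model$params$W_mu)
  v <- drop(model$params$W_e1[1:3, masks$module_slices[[1]]$hidden] %*%
              model$params$W_mu[masks$module_slices[[1]]$hidden, 1])
  x <- matrix(c(2, 1, 1,
                1, 2, 1), 2, 3, byrow = TRUE,
              dimnames = list(NULL, mem$genes))
  ga0 <- gene_attributions(model, x, node = 1, baseline = "zeros",
                           n_steps = 100)
  expect_equal(ga0$local[1, ], v * x[1, ], tolerance = 1e-9)
  expect_equal(unname(ga0$local[, "g3"]), c(0, 0))  # g3 not in P1

  # mirrored samples around the mean: raw locals cancel, magnitudes do not
  ga <- gene_attributions(model, x, node = 1, baseline = "dataset_mean",
                          n_steps = 100)
  expect_equal(ga$local[1, ], -ga$local[2, ], tolerance = 1e-9)
  expect_equal(ga$global, colMeans(abs(ga$local)))
  expect_gt(ga$global[["g1"]], 0)
})

test_that("attribution rankings and TSV exports are consistent", {
  pa <- fixture_a_attr(11)
  rk <- pause_ranking(pa)
  expect_s3_class(rk, "pathway_ranking")
  expect_setequal(rk$order, seq_along(rk$pathways))
  path <- write_attribution_tsv(pa, tempfile(fileext = ".tsv"))
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_identical(tab$pathway[1], rk$pathways[rk$order[1]])
  expect_identical(tab$rank, seq_len(nrow(tab)))
})
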