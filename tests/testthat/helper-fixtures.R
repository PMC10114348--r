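# Shared fixtures.  Trained models are cached per session so that the
# attribution, benchmark and acceptance tests reuse the same fits.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

suite_fixtures <- function() memo("suite", make_benchmark_suite(1))

# Tiny 3-pathway dataset and model for unit tests (seconds to train).
small_sim <- function() memo("small_sim",
  simulate_pathway_data(400, n_pathways = 3, genes_per_pathway = 8,
                        noise_sd = 0.1, seed = 7))

small_model <- function() memo("small_model", {
  sim <- small_sim()
  pmvae(sim$X, gene_sets = sim$gene_sets, min_genes = 3,
        max_epochs = 80, batch_size = 128, seed = 2)
})

# Fixture (a) models used by the acceptance checks (3 seeds).
fixture_a_model <- function(seed) memo(paste0("fit_a_", seed), {
  sim <- suite_fixtures()$a
  pmvae(sim$X, gene_sets = sim$gene_sets, max_epochs = 150,
        batch_size = 64, seed = seed)
})

fixture_a_attr <- function(seed) memo(paste0("attr_a_", seed),
  pathway_attributions(fixture_a_model(seed), suite_fixtures()$a$X,
                       n_steps = 200))

# Two-pathway toy membership: P1 = {g1, g2}, P2 = {g2, g3}.
toy_membership <- function() {
  M <- matrix(c(1L, 1L, 0L,
                0L, 1L, 1L), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("P1", "P2")))
  structure(list(genes = rownames(M), pathways = colnames(M), M = M,
                 sizes = colSums(M), unassigned = character()),
            class = "pathway_membership")
}

# Disjoint-pathway membership over arbitrary block sizes.
block_membership <- function(sizes, gene_prefix = "g") {
  genes <- paste0(gene_prefix, seq_len(sum(sizes)))
  K <- length(sizes)
  M <- matrix(0L, length(genes), K,
              dimnames = list(genes, paste0("P", seq_len(K))))
  at <- 1L
  for (j in seq_len(K)) {
    M[at:(at + sizes[j] - 1L), j] <- 1L
    at <- at + sizes[j]
  }
  structure(list(genes = genes, pathways = colnames(M), M = M,
                 sizes = colSums(M), unassigned = character()),
            class = "pathway_membership")
}

# Write a GMT file from name -> gene vectors; returns the path.
write_gmt_lines <- function(sets, path = tempfile(fileext = ".gmt")) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "desc", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  path
}

# Put a linear toy model into exact-linear operating conditions: identity
# batch norm (gamma compensates the BN epsilon) and nonnegative weights so
# ELU stays in its identity range for positive inputs.
linearize_model <- function(model) {
  H <- model$masks$meta$H
  model$params$g_e <- rep(sqrt(1 + 1e-5), H)
  model$params$g_d <- rep(sqrt(1 + 1e-5), H)
  model$params$be_e <- numeric(H)
  model$params$be_d <- numeric(H)
  model$params$b_e1 <- numeric(H)
  model$params$b_d1 <- numeric(H)
  model$buffers$rmean_e <- numeric(H)
  model$buffers$rvar_e <- rep(1, H)
  model$buffers$rmean_d <- numeric(H)
  model$buffers$rvar_d <- rep(1, H)
  model
}

# Dense-quadrature attributions on a fixed 20-sample subset of fixture (a),
# shared by the completeness and oracle-equivalence checks.
fixture_a_subset <- function() memo("subset_a", {
  set.seed(99)
  sort(sample(nrow(suite_fixtures()$a$X), 20))
})

fixture_a_dense_attr <- function() memo("attr_a_dense",
  pathway_attributions(fixture_a_model(11),
                       suite_fixtures()$a$X[fixture_a_subset(), ],
                       n_steps = 1e5))

# pmVAE / cpmVAE pair trained on fixture (b) under a shared seed.
fixture_b_pair <- function(seed) memo(paste0("fit_b_", seed), {
  sim <- suite_fixtures()$b
  list(
    pm = pmvae(sim$X, gene_sets = sim$gene_sets, max_epochs = 60,
               batch_size = 64, seed = seed),
    cpm = pmvae(sim$X, gene_sets = sim$gene_sets, conditions = sim$batch,
                max_epochs = 60, batch_size = 64, seed = seed))
})
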