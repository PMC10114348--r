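# pmvae — pathway-module VAEs with principled pathway attributions

`pmvae` is an R package for *interpretable unsupervised analysis* of
bulk and single-cell gene expression.  It fits variational autoencoders
whose encoder and decoder are split by binary masks into per-pathway
modules (defined by a GMT gene-set collection, e.g. Reactome), and then
answers the two questions deep autoencoders normally cannot:

* **Which pathways matter?**  Path-integral (Aumann–Shapley /
  integrated-gradient) attributions allocate the model's
  reconstruction-loss reduction to latent pathway nodes,
  \[ \phi_i(z) = (z_i - z_i') \int_0^1
     \partial_i\, \ell\bigl(z' + \alpha(z - z')\bigr)\, d\alpha, \qquad
     \ell(z) = \lVert x - g(z) \rVert_2^2 , \]
  so that \(-\Phi_i = -\mathbb E[\phi_i]\) reads as "variance explained
  by pathway *i*" — the deep-model analogue of PCA eigenvalues.
* **Which genes drive a pathway node?**  The same construction applied
  to the encoder map \(f_k(x)\), summarized by mean absolute local
  attribution per gene.

The models train with the pathway-module local reconstruction loss
\(\frac1K \sum_p \frac{N}{N_p} \lVert \hat x^{(p)} - x^{(p)} \rVert^2\);
a conditional variant takes nuisance labels (e.g. data source) into
every module and adds an HSIC independence penalty for batch
correction.  Rankings are validated with impute/retrain ablation
benchmarks (trapezoidal AUC) against logistic-regression, KL-divergence,
latent-scale and random baselines, plus a k-means/ARI batch-mixing
diagnostic.  A seeded linear-Gaussian simulator with exact per-pathway
variance shares makes every claim testable without downloads.

## Worked example

```r
library(pmvae)

suite <- make_benchmark_suite(1)      # canonical synthetic fixtures
sim <- suite$a                        # 2000 cells x 300 genes, 10 pathways
fit <- pmvae(sim$X, gene_sets = sim$gene_sets,
             max_epochs = 150, batch_size = 64, seed = 11)
print(fit)
#> Unconditional pathway-module VAE
#>   300 genes -> 10 modules (12 hidden, 1 latent each) -> 10 latent nodes
#>   trained 150 epochs on 2000 samples; best epoch 80 (val recon 3.3848)

pa <- pathway_attributions(fit, sim$X, n_steps = 200)
cor(-pa$pathway_global, ground_truth_shares(sim), method = "spearman")
#> [1] 1
completeness_report(pa)$max_rel      # worst per-sample completeness gap
#> [1] 5.193422e-06
```

The ranking recovers the planted variance-share ladder exactly
(Spearman 1), and per-sample attributions sum to the reconstruction-loss
difference to within 5 × 10⁻⁶ relative — the completeness axiom that
gives the attributions their variance-explained interpretation.  The
ablation benchmark confirms the ranking is informative:

```r
oracle <- pmvae:::.new_ranking("oracle", names(shares),
                               shares <- ground_truth_shares(sim))
impute_benchmark(fit, sim$X, oracle)$auc            # ground-truth order
#> [1] 0.241
impute_benchmark(fit, sim$X, pause_ranking(pa))$auc # attribution order
#> [1] 0.241
impute_benchmark(fit, sim$X, random_score(names(shares), 1))$auc
#> [1] 0.172
```

For multi-source data, the conditional model removes batch structure
from the embedding: on the batched fixture, k-means clusters the plain
pmVAE embedding by data source almost perfectly (ARI ≈ 1.0) while the
HSIC-regularized cpmVAE embedding is well mixed (ARI ≈ 0.02).

A shell interface with `simulate`, `train`, `attribute`,
`gene-attribute`, `rank`, `impute-bench` and `retrain-bench` subcommands
is installed at `system.file("scripts", "pmvae", package = "pmvae")`.

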