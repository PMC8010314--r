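# wpdinm

Ranks proteins by predicted **essentiality** from a weighted heterogeneous
protein–domain interaction network. Essential proteins — those whose
deletion is lethal — are enriched among network hubs (the
centrality–lethality rule), but topology alone is a weak predictor on noisy,
incomplete interactomes. This package fuses the interaction network with
four orthogonal biological signals: gene-expression dynamics, protein-domain
composition, subcellular localization and cross-species orthology. It is
aimed at computational biologists benchmarking essentiality predictors or
prioritizing candidate genes in organisms with a mapped interactome.

## Method

Given a binary PPI network `OppiM` over `O` proteins and a binary
protein-by-domain annotation matrix `OpdiM` over `Q` domains:

1. **Weighted PPI network.** Each expression time series `Gep(p, 1..M)` is
   transformed to a magnitude spectrum
   `DF(p)(t) = |Σ_y Gep(p,y)·e^(−i2πty/M)|`, and pairs are compared with a
   Gaussian interaction-profile kernel
   `GK(p_i,p_j) = exp(−α_p‖DF(p_i)−DF(p_j)‖²)` whose bandwidth `α_p` is the
   inverse mean squared spectrum norm. Pairs without expression fall back to
   the common-neighbour similarity
   `TFP(p_i,p_j) = (|Com|+1)/((deg_i+1)(deg_j+1))`. Known edges get
   `β·PA + (1−β)`; non-adjacent 2-hop pairs with expression get `TFP·GK`.
2. **Weighted DDI network.** Domains are compared with the same kernel over
   their annotation-profile columns of `OpdiM`.
3. **Weighted PDI network.** An `(O+Q)×(O+Q)` block matrix whose
   protein–domain block averages the annotation propagated through weighted
   PPI rows and through weighted DDI columns.
4. **Initial scores.** Each domain distributes one unit of score over its
   member proteins proportionally to the protein–domain weights (`PSD`);
   three normalized feature scores — subcellular localization `FS_SL`,
   triangle density `FS_TRI`, orthology `FS_ORT` — combine as
   `FS = φ·FS_SL + θ·FS_TRI + τ·FS_ORT`, and
   `S0 = ω·PSD + (1−ω)·FS`.
5. **Iterative refinement.** A directed weight-allocation matrix `WAPM`
   routes each protein's score through its strongest shared neighbour
   (row-normalized to total mass `ρ`), and
   `S_{t+1} = μ·WAPM·S_t + (1−μ)·S0` is iterated to its fixed point
   (`‖S_{t+1}−S_t‖² < ε`), a damped PageRank with restart vector `S0`.

Defaults: `β=0.5, φ=0.25, θ=0.35, τ=0.45, ω=0.7, μ=0.4, ρ=0.85, ε=1e−6`.
See `vignette("wpdinm-methods")` for rationale and numerical details.

## Worked example

```r
library(wpdinm)

bundle <- generate_fixture_bundle(
  fixture_config(n_proteins = 120, n_domains = 25, seed = 7))
res <- wpdinm_score(bundle)
print(res)
#> wpdinm_result: 120 proteins ranked; 7 iterations, final residual 1.511201e-07
head(res$ranking, 3)
#>   rank protein_id     score
#> 1    1      P0042 0.9038740
#> 2    2      P0046 0.7499570
#> 3    3      P0103 0.6183504

roc_pr_auc(res$scores, bundle$essentials)$auc_roc
#> [1] 0.9409722
top_fraction_hits(res$ranking, bundle$essentials)
#>   fraction  k hits  hit_rate
#> 1     0.01  2    1 0.5000000
#> 2     0.05  6    4 0.6666667
#> 3     0.10 12    9 0.7500000
#> 4     0.15 18   14 0.7777778
#> 5     0.20 24   17 0.7083333
#> 6     0.25 30   22 0.7333333
```

The generator plants 20% of proteins as essential with doubled attachment
mass, domain annotations, compartment memberships and orthology counts; the
ranking recovers them with ROC AUC 0.94 here. `P0042` tops the list because
it is a domain-rich, highly conserved hub. Baselines for comparison come
from `baseline_centrality(bundle$network, "DC")` (also `BC`, `CC`, `EC`,
`NC`).

Real data run through the same path: six plain TSV inputs (PPI edge list,
protein–domain pairs, expression series, protein–compartment pairs,
orthology counts, essential ids) via `load_input_bundle()` /
`run_pipeline()`, or the command-line wrapper:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "wpdinm.R", package = "wpdinm"))')" \
  run --ppi ppi.tsv --domains domains.tsv --expr expression.tsv --out results/
```

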