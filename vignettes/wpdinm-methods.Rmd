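---
title: "Essential-protein ranking over weighted protein-domain networks: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Essential-protein ranking over weighted protein-domain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wpdinm)
```

## The problem and the model

Essential proteins tend to be network hubs, but binary interactomes are
noisy and incomplete, so a useful predictor must pool topology with
independent biological evidence. This package scores essentiality by
propagating evidence over a *heterogeneous* network joining proteins and
their constituent domains, on the reasoning that essentiality frequently
acts through domains: a domain shared by many central proteins is itself
evidence for every protein carrying it.

The pipeline has five stages.

**Expression-aware edge re-weighting.** A gene-expression time series of
length $M$ is mapped to its magnitude spectrum
$DF(p)_t = \left|\sum_{y=1}^{M} Gep(p,y)\, e^{-i 2\pi t y / M}\right|$,
$t = 0..N-1$. Working with magnitudes discards phase, so two co-regulated
genes whose programs are shifted in time still compare as similar — the
advantage of the frequency domain over direct correlation of the raw
series. Similarity is a Gaussian interaction-profile kernel
$GK(p_i, p_j) = \exp(-\alpha_p \lVert DF(p_i) - DF(p_j)\rVert^2)$ with
bandwidth $\alpha_p = \alpha'_p \big/ \frac{1}{|P|}\sum_k \lVert DF(p_k)\rVert^2$,
the standard normalization that makes the kernel scale-free in the data.
Pairs lacking expression fall back to the purely topological
$TFP(p_i,p_j) = (|Com(p_i,p_j)|+1) / ((|Np(p_i)|+1)(|Np(p_j)|+1))$.
A known edge weighs $\beta \cdot PA + (1-\beta)$ — so every true
interaction keeps weight at least $1-\beta$ and the similarity modulates
the remainder — while a non-adjacent pair sharing a neighbour, with
expression on both sides, receives the product $TFP \cdot GK$,
letting strong indirect evidence create weighted shortcuts.

**Domain similarity.** Domains are compared by the same kernel over their
annotation-profile columns of the binary protein-by-domain matrix:
domains annotating near-identical protein sets get similarity near one.
No structural domain-domain database is consulted; the similarity is
purely annotation-derived.

**Heterogeneous assembly.** The $(O+Q)\times(O+Q)$ block matrix keeps the
weighted PPI and DDI matrices as its diagonal blocks; the protein-domain
block averages the binary annotation propagated through weighted PPI rows
(row-normalized) and through weighted DDI columns (column-normalized).
The two propagation matrices are declared as protein-by-domain, yet their first two branches address
protein-protein and domain-domain pairs; assembling one symmetric block
matrix is the only reading under which the later domain-to-protein
allocation indexing is well-defined, and it is what this package does.
A protein with an all-zero weighted-PPI row contributes nothing through
the first route ($0/0 \to 0$: there is no information to propagate).

**Initial scores.** Every domain holds one unit of score and allocates it
over its member proteins proportionally to the protein-domain block
entries (uniformly if those are all zero, so no domain's unit is lost and
the allocation rows always sum to one; in practice the unit-diagonal DDI
block makes member entries strictly positive). The resulting
domain-derived vector $PSD$ sums exactly to $Q$. Three feature scores
join it: subcellular localization (sum over the protein's compartments of
compartment size over mean compartment size — rewarding presence in
well-populated compartments), triangle density (mean over incident edges
of one plus the triangles the edge closes, max-normalized; triangles mark
locally stable modules), and orthology (conservation count,
max-normalized). The combination is
$FS = \varphi FS_{SL} + \theta FS_{TRI} + \tau FS_{ORT}$ and
$S_0 = \omega \cdot PSD + (1-\omega) \cdot FS$.

**Damped iteration.** A directed allocation matrix routes score between
proteins through their *strongest shared neighbour*: for the ordered pair
$(i,j)$ with common neighbours in the weighted network, the raw entry is
$WppiM(i, p_T)\cdot WppiM(p_T, j)$ where $p_T$ maximizes the weight
towards $j$; nonzero rows are rescaled to sum to $\rho$. Scores then
follow $S_{t+1} = \mu\, WAPM\, S_t + (1-\mu) S_0$ — a PageRank-style
damped iteration whose restart vector is the evidence-rich $S_0$ rather
than the uniform vector. Since row sums are at most $\rho$ and
$\mu\rho < 1$, the map is a contraction: the iteration converges
geometrically to the unique solution of
$(I - \mu\, WAPM)\,S = (1-\mu)S_0$, which the tests verify against a
direct linear solve. The final ranking is descending by score, ties
broken by ascending protein id — fully deterministic.

## Parameters

| name | default | role |
|------|---------|------|
| `beta` | 0.5 | share of a known edge's weight modulated by similarity; the rest is the constant edge prior |
| `phi`, `theta`, `tau` | 0.25, 0.35, 0.45 | weights of the localization, triangle and orthology features |
| `omega` | 0.7 | share of $S_0$ carried by the domain-derived score |
| `mu` | 0.4 | damping: share of each update carried by propagation vs. restart |
| `rho` | 0.85 | total allocation mass per protein per step (classic damping convention; the method's formulation leaves it open) |
| `epsilon` | 1e-6 | stop when the squared update norm falls below it |
| `dft_length` | `M` | spectrum length; `M` is the canonical choice and preserves Parseval's identity |
| `alpha_prime`, `delta_prime` | 1 | kernel bandwidth scalings, unit by interaction-profile convention |

The three feature weights are used verbatim even though they sum to 1.05
rather than 1 — they are the operating point at which the method is
specified —
and `normalize_feature_weights = TRUE` rescales them to unit sum for
users who prefer a convex combination. The localization feature is *not*
max-normalized before combination (the other two are, by definition);
this follows the defining formulas literally and means $FS_{SL}$ can exceed
one for multi-compartment proteins.

## Numerical and structural choices

* **Sparsity of the re-weighted network.** The off-edge branch
  ($TFP \cdot GK$) is evaluated only for pairs sharing at least one
  neighbour. Evaluating it for all $O^2$ pairs would make unrelated
  isolated proteins maximally similar ($TFP = 1$) and densify the matrix
  quadratically; the 2-hop restriction preserves the formula's intent on
  exactly the pairs where common-neighbour evidence exists. The same
  support is used for the allocation matrix, whose construction needs a
  shared neighbour anyway.
* **Edges without expression on both endpoints** use the topological
  fallback inside the edge branch, but the off-edge product is left at
  zero when either spectrum is undefined: inventing a kernel value there
  would manufacture similarity from no data.
* **Spectrum periodicity.** The transform's exponent uses the series
  length $M$ even when $N > M$ points are requested, so magnitudes repeat
  with period $M$; with $N = M$ (the default)
  $\sum_t DF_t^2 = M \sum_y x_y^2$, which the tests assert to $10^{-9}$
  relative error against an independent quadratic-time evaluation.
* **Stopping vs. accuracy.** The iteration stops on the squared update
  norm. At the default $\varepsilon = 10^{-6}$ the iterate is within
  about $10^{-5}$ of the exact fixed point — ample for a ranking, since
  score gaps are orders of magnitude larger; the oracle-equivalence tests
  tighten $\varepsilon$ to drive the iterate to $10^{-8}$ agreement with
  the direct solve. Non-convergence within `max_iter` (impossible for
  $\mu\rho < 1$, which the configuration guarantees) is an error, not a
  silent truncation.
* **Node indexing.** Protein order is first-appearance order among the
  surviving (deduplicated, non-self) edges of the input, with proteins
  seen only in self-loops appended as isolated nodes. Defining order on
  surviving edges — rather than raw file tokens — makes loading
  idempotent: writing a loaded network back to an edge list and reloading
  reproduces the identical object, which the tests assert byte-for-byte.
* **Ties.** Everywhere a maximum or a sort can tie (strongest shared
  neighbour, final ranking), ties break by ascending protein id, making
  every run reproducible without a random tie-break.
* **Degenerate inputs.** Missing optional files load as empty structures
  whose features contribute zero; an all-zero spectrum set or a domain
  without members is a hard error (the loader prevents the latter by
  dropping unannotated domains with a message).

## The synthetic generator

`generate_fixture_bundle()` emulates the six inputs of a real study at
desk scale: a preferential-attachment interactome grown in random node
order, where planted essentials (20% by default) carry twice the
attachment mass and so become hubs; domain annotations, compartment
memberships and orthology counts drawn from Poisson distributions whose
rates are doubled for essentials (rates 1.5, 1.5 and 3 for
non-essentials — a few domains and compartments per protein and a
moderate conservation count, as in typical yeast-scale annotation); and
expression series of length 36 — three full cycles of a unit-amplitude
sinusoid with protein-specific phase plus Gaussian noise (s.d. 0.25),
with half the edges sharing phase across endpoints so the spectral kernel
carries edge signal, and 10% of proteins lacking expression entirely so
the topological fallback is exercised. Everything is deterministic given
the seed, and the written files are byte-identical across runs.

What the generator does *not* emulate: false-positive/false-negative
interaction structure, correlated annotation errors, the heavy-tailed
domain-size distribution of real annotation databases, or yeast-scale
dimensions (thousands of proteins). Passing the planted-recovery tests
therefore shows the pipeline extracts exactly the four signals it claims
to use, at realistic sparsity — not that it attains any particular
accuracy on real interactomes. The test suite and acceptance script run
at 300 proteins and 60 domains, with five generator seeds for the
stochastic recovery checks; the ablation condition (all enrichment
ratios 1, no shared phase) verifies that recovery collapses to chance
when no signal is planted, i.e. that the pipeline does not manufacture
separation from the generator's mechanics.

## Known limitations

* The off-edge similarity restriction to 2-hop pairs is a design
  decision, not forced by the formulas, and slightly changes
  which non-edges receive weight; users wanting the dense variant must
  modify `build_weighted_ppi()`.
* The allocation step treats all domains as equally important (one unit
  each); no domain-essentiality prior is supported.
* Evaluation includes five classical centrality baselines (DC, BC, CC,
  EC, NC); subgraph- and information-centrality baselines and composite
  competitor methods are out of scope, though externally
  produced rankings can be compared via `ranking_overlap()`.
* ROC/PR areas use trapezoidal integration with half-credit for ties;
  no significance testing of AUC differences is provided.
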