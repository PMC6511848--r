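---
title: "Cross-species network embeddings: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species network embeddings: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(munk)
```

## The model

The package treats cross-species functional similarity as an inner product
in a shared reproducing-kernel Hilbert space (RKHS). Three ingredients make
that concrete.

**Diffusion kernel.** For an undirected, unweighted PPI network with
adjacency `A` and degree matrix `D`, the regularized Laplacian kernel is
`K = (I + λL)⁻¹` with `L = D − A`. It arises as the solution operator of
the guilt-by-association objective

$$\hat y = \arg\min_{y'} \sum_i (y'_i - y_i)^2
  + \lambda \sum_{i,j} a_{ij} (y'_i - y'_j)^2,$$

whose stationarity condition gives `ŷ = (I + λL)⁻¹ y` (`smooth_labels()`
solves this linear system directly rather than inverting). `K` is symmetric
positive definite with eigenvalues in `(0, 1]`, hence a valid kernel, and
it discounts paths through high-degree nodes — both properties we rely on.

**Factorization.** Any kernel matrix factorizes as `K = CCᵀ`; the rows of
`C` are RKHS coordinates, unique only up to an orthogonal rotation. The
package factorizes by symmetric eigendecomposition, `C = V diag(√e)`. All
cross-species outputs are invariant to the orthogonal ambiguity (this is a
tested property), so the particular factor returned is a representation
convenience, not a modelling choice.

**Landmark solve.** Landmarks are homolog pairs confidently mapped between
the species. Writing `C₁L` for the source landmark rows and `D₂L` for the
target-kernel rows at the landmark targets, the target coordinates must
satisfy `C₁L Ĉ₂ᵀ = D₂L`. This system is underdetermined whenever there are
fewer landmarks than embedding dimensions; among the solution set
`Ĉ₂ᵀ = C₁L⁺ D₂L + (I − C₁L⁺C₁L) W` the package fixes `W = 0`, the
minimum-Frobenius-norm solution. Cross-species scores are
`D₁₂ = C₁ Ĉ₂ᵀ`, and reciprocals of positive scores serve as
dissimilarities.

The two assumptions inherited by everything downstream: functional
similarity is adequately captured by a network kernel, and the landmark
homologs really do correspond functionally. Where either fails (heavily
rewired interactomes, spurious homology), cross-species scores degrade
gracefully toward noise rather than failing loudly.

## Parameters that matter

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `lambda` | 0.05 | Diffusion strength (dimensionless). Any `λ > 0` yields a valid kernel; small values keep diffusion local and the kernel well-conditioned. The embedding-contract and contrast properties are insensitive to it. |
| `n_landmarks` | `min(400, candidates)` | Anchors for the target solve. More landmarks enlarge the subspace in which target nodes are resolved; 400 matches the regime where matching-quality plateaus on real interactome sizes. |
| `strategy` | `"random"` | Landmark choice. `"degree"` (average within-species degree rank) helps only for very small landmark sets. |
| `k` (k-functional similarity) | 100 | A shared GO term counts only if it annotates ≤ k proteins per species — restricts to informative terms. |
| `tau` (phenologs) | 0.001-quantile | Dissimilarity threshold defining "functionally similar". Stringent by design: it sharply limits the candidate relation and hence the number of phenolog predictions. |
| `n_folds` / inner folds | 4 / 3 | Outer CV mirrors the evaluation protocol; the inner 3-fold CV picks the forest size from `{100, 250, 500}` by held-out AUPR. The grid is intentionally small; AUROC is flat across it on planted data. |
| simplex step | 0.25 (tests), 0.05 (production) | Grid resolution over species weights in multi-species prediction. |

## What the synthetic generator emulates — and what it does not

`make_network_pair()` grows the source network by duplication–divergence
(each new node copies a random node's neighbours with retention 0.4, plus
an anchor edge), which reproduces the heavy-tailed degree distributions of
real PPI networks, then tops up with uniform edges to the requested density
(default 0.03, mean degree ≈ 9 — typical of two-cores of curated
interactomes). The target network is a relabeled copy with a fraction of
edges (default 10%) removed and replaced by random non-edges, emulating
interactome divergence; the true correspondence is recorded. Both networks
are reduced to a stable fixed point of the largest-component/two-core
preprocessing so that the recorded correspondence survives any later
preprocessing unchanged. The two-core matters: degree-1 leaves hanging off
one parent are topologically indistinguishable and would receive identical
scores.

`plant_sl_interactions()` emulates the pathway structure of
synthetic-lethal screens. Pathways are connected neighbourhoods wired up as
cohesive modules (within-pathway edge probability 0.6, as in protein
complexes), and redundant pathway couples additionally share partners
across the couple (probability 0.3) — redundancy in real interactomes shows
up as shared interaction neighbourhoods. SL pairs are drawn within
pathways and between coupled pathways; non-SL pairs span unrelated
pathways, including non-redundant background modules (default 12) planted
the same way, mirroring the fact that screened non-interacting pairs come
from a broad gene universe rather than only from redundant complexes. The
planted wiring is carried into the target network through the true
correspondence (minus the divergence fraction), and the op returns the
augmented pair, which downstream embedding must use. Without module
cohesion a diffusion embedding cannot resolve 10-gene neighbourhoods, and
with negatives drawn only from redundant couples the task is not linearly
separable even in principle; both would say nothing about the method.

`make_toy_ontology()` builds a small DAG exercising all three relation
types (`is_a`, `part_of`, `has_part`), annotates module genes with
module-specific terms in both species, and mirrors modules as phenotypes;
`noise` randomizes a fraction of annotations and memberships.

What the generators do **not** emulate: sequence evolution (homologs are
exact by construction), weighted or directed interactions, study-specific
ascertainment bias of interactome screens, annotation incompleteness
structured by study bias, or many-to-many orthology. Passing tests
therefore demonstrate that the implementation recovers signal the model is
built for under PPI-like topology; they do not certify performance on any
real interactome.

## Numerical choices

* Kernels are inverted by Cholesky factorization and symmetrized as
  `(M + Mᵀ)/2` to suppress round-off asymmetry; validity demands symmetry
  within `1e-10` and eigenvalues above `−1e-8`.
* The eigendecomposition drops eigenvalues below `1e-10` (defining the
  embedding dimension `k`) and fixes each column's sign so its
  largest-magnitude entry is positive, making factors bit-reproducible.
* The pseudoinverse uses SVD with a relative cutoff of `1e-12` times the
  largest singular value; dropped singular values are reported.
* Non-positive cross-species scores have no meaningful reciprocal and map
  to an `Inf` dissimilarity sentinel; all contrast statistics use finite
  values only.
* Node order is lexicographic everywhere, so every derived matrix has a
  fixed, reproducible row order; ties in landmark degree ranking break by
  source identifier; Hungarian ties resolve by the solver's fixed
  construction.
* All stochastic steps take explicit seeds and restore the caller's RNG
  state; identical seeded invocations are byte-identical, including the
  command-line outputs (temp-file-plus-rename writes).

## Design choices where the design was open

* **Direction convention.** The fitting function uses the networks exactly
  as passed; the documented convention is to embed the smaller network
  into the larger.
* **Landmark exclusion.** Landmark genes are excluded from every
  evaluation pair set (contrast, matching recovery, degree null): they
  anchor the solve and would trivially score well.
* **GO consistency with empty term sets.** Matched pairs with both sets
  empty are uninformative and are excluded from the mean; exactly one
  empty set contributes 0. Propagated annotations are the default for
  GO-consistency and k-functional similarity; function prediction uses the
  specific (unpropagated) annotations, and both modes are exposed.
* **Cross-species information content.** Resnik IC for cross-species pairs
  is computed on the caller-supplied corpus; the natural choice is the
  union corpus of the two species, and that is what the package's own
  pipelines pass.
* **Phenolog significance.** The scan maps target-species phenotype genes
  through the thresholded relation into the source universe, scores
  overlap by the hypergeometric upper tail, and estimates FDR q-values by
  rerunning the scan on gene-label-permuted maps (both sides). Overlap is
  counted in genes; the number of related cross-species gene pairs is
  reported alongside as a diagnostic. The universe defaults to source
  genes that appear in the relation and in at least one phenotype.
* **Label-smoothing solve.** `smooth_labels()` solves the linear system
  rather than forming the inverse, and its output is verified against a
  generic quadratic-programming minimizer in the tests.
* **Persistence.** All on-disk formats are TSV (matrices with an `id`
  column, OBO-subset term files); desk-scale matrices do not justify a
  binary container.

## Problem sizes used by the test-suite

The property checks run at `n = 300` nodes, density 0.03, 10% rewiring,
20% landmarks (10 generator seeds for the correspondence contrast; 99
degree-preserving permutations for the null; 200 SL and 200 non-SL pairs
per species for classification; 45 × 45 random phenotype maps for null
calibration). These sizes give stable statistics while keeping the full
suite in the low minutes; the same conditions are what
`scripts/acceptance.R` re-runs end to end.

## Known limitations

* Dense linear algebra throughout: networks beyond a few thousand nodes
  per species will need sparse or low-rank kernel approximations.
* Only the regularized Laplacian kernel is implemented, although any
  PSD matrix passes the same interfaces.
* One-to-one landmark candidates only; paralog families must be resolved
  before fitting.
* Multi-species use solves each target independently against one source
  RKHS; there is no joint optimization across three or more networks.
* The linear-SVM view of synthetic lethality depends on the target
  embedding being resolved in enough dimensions — with very few landmarks
  the minimum-norm solve confines target coordinates to a small subspace
  and only nonlinear classifiers retain accuracy.
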