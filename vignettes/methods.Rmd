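---
title: "Methods: similarity-based inductive matrix completion for circRNA–disease association prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity-based inductive matrix completion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circimc)
```

## The problem and its assumptions

Validated circRNA–disease associations number in the hundreds, against tens of
thousands of annotated circRNAs. `circimc` treats prediction as a
recommender-system problem: the binary matrix `A` is assumed to be a partial
observation of a low-rank interaction structure, with the missing structure
recoverable from side information. Two assumptions do the heavy lifting:

* **Guilt by similarity** — circRNAs with similar sequences, and diseases
  close in the ontology, tend to share associations. This justifies building
  entity features from similarity kernels rather than from `A` alone.
* **Positive-unlabeled data** — a `1` in `A` is a validated association; a
  `0` is *unknown*, not a negative. The solver's data-fit term is therefore
  restricted to the observed set `Ω = {(i,j) : A_ij = 1}`, and the
  nuclear-norm penalty supplies the inductive bias that keeps the completion
  from trivially saturating.

## Kernels

**Sequence.** The weighted Levenshtein distance uses insertion/deletion cost
1 and substitution cost 2. With those costs a substitution is exactly one
deletion plus one insertion, which gives the identity
`dist = len_a + len_b − 2·LCS`, bounds the distance by `len_a + len_b`, and
hence keeps `Sim_lev = 1 − dist/(len_a + len_b)` inside `[0, 1]`. The DP is
implemented in C++ (`O(len_a · len_b)` per pair); a banded variant was
deliberately not implemented since desk-scale inputs are short.

**Semantic.** The Wang measure decays an ancestor's contribution by a factor
`w_e = 0.7` per `is_a` edge, taking the maximum over directed paths — in a
multi-parent DAG every upward path is propagated and the max wins, which with
a uniform `w_e` equals `w_e^d` for shortest-path distance `d`. Terms sharing
no ancestor get similarity 0 (the degenerate case is not specified by the
measure; an empty intersection has zero shared mass, so 0 is forced). The
implementation recurses over the ancestor sub-DAG with memoization, so
exponential path enumeration never happens.

**GIP.** The Gaussian interaction profile kernel's bandwidth is normalized by
the mean squared profile norm of the matrix *currently in effect*. That
qualifier matters: inside cross-validation the kernel is recomputed from the
training matrix with the held-out entry zeroed (see below).

**Integration.** `CS` and `DS` are unweighted arithmetic means of the two
kernels per entity type. A `weight` argument exposes the convex combination
for sensitivity analysis; reweighting experiments on the curated datasets
report little effect, so 0.5 is the fixed default.

## Feature extraction

Features are the left singular vectors of the *uncentered* similarity matrix,
truncated by the dominating-energy rule: the smallest `f` with
`Σ_{i≤f} σ_i / Σ_j σ_j ≥ α`. Defaults are `α_c = 0.6`, `α_d = 0.9` (the
configuration shared by most of the curated datasets; one dataset prefers
`α_c = 0.7`). Three deliberate choices:

* **No mean-centering.** "PCA via SVD" is applied to the similarity matrix
  as-is; centering would destroy the unit diagonal and is not part of the
  described procedure.
* **Unscaled orthonormal vectors.** Columns are not scaled by `√σ`. With
  orthonormal `C` and `D` the gradient of the data-fit term is 1-Lipschitz,
  so the proximal parameter `τ = ‖C‖₂²·‖D‖₂² = 1` exactly — no line search.
* **Deterministic sign.** Each column's largest-magnitude entry is made
  positive (first index on ties), so results are reproducible across LAPACK
  backends. Singular-value ties keep the decomposition's ordering.

The retained energy is stored on the `feature_matrix` object so users can
audit how much spectrum a given `α` actually kept.

## The solver

The objective `λ‖Z‖_* + ½‖R_Ω(C Z Dᵀ − A)‖_F²` (`λ = 1` by default) is
minimized by accelerated proximal gradient with singular value thresholding:

```
Z_k  = svt_prox(Y_k − (1/τ)∇f(Y_k), λ/τ)
t_{k+1} = (1 + √(1 + 4 t_k²)) / 2
Y_{k+1} = Z_k + ((t_k − 1)/t_{k+1})(Z_k − Z_{k−1})
```

with `∇f(Y) = Cᵀ R_Ω(C Y Dᵀ − A) D` and `Z₀ = 0`. The reference description
names the accelerated SVT scheme (and a "linear Bregman iteration" speedup)
but gives no update equations; the standard Nesterov scheme above is the
design choice, with a **monotone safeguard**: if a momentum step would
increase the objective, momentum is reset and a plain proximal step is taken
from the previous iterate, which guarantees the non-increasing objective
trace the method is described as having. Iterations stop when the relative
gap `1 − obj_k/obj_{k−1}` falls below `10⁻⁵` (guarded for `obj = 0`), or at
`max_iter = 500`. A quadratic-approximation term that appears undefined in
the reference derivation (`P(Z)`) is omitted; the derivation is
self-consistent without it.

Numerical notes: `svt_prox` is the exact proximal operator of the nuclear
norm (verified in the tests against an independent multi-start quasi-Newton
minimizer); the solution is invariant under column sign flips of `C` and `D`;
and with `λ = 0` and full observation the solver reduces to the least-squares
projection onto the feature spaces, which the tests check via residual
orthogonality.

## LOOCV protocol

For each known association `(i, j)`: zero `A_ij`, recompute both GIP kernels,
both integrated similarities and both feature matrices from the training
matrix, re-solve, then record the held-out pair's score (label 1) and the
scores of every circRNA never associated with disease `j` (labels 0).
Negatives are restricted to the held-out disease's column, per the protocol's
"candidate sample" definition. Recomputing the kernels per fold is the
package's choice — the reference protocol is silent — because reusing
full-data kernels would leak the held-out label through the GIP profiles.

The phrase "highest value as the final score" is ambiguous; the default
reading (`aggregate = "max"`) keeps, for each candidate pair scored in
several folds, its maximum score across folds. The alternative
(`aggregate = "none"`, every fold's scores pooled without deduplication) is
exposed behind the same flag. AUC uses the Mann–Whitney statistic with ties
credited ½, which equals trapezoidal integration of the ROC curve.

## Synthetic data: what it emulates and what it does not

The generators produce (a) uniform random A/C/G/T sequences, 100–300 nt by
default — a desk-scale stand-in for circRNA exonic lengths; (b) a rooted
random DAG ontology (each term takes 1–2 uniform parents among earlier
terms); (c) an association matrix planted from
`signal · U Vᵀ / √rank + noise` with unit-variance Gaussian noise, binarized
at the top `⌈density·m·n⌉` entries. Rows or columns left empty are repaired
by adding their best-scoring entry (the stated feasibility precondition
`density·m·n ≥ max(m,n)` is intentionally not enforced: the repair guarantees
the dataset invariants for any positive density, and the canonical 40×10
fixture at density 0.1 relies on it). `signal = 3` means planted structure
three times the noise scale; `signal = 0` is the null world. In `coupled`
mode circRNAs are k-means-clustered on the latent factors and each sequence
is a mutated copy (per-base rate 0.1) of its cluster template, so the
sequence kernel carries the same signal the associations do.

What a green test on this world establishes: the pipeline recovers planted
low-rank structure well above chance (LOOCV AUC ≈ 0.76 on the canonical
fixture) and stays near chance on the null. What it does not establish: the
published AUCs on curated datasets (≈ 0.83–0.87), which depend on the
authors' specific curation and cannot be recomputed without their data files;
real Disease Ontology topology; realistic backsplice sequence composition; or
calibration of absolute scores. One caveat worth knowing: at very small
matrix sizes the LOOCV AUC of *null* data drifts above 0.5, because circRNA
degree (number of known associations) alone predicts rank position — a known
property of LOOCV on bipartite link prediction, not label leakage; the
signal-monotonicity test therefore runs at the canonical 40×10 scale.

## Defaults at a glance

| parameter | default | meaning |
|---|---|---|
| insertion/deletion/substitution | 1 / 1 / 2 | Levenshtein edit costs |
| `w_e` | 0.7 | semantic decay per ontology edge |
| `weight` | 0.5 | kernel integration weight |
| `alpha_circ`, `alpha_disease` | 0.6, 0.9 | SVD energy thresholds |
| `lambda` | 1 | nuclear-norm weight |
| `tau` | auto (=1) | proximal step, Lipschitz constant of the gradient |
| `tol` | 1e-5 | relative objective-gap stop rule |
| `max_iter` | 500 | iteration cap |

## Known limitations

* Entity identity is exact string match after whitespace trimming; no alias
  resolution across circRNA databases — merging datasets with inconsistent
  identifiers silently keeps both copies.
* The solver is dense; matrices beyond a few thousand entities per side will
  be slow (LOOCV refits the model once per known association).
* Scores are uncalibrated margins, not probabilities.
* k-fold CV, bootstrap confidence intervals and comparisons against other
  predictors are out of scope.
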