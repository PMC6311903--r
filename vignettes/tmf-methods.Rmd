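---
title: "Triple matrix factorization for drug-target interaction prediction: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triple matrix factorization for drug-target interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmfdti)
```

## The problem

Drug–target interaction (DTI) screening asks four distinct questions,
depending on whether the drug and the protein target are already in the
training data: completing missing cells among known entities (S1), scoring a
new compound against known targets (S2), scoring known drugs against a newly
discovered target (S3), and the double cold start — new compound against new
target (S4). Most matrix-factorization predictors handle S1–S3 but have no
principled way to score S4, because a brand-new entity has no interaction
profile to factor. And almost none of them can tell a medicinal chemist
*which* chemical substructures paired with *which* sequence patterns drive
the predicted interactions.

`tmfdti` addresses both problems with one bilinear model.

## The model

Let `A` be the binary m × n interaction matrix (rows = drugs, columns =
targets), `F_d` the m × p drug feature matrix (e.g. 881-bit PubChem
fingerprints) and `F_t` the n × q target feature matrix (e.g. frequencies of
the 8000 amino-acid trimers). The working assumption is a bilinear link

    A ≈ F_d Θ F_t'

where the p × q *bi-projection matrix* Θ couples drug features to target
features. Solving for Θ directly is hopeless in the regimes this model is
meant for: p and q exceed m and n by orders of magnitude and fingerprint
bits are strongly multicollinear (the "≥ 32 H" bit implies the "≥ 16 H"
bit), so `F_d' F_d` is singular; and the p × q normal-equation system is too
large to form. The factorization therefore goes through a rank-r latent
space:

    J = ||A − A_d A_t'||² + ||A_d − F_d B_d||² + ||A_t − F_t B_t||²
        + λ||A_d||² + μ||A_t||² + α||B_d||² + β||B_t||²

`A_d` (m × r) and `A_t` (n × r) factor the interaction topology; the ridge
regressions `B_d` (p × r) and `B_t` (q × r) tie each latent factor to the
explicit features. All four scoring scenarios collapse to one formula,

    score(x, y) = f_x B_d (f_y B_t)'   =   f_x (B_d B_t') f_y'

with `f_x`, `f_y` the feature rows of the (known or new) drug and target —
evaluated through the two skinny products, never through the p × q matrix
`Θ* = B_d B_t'`.

## Fitting

`tmf_fit()` runs alternating least squares in the fixed sweep order
`A_d → A_t → B_d → B_t`, each update the exact closed-form minimizer of `J`
in that block:

* `A_d = (A A_t + F_d B_d)(A_t'A_t + I + λI)⁻¹` and symmetrically for `A_t`;
* `B_d = (F_d'F_d + αI)⁻¹ F_d' A_d` and symmetrically for `B_t`.

Because every step is an exact coordinate minimization, `J` is
non-increasing; the fitter records the per-cycle trace and *raises an error*
if `J` ever rises beyond 1e-9 relative slack, since that can only mean an
inconsistent update formula. Iteration stops when the relative change of `J`
drops below `rel_tol` (default 1e-6) or after `max_iter` (default 200)
cycles. The sweep order is not mathematically forced — any order descends —
but fixing one makes runs bit-reproducible.

In the pair-completion scenario some cells of `A` are blinded, so the
matrix-form `A_d`/`A_t` updates are unavailable. `tmf_fit_masked()` replaces
them with exact per-row solves over each row's observed cells,

    (Σ_{j∈Ω_i} a_tj a_tj' + (1+λ)I) x = Σ_{j∈Ω_i} a_ij a_tj + (F_d B_d)_i ,

which is the unique coordinate minimizer of the masked objective; with an
all-ones mask it reproduces `tmf_fit()` to machine precision (this reduction
is asserted in the test suite). Rows or columns with no observed cell fall
back on the feature prior `F_d B_d` and are logged.

### Initialization

* `A_d`, `A_t`: truncated SVD of the (masked) training matrix, split
  symmetrically as `U_r √Σ_r` and `V_r √Σ_r`, so the starting product is the
  best rank-r approximation of `A`.
* `B_d`, `B_t`: partial least-squares regression of the initial factors on
  the features (NIPALS deflation, centering on, scaling off), which stays
  finite under the multicollinearity and p > m regimes where ordinary least
  squares breaks. Component count is `min(r, p, m−1)` per side. Whether
  centering belongs inside this step is genuinely open; centering was chosen
  because NIPALS without it privileges the feature-mean direction, and the
  choice only affects the starting point, not the fixed-point equations.

### Tunable parameters

| parameter | meaning | default |
|---|---|---|
| λ, μ | ridge on latent factors (unitless) | scenario-specific, see below |
| α, β | ridge on regression coefficients | scenario-specific |
| r | latent dimension | `"auto"` = ⌊rank(A_trn)/2⌋ |
| max_iter | ALS cycles | 200 |
| rel_tol | relative ΔJ stopping threshold | 1e-6 |

The per-scenario defaults — S1: λ=μ=1.0, α=β=0.5; S2: 0.05/0.5; S3:
0.5/0.05; S4: 0.05/0.5 — are the values selected by grid search over
{0.005, 0.05, 0.5, 1} on the public Yamanishi benchmark, always with λ=μ and
α=β since drugs and targets play technically equal roles. The `"auto"` rank
rule halves the numerical rank of the training matrix (singular values above
`max(m,n)·eps·σ_max`); larger r buys little accuracy at more cost.

## Cross-validation that respects the scenario

Naive cell-wise CV leaks information in cold-start settings, so each
scenario gets its own splitter:

* **S1** (`split_s1`): only cells whose drug has ≥ 2 known targets *and*
  whose target has ≥ 2 known drugs are eligible (degrees computed on the
  full matrix before splitting, so eligibility is fold-independent); both
  positive and zero cells at those coordinates enter the fold pool. Training
  uses the masked fitter.
* **S2 / S3** (`split_entities`): whole drug rows (target columns) are
  blinded, default 10 folds.
* **S4** (`split_s4`): drugs and targets are partitioned independently
  (default 5 × 5, which keeps the per-round test block large enough to
  contain positives); the round's test cells are the held-out block, its
  training cells the retained block, and the two mixed blocks attend
  *neither* phase, so no training cell ever shares a row or column with a
  test cell.

`run_cv()` pools each repetition's test scores across rounds into one AUPR
and one AUC (the alternative — averaging per-round AUPRs — is noisier and
undefined for rounds without positives), and reports mean ± sd over
repetitions, repetition i reseeded as `seed + i − 1`. AUPR is computed as
step-wise average precision, not trapezoidal interpolation, which
overestimates PR area; AUC is the rank statistic with ties counted ½. Both
are verified against brute-force enumerating oracles. Negatives among S1's
eligible cells are not subsampled.

## Interpretation matrices

From a fitted model, `build_projections()` returns:

* `Θ* = B_d B_t'` (p × q): the sign of entry (i, j) says whether drug
  feature i together with target feature j tends to occur in interactions
  (+), in non-interactions (−), or nowhere in the data (exactly 0); the
  magnitude is the intensity.
* `Θ_d = Θ* F_t'` (p × n): column j profiles which drug features are shared
  by the drugs interacting with target j.
* `Θ_t = (F_d Θ*)'` (q × m): column j profiles which target features are
  shared by the targets of drug j. (Stored q × m, which is what the defining
  formula gives; use the transpose for a drugs-as-rows view.)

`rank_feature_pairs()` sorts Θ*'s entries with deterministic index-based
tie-breaking; `feature_pair_support()` counts, for one (substructure,
k-mer) pair, the carrying drugs and targets and the fraction of their
cross-pairs that are known interactions; `frequent_positive_features()`
reproduces the occurrence-table analysis (a feature qualifies with at least
one strictly positive projection entry — the stricter positive-row-sum
reading is available via `mode = "rowsum"`, and the occurrence denominator
is all entities, not just qualifying ones); `entity_feature_profile()`
gives per-target (per-drug) top/bottom feature lists. Exact zeros carry the
"absent from the dataset" meaning, so they are excluded from ranked lists
and reported as a count; values within 1e-12 of zero but not exactly zero
are counted separately as numerically zero rather than silently merged.

## The synthetic generator

Real benchmark data cannot ship with the package, so `generate_dataset()`
plants the exact structure the model assumes: binary features (Bernoulli
bits, default density 0.3, roughly the set-bit fraction of small-molecule
PubChem fingerprints), a rank-r coupling `Θ_true = G_d G_t'` with Gaussian
factors, scores `Z = F_d Θ_true F_t'`, labels by thresholding Z at the
(1 − density) quantile, and optional symmetric label flips. Default study
conditions: 50 drugs × 40 targets, p = q = 12, r = 3, 10% density, 2% noise.
Tanimoto similarity matrices of the feature bits are attached so the
SVD-featurization route (`features_from_similarity`, which symmetrizes,
clamps negative eigenvalues and keeps components above
`k·eps·λ_max`) is exercisable end to end. A Dirichlet feature mode mirrors
k-mer-frequency features.

What the generator deliberately does *not* emulate: the scale of real
fingerprint/k-mer spaces (881 and 8000 columns), the heavy-tailed degree
distributions of curated DTI networks, block structure from protein
families, and similarity matrices that are not PSD. Passing recovery tests
therefore demonstrates correctness of the machinery, not benchmark-level
performance.

One consequence of the quantile-threshold design is worth stating plainly:
the planted labels are an *indicator* of the bilinear score, not the score
itself, so even the best bilinear fit cannot rank the training labels
perfectly (on the package's standard conditions the ceiling is ≈ 0.92 AUPR
for a direct ridge solution of the full bilinear system, and blocked
double-cold-start CV lands well below that). Recovery tests should
therefore be read against the chance level (the interaction density, 0.10)
and against that ceiling, not against 1.0. Ranking the noise-free labels by
the *planted* Z is, by construction, perfect — that is the sanity anchor
the suite uses.

## Numerical conventions and degenerate inputs

* Eigenvector/singular-vector sign ambiguity is fixed by making each
  vector's largest-magnitude entry positive; exact eigenvalue ties are
  ordered by pivot position. Output is platform-stable.
* All ranked outputs break score ties by (drug index, target index) or
  feature index, ascending, so candidate lists are reproducible.
* k-mer rows are normalized by the window count (L − k + 1); rows sum to 1,
  making sequences of different lengths comparable. Counts-vs-frequencies
  is an open choice in the field; frequencies were chosen and the scale
  only rescales `B_t` at fixed features.
* An all-zero training matrix has rank 0 and no meaningful latent space:
  `resolve_latent_dimension` refuses it, and `run_cv` skips such rounds
  with a warning rather than fabricating scores.
* Constant fingerprint columns are reported but kept — dropping them would
  desynchronize bit positions from the fingerprint dictionary, and the
  ridge terms absorb the collinearity.
* Unlabeled cells are hard zeros during fully-observed training (the
  transductive convention); "unobserved" is expressed only through a mask,
  never by sentinel values in `A`.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run on synthetic instances of
m, n ≤ 50 with p, q ≤ 15 and 2–3 CV repetitions — large enough to exercise
every code path (masked and full ALS, all four splitters, both featurization
routes) while keeping a full run in well under a minute. The public
benchmark scale (hundreds of drugs, 881/8000 features, 50 repetitions) is
reached by the same functions with larger arguments; `score_pairs` never
materializes Θ*, so p·q only matters when the interpretation matrices are
explicitly requested.

## Known limitations

* Squared loss treats unlabeled pairs as true negatives; confidence-weighted
  or ranking losses are out of scope.
* No probability calibration: scores are relative confidences for ranking,
  not interaction probabilities.
* The masked fitter solves one r × r system per row and per column per
  cycle; for very large, very sparse matrices a conjugate-gradient variant
  would be preferable.
* PLSR is used only for initialization; the final `B` factors come from the
  ridge-regularized fixed point, so multicollinearity influences the
  solution through λ…β, not through component choice.
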