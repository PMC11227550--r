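---
title: "Functional representation and decomposition of landmark shape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional representation and decomposition of landmark shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its method: the model behind each
stage, the parameters that matter, the numerical conventions, and the design
choices that were genuinely open. The README shows the worked example; here
we explain *why* the pieces are the way they are.

## From landmarks to curves

A specimen's raw datum is an ordered sequence of `N` digitised 2D landmarks.
Two preprocessing stages are uncontroversial and standard:

**Replicate averaging.** Digitising each image `R` times and averaging the
raw coordinates per landmark (`average_replicates()`) reduces observer error
by roughly `1/sqrt(R)` in each coordinate. Averaging happens on raw
coordinates *before* alignment: observer error lives in image space, and the
mean of raw digitisations is the natural estimate of the digitised point.
`replicate_error()` quantifies the per-round deviation.

**Generalised Procrustes analysis.** `gpa()` centres each configuration,
scales it to unit centroid size, and iterates optimal rotations onto a
consensus that is recomputed and renormalised each sweep. We use *full*
Procrustes alignment (every configuration fixed at unit centroid size)
because size standardisation is part of the registration contract; partial
alignment would leave a scale nuisance in every downstream stage. Rotations
are constrained to determinant +1: anatomical views must never be mirrored,
so the reflection branch of the orthogonal Procrustes solution is excluded.

The aligned specimen is then read as a vector-valued function over the
landmark-index continuum: landmark `j` sits at `t_j = (j − 1)/(N − 1)` on
`[0, 1]`, giving an x-curve and a y-curve per view. Two choices deserve
comment:

- *Parameterisation.* The digitisation order is the only ordering the
  landmark scheme defines, so the default grid is uniform in index. An
  arc-length option (`parameterisation = "arclength"`, spacing grid points
  by consensus segment lengths) is available for schemes where landmarks are
  strongly unevenly spaced along the outline, but it is not the default: it
  makes the functional representation depend on the consensus estimate.
- *Smoothing.* By default the curves are the raw grid values — the embedding
  is lossless, and the data-driven eigenbasis of the decomposition supplies
  all the smoothing the method needs. Optional least-squares B-spline
  smoothing (`smoothing = list(n_basis, order)`) is provided for noisy
  digitisations; at `n_basis = N` it interpolates, reproducing the raw data,
  so the option is a strict generalisation.

No curve registration or warping is applied: landmarks are already in
correspondence across specimens by construction, so the functional domain
needs no alignment.

All inner products on curves use trapezoidal quadrature on the grid; the
weights sum to the domain length 1, so eigenvalues are on the scale of
integrated variance.

## The multivariate decomposition

`mfpca()` implements the score-based estimator. Per element, `ufpca()`
eigen-decomposes the weighted covariance through the symmetrised
`W^{1/2} K W^{1/2}` route — this keeps the matrix exactly symmetric, so the
eigenvectors are orthogonal to machine precision, and the back-transform
`W^{−1/2}` makes the eigenfunctions orthonormal under the quadrature inner
product rather than the Euclidean one. The univariate scores are collected
into `Xi`, and the eigen-analysis of `Z = Xi'Xi/(n − 1)` couples the
elements; the covariance divisor is `n − 1` at both stages, consistently.

Properties the test suite verifies, which are worth knowing when reading
results:

- With full univariate retention the estimator is *exact*: its eigenvalues
  and scores coincide with a quadrature-weighted PCA of the concatenated
  centred curves, and the truncated Karhunen–Loève expansion reconstructs
  the centred data to numerical precision.
- The multivariate score covariance is diagonal with the eigenvalues on the
  diagonal — scores are uncorrelated by construction.

**Truncation.** The retention rule is a per-element proportion-of-variance
threshold, default `pve_threshold = 0.99`, applied again at the multivariate
stage; `n_components` overrides the multivariate truncation. 0.99 keeps the
univariate stage close to lossless (protecting the exactness property above)
while still discarding numerically negligible components. The
proportion-of-variance denominator is the sum of *all numerically nonzero*
eigenvalues (threshold `1e-10` times the largest), so reported percentages
refer to the data's actual variance, not the retained subspace. The pipeline
guarantees at least `k` multivariate components survive truncation, since
the downstream stages consume exactly `k = 3` scores.

**Sign convention.** Eigenvectors are sign-fixed by making their largest-
magnitude entry positive (ties broken by lowest index), and scores and
eigenfunctions are flipped consistently. Eigen-decomposition signs are
otherwise arbitrary, and this convention makes every result bit-stable
across runs — a precondition for the determinism contract. Among exactly
equal eigenvalues only the spanned subspace is identified; the deterministic
sign fix keeps the reported basis stable but it should not be
over-interpreted.

The classical branch, `classical_pca()`, is covariance-form PCA (divisor
`n − 1`) of the flattened Procrustes coordinates. No tangent-space
projection is applied before PCA: Procrustes coordinates are used directly,
which keeps the two branches strictly comparable (both consume the identical
aligned dataset) and matches common practice for small shape variation,
where the curvature correction is far below the noise level. At most
`min(n − 1, 2N)` components are retainable; trailing numerically-zero
eigenvalues are dropped at relative tolerance `1e-10`.

## Discriminant analysis and classification

`lda_fit()` builds the within- and between-class scatters from their
explicit formulas (`W` with divisor `n − M`, `B` with divisor `M − 1`,
both from the one-hot indicator algebra) and solves the generalised
eigenproblem by Cholesky whitening of `W` — numerically preferable to
forming `W^{−1}B`, which the test suite uses only as an independent oracle.
The between-scatter is computed in the symmetric outer-centred form
`(GH − 1ρ̄')'(GH − 1ρ̄')`, the only reading that yields a symmetric positive
semidefinite matrix. If `W` is singular (collinear scores), a ridge of
`1e-8 · trace(W)/K` is added with a warning rather than failing: the
degeneracy is an input property the user should see, not a dead end. With
`K = 3` scores and `M = 3` classes there are `min(K, M − 1) = 2` axes, and
each axis's eigenvalue share — its separation percentage — sums to 100 by
construction.

The discriminant consumes the first `K = 3` component scores of either
branch. Three is the package default throughout because it is the standard
"small-K" operating point for score-based shape classification: it keeps
all classifiers in a low-dimensional, well-conditioned regime while the
leading components carry the bulk of between-class signal.

`evaluate_protocol()` is deliberately plain: stratified 70:30 split
(per-class training count `round(0.7 · n_c)`, round-half-to-even, clamped so
both sides keep every class), 20 replicates, plain proportion-correct
accuracy, sample sd over replicates. All four classifiers share the same
splits within a replicate — the fairest comparison, since between-split
variance then cancels in differences. Hyperparameters the protocol leaves
open are fixed at conventional defaults and exposed in `classifier_spec()`:
SVM cost 1 and `gamma` set from the feature variance (the `1/(2σ²)` form is
available by passing `gamma` explicitly), 500 trees and `floor(sqrt(K))`
features per split for the forest, elastic-net mixing `α = 0.5` with penalty
strength from stratified 5-fold CV on the training set only. Scores enter
the classifiers unstandardised: principal component scores already carry
meaningful, variance-ordered scales.

Gaussian naive Bayes is computed in-package directly from the Bayes
posterior formula (log-space, with a `1e-9` variance floor against constant
features) because the package treats posterior normalisation as an exact
contract; a test cross-checks it against an independent implementation.

## What the synthetic generator emulates — and what it does not

`simulate_dataset()` mirrors the data-generating situation of a replicated
digitisation study: class template shapes, individual shape variation,
arbitrary image placement (similarity transform per specimen), and `R`
digitisation rounds with independent observer noise added in shape space
*before* the transform, so replicate error scales with the specimen as it
does on real images.

Defaults were chosen once to mirror a three-species craniodental study
design: three classes of 29/30/30 specimens, 25 landmarks (a dorsal-view
count), 3 replicates, template separation `δ = 0.10` in full-Procrustes
units (a species-level shape difference), individual landmark sd
`σ_L = 0.025`, digitisation sd `σ_D = 0.005` (observer error several times
smaller than biological variation), rotations uniform on `±π`, scale
0.75–1.25, translations `±50` image units. Templates sit on a perturbed
ellipse so that landmark order traces a closed outline, making the
index-ordered curve representation geometrically meaningful; class
displacement fields are smooth, projected into the tangent space of the
base shape, orthogonalised, and calibrated by root-finding so every pairwise
template distance hits `δ` within 2%.

Two honest limitations of the generator, which bound what passing tests
prove about real data:

- Individual variation is *independent per landmark*. Real craniodental
  variation is spatially smooth and low-rank, which concentrates variance in
  the first few components; iid landmark noise spreads it across all
  `2N − 4` shape dimensions. Synthetic first-two-component variance shares
  are therefore much lower than on real crania, and the functional branch's
  practical advantage on smooth biological variation is *not* demonstrated
  by these fixtures — only the correctness of every computation is.
- There is no allometry (no size–shape covariation) and no landmark-type
  structure: semilandmark annotations are carried but, as in the package's
  analysis pipeline generally, never treated differently (no sliding).

## Numerical conventions, in one place

- GPA: consensus initialised from the first configuration (after
  centring/scaling); convergence when the consensus RMS change drops below
  `tol = 1e-8`; `max_iter = 100`; non-convergence is a warning with results
  returned, not an error; a final rotation pass makes each configuration
  exactly optimal against the stored consensus. The least-squares objective
  is recorded per sweep and is provably non-increasing.
- Degenerate configurations (all landmarks coincident) are errors wherever
  size or alignment is required.
- Quadrature: trapezoidal; exact for linear integrands on the grid.
- Eigenvalue floors: negative round-off eigenvalues are clipped at zero;
  "numerically nonzero" always means `> 1e-10` relative to the largest.
- All stochastic stages (simulation, splits, bootstraps, folds) draw their
  seeds deterministically from a single master seed; two runs with the same
  configuration are byte-identical, which the acceptance suite checks
  against files on disk.
- Problem sizes in the shipped tests are chosen for sharp oracles rather
  than realism (e.g. `n = 6`, `d = 2`, `N = 4` for the dense decomposition
  oracle); the end-to-end ladder runs the full study-scale protocol
  (90 specimens, 20 split replicates, four classifiers) across four
  separation-to-noise ratios.

## Known limitations

- 2D only; `LM3=` records are rejected by design.
- No sliding-semilandmark treatment, no tangent-space projection, no
  missing-landmark estimation, no curve warping — each excluded
  deliberately, as noted above.
- The spline-parameterised random-effects variant of functional discriminant
  analysis (for sparsely/irregularly sampled curves) is out of scope; the
  discriminant operates on decomposition scores, which is the appropriate
  form when every specimen is observed on the same complete grid.
- The combined-views analysis concatenates per-view alignments (GM branch)
  or stacks per-view curve elements into one `2V`-element datum (functional
  branch). Score-level concatenation after per-view decomposition would be a
  defensible alternative reading; the element-level stacking was chosen
  because it lets the decomposition model cross-view covariance, which is
  the point of a multivariate functional analysis.
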