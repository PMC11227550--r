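# funmorph

Functional-data analysis of landmark-based shape, for morphometricians who
want to go beyond treating a landmark configuration as a bag of coordinates.

## The problem

Landmark-based geometric morphometrics (GM) describes an organism's shape by
the 2D coordinates of `N` homologous points digitised in a fixed order on its
image — for example the 25, 50 and 47 landmarks of the dorsal, jaw and
lateral views of a small-mammal cranium. After generalised Procrustes
analysis (GPA) removes translation, scale and rotation, the classical
workflow runs PCA on the flattened Procrustes coordinates and feeds the
leading scores to ordination, discriminant analysis and classifiers.

Treating the `N` coordinates as unrelated variables ignores that consecutive
landmarks trace a curve along the anatomy. `funmorph` instead represents each
aligned specimen as a *vector-valued function* over the landmark-index
continuum: landmark `j` maps to `t_j = (j-1)/(N-1)` on `[0, 1]`, giving one
x-curve `X(t)` and one y-curve `Y(t)` per specimen (two per view; `2V` for
`V` views analysed jointly). The sample of curves is decomposed by
**multivariate functional PCA (MFPCA)**, estimated score-wise:

1. For each element `p` (each coordinate curve family), fit a univariate
   FPCA: eigen-decompose the quadrature-weighted sample covariance
   `K_p(s, t)`, giving eigenfunctions `phi_{p,j}` and scores `xi_{p,j}^{(i)}`
   for `j = 1..J_p`.
2. Collect all univariate scores of specimen `i` into row `i` of
   `Xi ∈ R^{n×J}`, `J = Σ_p J_p`, and form the block score-covariance
   `Z = Xi' Xi / (n − 1)`.
3. Eigen-decompose `Z` into eigenvalues `lambda_j` and orthonormal
   eigenvectors `v_j`.
4. The multivariate eigenfunctions combine the univariate ones through the
   blocks of `v_j`, and the multivariate scores are `Xi v_j`.

With full univariate retention the estimator is exact (it reproduces the
quadrature-weighted PCA of the concatenated curves); with a variance
threshold it is the practical truncated Karhunen–Loève expansion.

The first `K = 3` scores of either branch (classical GM-PCA or the
functional decomposition) feed:

- **linear discriminant analysis** built from the explicit scatter matrices
  `W = (ρ − GH)'(ρ − GH)/(n − M)` and `B = (GH − 1ρ̄')'(GH − 1ρ̄')/(M − 1)`,
  whose generalised eigenvectors maximise `a'Ba / a'Wa`; each axis's
  eigenvalue share is its *separation percentage*;
- a **replicated classification protocol**: stratified 70:30 train/test
  split repeated 20 times; Gaussian naive Bayes, RBF-kernel SVM, random
  forest and elastic-net multinomial GLM fitted on the training scores;
  mean ± sd test accuracy reported per classifier.

A synthetic generator (`simulation_spec()` / `simulate_dataset()`) emits
class-structured landmark data — template shapes a prescribed Procrustes
distance apart, individual landmark noise, random similarity transforms,
replicated digitisation — through the same TPS entry points as real data, so
the whole pipeline is testable end to end.

## Worked example

A synthetic three-class study at a realistic scale (29/30/30 specimens,
25 landmarks, 3 digitisation replicates):

```r
library(funmorph)

spec <- simulation_spec(n_per_class = c(29, 30, 30), seed = 1)
sim  <- simulate_dataset(spec)

lm_avg <- average_replicates(sim$replicates)   # mean of the 3 digitisations
fit <- gpa(lm_avg)
fit
#> Generalised Procrustes analysis
#>   specimens:   89
#>   landmarks:   25
#>   iterations:  4  (converged)

mf <- fit |> to_functional() |> mfpca()
glance(mf)
#> # A tibble: 1 × 4
#>       n n_components n_eigenvalues pve_first2
#>   <int>        <int>         <int>      <dbl>
#> 1    89           42            46      0.174

scores <- shape_scores(mf, k = 3)
round(separation_percentages(lda_fit(scores)), 2)
#> [1] 60.57 39.43

proto <- evaluate_protocol(scores[, c("label", "PC1", "PC2", "PC3")],
                           reps = 20, seed0 = 1)
tidy(proto)
#> # A tibble: 4 × 3
#>   classifier mean_accuracy sd_accuracy
#>   <fct>              <dbl>       <dbl>
#> 1 NB                 0.935      0.0237
#> 2 SVM                0.931      0.0276
#> 3 RF                 0.933      0.0309
#> 4 GLM                0.944      0.0306
```

Reading the numbers: GPA converged in 4 sweeps; the functional decomposition
keeps 42 of 46 nonzero components at the default 99% variance threshold
(the generator's per-landmark noise spreads variance widely, so the first
two components carry 17.4% — see the vignette for why real craniodental data
concentrates far more); the first discriminant axis carries 60.6% of the
between-class separation; and all four classifiers sit near 93–94% mean test
accuracy over the 20 splits.

`run_pipeline()` chains all of the above for several views at once, runs the
classical GM branch and the functional branch off the identical aligned
dataset, and writes score tables, eigenvalue tables, discriminant
coordinates and the accuracy report to disk. `autoplot()` methods produce
the standard ordination, discriminant and accuracy figures. A thin CLI lives
at `inst/scripts/funmorph` (`simulate`, `run-all`).

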