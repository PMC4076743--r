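# parcelbench

Benchmarking brain parcellations derived from multi-subject functional
contrast images: which clustering algorithm, and how many parcels?

`parcelbench` is for neuroimaging researchers who build group-level
parcellations from per-subject standardized-effect maps and need a
principled way to compare algorithms and to choose the number of parcels
K. It implements:

* **Four parcellation algorithms** over a voxel domain: k-means on
  PCA-reduced signals, spatially constrained Ward agglomeration
  (guaranteed-connected parcels, full merge tree reusable across K),
  spectral clustering on a functionally weighted voxel adjacency graph,
  and a signal-free geometric reference.
* **A per-parcel mixed-effects scoring model**. Within a parcel c and
  contrast, pooling the p = |c|·N values across N subjects,

      y = μ1 + Xβ + ε,   β ~ N(0, σ₂²I),  ε ~ N(0, σ₁²I)

  so marginally y ~ N(μ1, σ₁²I + σ₂²XXᵀ). σ₁ is the within-subject
  standard deviation, σ₂ the between-subject one. Parameters are
  estimated by EM with exact block-wise likelihoods; any fixed labeling
  (including an external atlas volume) can be scored.
* **Three families of model-selection criteria**: BIC
  (−2ℓ + 3 log p per parcel and contrast, summed), cross-validated
  log-likelihood (shuffle-split over subjects, clustering re-estimated
  on each training set), and bootstrap reproducibility (mean pairwise
  adjusted Rand index / adjusted mutual information across re-clustered
  subject resamples).
* **A 2D simulation bench** with known ground truth — piecewise-constant
  parcel means, a shared per-subject offset, pixel noise, optional
  integer spatial jitter and Gaussian smoothing — plus an orchestrated
  replication study (`run_model_selection_experiment`) contrasting the
  liberal behaviour of accuracy-based criteria with the conservative
  behaviour of reproducibility-based ones.

3D NIfTI contrast volumes and masks are supported through
`signal_from_nifti()` / `write_parcellation_nifti()`.

## Worked example

Simulate a 10-subject dataset on a 20 × 25 grid (5 true parcels, unit
within- and between-subject noise, 1-pixel jitter, fwhm 1.17 smoothing),
parcellate it with constrained Ward, and score the result:

```r
library(parcelbench)

ds <- simulate_parcel_dataset(
  simulation_config(jitter = 1, fwhm = 1.17), seed = 3)
ds$signal
#> <parcel_signal> 10 images (10 subjects x 1 contrasts) over 500 voxels
#>   grid: 20 x 25

p <- parcellate(ds$signal, "ward", K = 5)
p
#> <parcellation> 500 voxels in 5 parcels (ward, connected)

adjusted_rand(ds$truth$labeling, p$labels)
#> [1] 0.4302584
```

The recovery ARI of 0.43 is typical under jitter: displaced subjects
blur the parcel boundaries, so even the correct K does not recover the
template exactly. Scoring the parcellation fits one mixed-effects model
per parcel:

```r
glance(fit_parcellation_model(ds$signal, p))
#> # A tibble: 1 × 6
#>       K n_fits loglik    bic mean_sigma1 mean_sigma2
#>   <int>  <int>  <dbl>  <dbl>       <dbl>       <dbl>
#> 1     5      5 -5740. 11580.       0.796       0.846
```

Sweeping K shows the characteristic variance re-allocation — finer
parcellations are more homogeneous within subject (σ₁ falls) while the
parcel means vary more across subjects (σ₂ rises) — and the BIC keeps
improving with K on smoothed data, which is exactly why it over-selects:

```r
variance_component_curve(ds$signal, "ward", K_grid = c(2, 5, 10, 20))
#> # A tibble: 4 × 5
#>       K sigma1 sigma2 loglik    bic
#>   <int>  <dbl>  <dbl>  <dbl>  <dbl>
#> 1     2  0.759  0.821 -6147. 12338.
#> 2     5  0.796  0.846 -5740. 11580.
#> 3    10  0.804  0.867 -5599. 11365.
#> 4    20  0.729  0.942 -5504. 11299.

bootstrap_reproducibility(ds$signal, "ward", K = 5, B = 10,
                          metric = "ari", seed = 1)
#> <stability_estimate> B = 10, mean ARI = 0.6552
```

Bootstrap ARI declines as K grows (here 0.66 at K = 5), so
reproducibility-based selection is conservative where BIC is liberal.
The full replicated study is one call:

```r
ex <- run_model_selection_experiment(experiment_config(
  simulation = simulation_config(jitter = 1, fwhm = 1.17),
  methods = c("ward", "kmeans", "spectral"),
  criteria = c("BIC", "B-AMI"), replications = 20, seed = 42))
glance(ex)      # median selected K* and mean recovery per method/criterion
autoplot(ex)    # the selected-K distributions
```

See the vignette (`vignettes/parcellation-model-selection.Rmd`) for the
model, the algorithms, the simulation design and the package's known
limitations.

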