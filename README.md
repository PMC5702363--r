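# stableHMRF

Heavy-tailed hidden Markov random field segmentation of volumetric images.

Intensity histograms of brain tissues in T1 MRI — and of many other
tomographic modalities — are asymmetric and heavy-tailed, so the Gaussian
mixture assumption behind classical EM-HMRF tissue segmentation breaks down
in the presence of impulsive outliers. `stableHMRF` implements an
expectation-maximization hidden Markov random field segmenter whose class
densities are **α-stable distributions** — the four-parameter family
S(α, β, γ, δ) that contains the Gaussian as its α = 2 limiting case
(σ = √2·γ) and allows arbitrarily heavy tails (smaller α) and skewness
(β ≠ 0). The Gaussian EM-HMRF is available as the built-in limiting-case
baseline, so the two assumptions can be compared on identical machinery.

## Model

Voxel labels x (two tissue classes on a masked 3D grid) are a Markov random
field with a Potts prior over 6-connected neighbor pairs,

    U(x) = Σ_{⟨i,j⟩} β_C · (1 − 1[x_i = x_j]),       β_C = 0.5 by default,

and observations y are conditionally independent given the labels, each
following its class's α-stable density f(y_i; θ_{x_i}). Segmentation is MAP
estimation, i.e. minimization of the posterior energy

    U(x | y) = Σ_i −log f(y_i; θ_{x_i}) + U(x),

by classification-EM: each iteration refits every class's parameters by
maximum likelihood on its currently allocated voxels (the M-step; mixture
weights are the allocated proportions) and then updates the labels by
iterated conditional modes (ICM) sweeps (the MAP step). With β_C = 0 the
model reduces to a spatial-free finite mixture classifier.

α-stable densities lack closed forms (outside the Gaussian and Cauchy
cases) and are evaluated numerically: FFT inversion of the characteristic
function in Nolan's S0 parameterization on a cached standardized grid, with
analytic Pareto tails far out. Sampling uses the Chambers–Mallows–Stuck
transform; estimation uses quantile (McCulloch-style) initialization
followed by bounded quasi-Newton likelihood maximization.

## Worked example

The package ships a synthetic benchmark: a hollow sphere (shell between
radii 5 and 8 voxels) in a 20×20×20 grid, class 1 (background + core)
drawn from S0(α=1.4, β=1, γ=10, δ=0) and class 2 (shell) from
S0(α=1.8, β=0, γ=10, δ=20) — two heavily overlapping, impulsive
components whose pooled histogram is unimodal.

```r
library(stableHMRF)
ph  <- hollow_sphere_phantom(phantom_spec(family = "stable", seed = 1))
res <- em_hmrf(ph$image, ph$truth,
               hmrf_config(family = "stable", beta_c = 0.5, seed = 1))
res
#> EM-HMRF segmentation (stable family, beta_c = 0.5): 4 iteration(s), converged
#> final posterior energy: 35469.2, log-likelihood: -34538.2
#> component [stable], weight 0.8006: S0(alpha=1.373, beta=1, gamma=9.944, delta=-0.3357)
#> component [stable], weight 0.1994: S0(alpha=1.837, beta=-0.05585, gamma=9.106, delta=22.06)
score_segmentation(res$labels, ph$truth)
#> segmentation score over 8000 voxels: accuracy 0.9699
#>   Dice class1: 0.9812
#>   Dice class2: 0.9249
```

The fitted components recover the generating parameters and the
segmentation reaches ~97% voxelwise accuracy. The Gaussian baseline on the
same volume collapses — one component inflates its standard deviation to
absorb the outliers (σ̂ = 386 vs 17.5 here) — and drops to ~77% accuracy
after label matching:

```r
res_g <- em_hmrf(ph$image, ph$truth,
                 hmrf_config(family = "gaussian", seed = 1, min_class_size = 2))
score_segmentation(match_labels(res_g$labels, ph$truth)$labels, ph$truth)
#> segmentation score over 8000 voxels: accuracy 0.7654
#>   Dice class1: 0.8667
#>   Dice class2: 0.0198
```

On Gaussian-noise data both families agree (~95% accuracy) and the stable
fit lands exactly on the α = 2 boundary with γ̂ = σ̂/√2, where β is flagged
undefined.

## Command line

A thin launcher wraps the same functions:

```sh
Rscript inst/cli/stablehmrf phantom --family stable --seed 1 \
    --out-image img.nii.gz --out-labels truth.nii.gz
Rscript inst/cli/stablehmrf segment --input img.nii.gz --init truth.nii.gz \
    --family stable --beta-c 0.5 --out-labels seg.nii.gz --trace trace.csv
Rscript inst/cli/stablehmrf evaluate --pred seg.nii.gz --truth truth.nii.gz
```

For real MRI use, `segment --atlas map1.nii.gz,map2.nii.gz,...` builds the
initial labeling from pre-registered expert label maps by majority vote
(`atlas_init()`); registration itself is out of scope. Applying the
pipeline to a real atlas-annotated dataset such as the IBSR repository
requires downloading that data and registering its label maps externally,
so it is not part of the automated checks.

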