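# bibseg

Bayesian multi-atlas segmentation of the corpus callosum on the midsagittal
plane.

## The problem and who this is for

The corpus callosum (CC) is the bright white-matter arc on the midsagittal
slice of a T1-weighted brain MRI; its area and regional thickness are
standard endpoints in studies of epilepsy, autism, Alzheimer's disease and
alcohol exposure. Automatic CC segmentation has to combine two kinds of
evidence: where the CC *should* be (shape and location, stable across
subjects after registration) and what the boundary *looks* like locally
(where the thin, equally bright fornix is the classic false positive).
`bibseg` is for researchers who need a reproducible 2D CC segmenter with
both baselines and the fused method in one place, plus a synthetic phantom
generator so the whole pipeline can be developed and tested without access
to labelled MRI.

## The method

Each pixel *i* of the cropped midsagittal slice is labelled by comparing
class posteriors `p(ε_i | c_l) p(c_l)` for `l ∈ {f, b}`:

* **Prior — multi-atlas voting (PIEMV).** Atlases warped to the target are
  ranked by mean local normalized cross-correlation (7×7 windows); the top
  10 masks are fused by per-voxel label frequency,
  `p(c_l) = Σ_a δ(L_a(i), l) / N`.
* **Likelihood — sparse-representation error (LESRE).** From the 30 (or all
  available) most similar atlases by sum of squared differences, every
  patch in a 7×7 search window around *i* enters a foreground or background
  dictionary according to its atlas label. Patches are 13×13, three
  channels (intensity, gradient magnitude, gradient direction), channel-
  scaled and L2-normalized. The target patch is sparsely coded against each
  dictionary by orthogonal matching pursuit; the ratio of the two residual
  norms `ε = ε_f / ε_b` is the likelihood's argument.
* **Fusion (BIbS).** Per class, a gamma density `ε^(α−1) e^(−ε/β) /
  (Γ(α) β^α)` is calibrated on error ratios pooled by true label over a
  leave-one-out pass through the atlas cohort. The label is foreground iff
  `log p(ε|f) − log p(ε|b) + log p_f − log p_b ≥ 0`, evaluated on the
  prior's uncertain band (`0 < p_f < 1`); unanimous voxels follow the
  prior.

Evaluation ships with the Dice index `2|A∩B|/(|A|+|B|)×100`, 4-connected
component counts, Euler numbers (components minus holes), a leave-one-out
harness and parameter sweeps.

## Worked example

```r
library(bibseg)

# a reproducible cohort of 12 synthetic phantoms with ground truth
cohort <- generate_cohort(12, phantom_params(), seed = 42)
model  <- bibs_fit(cohort, bibs_config())   # calibrate the gamma likelihood
print(model)
#> Bayesian corpus-callosum segmentation model (12 atlases)
#> Gamma likelihood of the reconstruction-error ratio
#>   foreground: alpha = 49.78, beta = 0.01606 (mean 0.7996, n = 3827)
#>   background: alpha = 69.52, beta = 0.01789 (mean 1.244, n = 3738)
#>   fit: mle_newton
#>   config hash: 7f4be0f5

target <- cohort$atlases[[1]]
seg <- predict(model, target$image)         # full Bayesian segmentation
print(seg)
#> <cc_decision 64 x 96: 645 foreground, 678 full-Bayes voxels>
dice(seg$mask, target$mask)
#> [1] 98.52409
count_components(seg$mask); euler_number(seg$mask)
#> [1] 1
#> [1] 1
```

The calibrated model says foreground patches reconstruct about 36% better
from the foreground dictionary (mean ratio 0.80) while background patches
reconstruct worse from it (mean ratio 1.24); the decision used the full
Bayesian rule on the 678 voxels where the 10 voting atlases disagreed and
followed their unanimous vote elsewhere. The result overlaps the ground
truth at 98.5 Dice and is a single hole-free region (1 component, Euler
number 1) — the topology a tractography seed requires.

`predict(model, target$image, method = "piemv")` and `method = "lesre"`
give the prior-only and likelihood-only baselines;
`leave_one_out(cohort, config = bibs_config())` runs all methods round-robin
and `summary()` of its result reports per-method mean ± sd Dice and paired
tests.

## Command line

A thin wrapper over the same functions (exit codes: 0 ok, 1 usage, 2 data,
3 numerical):

```sh
Rscript inst/cli/bibseg.R simulate  --n 20 --out cohort/ --seed 7
Rscript inst/cli/bibseg.R calibrate --atlases cohort/ --out model.json
Rscript inst/cli/bibseg.R segment   --target cohort/phantom_000_image.png \
    --atlases cohort/ --model model.json --out seg.png \
    --gold cohort/phantom_000_mask.png
Rscript inst/cli/bibseg.R evaluate  --atlases cohort/ --out eval.csv
```

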