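# fastvision

Constrained maximum-entropy image sketches and the computational chain of a
flicker-adaptation contrast psychophysics experiment, in R.

## The problem

A fast, coarse visual channel with magnocellular characteristics is thought
to support rapid scene recognition. A behavioural way to probe it: compress
natural images into **sketches** that retain only their most informative
local features, measure contrast thresholds for recognizing them in a
two-alternative forced-choice (2AFC) task, and test whether desensitizing
the magnocellular pathway with 10 Hz luminance flicker elevates those
thresholds — while control tasks (motion direction and orientation
discrimination of noisy Gabors) separate transient- from sustained-channel
contributions.

This package is for vision scientists who want to build such stimuli, and
for anyone who wants a fully tested, reproducible implementation of the
analysis chain, including a synthetic observer cohort that makes every
downstream stage verifiable without human data.

### The sketch model

From 1-bit images, all 512 possible 3×3 binary patches are counted at every
pixel (overlapping windows included). The sketch keeps exactly the pixels
whose patch belongs to the feature set **S** maximizing the transmitted
Shannon entropy under two resource constraints,

```
maximize   H(S) = Σ_{i∈S} p_i log2(1/p_i)
subject to |S| ≤ N   (capacity, default 50)
           Σ_{i∈S} p_i ≤ W   (bandwidth, default 0.05)
```

solved by a refined greedy (production) and an exhaustive oracle (small
alphabets, for validation).

### The analysis chain

Per subject, task and condition: Bernoulli maximum-likelihood fits of the
cumulative-Gaussian 2AFC psychometric function `p(c) = 0.5 + (0.5 − λ)
Φ((c − μ)/σ)`; thresholds `T` at 75% correct; paired Wilcoxon signed-rank
tests (exact for n ≤ 25, even under ties) with rank-biserial effect sizes
and bootstrap CIs; threshold elevations `100 (T_flicker − T_baseline) /
max contrast`; Friedman test with Kendall's W and Conover post hocs across
tasks.

## Worked example

```r
library(fastvision)

## sketch extraction on a synthetic 1-bit texture
set.seed(7)
img <- matrix(as.integer(runif(60 * 80) > 0.55), 60, 80)
d   <- patch_distribution(img)
fs  <- select_features_greedy(d, N = 50, W = 0.05)
fs
#> Feature set: 47 patterns (N = 50, W = 0.05)
#>   total probability: 0.049956
#>   entropy: 0.4923 bits
generate_sketch(img, fs)
#> Sketch 60x80: 226 pixels retained (density 0.0500)
```

The selected features use essentially the whole bandwidth (0.04996 of the
cap 0.05), and the sketch density equals that total probability — the
bandwidth cap *is* the expected fraction of retained pixels.

```r
## full simulated experiment: 30 subjects x 3 tasks x 2 conditions,
## 6400 trials per subject, then the complete statistics chain
cfg <- experiment_config(seed = 42)
b   <- run_experiment(cfg)
report(b)
#> Task: image (n = 30)
#>   baseline threshold: M = 0.151, SD = 0.051
#>   flicker threshold:  M = 0.311, SD = 0.099
#>   Wilcoxon W = 0, p = 1.83e-06 (normal approximation); rrb = -1.000, 95% CI [-1.000, -1.000]
#>   mean threshold elevation: 16.04% of max contrast (significant)
#> ...
#> Task: orientation (n = 30)
#>   baseline threshold: M = 0.039, SD = 0.013
#>   flicker threshold:  M = 0.040, SD = 0.013
#>   Wilcoxon W = 146, p = 0.0769 (normal approximation); rrb = -0.372, 95% CI [-0.708, 0.049]
#>   mean threshold elevation: 1.19% of max contrast (not significant)
#>
#> Across tasks: Friedman chi2(2) = 53.07, p = 3e-12, Kendall's W = 0.884
```

Flicker elevates the image-task threshold by ~16% of the maximum contrast
and the motion threshold by ~10%, while the orientation threshold is
untouched — the elevation/elevation/null signature of a transient-channel
manipulation. The per-task means track the generator's set points (image
0.14 → 0.29, motion 0.045 → 0.063, orientation unchanged), with the small
upward offsets expected from the image task's lapse rate and the
log-normal between-subject spread.

See the vignette (`vignettes/flicker-sketch-pipeline.Rmd`) for the model's
assumptions, every tunable parameter, and the design decisions.

A thin command-line wrapper is installed at `inst/cli/fastvision.R`
(`simulate`, `report`, `sketch-dist`, `sketch-select`, `sketch-render`).

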