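---
title: "Sketch stimuli, synthetic observers, and the flicker-adaptation analysis chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sketch stimuli, synthetic observers, and the flicker-adaptation analysis chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastvision)
```

## The scientific setting

Rapid scene recognition is thought to rely on a fast, coarse visual channel
with magnocellular characteristics: transient, achromatic, highly sensitive
to luminance contrast. One way to probe it behaviourally is to desensitize
that channel with prolonged luminance flicker and measure how contrast
thresholds change across tasks that load on it to different degrees.
`fastvision` implements the full computational chain of such an experiment:

1. **Sketch stimuli.** Natural images, reduced to 1-bit black/white, are
   compressed into *sketches* that retain only the pixels whose local 3×3
   pattern belongs to an "optimal" feature set. The feature set maximizes
   the Shannon entropy transmitted by the retained patterns under two
   resource constraints: a capacity cap *N* on the number of distinct
   features the system may store, and a bandwidth cap *W* on the total
   probability (equivalently, the expected fraction of retained pixels).
   The stimuli of the reference paradigm use *N* = 50 and *W* = 0.05.
2. **Companion stimuli.** Drifting and tilted Gabor patches in static
   Gaussian noise (the motion and orientation control tasks), the 10 Hz
   uniform-field flicker adapter, random-pixel masks, and contrast-scaled
   renderings of all of these against a 12 cd/m² grey background with black
   at 7 and white at 22 cd/m².
3. **A synthetic observer cohort** producing trial-level two-alternative
   forced-choice (2AFC) data with the psychometric structure the analysis
   assumes, so the entire downstream chain is testable without human data.
4. **Psychometric fitting** (cumulative Gaussian, Bernoulli maximum
   likelihood, 75%-correct thresholds) and the **nonparametric statistics
   chain**: Shapiro–Wilk gate, paired Wilcoxon signed-rank tests with
   rank-biserial effect sizes, bandwidth-normalized threshold change
   scores, and a Friedman test with Kendall's W and Conover post hocs.

## The sketch model

All 512 possible 3×3 binary patches are counted at every pixel with a
complete neighborhood, overlapping windows included, pooled over a training
set of images (`patch_distribution()`). Selection then maximizes

$$H(S) = \sum_{i \in S} p_i \log_2 \frac{1}{p_i}
  \quad\text{s.t.}\quad |S| \le N,\; \sum_{i \in S} p_i \le W .$$

This is a two-constraint knapsack. The package ships two solvers:

* `select_features_exact()` — exhaustive over all subsets, feasible for
  alphabets of ≤ 20 observed patterns; used as the gold standard.
* `select_features_greedy()` — the production solver. The base scan ranks
  patterns by descending entropy contribution $p\log_2(1/p)$ (ties broken
  by ascending pattern code) and admits each pattern that keeps
  $\sum p \le W$. Because that scan can pack the bandwidth poorly — the
  entropy contribution peaks at $p = 1/e$, so a few heavy patterns can
  crowd out better combinations of light ones — the default adds a
  deterministic refinement: the scan is repeated with the candidate list
  truncated at every probability ceiling (capturing "all patterns lighter
  than x" solutions), and the best solution is then improved by
  drop-and-refill moves until no move raises the entropy. On small
  alphabets (≤ 24 patterns) drops of up to three patterns are explored
  with all truncated refill orders; on full 512-pattern alphabets only
  single drops with the plain refill order are used, keeping runtime well
  under a second. `refine = FALSE` restores the plain scan.

Design choices where the procedure is under-determined, fixed once and
recorded in outputs:

* **Binarization** threshold defaults to the per-image median (balancing
  black and white mass); a fixed threshold is available. The method used is
  recorded in the `provenance` field.
* **Borders.** Patches are only counted at centers with a complete 3×3
  neighborhood, and sketch borders are background — no padding, so patch
  statistics are unbiased by invented pixels.
* **Pattern encoding** is row-major with the top-left pixel as most
  significant bit, making serialized feature sets bit-exact.
* A pattern and its contrast-reversed or rotated variants are treated as
  distinct features.

```{r sketch-example}
set.seed(7)
img <- matrix(as.integer(runif(60 * 80) > 0.55), 60, 80)
d <- patch_distribution(img)
fs <- select_features_greedy(d, N = 50, W = 0.05)
fs
sk <- generate_sketch(img, fs)
sk
```

The achieved sketch density equals the summed probability of the selected
patterns under the image's own statistics, which is why it tracks the
bandwidth cap.

## Stimulus generation

`render_at_contrast()` maps a three-state sketch (black / white /
background) to luminances by linear interpolation from the background
(contrast 0) to the full luminance map (contrast 1). This anchoring was
chosen because the background (12 cd/m²) is *not* the midpoint of black (7)
and white (22): scaling symmetric about the stimulus mean could not
reproduce the stated full-contrast luminances. A consequence worth noting:
the full-contrast Michelson contrast of the black/white pair is
`michelson_contrast(22, 7)` ≈ 0.517, slightly above the nominal 50%; the
luminances are treated as ground truth.

Gabor patches (`make_gabor_frames()`) use a sinusoidal carrier under a
Gaussian envelope whose standard deviation defaults to size/6, so ±3 SD
spans the stated 5° patch. The phase advances by 360·(temporal
frequency)/(frame rate) degrees per frame — 30°/frame for 10 Hz at 120 Hz.
A single static Gaussian noise field (SD 50 in 8-bit pixel units) is drawn
per trial from its seed and added *after* contrast scaling of the carrier,
so contrast manipulations do not alter the noise power; frames are clipped
to the 8-bit display range. The flicker adapter alternates two uniform
fields as a square wave (10 Hz: 6-frame half periods at 120 Hz); half
periods that do not divide the frame rate are rounded to the nearest frame
with a warning. All generation is deterministic given specification and
seed.

## The synthetic cohort

`simulate_cohort()` emulates the study design: 30 subjects, three tasks
with the tested contrast ladders (image: 10 levels from 0.02 to 1; motion:
12 levels from 0.01 to 0.2; orientation: 10 levels from 0.01 to 0.1), two
conditions, and 100 trials per level — 6400 trials per subject. Each trial
is a Bernoulli draw from

$$p(c) = \tfrac12 + \left(\tfrac12 - \lambda\right)
  \Phi\!\left(\frac{c - \mu}{\sigma}\right),$$

the cumulative-Gaussian 2AFC model with guess rate fixed at 0.5 and lapse
rate $\lambda$.

The generator is parameterized by the quantity the analysis estimates —
the 75%-correct threshold — rather than by the location $\mu$ directly:
$\mu = T / (1 + \sigma_\text{rel}\, z_\text{crit})$ with
$\sigma = \sigma_\text{rel}\,\mu$, which reduces to $T = \mu$ whenever the
lapse is 0. Its defaults are the study conditions:

| parameter | image | motion | orientation | rationale |
|---|---|---|---|---|
| median baseline threshold | 0.14 | 0.045 | 0.037 | group means reported for human observers in this paradigm |
| flicker factor (× threshold) | 0.29/0.14 ≈ 2.07 | 0.063/0.045 = 1.4 | 1.0 | ratio of reported flicker to baseline means |
| lapse rate | 0.1 | 0 | 0 | the image task's pooled curve saturates near 90%; the control tasks reach ceiling |
| relative spread σ/μ | 0.5 | 0.5 | 0.5 | spans ~chance to ~ceiling over each ladder (Weber-like: shape invariant on log contrast) |
| between-subject geometric SD | 1.4 | 1.4 | 1.4 | log-normal spread giving individual-threshold ranges comparable to published cohorts |

The flicker effect is modeled as a *multiplicative* threshold shift with
σ scaling along — the simplest mechanism consistent with reported group
means; printed summaries cannot distinguish it from an additive shift, and
this choice is flagged as such. The adapter's temporal dynamics (10 s
initial, 2 s top-ups) are kept in the stimulus layer only; they do not
enter the trial-level simulation. Task/session order is irrelevant to the
i.i.d. simulation and is not modeled. What passing tests on this generator
show is that the *analysis chain* is correct and well calibrated — not
that human observers behave like the generator; real data add sequential
dependencies, drifting criteria and non-stationary lapses that the
generator deliberately omits.

## Psychometric fitting

`fit_cumulative_gaussian()` maximizes the Bernoulli likelihood on
per-level counts with box-constrained quasi-Newton optimization (analytic
gradients, two location × two spread starting points, preferring cleanly
converged starts). The lapse is fixed at 0 for the control tasks and free
up to 0.15 for the image task, whose curve saturates below 100%; the mode
used is recorded per fit. Maximum likelihood was chosen over least squares
on proportions because it is the correct likelihood for binary trials; a
proportions-based fit can be emulated by passing pooled counts.

Degenerate data (all responses correct, or performance never rising above
chance so the location runs to its box boundary) are reported with
`converged = FALSE` and a diagnostic, never as a silent estimate.
`threshold_at()` inverts the fitted curve analytically,
$T = \hat\mu + \hat\sigma\,\Phi^{-1}\!\big((0.75 - 0.5)/(0.5 -
\hat\lambda)\big)$ — exact, hence preferred over iterative bisection —
and flags thresholds outside the tested ladder as extrapolated rather than
dropping them.

## The statistics chain

Thresholds are compared with the nonparametric branch throughout,
mirroring the reference analysis (whose threshold distributions failed
Shapiro–Wilk normality); `normality_gate()` documents the routing.

* `wilcoxon_signed_rank()` drops zero differences, uses average ranks for
  ties, and reports the smaller of the signed rank sums. For effective
  n ≤ 25 the p value comes from the exact null distribution, computed by
  convolution over sign assignments on doubled ranks (exact even under
  ties); beyond that, a normal approximation with continuity and tie
  corrections is used.
* `rank_biserial()` is $(R^+ - R^-)/(R^+ + R^-)$ with a seeded percentile
  bootstrap CI over pairs (default 10,000 resamples); an analytic CI is
  deliberately not attempted.
* `threshold_relative_change()` is $100\,(T_\text{flicker} -
  T_\text{baseline})/c_\text{max}$, the elevation as a percentage of the
  task's maximum tested contrast, making tasks with very different ladders
  comparable. Applied to the reported image-task group means (0.14, 0.29,
  max contrast 1) it gives exactly 15%.
* `friedman_np()` uses within-row average ranks with the standard tie
  correction and reports Kendall's $W = \chi^2/(n(k-1))$; the reported
  $\chi^2(2) = 14.47$ with $n = 30$ converts to $W = 0.2412$.
* `conover_posthoc()` implements the textbook (1999) Conover procedure:
  rank-sum differences over the pooled standard error with the concordance
  shrinkage term, $t$ with $(n-1)(k-1)$ df, Bonferroni-multiplied p values.
  Several variants of this statistic circulate; the formulation used is
  spelled out in the function documentation. Under perfect concordance the
  standard error vanishes and the statistics are infinite by convention.

## Numerical and testing choices

* Bandwidth feasibility uses a 10⁻¹² tolerance; probability tables must
  sum to 1 within 10⁻⁹.
* All randomness flows from explicit seeds through per-(subject, task,
  condition) derived substreams, so cohort generation is bit-reproducible
  and order-independent, and library calls never disturb the caller's RNG
  state.
* The test suite validates the greedy selector against the exhaustive
  solver on 1000 random small alphabets, the exact Wilcoxon against full
  2ⁿ enumeration, Friedman against `stats::friedman.test`, the Conover
  statistics against a step-by-step hand computation, and the end-to-end
  pipeline for type-I calibration (null cohorts) and reproduction of the
  elevation/elevation/null pattern across seeded replicates. End-to-end
  checks run at the full study design (30 subjects, 100 trials per level);
  replicate counts (200 for calibration, 100 for the pattern rate) were
  chosen to give ~1.5% standard errors on the estimated rates.

## Limitations

* The sketch pipeline reproduces the *procedure*, not the published
  stimulus set: the source photographs are not bundled, and binarization
  details of the originals are unknown.
* The observer model is intentionally minimal — no learning, adaptation
  dynamics, serial dependence, or attention fluctuations beyond a constant
  lapse.
* Whether the published fits used free lapses or raw proportions is not
  documented; both modes are provided, and the defaults (free lapse for
  the image task only) follow the shape of the pooled curves.
* Bayesian/hierarchical psychometric fitting and adaptive staircases are
  out of scope.
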