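---
title: "scenegaze: models, synthetic world, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scenegaze: models, synthetic world, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scenegaze)
```

This vignette is the package's own account of its methods: what each stage
assumes, which parameters matter (units, defaults, and why), what the
synthetic-data generator does and does not emulate, and where genuinely
open design choices were settled.

## 1. Geometry

All pixel–degree conversions use the exact full-angle formula
$\theta = 2\,\mathrm{atan}\!\left(\frac{s}{2d}\right)$, with $s$ the
physical extent of the pixels (per-axis pixel pitch × count) and $d$ the
viewing distance. On the reference setup (516.9 × 323.1 mm screen at
1920 × 1200 px, viewed from 500 mm) a 1200 × 900 px stimulus subtends

```{r}
geom <- default_geometry()
c(h = pixels_to_degrees(1200, "horizontal", geom),
  v = pixels_to_degrees(900, "vertical", geom))
```

The small-angle approximation would differ in the second decimal at these
eccentricities, which is why the full formula is used. Pixel coordinates
are 0-based, origin top-left, pixel centers on integers — the same
convention as the raster masks, so a fixation can be classified by direct
matrix lookup.

## 2. Graph-based saliency

`compute_saliency()` follows the graph-based scheme: per feature map a
fully connected graph over a coarse working grid, edge weight
$w_{ij} = d(i,j)\, e^{-\mathrm{dist}(i,j)^2 / 2\sigma^2}$, activation =
stationary distribution of the row-normalized chain, then a concentration
pass with $w_{ij} = a_j\, e^{-\mathrm{dist}^2/2\sigma^2}$.

Parameters (all config arguments):

* **working resolution** `work_dim = c(32, 24)` — preserves the 4:3 aspect
  of the reference stimuli and keeps the dense 768-node chain tractable;
  the upsampling back to image size is bilinear.
* **falloff** `sigma_frac = 1/8` of the grid width (σ = 4 grid units).
* **dissimilarity**: $|\log f_i - \log f_j|$ when the map is strictly
  positive (intensity), absolute difference otherwise (opponency and
  Gabor-energy maps legitimately touch zero). The log form makes the
  intensity channel invariant to global intensity scaling, which a test
  asserts.
* **channels** — intensity (mean RGB), red–green and blue–yellow
  opponency, even-Gabor energy at 0°/45°/90°/135° (9 × 9 kernels,
  wavelength 4, σ = 2, zero-mean); **scales = 2** pyramid levels
  (Gaussian blurs at σ = 2 per level). The original study does not state
  which channels/scales its saliency tool ran with; these defaults are an
  explicit configuration of this package, not an inference about that
  tool.
* **equilibrium solver**: power iteration, tolerance 1e-10, max 10,000
  iterations, uniform teleportation mass 1e-6 guaranteeing irreducibility.
  The tolerance is orders of magnitude below anything that could move an
  80th-percentile cutoff downstream.

Degenerate (constant) images yield an all-zero map with a `uniform` flag
and a warning, rather than 0/0; the percentile partition then labels the
whole scene low-saliency, the only consistent reading. Convolutions and
blurs use edge-replicate padding — zero padding would fabricate contrast
along the borders of a uniform image.

An Itti–Koch-style center–surround fallback (`method = "itti"`) sits
behind the same interface; it is provided for robustness comparisons and
is not the tested analysis path.

## 3. Event detection

A sample is in-saccade when angular velocity exceeds **30°/s** or
acceleration exceeds **8000°/s²** (OR, the permissive reading; the
thresholds are arguments). Velocity is a central difference over a
5-sample window after converting positions to degrees about the screen
center; acceleration is the central difference of that velocity. The
differencing window is a smoothing choice — the thresholds come from the
detection convention, the estimator is unstated there, and a ±2-sample
window suppresses single-sample noise spikes without displacing onsets by
more than ~2 samples.

Blink-flagged samples, padded by **25 ms** on each side (argument
`blink_pad_ms`), belong to neither event class; event segmentation is a
partition, so fixation + saccade + blink time equals trial duration at
sample resolution (asserted as a property test). Samples whose
differencing window touches a blink keep their fixation label rather than
risk spurious blink-adjacent saccades.

## 4. Baselines, drift correction, exclusions

The baseline of a trial is the mean valid gaze over the **300 ms** before
stimulus onset. Per participant, x and y baseline coordinates separately
undergo *recursive outlier removal*: temporarily remove the current max
and min, compute mean and SD (n−1 denominator) of the remainder,
permanently discard a temporary value outside mean ± 3 SD, return the
rest, repeat until stable. Sequences shorter than 3 (or whose remainder
after removing extremes is shorter than 2) are returned unchanged — the
SD would be undefined. The procedure is idempotent, which a 1000-case
property test checks against an independently scripted oracle.

Trials with a removed x or y coordinate, or missing baseline data, get
both coordinates replaced by the participant's mean valid baseline and
are flagged out of first-fixation analyses (their starting position is
not trustworthy). Drift correction subtracts (baseline − cross) from all
fixation positions, preserving durations and inter-fixation distances
exactly.

Exclusion rules, in this order: trials with a blink-free fraction below
**80%** of the presentation; participants missing responses in more than
**25%** of response trials; participants with more than **20%**
missing-or-outlier baselines. Boundary cases stay in (the rules are
strict inequalities), and the report lists every drop with its rule.

## 5. Density maps and metrics

A trial's density map starts from zeros at scene resolution, adds each
retained fixation's duration (ms) at its rounded pixel, convolves with an
isotropic Gaussian of SD **36 px** (≈1° on the reference geometry),
truncated at 4 SD with *no* boundary renormalization — mass falling
off-image is lost, which slightly depresses scores of edge-adjacent ROIs
and is documented rather than hidden. The map is divided by its maximum.
Note the stated kernel ("36 px or 1°") is internally inconsistent with
the stated geometry (1° ≈ 33.5 px horizontally); the pixel value is
authoritative here and the discrepancy is simply recorded.

The trial-initial fixation — the one continuing the pre-stimulus cross
fixation past stimulus onset — is discarded once per trial, before the
response-window split. A fixation spanning the response click is split at
the click with durations apportioned; with no click the task-relevant
window is the whole presentation.

Scores: an ROI's raw score is its share of total density (they sum to 1
over the partition); the area-normalized score divides by the ROI's area
share, so uniform viewing scores 1 everywhere. The fixation-count variant
weights each fixation equally, classifying it by the label at its rounded
position (the partition is exhaustive, so no tolerance disc or tie rule is
needed). First-fixation frequencies classify each of the first three
scene-driven fixations and normalize by the mean area share across the
analyzed scenes. A per-component variant additionally divides by the
number of connected components (8-connectivity by default — hand-drawn
masks have diagonal stair-steps).

"Eighth percentile": the low/high-saliency cutoff is read as the eighth
*decile* (q = 80). The literal 8th percentile would label ~92% of every
scene highly salient, contradicting the cutoff's purpose of isolating the
few genuinely conspicuous regions; both readings remain available through
the `q` argument, and q is recorded on every `roi_set`.

## 6. Inference

`rm_anova()` implements the univariate within-subject decomposition for
any number of fully-crossed within factors: per effect, subjects' cell
means are projected onto orthonormal contrasts; the error stratum is the
subject × effect interaction. Sphericity: Greenhouse–Geisser
$\hat\varepsilon$ from the covariance of the contrast scores, converted
to Huynh–Feldt
$\tilde\varepsilon = \frac{n k \hat\varepsilon - 2}{k(n - 1 - k\hat\varepsilon)}$
and clipped at 1 (k = effect df); corrected p-values scale both degrees
of freedom by $\tilde\varepsilon$. Two-level factors have ε = 1 by
construction. Generalized η² divides an effect's SS by (its SS + the sum
of *all* error SS), the convention for purely within designs. The
implementation is tested against base R's `anova.mlm` epsilons and
`aov()` error strata — independent code paths.

`rm_power()` uses the conventional noncentral-F formulation
$\lambda = f^2 n m/(1-\rho)$ with sphericity (ε = 1) by default, ε
exposed for sensitivity analysis. For the planning scenario n = 40,
m = 4, f = 0.25, ρ = .50, α = .05 it returns 0.971, cross-validated by a
50,000-replicate simulation under the compound-symmetric alternative
(binomial 3-SE agreement, asserted in the acceptance suite).

```{r}
rm_power(n = 40, m = 4, f = 0.25, rho = 0.5)
```

## 7. The synthetic world

`generate_scene()` plants non-overlapping skin-toned head ellipses, larger
body ellipses, and high-contrast colored distractor blobs on a smoothly
textured mid-gray background (defaults: 6 heads, 6 bodies, 8 distractors
on 1200 × 900 px — head counts of the magnitude reported for naturalistic
social scene sets). Distractors guarantee the saliency stage has genuine
structure. Placement is rejection sampling with bounded retries; failure
raises a placement error rather than silently overlapping.

`simulate_trial()` emits samples at 1000 Hz: a 2 s cross-fixation
pre-phase (the baseline source), then alternating fixations and saccades
for the 10 s presentation. Its stated generative model:

* **targets**: category drawn from `preference_weights` (default
  head 0.6, body 0.2, low-sal 0.05, high-sal 0.15 — a strong free-viewing
  head preference), landing point uniform within the category's pixels;
* **fixation durations**: gamma(shape 4, mean 250 ms) — right-skewed,
  positive, typical scene-viewing magnitude;
* **saccades**: straight path with raised-cosine velocity profile, peak
  velocity uniform in 200–400°/s, duration 2·amplitude/peak. Targets
  closer than 1° are resampled: a raised-cosine saccade below ~0.3°
  cannot cross the 30°/s threshold, and the world is constructed so that
  every planted saccade is detectable;
* **jitter**: AR(1) tremor (φ = 0.95, stationary SD 1 px) rather than
  white noise — white noise at 1000 Hz would alias into apparent
  velocities far above the saccade threshold, contradicting the intended
  sub-threshold fixation phase;
* **drift**: one constant offset per trial, N(0, 5 px) per axis, added to
  *all* samples including the pre-phase, so baseline correction can
  recover it;
* **blinks**: Poisson (0.05/s), gamma durations (mean 150 ms, shape 4),
  samples flagged invalid with positions NA — never dropped;
* **responses**: per-task lognormal reaction times (medians ≈ 3 s
  defining, 6 s counting, 4.5 s estimating; free viewing has none),
  matching the reported ordering of task RTs; draws beyond the 10 s
  presentation become missing responses.

Reproducibility: one master seed; child seeds are derived by a
multiplicative hash of (master, subject, trial) kept below 2³¹, so
datasets are identical across runs and machine word sizes.

**What the generator does not emulate** — and hence what a green test does
not establish: photorealistic image statistics; scanpath order and
center-of-gravity effects (only *marginal* ROI preferences are modeled);
central bias; smooth pursuit; pupil dynamics; calibration decay within a
session (drift is constant per trial). Pipeline validation on this world
demonstrates correctness of the computations, not psychological validity
of any particular parameter value.

## 8. Scaling of the acceptance runs

The parameter-recovery acceptance check runs the stated design — 20
subjects × 15 social scenes × 100 seeded replicates, head weight 0.6 with
the remainder split evenly — on 200 × 150 px scenes sampled at 500 Hz.
This is purely a compute-budget scaling (~4 s per replicate on one CPU);
the smoothing kernel scales proportionally (6 px), and every threshold,
correction and scoring rule is the default. Spot checks at full scene
scale in the unit tests behave identically; the recovered head score
ranks first in 100% of replicates at either scale.

## 9. Known limitations

* The GBVS implementation targets the *scheme*, not numerical replication
  of any particular release of the original tool; maps agree
  qualitatively (peaks on conspicuous blobs, [0,1] range) but not
  pixel-for-pixel with other implementations.
* Density-map normalization by the maximum makes per-trial maps
  comparable in shape, not in absolute level; all downstream scores are
  ratios, which is why this is harmless here.
* `rm_anova()` covers fully-crossed within-subject designs with complete
  (or listwise-completed) data; between-subject factors and mixed models
  are out of scope.
* The CLI is a thin convenience layer over the exported functions; the R
  API is the contract.
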