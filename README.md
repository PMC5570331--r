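# scenegaze

Saliency-referenced analysis of gaze behavior in natural scenes.

## The problem

When people view complex scenes, where they look is shaped both by
low-level image conspicuity ("saliency") and by the content of the scene —
in particular by *social* content such as human heads and bodies, which
attracts gaze far in excess of its physical saliency or its area. Studying
this competition with an eye tracker requires a long chain of processing:
computing a saliency map per stimulus, segmenting raw gaze samples into
saccades and fixations, drift-correcting fixations against a pre-stimulus
baseline, partitioning each scene into regions of interest (ROIs),
accumulating duration-weighted fixation density maps, normalizing ROI
scores by ROI area, and finally running repeated-measures inference.

`scenegaze` implements that entire chain as composable, tested R
functions, plus a synthetic-data module that generates scenes and gaze
recordings with *known ground truth* so that every stage — and the
pipeline end to end — can be validated without access to any proprietary
stimulus set or participant recordings.

## The core methods

**Graph-based saliency.** For each feature channel (intensity, red–green
and blue–yellow opponency, oriented Gabor energy) a fully connected graph
is built over a coarse working grid; the edge weight between locations
*i, j* is the feature dissimilarity `d(i,j)` times a Gaussian falloff
`exp(-dist²/2σ²)` in grid distance. The activation map is the stationary
distribution **π** of the row-normalized Markov chain (`markov_equilibrium()`,
power iteration with a 1e-6 teleportation mass), followed by a second
"concentration" pass whose edge weights are the target node's activation.
Channel maps are summed, upsampled, and min–max normalized to [0, 1].

**Event detection.** Angular velocity (central difference over a 5-sample
window on positions converted to degrees) and acceleration are thresholded
at 30°/s and 8000°/s²; maximal supra-threshold runs are saccades, the
intervals between them fixations, and blink-flagged spans belong to
neither.

**ROI partition.** Hand-drawn (or planted) head/body masks are taken
verbatim; the remaining pixels are split at the `q`-th percentile
(default 80) of their own saliency distribution into low- vs
high-saliency background. The area-normalized density score of an ROI is

```
score(ROI) = (Σ density in ROI / Σ density in scene) / (area(ROI) / area(scene))
```

so 1 means "viewed exactly as much as its size predicts".

**Inference.** `rm_anova()` performs the univariate within-subject
decomposition with Huynh–Feldt ε (clipped at 1) and generalized η²;
`rm_power()` computes a-priori power via the noncentral F with
λ = f²·n·m/(1−ρ).

## Worked example

```r
library(scenegaze)

# four synthetic scenes with planted heads/bodies and salient distractors
scenes <- lapply(1:4, function(i)
  prepare_scene(generate_scene(scene_spec(size_px = c(300, 225), seed = i))))

# six subjects view every scene under free viewing and a counting task;
# the simulated observers prefer heads with weight 0.6
ds <- simulate_dataset(6, scenes, tasks = c("free", "count"), seed = 42)
an <- analyze_dataset(ds, windows = "pre")

summarize_roi_preference(an, window = "pre", tasks = "free")
#>        roi mean_normalized n_subjects
#> 2     head       8.2732334          5
#> 3 high_sal       1.3320020          5
#> 1     body       1.2770648          5
#> 4  low_sal       0.6035199          5
```

Heads are viewed ~8× more than their area predicts; low-saliency
background is under-viewed (0.60). One of the six simulated subjects was
dropped by the exclusion rules (`an$exclusions` lists the rule that
fired), which is why `n_subjects` is 5.

```r
d <- subset(an$density, window == "pre" & !is.na(normalized))
rm_anova(d, dv = "normalized", within = c("task", "roi"),
         subject = "subject_id")
#>     effect df_num df_den        F epsilon_hf p_uncorrected p_corrected  eta2_g
#> 1     task      1      4 2.64e-02      1.000      8.79e-01    8.79e-01 0.00118
#> 2      roi      3     12 1.18e+03      0.459      4.25e-15    8.24e-08 0.98884
#> 3 task:roi      3     12 2.23e-01      0.622      8.79e-01    7.92e-01 0.02820

rm_power(n = 40, m = 4, f = 0.25, rho = 0.5)
#> [1] 0.970577
```

The ROI main effect dominates (the simulation plants a strong head
preference and no task effect), and a 40-subject, 4-level within design
has 97% power for a medium effect (f = 0.25) at ρ = .50 — above the 95%
planning threshold.

## Command line

`inst/cli/scenegaze` exposes the stages as subcommands:

```sh
scenegaze simulate  --subjects 2 --scenes 4 --size 300x225 --out-dir data/
scenegaze saliency  --image data/scene01.png --out-dir out/
scenegaze rois      --saliency out/scene01_saliency.png --mask data/scene01_mask.png --out-dir out/
scenegaze preprocess --gaze data/gaze.csv --meta data/metadata.csv --out-dir out/
scenegaze density   --fixations out/fixations.csv --size 300x225 --out-dir out/
scenegaze stats     --metrics out/metrics.csv --dv normalized --within roi --out-dir out/
```

## Vignette

`vignettes/scenegaze-methods.Rmd` documents the models, the synthetic
world and its deliberate simplifications, all tunable parameters with
their defaults and units, numerical choices, and known limitations.
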