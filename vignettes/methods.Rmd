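---
title: "Histogram-morphology features for dementia staging: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Histogram-morphology features for dementia staging: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admorph)
```

## The model

`admorph` quantifies brain atrophy in a single 2-D MRI slice through the
morphology of its intensity histogram. In T1-like contrast, a slice has
three dominant intensity populations — dark background/CSF, mid-grey
cortical grey matter, bright white matter — which appear as modes of the
histogram. As dementia progresses, grey matter is replaced by dark void
space: the grey mode shrinks, the valleys between modes move, and the
geometry of the smoothed histogram envelope changes in measurable ways.

The pipeline is deterministic for a fixed image and configuration:

1. *Linear stretch* to `[0, 255]`, which standardizes acquisition
   differences without altering tissue ordering (the map is monotone, so
   pixel-count ratios between tissues are unchanged).
2. *Zero-phase lowpass smoothing* of the 256-bin histogram.
3. *Threshold selection* from the local minima of the smoothed envelope:
   `Th1` = second minimum, `Th2` = last minimum; `(x3, y3)` = absolute
   envelope maximum.
4. *Slope/distance geometry* between those three points.
5. *Segmentation* by strict inequalities (`Th1 < I < Th2` grey,
   `I > Th2` white) and the derived volume, moment, grey-to-white-ratio
   and shrinkage features.

### Assumptions

- 8-bit single-channel slices with an essentially black background. The
  brain mask is recovered by thresholding above intensity 0, closing with
  a 3×3 box, filling holes and keeping the largest connected component;
  no algorithm beyond this is attempted because the target imagery is
  already skull-focused with pure-black surround. Interior dark voids
  (ventricles, atrophic cavities) are *inside* the mask by the
  hole-filling step — the shrinkage denominator depends on this.
- At least three histogram modes separated by genuine valleys. Slices
  violating this (constant slices, bimodal slices) produce a per-image
  failure record rather than an exception, and batch extraction skips
  them.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `passband_edge` | 0.005 | fraction of Nyquist on the bin axis | heavy envelope smoothing; only the coarse mode structure should survive |
| `stopband_atten` | 60 | dB | suppresses spiky histogram detail by three orders of magnitude |
| `transition_width` | `0.15 * (1 - passband_edge)` | fraction of Nyquist | sets the kernel length (~59 taps, main lobe ±13 bins). The minimum-order design convention ties the transition band to the free spectral range; a much narrower transition would require a kernel far longer than the 256-bin histogram and flatten it entirely, destroying the valleys the thresholds are read from |
| `floor_rel` | 0.005 | fraction of envelope max | values below this are treated as empty before extremum detection; a 60 dB filter leaks ~`10^-3` of a dominant spike into its stopband sidelobes, and without the floor that leakage seeds spurious valleys around isolated spikes |
| `th1_rule` | `second_minimum` | — | the default follows the threshold definition in terms of minima; `first_maximum` implements the alternative reading in which `Th1` is the first envelope peak, for comparison |
| `mask$threshold` | 0 | intensity | pure-black background assumption |
| MRMR `bins` | 16 | equal-frequency bins | robust to outliers; enough resolution for 4 classes |
| chi-square `bins` | 10 | equal-width bins | conventional contingency granularity |

## Numerical choices

- **Rounding** in the stretch is round-half-up, then clipping — fixed so
  results are platform-independent (R's `round()` is banker's rounding).
- **Zero-phase filtering** is implemented by convolving with the
  symmetric taps and keeping the centred segment, with mirror padding at
  both ends. This compensates the group delay exactly and keeps extremum
  locations unbiased; a constant histogram passes through unchanged
  (unity DC gain), and smoothing is linear. Negative filter output is
  clamped to zero in `smooth_histogram()` since the envelope represents
  counts; the clamp only engages where the envelope is essentially empty.
- **Extrema**: a strict-inequality neighbour rule with plateaus collapsed
  to their midpoint bin. Only interior extrema count. After contrast
  stretching the top bin 255 is always occupied and the envelope usually
  decays into it; an endpoint-eligible rule would make bin 255 the "last
  minimum" of nearly every real slice and empty the white-matter mask, so
  endpoints are excluded (this matches the behaviour of the common
  `islocalmin`-style detectors).
- **Occupied range**: extremum search and the absolute maximum are
  restricted to the raw histogram's occupied intensity range, making the
  geometry invariant to zero-count bins beyond it.
- **Tie-breaks**: the absolute maximum takes the smallest bin; MRMR ties
  take the earlier column.
- **Degenerate inputs**: constant images stretch to all-zeros with a
  warning; coincident threshold points give distance 0 and an undefined
  (NaN) slope; `x3 = x1` with distinct heights gives a signed-infinity
  slope sentinel and a `degenerate_slope` flag; empty white matter makes
  GWR undefined and flags the image. Failed extractions never abort a
  batch; they are excluded and logged.
- **Tissue moments** use population denominators (`n`, not `n - 1`), and
  skewness of a zero-variance tissue is defined as 0 (a constant patch is
  symmetric); this keeps noiseless-phantom feature vectors finite.

## The 17-feature completion

Fifteen features are unambiguous: 2 thresholds, 2 slopes, 3 distances,
2 volumes, 2 means, 2 standard deviations, GWR, shrinkage. The feature set
is specified as 17 statistical-moment-based descriptors; the package
completes it with the grey and white skewness — the next central moment in
the same family. This choice is declared here prominently so users who
prefer a different completion can substitute their own columns; all
downstream code is agnostic to the feature semantics.

## Evaluation protocol

The evaluation harness reconciles two conventions: it runs 10 repetitions
(the "tenfold" count) of a stratified 60/20/20 train/validation/test split
(the stated partition fractions), reporting the mean and standard
deviation of each metric over repetitions. The validation partition is
reserved for model selection; the shipped classifiers use fixed
hyperparameters (quadratic-kernel SVM; one-hidden-layer 10-unit neural
network capped at 1000 iterations; k = 1 nearest neighbour; CART tree;
linear/quadratic discriminants; kernel-free naïve Bayes; random-forest
ensemble), so it is simply held out. A pure stratified k-fold mode is
available via `mode = "cv"`. Multiclass recall, specificity, precision and
F1 are macro-averaged — the conservative choice under the heavy class
imbalance typical of dementia-staging data; MCC is the multiclass R_K
statistic and kappa is Cohen's kappa, both computed from the full C×C
confusion matrix.

MRMR uses the MID (difference) criterion with equal-frequency
discretization and base-2 logarithms — the canonical deterministic
variant. The reported score is the greedy objective at selection time, so
the drop-off across ranks is meaningful. One consequence worth knowing:
an *exact duplicate* of an already-selected feature is penalized by the
full entropy of the shared values, which typically exceeds its relevance,
so duplicates sink below even uninformative features. The redundancy
penalty equals the relevance exactly when the duplicated feature takes
only as many distinct values as there are classes.

## The phantom generator

`generate_phantom()` builds a concentric brain-like slice: elliptical
outline, a thin CSF-like rim (default level 40), a grey-matter annulus
(level 100), a white-matter core (level 200) sized to a target grey:white
area ratio (default 1.5), and atrophy carved as background-level voids — a
central ventricle, scattered interior blobs, and a few sulcal notches
opening to the background. Stage `s` in 0–3 maps to void fractions
0.02/0.08/0.18/0.30 and outline scales 1.00/0.96/0.92/0.87, with small
uniform jitter per phantom in `generate_phantom_dataset()`. Gaussian noise
(default σ = 5) is added *inside* the brain only: the emulated imagery has
exactly-zero backgrounds, and keeping the background clean is what makes
the threshold-at-zero mask well posed.

The CSF rim is not cosmetic: the second-minimum threshold rule needs an
early valley to skip. In real slices the background spike and the
partial-volume smear supply it; in a phantom without the rim the envelope
has exactly two interior minima, the "second" and "last" coincide, and
thresholding correctly reports failure. The rim reproduces the real
histogram topology with an anatomically sensible structure.

Ground truth is exact integer bookkeeping from the label map (grey/white
areas, mask area, GWR, shrinkage). What the phantoms do *not* emulate:
anatomical shape variability, partial-volume gradients at tissue borders,
bias fields, Rician noise statistics, or 3-D structure. Passing tests on
phantoms therefore demonstrates that the algorithm recovers its own
quantities faithfully under controlled conditions — not that the features
separate real dementia stages; that claim is only assessable on clinical
data.

## Problem sizes used in the shipped checks

The package's own test suite and `scripts/acceptance.R` run entirely on
generated data: 1,000 random images/envelopes for the counting and
extremum checks, 8 noiseless phantoms for threshold recovery, 52 noisy
phantoms (13 per stage, σ = 5) for GWR/shrinkage recovery, 500 random
confusion matrices against a brute-force metrics oracle, and a 200-per-
stage phantom dataset for the classifier-separation check — sizes chosen
to give stable statistics while keeping a full run in the order of a
minute on a single CPU.

## Known limitations

- Single 2-D slices only; no DICOM/NIfTI volumes, no registration, no
  bias-field correction, no skull stripping beyond the black-background
  mask.
- Exactly two thresholds; slices whose smoothed histogram has fewer than
  three separated modes fail extraction by design.
- The distance features `d1, d2, d3` and slopes mix bin units with count
  units; their magnitudes scale with image area. A probability-normalized
  variant can be obtained by dividing the histogram by `M * N` before
  smoothing, but the default follows the count-based definitions.
- No CSF/ventricle tissue class and no partial-volume modelling: pixels
  equal to a threshold belong to neither tissue.
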