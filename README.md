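# admorph

Handcrafted histogram-morphology features for staging Alzheimer's-type
neurodegeneration in 2-D brain MRI slices.

Dementia staging from structural MRI usually relies on deep networks whose
features are opaque. `admorph` implements the opposite approach: a small set
of mathematically defined descriptors of brain atrophy, computed from the
*shape of the smoothed intensity histogram* of a slice, that a reader can
inspect and reason about. It is aimed at researchers studying interpretable
atrophy markers and at anyone who needs a fully testable reference
implementation of adaptive histogram multi-thresholding for grey/white
matter segmentation.

## The method

For an 8-bit slice `I(m,n)` of size `M x N`:

1. **Contrast enhancement.** Linear stretching maps the intensity range to
   `[0, 255]`: `I_c = (I - I_min) / (I_max - I_min) * (2^k - 1)`, `k = 8`.
2. **Histogram smoothing.** The 256-bin histogram `P(l)` is filtered with a
   minimum-order, linear-phase Kaiser-window lowpass (passband edge 0.005 of
   Nyquist, 60 dB stopband attenuation), applied zero-phase so extremum
   locations are not displaced: `P_s = H_L * P`.
3. **Adaptive thresholds.** On the smoothed envelope, `(x1, y1)` is the
   *second* local minimum and `(x2, y2)` the *last* local minimum;
   `Th1 = x1`, `Th2 = x2`. The first minimum, sitting immediately after the
   dark background/CSF spike, is skipped. `(x3, y3)` is the absolute
   maximum of `P_s`.
4. **Histogram geometry.** Slopes `alpha1 = (y3-y1)/(x3-x1)`,
   `alpha2 = (y3-y2)/(x3-x2)` and Euclidean distances `d1, d2, d3` between
   the three points in the (bin, height) plane.
5. **Segmentation.** Grey matter: `Th1 < I_c < Th2`; white matter:
   `I_c > Th2`. Per-tissue volume (pixel count), mean, standard deviation
   and skewness are computed, plus the grey-to-white ratio
   `GWR = V_gm / V_wm` and the shrinkage
   `(V_gm + V_wm) / V_mask` — the fraction of the brain mask still
   occupied by tissue, which falls as atrophy replaces tissue with void.

The 17 features (`th1, th2, alpha1, alpha2, d1, d2, d3, grey_volume,
white_volume, grey_mean, white_mean, grey_std, white_std, grey_skew,
white_skew, gwr, shrinkage`) feed MRMR or chi-square ranking
(`mrmr_rank()`, `chi2_rank()`) and a classifier harness
(`split_and_evaluate()`) that reports accuracy, macro recall, specificity,
precision, F1, the multiclass Matthews correlation coefficient and Cohen's
kappa over repeated stratified 60/20/20 splits.

Because the public dementia MRI collections cannot be redistributed, the
package ships a synthetic brain-phantom generator
(`generate_phantom_dataset()`) producing concentric CSF/grey/white
phantoms with stage-dependent atrophy (growing void fraction, shrinking
outline) and exact pixel-level ground truth, so the entire pipeline is
testable offline.

## Worked example

```r
library(admorph)
p <- generate_phantom(phantom_spec(stage = 2, seed = 7))  # mild dementia
print(p)
r <- extract_features(p$image)
print(r)
```

```
Brain phantom: 128x128, stage 2, void 0.18, noise sd 5.0 (seed 7)
  truth: grey 3337, white 1818, mask 6778, GWR 1.836, shrinkage 0.761
17-feature vector:
         th1          th2       alpha1       alpha2           d1           d2
     81.0000     178.0000     -10.6952      -4.8669     870.0885     884.4077
          d3  grey_volume white_volume    grey_mean   white_mean     grey_std
     97.0000    3337.0000    1818.0000     118.6188     237.2415       5.9819
   white_std    grey_skew   white_skew          gwr    shrinkage
      6.0272      -0.0225       0.0275       1.8355       0.7600
```

The thresholds 81/178 sit in the valleys between the background/CSF, grey
(mean 118.6 after stretching) and white (mean 237.2) intensity modes. The
extracted volumes equal the constructed truth exactly, the grey-to-white
ratio 1.8355 matches the truth 1.836, and the shrinkage 0.760 (vs truth
0.761) reflects the 18% void fraction of a stage-2 phantom.

A shell interface wraps the same functions:

```sh
Rscript inst/cli/admorph.R phantom  --n-per-stage 50 --out phantoms --seed 1
Rscript inst/cli/admorph.R extract  --input phantoms_by_class --output features.csv
Rscript inst/cli/admorph.R rank     --features features.csv --method mrmr
Rscript inst/cli/admorph.R classify --features features.csv --model svm --seed 1
Rscript inst/cli/admorph.R run-all  --out results --n-per-stage 25 --seed 1
```

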