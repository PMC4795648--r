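# holoface

Holistic face perception — faces seeming to be processed "as wholes"
rather than as independent parts — is usually described qualitatively.
`holoface` implements a precise computational account: a four-layer
feedforward model of the ventral visual stream in which a single
property, the **spatial tuning size** of face-selective model neurons,
controls whether processing is face-like or object-like, as measured by
the three classic behavioral markers of holism:

* the **composite face effect** (CFE) — identical top face-halves are
  harder to judge "same" when fused with different, aligned bottom
  halves than when the halves are misaligned;
* the **face inversion effect** (FIE) — turning faces upside-down
  hurts discrimination, behaviorally and at the single-neuron level;
* the **whole-part effect** (WPE) — memory for a face part (the eyes)
  is better when tested in the whole-face context than in isolation.

## The model

Images pass through an HMAX-style hierarchy:

| layer | operation |
|-------|-----------|
| S1 | Gabor filtering (4 orientations, 11×11, λ = 5.6 px) of a 10-scale pyramid (factor 2^(1/4)); responses are absolute normalized dot products in [0, 1] |
| C1 | max over 8×8 S1 units × 2 adjacent scales (stride 3) — local position/scale tolerance |
| S2 | Gaussian radial basis match of stored templates at every position and band: exp(−d²/2σ²), σ = 1/3 |
| C2 | global max over each template's S2 pyramid — one invariant response per template |

Templates are stored C1 patches sampled at random positions inside the
face footprint at C1 band 7: 20 per training face × 50 faces = 1000
templates per tuning size.  Tuning sizes are **large** (12×12×4 C1
units), **medium** (8×8×4) and **small** (4×4×4), with medium/small cut
as central sub-blocks of the same large patch.  A face spans about
17×22 C1 units at that band, so even a large template covers less than
half a face.

Because the original face photographs are not redistributable, the
package generates synthetic identities with the same format (80×120 px
oval faces on a black 256×256 field, identical in-oval pixel mean and
variance) from jittered geometric parts plus an identity-specific
texture field; a loader hook accepts real images instead.

## A worked example

```r
library(holoface)

train <- render_identity_set(seq(1, 19, 2), seed = 1)  # odd ids train
bank  <- learn_bank(train, per_image = 20, seed = 7)
bank
#> <template_bank> 200 templates per size class (large/medium/small), band 7, seed 7

test <- render_identity_set(seq(2, 20, 2), seed = 1)   # even ids test
fie  <- run_fie_behavioral(bank, test, n_resamples = 200, seed = 2)
glance(fie)
#> # A tibble: 3 × 4
#>   size_class effect    sem p_boot
#>   <chr>       <dbl>  <dbl>  <dbl>
#> 1 large       0.498 0.0195      0
#> 2 medium      0.137 0.0151      0
#> 3 small      -0.113 0.0264      1
```

`effect` is the mean upright-minus-inverted C2 dissimilarity over all
face pairs: large-tuning neurons lose most of their face-discrimination
signal under inversion (a strong inversion effect), medium-tuning
neurons less, and small-tuning neurons are essentially unaffected —
"object-like" processing.  `p_boot` is the proportion of neuron
bootstrap resamples in which the effect was not positive.
`autoplot(fie)` and `plot_effect_sizes(fie)` draw the standard
condition and effect-size panels, and `run_cfe()` / `run_fie_neural()` /
`run_wpe()` produce the other markers in the same form.  `run_all()`
chains generation, learning and all four analyses from one seeded
config and writes JSON results plus a manifest.

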