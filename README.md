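# smartRotate

Smart rotation planning for multi-view light-sheet microscopy (SPIM).

In a multi-view SPIM experiment the sample rotates about a vertical axis
and is imaged from several angles, but each view only images the angular
sector close to both the illumination and the detection objective well.
Users conventionally pick *n* equally spaced angles "blindly". Real embryos
are optically and fluorescently inhomogeneous — pigment absorbs, labelling
density varies — so blind spacing wastes exposures and phototoxicity budget.

smartRotate measures, per view, how much of the sample is actually imaged
well, and selects the view set that maximises predicted coverage:

1. **Information content** — each camera plane is tiled into blocks and
   scored by the Shannon entropy of its normalised DCT-II power spectrum,
   `S = -Σ p log p`, `p = F²/ΣF²` (orthonormal DCT-II, so Parseval holds).
   Structured signal concentrates the spectrum (low `S`); noise spreads it.
2. **Projection + registration** — raw maximum-intensity and entropy
   minimum-intensity projections along the rotation axis; views are
   registered into a sample-fixed frame by stage-seeded rotation plus
   phase-correlation translation (the stage is trusted).
3. **Angular response** — foreground blocks (entropy below a level
   calibrated on a blank acquisition) are binned by azimuth into 10°
   regions, giving each region's measured response `C_α(x)` versus imaging
   angle `x`.
4. **Coverage model** — each region's response is fitted with a von Mises
   curve `C_α(x) = A/(2π I₀(κ)) · exp(κ cos(x − μ))`: `A` is fluorophore
   content, `κ` optical accessibility (FWHM = 2 arccos(1 − ln2/κ)), `μ` the
   optimal imaging angle.
5. **Selection** — a view set's predicted coverage is the per-region
   capped additive response over its fitted optimum, averaged over regions;
   `selectViews()` maximises it exhaustively or greedily, with
   deterministic tie-breaking. `updateSampleProfile()` substitutes freshly
   acquired views for cheap time-lapse updates.

A full multi-view SPIM simulator (`makePhantom()`, `acquireView()`) with
embryo-like phantoms, Beer–Lambert attenuation, depth-dependent blur,
obstruction sectors and Poisson+Gaussian noise provides ground truth for
validating the whole workflow end to end.

## Worked example

Simulate an inhomogeneous embryo (density lobe at 90°, absorbing sector
over [180°, 260°)) imaged from 24 angles, then run the evaluation step and
pick 3 views:

```r
library(smartRotate)
dir <- file.path(tempdir(), "demo")
man <- simulateViews(defaultSimConfig(seed = 7), dir)
res <- evaluateViews(man, nViews = 3)
res$selection
#> ViewSetScore (exhaustive): angles {135, 225, 345} deg, mean coverage 0.959
```

The selected angles are not equally spaced: they concentrate on the usable
arc and the dense lobe. A region's fit shows the model quantities:

```r
regionFits(res$profile)[["90"]]
#> VonMisesFit: A=136.5, kappa=1.796, mu=315.2 deg, Cmax=66.0, FWHM=104.2 deg
```

Region [90°, 100°) is best imaged from a stage angle of ~315° (the fixed
≈ −135° offset between a region and its optimal view), with an
accessibility FWHM of ~104°. Sweeping the number of views compares smart
against blind equal spacing (best/mean/worst over all offsets):

```r
round(coverageCurve(res$profile, maxViews = 6), 3)
#>  n smart blind_best blind_mean blind_worst
#>  1 0.465      0.465      0.369       0.192
#>  2 0.752      0.733      0.598       0.496
#>  3 0.940      0.866      0.800       0.744
#>  4 0.979      0.916      0.893       0.860
#>  5 0.982      0.967      0.920       0.884
#>  6 0.982      0.946      0.936       0.915
```

Three smart views reach a predicted coverage that blind spacing needs about five views to match,
and the marginal gain of each added view shrinks — the diminishing-returns
behaviour that motivates imaging with fewer, better-chosen angles.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/smartrotate.R simulate --config sim.yaml --out DIR
Rscript inst/cli/smartrotate.R evaluate --manifest DIR/views.json --n-views 4 --out DIR/report
Rscript inst/cli/smartrotate.R update --manifest DIR/views.json \
    --previous DIR/report/profile.json --new view_030.tif,view_120.tif --out DIR/report
Rscript inst/cli/smartrotate.R coverage-curve --profile DIR/report/profile.json --out curve.csv
```

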