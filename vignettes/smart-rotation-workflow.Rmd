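---
title: "The smart rotation workflow: model, assumptions and design choices"
author: "smartRotate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The smart rotation workflow: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In multi-view selective plane illumination microscopy (SPIM) a sample such
as a zebrafish embryo is rotated about a vertical axis and imaged from
several angles. Each view images only a limited angular portion of the
sample well: signal degrades with the depth of both the illumination path
(shadowing, absorption) and the detection path (scattering, aberration), so
the usable sector sits between the illumination and the detection objective
and rotates with the stage. Users conventionally pick n equally spaced
("blind") angles. Real samples, however, are neither optically nor
fluorescently homogeneous -- pigment patches absorb light, labelling density
varies around the sample -- so equally spaced views can waste exposures on
angles that contribute little, and the best configuration can change over a
time lapse as the sample develops.

smartRotate implements the alternative: measure, per view, how much of the
sample is actually imaged well; summarise this by angular region; fit a
circular response model per region; and choose the set of n angles that
maximises the predicted overall coverage. A built-in multi-view SPIM
simulator provides ground truth for validating every stage.

## Information content: block-wise DCT-II spectral entropy

Image quality is scored per square block (patch) of each camera plane. A
block `I(i,j)` of edge `N` is transformed with the orthonormal 2D DCT-II,
the power spectrum is normalised to a distribution
`p = F^2 / sum(F^2)`, and the score is the Shannon entropy
`S = -sum(p log p)` in nats, bounded by `[0, 2 log N]`. Structured content
concentrates spectral power into few coefficients (low entropy); pure noise
spreads it (high entropy); the normalisation makes `S` invariant to
intensity scaling. Two conventions deserve note:

* The DCT normaliser is applied on the frequency indices (the orthonormal
  convention, under which Parseval's identity holds and which matches the
  standard DCT-II definition). The suite verifies the fast transform against
  a direct `O(N^4)` double-sum evaluation.
* An all-zero (or below-floor) block formally has `S = 0`,
  indistinguishable from perfect structure. Such blocks are flagged *empty*
  and excluded from all downstream counting: a dark block carries no
  information. Edge pixels that do not fill a block are dropped rather than
  padded, since padding would inject artificial spectral content. The DC
  coefficient is kept in `p` (it is part of the spectrum and carries the
  distinction between flat-bright and structured blocks).

Stacks are encoded per camera plane in 2D; there is no 3D DCT. For
registration and response measurement everything is collapsed along the
rotation axis (y): a maximum intensity projection of the raw stack and a
*minimum* intensity projection of the block entropies, on a grid blocked in
x and at plane resolution in z. The minimum is taken over non-empty blocks
only.

Block size defaults to 16 px in `entropyMap()`. The workflow front end
(`evaluateViews()`) defaults to 8 px with a stride of 4 px: the simulated
frames are 128 px across -- a 2k-pixel camera frame scaled down by 16 --
and a proportionate block keeps roughly 16 tiles across the field of view,
while the overlapping stride samples the angular response on a finer grid
without changing the metric itself. Both are plain parameters.

## Foreground calling and the blank calibration

The entropy scale is not absolute: it shifts with noise level, exposure and
gain. Foreground is therefore called against a *predetermined background
level* calibrated from a blank (sample-free) acquisition pushed through the
identical pipeline (per-plane entropy, then minimum projection -- the
minimum of several noise draws is itself lower than one draw, so
calibrating on anything but the min-projected blank would bias the
threshold). The level is the 5th percentile of the blank's non-empty cell
entropies minus a safety margin (default 0.5 nats in the workflow): content
*lowers* entropy, so a cell is foreground iff its entropy falls below the
level. The margin guards against sub-noise signal smears -- the metric is
sensitive enough to react to structure well below the noise floor, which a
microscopist would not call usable signal. By construction, pure-noise
inputs yield a foreground fraction at most the calibration percentile.
Automated (Otsu-style) thresholding is deliberately not offered.

## Registration

With a single rotational degree of freedom, registration is performed on
the 2D raw maximum-intensity projections only (full 3D registration is out
of scope), and the recovered transform is then applied to the entropy
projections by nearest-neighbour resampling of cell centres -- block-valued
data should not be interpolated. The default engine trusts the rotation
stage: the moving projection is rotated by the nominal stage angle and only
the residual translation is recovered, by phase correlation with sub-pixel
parabolic refinement. An optional rotation-refinement window (scored by the
phase-correlation peak) exists for stages with backlash; it is off by
default because refining an already accurate rotation against noisy content
can only inject error, and a refinement that aligns worse than the
unrefined stage transform is discarded in any case. The translation search is bounded (16 px by default): the
sample is mounted on the rotation axis, and an unbounded search can lock
onto the camera-fixed illumination/detection vignetting pattern, which is
identical in every view. Pairs whose aligned overlap correlates below 0.2
are declared featureless and fall back to the nominal stage transform,
flagged `nominal-only`. A lightweight feature engine (blob centroids,
mutual-nearest-neighbour matching, least-squares rigid estimation) is
provided as an alternative; the rotation-axis centre can be estimated by a
coarse-to-fine grid search when it is not optically aligned.

## The angular response and the von Mises coverage model

Foreground cells, mapped into the registered sample-fixed frame, are binned
by the azimuth of their centres about the rotation axis (10 degree bins by
default, half-open, counterclockwise from +x). For each angular region
`a`, the count as a function of imaging angle `x` is the measured response
`C_a(x)`, modelled as a scaled von Mises curve

    C_a(x) = A / (2 pi I0(kappa)) * exp(kappa * cos(x - mu))

where `A` (the integral of the curve over one turn) encodes the region's
fluorophore content, `kappa` its optical accessibility (concentrated
response = usable from few angles), and `mu` the optimal imaging angle. The
region's accessibility is also summarised as the full width at half maximum,
`FWHM = 2 arccos(1 - ln 2 / kappa)`, set to 360 degrees when the half level
is never reached (`kappa <= ln2 / 2`).

Fitting choices (the source method states none): ordinary least squares on
counts via Levenberg-Marquardt, with a Poisson-deviance weighting offered as
an option; deterministic initialisation (count-weighted circular mean for
`mu`, the standard A(kappa) inversion of the mean resultant length for
`kappa`, trapezoidal mass for `A`); eight seeded restarts only on failure.
Profiles with several local maxima after 3-sample circular smoothing are
flagged `multi_peak` and only the highest peak is fitted (samples beyond 90
degrees from it are dropped); modelling secondary peaks is out of scope.
The reported peak is capped at 1.5x the largest observed sample, and an
all-zero profile yields the flagged degenerate fit `A = 0, kappa = 0`.

## Scoring and selecting view sets

The coverage of a candidate view set is predicted from the fitted curves
(so any angle can be scored, not only acquired ones): per region, the
responses of the chosen angles are summed -- the additive model -- and
capped at the region's fitted optimum `C_max`; the region fraction is this
combined value over `C_max` (defined as 1 where `C_max = 0`, i.e. regions
with no content place no constraint), and a set's score is the mean
fraction over all regions. The cap is an interpretation: without it,
overlapping views could report more than the region can deliver. Overlap
between nearby views is not discounted beyond the cap.

`selectViews()` either enumerates all `choose(N, n)` subsets (guarded at
10^6) or builds the set greedily by marginal gain. Ties are broken
deterministically: maximal minimum pairwise angular spacing, then
lexicographic order. The capped-additive objective is monotone and has
diminishing returns along the greedy path, and the greedy-vs-exhaustive gap
is measured in the test suite (over random profiles it stays far above the
0.63 worst-case bound familiar from submodular maximisation).

For time lapses, `updateSampleProfile()` substitutes freshly acquired
samples at their angles into the stored profiles and refits every region;
only the new views are pushed through quality and registration. A full
evaluation (24 views) at long intervals plus cheap updates in between is
the intended cadence. The tracking speed of an update is proportional to
the fraction of views refreshed: substituting all 24 views moves the fitted
amplitude lobe with the sample within one bin, while refreshing only the
n views in use per step yields a correspondingly slower -- but still
monotone -- drift of the profile (the suite asserts both).

## The simulator and what it does (not) emulate

`makePhantom()` draws emitters as an inhomogeneous Poisson process on an
ellipsoidal shell (default radii 130 x 160 x 130 um, 30 um thick) with an
azimuthal density `1 + sum a_m cos(m (phi - phi_m))`, restricted to an
equatorial band (|y| <= 0.75 of the y radius): embryos are open, elongated
structures, and a closed shell would put always-visible polar caps right on
the rotation axis, an azimuth-independent pedestal no real sample has.
Obstruction sectors (azimuth x radius intervals with extra attenuation per
um) emulate pigment or dense tissue.

`acquireView()` rotates the emitters by minus the stage angle and renders:
Beer-Lambert illumination attenuation integrated along the straight +x ray
(nominal tissue coefficient `1/l_ill` plus the phantom's extra base term
plus obstruction terms; no refraction or beam steering); detection
attenuation `exp(-depth/l_det)` along +z; a normalised Gaussian PSF whose
sigma grows linearly with the summed in-sample path (each emitter is
rendered with its own sigma at sub-voxel position -- an exact spatially
varying PSF rather than per-slab blurring); then Poisson shot noise and
Gaussian read noise, all deterministically seeded. Photon count is
conserved in the no-degradation limit and intensities are monotone in the
attenuation coefficients.

Default degradation (`spimOptics()`): attenuation lengths 30 um, PSF
sigma 4 um growing at 0.02 per um of path, 3 um voxels in a 128^3 stack
(384 um field), read noise 2 counts, emitters of 3000 photons at a density
of 1e-3 per um^3 (about 5800 emitters). These were fixed once, during the
design of the study conditions, by two requirements: signal should stay
detectably above the read noise out to roughly 150-250 um of combined
illumination + detection path (the useful single-view depth scale of SPIM
in semi-transparent embryos), and the per-view well-imaged sector must be a
genuinely narrow wedge -- with much weaker attenuation the spectral-entropy
metric, which reacts to signal well below a microscopist's usable level,
sees nearly the whole sample from every angle and the selection problem
degenerates. The simulated studies in the test suite run at this full
geometry for the end-to-end claims and at a reduced 64^3 / 6 um geometry
(same field of view and physics) for unit-level checks and the time-lapse
study; the workflow smoke tests use 48^3 bundles.

What the simulator does not emulate: refractive beam steering and striping,
wave-optics light-sheet propagation, camera-specific noise beyond
Poisson + Gaussian, multi-channel imaging, and sample deformation. Passing
the simulated end-to-end tests therefore shows that the workflow correctly
recovers and exploits angular inhomogeneity of the kind modelled
(absorption and labelling density), not that it is robust to every optical
artefact of a real instrument.

## Study conditions asserted by the tests

* Homogeneous control (no modulation, no obstruction): the fitted `mu` per
  region minus the region azimuth is constant across all 36 regions within
  one 10-degree bin -- the "optimal angle sits at a fixed offset between
  illumination and detection" property -- and all equally sized blind sets
  score within 2% of each other.
* Inhomogeneous study (0.8 density modulation at 90 degrees plus an 80
  degree wide obstruction sector [180, 260) at 0.08/um): the measured
  union-foreground coverage of the smart n = 3 selection is at least that
  of the best blind equally spaced n = 3 set, and the greedy coverage curve
  over n = 1..8 has non-increasing marginal gains. The obstruction strength
  is the documented inhomogeneity level at which the smart advantage
  appears: with a mild obstruction the measured optimum is a plateau and
  smart merely ties the best blind offset.
* Registration: synthetic rigid transforms recovered within 0.5 degree and
  0.5 px on full-size projections; the 24-view loop of successive pair
  registrations closes within 1 degree and 1 px.
* Model recovery: noiseless von Mises samples recovered within 1% / 1% /
  0.5 degree; under Poisson noise the median over 100 replicates recovers
  `mu` within 5 degrees and `kappa` within 20%.

## Known limitations

The response model is unimodal per region; alternative good angles are
flagged, not modelled. Counting is performed on the 2D min-projection, so
structures stacked along the rotation axis at the same (x, z) are counted
once; 3D counting would be a straightforward extension. Coverage overlap
between nearby views is handled only by the cap. The file-based workflow
replaces the original acquisition-computer protocol: `evaluate`/`update`
are pure functions over a manifest directory that an acquisition loop can
poll. Region weighting (prioritising a user-defined area) is not
implemented.
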