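---
title: "Quantifying eggshell speckling and testing its signalling role: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying eggshell speckling and testing its signalling role: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`eggspeckle` implements a complete, testable version of the workflow used to
ask whether protoporphyrin speckling on great tit eggs acts as a sexually
selected signal: objective pattern quantification from vision-calibrated
photographs, clutch-level aggregation into principal-component speckling
scores, and the standardized general linear and mixed models that relate
speckling to male provisioning and chick growth in a double cross-fostering
experiment. Because no field photographs or nest records ship with the
package, a first-class synthetic-data module provides images with exact
ground truth and simulated experiments with known generating effects; every
downstream stage is validated against those truths or against independent
numerical oracles.

# The luminance channel

Birds are believed to perceive pattern and texture through the achromatic
channel encoded by their double cones. `compute_cone_catch()` therefore
collapses the calibrated reflectance planes into relative double-cone photon
catches: per pixel, a weighted sum of the channel reflectances divided by the
catch of the gray reflectance standard, so a pixel spectrally identical to
the standard has catch exactly 1. The camera-to-cone transform is supplied as
a weight vector in configuration rather than derived from spectral
sensitivity curves: the original derivation depends on camera calibration
data that are not recoverable here, and a supplied weight vector keeps the
module exact and testable. The default (`visible` 1, `uv` 0) reflects that
maculation is essentially a luminance pattern; the UV plane is carried so it
can be inspected. No chromatic modelling and no low-light (mesopic)
adaptation is applied — whether the nest cavity is bright enough for these
patterns to be discriminated at all is deliberately out of scope.

# Granularity spectra

Each egg's bounding box is cut into upper (pointed end), middle and base
slabs of equal height (remainder row to the middle). Each region is resampled
to a square 256×256 working window (bilinear), the mean of the masked pixels
filling the area outside the egg so the shell texture, not the backdrop edge,
dominates the spectrum. The window is Fourier transformed and split into
seven non-overlapping octave annuli with filter sizes (band centres) 2, 4, 8,
16, 32, 64 and 128 cycles per image width; edges sit at the geometric
midpoints, each band's upper cutoff being bit-identical to the next band's
lower cutoff so no frequency is counted twice, and the outermost band is
extended to the Fourier-plane corners. Ideal (hard-cutoff) masks are used;
no window taper is applied, because the resampled texture fills the window
and any spectral leakage is absorbed into adjacent octaves identically for
all eggs. Band energy is the *mean* squared band-image intensity over the
egg mask — mean rather than sum, so energies do not scale with egg area —
and the whole-egg spectrum is the mask-area-weighted mean of the three
regional spectra. Whether the original analyses averaged regional spectra or
transformed concatenated regions is not determinable; area-weighted
averaging is this package's documented choice, and it makes the whole-egg
spectrum of three identical regions equal to any single region's spectrum
exactly.

Two conventions deserve emphasis:

- **Intensity scale.** Energies are computed on the 16-bit digital-count
  representation of the catch image (catch × 65535, the storage scale of the
  calibrated TIFFs), so pattern contrast is commensurate with population
  statistics reported on stored images. The scale is a parameter
  (`intensity_scale`) and affects contrast only, never marking size.
- **Anisotropy.** Regions are wider than tall, so resampling to a square
  stretches them vertically. The stretch is identical for all eggs
  photographed at the same distance, so cross-egg comparisons are unaffected;
  absolute filter sizes should be interpreted on the resampled window.

**Marking size** is the filter size of the maximum-energy band, reported as
the discrete band centre with no interpolation; exact ties break toward the
smaller filter size, i.e. toward the larger marking. An all-zero spectrum
(a patternless egg) yields `NA` flagged `no_pattern` rather than a number.
**Pattern contrast** is the square root of the summed band energies; it is
exactly linear in image contrast (doubling pigment darkness doubles it), a
property the test suite checks on noise-free renders.

# Coverage and dispersion

Pigment is separated from shell ground by Otsu's between-class-variance
criterion computed *within the egg mask* on a 65,536-level quantisation of
the masked intensities; the darker class is pigment. Thresholding is per egg
— illumination is already normalized per image via the gray standard — and
the threshold is recorded in the output. A constant image has no pattern: by
convention it yields an empty pigment mask with a warning rather than an
arbitrary split. The implementation is checked against an exhaustive search
over every candidate cutoff. **Coverage** is the pigmented fraction of the
mask; **dispersion** is the standard deviation of coverage across the three
regions, using the sample (n−1) denominator — with three regions the
population alternative differs only by a constant factor, so the choice is
fixed and documented rather than consequential.

# Clutch aggregation and the speckling score

The unit of analysis is the clutch. Metrics are natural-log transformed with
a fixed offset of 10⁻³ (coverage and dispersion can be exactly zero on
lightly marked eggs; for marking size and contrast the offset is numerically
irrelevant) and averaged over the first four eggs by lay order — the eggs a
field protocol photographs. PCA is performed on the correlation matrix, the
four variables having incommensurate units, with component signs fixed so
coverage loads positively: high PC1 means a more extensively, more darkly,
more unevenly speckled egg. By default the PCA pools all measured eggs and
clutch scores are means of per-egg scores; a `level = "clutch"` switch runs
the PCA on clutch-level means instead, and on simulated populations the two
orderings agree closely (rank correlation above 0.9 in the test suite).

# The synthetic egg and its calibration

`generate_egg_image()` renders anti-aliased filled discs multiplied onto a
uniform shell ground; overlapping spots take the darker value, so pigment
never exceeds `spot_darkness` and the rendered coverage ground truth is
exact (a pixel is pigmented when its spot opacity is at least 0.5). Spot
count is Poisson, spot diameter lognormal, and spot placement follows
relative regional densities along the egg's long axis, emulating the
blunt-end ring bias of real great tit eggs. Additive Gaussian sensor noise
and an attenuated UV copy complete the image. The lognormal diameter choice
is a modelling convenience — the true spot-size distribution on real eggs is
unknown — and the renderer makes no attempt at 3-D shading, nest backgrounds
or camera optics.

The defaults are a deliberate population model: with between-egg lognormal
heterogeneity in spot rate (CV 0.35), darkness (CV 0.15) and diameter
(CV 0.24), a population of 184 rendered eggs pushed through the full
measurement pipeline reproduces the published field means of all four
pattern variables (marking size 11.95, contrast 581.77, coverage 0.19,
dispersion 0.10) within three printed standard errors. The calibration
targets the *measured* values, so it exercises rendering, cone mapping,
region splitting, resampling, Fourier filtering and thresholding jointly.
What passing this envelope does **not** show: that real eggs have lognormal
spots, that real contrast arises at this pigment darkness (the darkness
default is tied to the 16-bit intensity convention), or that the PCA
structure of rendered eggs matches real eggs — rendered metrics co-vary more
strongly than field metrics because a single latent intensity drives rate
and darkness jointly, which is why the package's PC1 share (≈75%) exceeds
the field value (≈49%) and why the corresponding check is the qualitative
bound PC1 ≥ 40%.

# The simulated experiment

`generate_experiment()` builds a field season with the full double
cross-fostering structure. Egg-swap pairs are generated jointly — partners
share an incubation start date and differ in clutch size by at most two
eggs — so pairing is feasible by construction; `pair_clutches()` applies the
same rule to user data and fails loudly on an infeasible set rather than
relaxing the matching. Clutch sizes are uniform on 6–10. Chicks are swapped
at day 1 between broods of a second, disjoint pairing, rank-matched on mass
with ties broken under the seed, exchanging alternate ranks so every nest
rears chicks from exactly two other nests and none of its own; this is why
`n_nests` must be a multiple of 4 (with only one egg-swap pair, no disjoint
chick-swap pairing exists). Chick sex is Bernoulli(0.5); hatch failure is a
configurable drop rate, default 0, used to mimic field attrition (a rate of
0.25 yields roughly 290 chicks across 48 nests, the scale of the growth
analyses).

All responses follow configured *standardized* linear structures: slopes are
on Z-scales, the nest random intercept (one independent draw per
origin-within-foster brood) has SD `random_nest_sd`, and by default the
residual SD completes each response to unit total variance so that fitted
standardized coefficients estimate the generating slopes directly. Defaults
are the published standardized effects the field study detected — brood size
on male prey delivery 0.54, female mass on speckling −0.55, egg mass on
day-15 mass 0.25, female sex on day-15 mass −0.59, random-intercept variance
0.28 — while the speckling-to-provisioning slope defaults to 0, the null
world the experiment could not reject. Day-3 masses carry no fixed effects
and day-7 masses a weak egg-mass effect (0.16), mirroring the reported
pattern of mostly-null earlier-age models. Prey delivered per hour is
generated first and then split into a plausible visit rate and mean prey
size, so the identity prey = visits × size holds exactly. Raw scales (grams,
millimetres, dates) are cosmetic: the fitting layer re-standardizes, and the
tests verify the fits are invariant to affine rescaling of raw inputs.

A lightweight metrics-level twin, `simulate_egg_metrics()`, draws the four
pattern variables directly with a clutch-level latent factor and an optional
lay-order drift knob. It exists for simulations that need thousands of
replicated clutches (the first-four-versus-whole-clutch comparison) where
rendering images would be pointless; by default it has no lay-order drift,
so that comparison is null by construction.

# Inference

Numeric variables are Z-standardized before fitting; principal-component
scores, already standardized by construction, pass through bit-identically.
`fit_glm()` uses ordinary least squares and reports per-term marginal
(type-III-style) F statistics from the full model — printed field tables
with mixed per-term denominators suggest the original software handled terms
sequentially, but marginal tests on the full model are the cleaner default
and the difference is documented rather than emulated. `fit_lmm()` fits by
REML through `lmer`, with Satterthwaite fractional denominator degrees of
freedom (the approximation implied by fractional df in published mixed-model
tables), male as the sex reference level, and Wald 95% intervals on the
Satterthwaite df. The random factor is a single intercept per unique
origin-nest-within-foster-nest combination; the phrase is ambiguous between
one and two variance components, so the one-component reading is the default
and `random = "two_component"` adds a foster-nest intercept. Singular fits
are flagged, never masked.

lme4 does not report a standard error for the variance component, so the
package attaches one from the observed information of a closed-form REML
log-likelihood (block-diagonal Woodbury identities per group), evaluated at
the fitted variances with a numerical Hessian; the interval is Wald on the
log-variance scale. The same closed form doubles as an independent
cross-check of the REML estimate in the test suite: maximising it directly
reproduces lme4's variance components to 10⁻³. When the group variance is
estimated at the boundary the fixed effects collapse to the OLS path to
10⁻⁶, also verified.

`rejection_rate()` wraps generate–fit–test loops and reports per-term
rejection fractions with exact binomial intervals. Under the null generator
the speckling terms of both the provisioning GLM and the day-15 mixed model
hold their 5% level within ±0.02 over 1000 replicates, and the
first-four-versus-whole-clutch paired t-tests reject at ≈5% over 500
replicates (±0.025, the 99% binomial envelope at that size).

# Numerical choices and degenerate inputs

- Fourier band energies agree with a direct discrete-Fourier-sum oracle (an
  explicit DFT-matrix product) to 10⁻⁹ relative error on 64×64 inputs, and
  the seven bands jointly conserve the spectral energy of the covered
  annulus to the same tolerance.
- Band edges are shared bit-identically between adjacent bands; membership
  is half-open `(low, high]`.
- Otsu ties (identical between-class variance at several cutoffs) resolve to
  the darkest cutoff; the quantisation grid is 65,536 levels over the masked
  range.
- PCA reconstruction (scores through loadings back to standardized data) is
  exact to 10⁻⁸; percentages sum to 100 by the trace identity.
- Degenerate inputs have defined behaviour throughout: constant images
  (empty pigment mask, warning; all-zero spectrum, `no_pattern`), clutches
  with fewer than four eggs (explicit `partial` flag), identical paired
  differences (explicit zero-difference report), rank-deficient design
  matrices (error naming the aliased terms), empty broods and infeasible
  pairings (errors).

# Validation problem sizes

The shipped validation uses 64×64 windows for the Fourier and threshold
oracles; 184 rendered eggs for the population calibration envelope; 200
simulation replicates for effect recovery (28-nest experiments for the
provisioning and female-quality GLMs, 48 nests with 25% hatch attrition —
about 290 chicks — for the day-15 mixed model, requiring 95% CI coverage of
every generating value in at least 90% of replicates); 1000 replicates for
the null rejection rates; and 500 for the paired-t comparison. These sizes
give binomial/Monte-Carlo noise comfortably inside the tolerances they are
tested against.

# Known limitations

- Absolute marking size depends on the anisotropic region resampling and the
  256-px window convention; compare marking sizes only across images
  processed identically.
- The contrast unit is tied to the 16-bit intensity convention.
- The renderer's between-egg heterogeneity model (a shared latent intensity)
  overstates metric correlations relative to field data; analyses of PC2 on
  rendered populations are correspondingly less realistic.
- The experiment generator requires a multiple of four nests and models
  attrition as independent per-egg hatch failure; real seasons lose whole
  nests to desertion and predation, with the messier Ns that implies.
- Visual discriminability of the patterns in nest-cavity light is not
  modelled anywhere in the package.
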