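# eggspeckle

Quantifies protoporphyrin speckling on passerine eggshells from calibrated
multispectral photographs, and analyses double cross-fostering experiments
that ask whether egg patterning signals female quality to the male — the
*sexually selected eggshell coloration* (SSEC) question in cavity-nesting
passerines such as the great tit (*Parus major*). It is aimed at behavioural
ecologists who photograph eggs with UV-capable, vision-calibrated cameras and
need objective, repeatable pattern measurements plus the standardized
GLM/mixed-model machinery used to relate them to provisioning and chick
growth.

## What it computes

**Pattern quantification.** Visible and UV reflectance planes are combined
into a single avian double-cone (luminance) photon-catch image
\(q(x) = \sum_c w_c R_c(x) / q_\text{std}\), the channel on which avian
pattern and texture perception is assumed to operate. Each egg is cut into
upper, middle and base regions, and each region is Fourier-filtered into
seven non-overlapping octave bands with filter sizes (band centres) 2, 4, 8,
…, 128 cycles per image width. The *granularity spectrum* is the band-wise
mean squared intensity, area-weighted over regions. From it:

- **marking size** — the filter size of the maximum-energy band (smaller
  filter size = larger markings);
- **pattern contrast** — \(\sqrt{\sum_b E_b}\), an amplitude-scale measure of
  pigment darkness;
- **pattern coverage** — the pigmented fraction of the egg after Otsu
  thresholding within the egg mask;
- **pattern dispersion** — the SD of coverage across the three egg regions
  (unevenness of pigmentation).

Log-transformed metrics are averaged over the first four eggs of each clutch
and reduced by PCA on the correlation matrix; PC1 (sign-fixed so coverage
loads positively) is the clutch *speckling score*.

**Inference.** `fit_glm()` fits the male prey-delivery model (prey delivered
per hour = visit rate × mean prey size) and the female-quality model on
Z-standardized variables, reporting B, df, F, 95% CI and P per term.
`fit_lmm()` fits the day-3/7/15 chick-mass models by REML with a random
intercept for *origin nest nested within foster nest* and Satterthwaite
(fractional) denominator df, and reports the random-intercept variance with a
curvature-based SE.

**Synthetic data.** `generate_egg_image()` renders speckled eggs with exact
coverage ground truth; its defaults are calibrated so that a population of
rendered eggs reproduces the published population means of all four pattern
variables (marking size 11.95, contrast 581.77, coverage 0.19, dispersion
0.10). `generate_experiment()` simulates a complete double cross-fostering
season — whole clutches swapped at incubation start between nests matched on
start date and clutch size (±2 eggs), hatchlings swapped at day 1 matched for
mass rank so every nest rears chicks from two other nests and none of its
own — with configurable true standardized effects.

## Worked example

```r
library(eggspeckle)

# render one egg at the calibrated defaults and measure it
eg <- generate_egg_image(speckle_params(), seed = 7)
egg_pattern_metrics(eg$image)[1:4]
#>   marking_size pattern_contrast pattern_coverage pattern_dispersion
#> 1           16          622.793           0.2077             0.1236

# simulate a field season and fit the day-15 chick-mass mixed model
ex <- generate_experiment(experiment_params(n_nests = 48,
                                            hatch_drop_rate = 0.25, seed = 5))
fit_chick_mass(ex, day = 15)
#> LMM fit on standardized variables (n = 290, 96 origin-within-foster groups)
#>                  term      B     df     F  95% L  95% U       P
#>           (Intercept)  0.339 149.50 14.72  0.164  0.514 1.8e-04
#>             lay_date  0.055  88.57  0.51 -0.097  0.207 4.8e-01
#>            sexfemale -0.684 257.80 44.85 -0.885 -0.483 1.3e-10
#>          avg_egg_mass 0.225  86.32  9.26  0.078  0.372 3.1e-03
#>   ...
#> Random factor (origin nest within foster nest): variance 0.263 +/- SE 0.074
```

The egg shown has markings peaking in the 16-cycle band (medium spots),
covers 21% of the shell with pigment and is unevenly marked toward the blunt
end. In the simulated season the generating truths were a −0.59 female-sex
effect, a 0.25 egg-mass effect and a 0.28 random-intercept variance; the fit
recovers all three within its confidence bounds, while the three speckling
terms (generated null) stay null.

`run_pipeline(run_config(...))` chains everything — simulate experiment,
render and measure the first four eggs of each clutch, aggregate to clutch
PCA scores, fit the models — and writes CSVs plus a log;
`inst/cli/eggspeckle.R` exposes the same stages as shell subcommands.

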