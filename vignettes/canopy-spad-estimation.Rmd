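---
title: "Shade-aware SPAD estimation from canopy images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shade-aware SPAD estimation from canopy images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

SPAD meters give a fast, nondestructive proxy for leaf chlorophyll, but
reading three leaves per plant by hand does not scale to whole nurseries.
`canospad` implements an image-based alternative for containerized or
field-grown seedlings photographed from above: plant pixels are separated
from background, vegetation indices (VIs) are computed from
white-plate-corrected channel means, a screening stage removes
non-informative and mutually collinear indices, and regression models —
optionally aware of the shade treatment each seedling grew under — map the
retained indices to SPAD.

Shade is central. Shade netting is a routine nursery measure, it shifts the
chlorophyll distribution (the default study conditions have per-level mean
SPAD 18.39, 25.76, 31.81 and 29.26 under 0/25/50/75 % shade — chlorophyll
peaks at intermediate shade), and it darkens the scene. The pipeline
therefore treats shade twice: optically, through the white-plate
correction that cancels scene brightness; and statistically, through
dummy-variable or random-intercept terms that let models adapt to each
level.

## The synthetic study

No public per-seedling image set accompanies this problem, so the package
ships a first-class generator (`synth_dataset()`) whose defaults *are* the
study conditions, and every downstream stage is tested against its known
ground truth.

**Population.** `sample_population()` draws true SPAD per seedling from a
normal distribution per shade level, truncated below at 5, with 50
seedlings per level. The within-level standard deviation defaults to 3.6
SPAD: combined with the per-leaf meter noise (1 SPAD, averaged over three
leaves as in the field protocol) it puts the one-way ANOVA F statistic
across levels in the low hundreds, the magnitude typical of strong shade
trials of this size. Meter noise magnitude is not something a data sheet
pins down precisely; 1 SPAD per leaf reading is a realistic repeatability
figure and is a free configuration knob.

**Optics.** `spectral_model()` links chlorophyll to leaf reflectance with a
Beer–Lambert-like decay per band, `baseline * exp(-k * SPAD) + floor`. Only
the qualitative structure matters for what the pipeline must demonstrate:
red absorbs most (`k_red > k_green > k_red_edge > k_nir = 0`), the NIR
plateau is chlorophyll-blind, and soil is flat-ish and brighter in red than
vegetation. This yields the canonical correlation signs — NDVI and NDRE
rise with SPAD, the red/green ratio falls — without pretending to
radiative-transfer realism (no PROSPECT/SAIL, leaf angle distributions or
camera PSF; those are out of scope).

**Scenes.** `render_scene()` builds a co-registered pair per seedling: an
8-bit RGB image and a 16-bit five-band multispectral image (band order
blue, green, red, NIR, red edge; the green band is treated as centered near
560 nm, the physically plausible reading of its sensor specification), plus
a white reference panel at a known corner location and the ground-truth
plant mask. The scene emulates a region-of-interest crop centered on one
seedling, so the canopy occupies roughly a third to a half of the frame.
Noise has deliberate structure:

* a per-seedling lognormal factor per band (sd 0.10) — individual optical
  variation, which is what keeps index–SPAD correlations away from 1;
* a per-pixel brightness texture shared across bands (sd 0.05) — surface
  roughness, which cancels in band ratios the way real micro-shading does;
* a small independent per-band texture (sd 0.03), plus extra NIR/red-edge
  texture on plant pixels (sd 0.20) reflecting leaf structural variation,
  which gives the vegetation mode of an NDVI histogram its realistic width;
* extra broadband noise on the RGB channels (sd 0.08), typical of a
  consumer sensor, which also dithers the 8-bit quantization in dark
  scenes.

Illumination enters multiplicatively (defaults 1.0/0.75/0.5/0.25 across the
four shade levels) before DN quantization, so the white-plate correction is
genuinely exercised rather than vacuous. Quantization rounds to the nearest
DN level, as a camera ADC does; truncation toward zero would leave a
half-step bias that does not cancel in the white-plate ratio at the darkest
level.

What passing tests on these scenes shows — and what it does not: the
pipeline's algebra, segmentation and invariances are verified end to end on
images with known truth; transfer to real imagery still depends on factors
the generator deliberately omits (mixed boundary pixels, specular leaves,
non-flat illumination, instance overlap between neighboring plants).

`simulate_band_means()` is an analytic shortcut through the same optical
model that skips rendering; model-level simulation studies use it so that
their run time is spent on the models, not on re-exercising segmentation,
which has its own tests.

## Segmentation

Gray conversion uses ExG (`2G - R - B` on bit-depth-scaled channels) for
RGB and NDVI for the multispectral stack, both higher on vegetation, so the
default polarity is plant-is-high. Thresholds come from Kapur's
maximum-entropy criterion: valid pixels are histogrammed into 256
equal-width bins over the full observed range (`n_bins` is configurable;
256 is the 8-bit heritage default), and the cut maximizing the sum of the
two class entropies is returned, with empty bins contributing zero
(`x log x -> 0`), ties broken to the smallest cut, and natural logarithms
throughout (the base only rescales the criterion). The implementation is
vectorized over cuts; tests compare it against an independent brute-force
scan on random images, and an affine-equivariance property pins down the
full-range histogram convention.

Two practical choices deserve note. The white reference panel is a
calibration object at a known manifest location — neither plant nor natural
background — so `segment_scene()` excludes its pixels from the threshold
histogram and labels them background; leaving it in plants a third
histogram mode that entropy thresholding happily splits off instead of the
vegetation. And no morphological cleanup is applied by default; the
segmentation flow is conversion, threshold, mask.

## Index extraction

Per seedling, channel means are taken over the plant mask ("means first"),
divided by the white-panel means (panel treated as reflectance 1.0), and
only then pushed through the index formulas — ten RGB indices (ExG, ExGR,
NGRDI, NGBDI, RGRI, GBRI, CIVE, VEG, RGBVI, MGRVI) and ten multispectral
ones (NDVI, RVI, DVI, EVI, RDVI, REVI, NDRE, RERVI, REDVI, sCCCI). The
formulas are kept exactly as the package documents them, including two
forms that deviate from the commoner literature variants
(`RGBVI = (G^2 - B*R^2)/(G^2 + B*R^2)` and `RDVI = sqrt(NDVI/DVI)`); a
`literature_formulas` switch (default off) selects the standard variants.
Undefined values (zero denominators, negative radicands) are flagged
invalid rather than raised, and records with missing selected indices are
dropped from modeling with a logged count.

Note the exact identity `RERVI = REVI + 1`: any feature set containing both
is perfectly collinear. This is intentional — it is precisely the
pathology the screening stage must handle.

## Screening

Screening runs on the modeling split only. Each index gets a Pearson
correlation with SPAD and a two-sided t-based p-value; indices with
`p >= 0.05` are dropped (no multiplicity correction by default, matching
common practice in this literature; Holm is available behind a flag).
Variance inflation factors — `VIF_j = 1/(1 - R2_j)` from regressing index j
on the rest — diagnose multicollinearity in the usual bands (<10 none,
10–20 some, >20 serious), with near-singular fits capped at 1e6.

Selection is the Lasso, `argmin ||y - X beta||^2 + lambda * sum |beta_j|`
on standardized columns and centered response, solved by cyclic coordinate
descent with soft thresholding (tolerance 1e-8, at most 1e5 sweeps). The
sweep kernel is compiled (Rcpp) and works in covariance form from `X'X` and
`X'y`, because near-collinear index pairs make convergence slow at small
penalties. The penalty enters the objective once (not scaled by n);
`lambda` is chosen as the minimizer of 10-fold cross-validated MSE over 100
log-spaced penalties from `lambda_max = max_j |2 x_j' y|` down to
`1e-4 * lambda_max` (CV-minimum, not the 1-SE rule). Exactly aliased
columns — standardized duplicates such as the REVI/RERVI pair — make the
penalized optimum non-unique (any split of the shared weight is a
minimizer), so later aliases are dropped before the fit and reported, as
ordinary linear modeling does with aliased terms. Karush–Kuhn–Tucker
stationarity is checked on every returned solution and exposed in the
report.

A limitation worth stating: Lasso removes *exact* aliases deterministically,
but for merely near-collinear pairs the CV-minimal penalty frequently keeps
both members, so retained-set VIFs well above 10 are possible — and do occur
on the synthetic study, whose indices are driven by a single latent optical
variable per seedling and are therefore more mutually correlated than
indices from real canopies tend to be.

## Models

Four families relate the selected indices (and optionally shade) to SPAD:

* **OLR** — least squares via QR, implemented in the package. With shade,
  the design uses one-hot dummies without a global intercept, so each dummy
  coefficient is directly a shade-level intercept. Whether a separate
  global intercept should accompany the dummies is genuinely open; the
  no-intercept coding was chosen to keep the level parameters
  interpretable, and it spans the same column space either way.
* **LMM** — a random-intercept model per shade level, fitted by REML,
  implemented in the package: the variance ratio is profiled out of the
  restricted likelihood and optimized by bounded one-dimensional search on
  the log scale (tolerance 1e-8, boundary at zero checked explicitly);
  predictions for known groups add the BLUPs. Random *slopes* exist behind
  a flag in spirit only: four shade levels cannot support a rich
  random-slope structure, so random intercepts are the default and the
  tested configuration. Tests verify the fit against `lme4` and against the
  balanced-case shrinkage closed form.
* **RF** — bagged regression trees, delegated to `randomForest` (500
  trees, `ceiling(p/3)` features per split, minimum node size 2, unlimited
  depth). The literature this package follows reports no RF settings, so
  defaults are the field's customary ones.
* **SVR** — epsilon-SVR with an RBF kernel, delegated to `e1071`; the
  `(cost, gamma, epsilon)` triple is chosen by seeded 10-fold
  cross-validated MSE over log grids (`2^-3..2^10`, `2^-10..2^3`,
  `{0.01, 0.1, 0.5, 1}`), ties to the first grid point.

The linear algebra of the dummy and mixed models is package code because
those estimators are the analysis's substance; RF and SVR use the standard
solvers a practitioner would use. One reproducibility caveat: RF bootstrap
resampling is tied to row positions, so RF results are reproducible for a
fixed seed and row order, but not invariant to permuting the training rows;
OLR, the LMM, and an SVR fit at fixed hyperparameters are row-order
invariant.

## Evaluation

`split_plan()` partitions ids 3:1 (150 modeling / 50 test at default scale)
by uniform random sampling; stratification by shade is available but off by
default, since plain random sampling is the baseline protocol. Metrics are
`R2 = 1 - SSE/SST`, RMSE in SPAD units, and MAPE in percent. Test-set R2
uses the test-set mean in its denominator and may legitimately be negative.
Reported tables round half-up (4 decimals for R2/RMSE, 2 for percentages) —
`relative_change()` reproduces printed percent-comparison arithmetic under
exactly that convention. `anova_oneway()` is the classic equal-variance
F test across shade levels.

## Orchestration and problem sizes

`run_experiment()` drives generate → segment → extract → screen → fit →
evaluate from one configuration with a single master seed, from which every
stochastic stage (scene geometry, CV folds, split, RF, SVR) derives its own
sub-seed; identical configurations reproduce results bit for bit. The
summary table crosses 4 families x 2 image sources x 2 shade modes (the
shade-blind "LMM" is plain OLR, since a mixed model without grouping has no
random term). A thin command-line front end over these functions ships in
`inst/cli/canospad.R`.

Default problem sizes were chosen so a full desk run stays comfortable on
one core: 200 scenes at 96x96 pixels render in a few seconds; the complete
experiment including both SVR grid searches takes a few minutes. Simulation
tests scale down further (reduced SVR grids, 20 replicate seeds for the
shade-awareness contrast, 50 for REML parameter recovery at n = 200 with 8
groups — recovery of a variance component needs enough groups, so the
recovery study uses 8 rather than the study's 4).

## Known limitations

* Entropy thresholding misbehaves when one histogram mode is both tight
  and dominant; the generator's class balance and texture structure keep it
  in its well-behaved regime, and real scenes with extreme background
  dominance would need cropping (a crop rectangle can be supplied).
* Index–SPAD correlation magnitudes on synthetic data are a consequence of
  the chosen noise structure; only their signs and orderings are meaningful
  reproductions.
* MAPE is undefined when an observed SPAD is zero; the pipeline raises
  rather than silently skipping.
* The generator does not model mixed boundary pixels, specular highlights,
  instance overlap, or spatially varying illumination.
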