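---
title: "Quantifying El/Ca ratios in single coccoliths from NanoSIMS image stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying El/Ca ratios in single coccoliths from NanoSIMS image stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(coccosims)
```

# The measurement problem

A NanoSIMS records, for each pixel of a small raster (5--20 um across) and
for each of up to six tuned masses (here ^23^Na^+^, ^24^Mg^+^, ^39^K^+^,
^44^Ca^+^, ^88^Sr^+^, ^138^Ba^+^), the number of secondary ions detected
while a primary beam sputters the sample. Repeating the raster over many
cycles ("planes", typically 1000) both accumulates counts and profiles the
sample in depth, since each plane removes material.

For individual coccoliths of *Emiliania (Gephyrocapsa) huxleyi* --- calcite
plates 3--5 um across and ~500 nm thick deposited on a polycarbonate filter
--- the quantity of interest is the element-to-calcium ion-count ratio
$R_{el} = N_{el}/N_{Ca}$ accumulated over one coccolith, later converted to
a molar El/Ca ratio via calcite standards. Three artefacts stand between
the raw stack and an accurate $R_{el}$:

1. **Lateral contamination.** Sea-salt precipitates and organic remnants
   sit on or next to coccoliths. They are strongly enriched in Na, Mg, K
   and often Ba relative to Ca --- but never in Sr --- and must be excluded
   pixel-wise.
2. **Depth variability.** Surface-bound contamination and incompletely
   stabilised secondary-ion yields make the per-plane El/Ca ratio vary with
   depth; affected planes must be discarded, not averaged in.
3. **Isobaric interference.** The ^44^Ca~2~^+^ dimer is not mass-resolvable
   from ^88^Sr^+^ and adds $\delta$ expected mass-88 counts per detected
   ^44^Ca ion; the contribution is subtracted before the Sr/Ca ratio is
   formed. (The corresponding multimer interference on ^138^Ba is far
   smaller and is not corrected.)

The package implements the full chain --- alignment, segmentation,
depth-profile quality control, Ca-gated accumulation, dimer correction,
calibration, cohort statistics --- and, because raw instrument stacks are
rarely shareable, a ground-truthed synthetic stack generator so that every
stage can be validated against a known answer.

# The synthetic stack model

`generate_stack()` draws independent Poisson counts per pixel $x$, plane
$p$ and mass $m$ with expectation

$$\lambda_m(x,p) = \Big[(1-\omega(x))\,b_m + L_m(x) +
  \sum_c C_{c,m}(x)\,2^{-p/h_c}\Big]\,\big(1 + a_m 2^{-p/\tau}\big),$$

where $b_m$ is the filter background rate (counts px^-1^ plane^-1^),
$L_m$ the coccolith rate field ($L_{Ca}$ set by the phantom's `ca_rate`,
trace elements by their true ratios $R^*_{el}$), $C_{c,m}$ the contaminant
surface fields with sputtering half-lives $h_c$ (planes), and
$1 + a_m2^{-p/\tau}$ a per-mass yield-drift term emulating incomplete
pre-sputter stabilisation. All spatial fields are blurred with a Gaussian
beam point-spread function (FWHM 0.35--0.5 um, default 0.4). Mass 88
receives an additional independent Poisson term with expectation
$\delta\,\lambda_{Ca}(x,p)$ --- the dimer is additive; detecting a dimer
does not remove monomer detections.

Design choices worth stating explicitly:

* **Occlusion, not superposition, of the substrate.** $\omega(x)$ is the
  beam fraction covered by coccolith calcite. Where a lith covers the
  filter, the beam samples the lith surface, so the filter background is
  suppressed there instead of shining through. A purely additive background
  would contaminate every in-lith ratio with a substrate term that the
  physical measurement does not contain.
* **Exponential depth decay.** Contaminant particles are gradually
  sputtered away; a half-life parameterisation is the simplest monotone
  model and its parameters are stated per scenario. No attempt is made at
  SRIM-like sputtering physics, topography-dependent yields, or charging.
* **Independent Poisson counts** per pixel/plane/mass; no detector
  dead-time or quasi-simultaneous-arrival correction.
* **Exact plane binning.** Because sums of independent Poisson variables
  are Poisson with summed rates, `bin_planes = k` stores each group of $k$
  planes as one page drawn from the exact distribution of the plane sums.
  Every downstream statistic operates on 5-plane blocks (see below), so
  binned generation at `bin_planes = 5` is distributionally identical for
  the whole pipeline while being about five times faster. Per-plane
  generation remains the default.
* **Geometry convention.** Square pixels; pixel (row 1, col 1) centred at
  (0.5, 0.5) pitch; rows increase downward; plane 1 is the shallowest.

Three registered scenarios (`default_scenario()`) fix the study conditions:
`"clean"` (three uncontaminated liths, outer radii 2.1--2.3 um, Ca rate
2 counts px^-1^ plane^-1^, 128 x 128 px over 20 um, 500 planes, dimer
$\delta$ = 0.005), `"salt_speckled"` (one lith plus a salt particle on its
rim, a particle on the bare filter, and a thin surface film over the whole
lith that sputters away within the first ~100 planes), and `"drifty"`
(clean geometry with drift amplitudes 0.3/0.2/0.15/0.05 for Na/Mg/K/Sr,
150-plane half-life, stable Ca). Background rates are low-count filter
values (Ca 0.01, Na/K 0.002, Mg 2e-4, Sr 5e-5, Ba 2e-5 counts px^-1^
plane^-1^). Contaminant compositions are illustrative --- no quantitative
contaminant analysis exists to calibrate them against --- but they
reproduce the phenomenology that matters: strong Na/Mg/K/Ba enrichment, no
Sr, and depth decay.

What the generator does **not** emulate --- and hence what passing tests do
not establish about real data: lateral heterogeneity within a coccolith
(phantoms are uniform), topographic yield variation at lith edges,
stage-drift misalignment beyond integer pixel shifts, detector dead time,
and matrix effects between biogenic and inorganic calcite (which bound the
accuracy of any calibrated value; see Calibration).

# Processing stages

## Alignment and accumulation

`align_stack()` estimates one integer (dy, dx) shift per block of 50 planes
by maximising the cross-correlation of the block's accumulated ^44^Ca image
against a running accumulated reference, applies it to all masses, and
crops to the common valid window. Per-block integer shifts are used rather
than per-plane subpixel shifts because single planes carry too few Ca
counts for reliable registration, and integer shifts keep counts integral.
Ties between candidate shifts prefer the smaller displacement. An all-zero
Ca channel is an error that points to the `max_shift_px = 0` bypass.

## Segmentation

`segment()` classifies the accumulated field of view:

* **Coccoliths**: connected components of pixels whose accumulated ^44^Ca
  count reaches the `ca_quantile` = 0.90 quantile of all nonzero-Ca pixels,
  kept at `min_area_px` >= 20. A quantile threshold makes segmentation
  invariant under global count rescaling.
* **Contaminants**: connected components where any smoothed (3 x 3 mean)
  El/Ca accumulated-ratio image --- El among Na, Mg, K, Ba; never Sr ---
  exceeds `enrichment_factor` = 3 times the median of that ratio over
  coccolith pixels. Because single stray ions on the near-zero background
  can exceed any ratio threshold, a pixel additionally needs a smoothed
  element signal of at least `min_signal_frac` = 0.25 of the median
  coccolith signal for that element; the guard is fractional so rescale
  invariance is preserved exactly.
* Pixels passing both tests are classed contaminant (the conservative
  choice when contamination overlaps a coccolith --- the original
  coccolith label is retained in `labels_raw`, so the uncorrected region
  remains reconstructable and the choice auditable). The remainder is
  filter background.

Hand-drawn ROI maps can be supplied instead (`run_pipeline(roi_in = )`),
mirroring the manual practice the automated rule replaces.

One property of intensity-threshold ROIs is worth knowing: the threshold is
applied to the same Ca counts that later form the ratio denominator, so
pixels at the ROI boundary are selected partly on upward Ca noise. For the
scenario geometries here the induced bias on $R_{el}$ is a few tenths of a
percent --- negligible against per-coccolith counting errors, but visible
in high-replication bias studies, which therefore use geometry-defined
interior reference regions.

## Depth QC: the Poisson-corrected CV

For each coccolith ROI and element, `build_profile()` forms block sums
$n_{el}(b)$, $n_{Ca}(b)$ over consecutive 5-plane blocks and the ratio
series $r(b) = n_{el}(b)/n_{Ca}(b)$. The observed variability
$CV_{obs} = \mathrm{SD}(r)/\overline{r}$ (n-1 denominator, blocks weighted
equally) contains a floor from counting statistics alone; to first order
the relative variance of a ratio of independent Poisson sums is
$1/n_{el} + 1/n_{Ca}$, so

$$CV_P = \sqrt{\tfrac{1}{B}\sum_b \big(1/n_{el}(b) + 1/n_{Ca}(b)\big)},
\qquad CV_{corr} = \sqrt{\max(CV_{obs}^2 - CV_P^2,\, 0)}.$$

$CV_{corr}$ --- the residual, counting-corrected depth variability --- is
the measurement-precision figure attached to every reported ratio. Blocks
with zero element counts contribute $1/\max(n_{el},1)$; blocks with zero Ca
are dropped and counted. The quadrature subtraction is validated against a
Monte-Carlo oracle (stationary Poisson profiles) rather than against any
closed-form reference: the mean observed CV matches $CV_P$ to well within
2%, and the excess $CV_{obs}^2 - CV_P^2$ is centred on zero to the accuracy
of the first-order expansion (second-order $1/\lambda^2$ terms remain ---
at 50 element counts per block they amount to a few times $10^{-4}$ on the
squared scale, which a sufficiently large simulation can resolve).

## Stable-window selection

"Remove the planes over which most of the depth variation occurs" is
operationalised as: among all contiguous block windows covering at least
`min_fraction` = 0.5 of the blocks, select the longest whose $CV_{corr}$ is
at most `cv_target` = 0.10; break ties by larger total Ca counts, then by
deeper start (surface contamination and drift concentrate early). If no
window qualifies, the minimum-CV window is used and the result flagged
unstable. The search is exhaustive over the $O(B^2)$ windows using prefix
sums ($B \le 200$), so it is cheap and deterministic --- no changepoint
heuristics. Windows are selected per element, since depth stability is
element-specific; planes outside the window are excluded, never corrected.
Whether the original manual screening was rule-based is unknowable from the
outside; this rule is an explicit, configurable stand-in, and a result is
flagged surface-contaminated whenever the window discards more than 10% of
the blocks.

## Ca-gated accumulation

Within the stable window, `gated_ratio()` accumulates a (pixel, block) cell
only if it holds at least `gate_min_ca` = 1 detected ^44^Ca ion. The gate
is evaluated on 5-plane blocks, not single planes, because at typical Ca
rates the probability of detecting zero ^44^Ca ions in one pixel and plane
is substantial and a single-plane gate would bias the accounting; one ion
per block is the minimal "calcium was detected" reading. Gating keeps
pixels whose calcite emerges only after an overlying particle has sputtered
away, rather than discarding those pixels for all planes --- preserving
ions and hence precision. `gate_min_ca = 0` is the documented bypass that
reduces the gated ratio to the plain ratio. Contaminant-classed pixels are
excluded from coccolith sums even where they overlap the coccolith ROI.

## Dimer correction and calibration

`dimer_correct()` subtracts $\delta \cdot n_{Ca}$ from the gated mass-88
sums (floored at zero, with a warning when the floor binds); on ratios this
is exactly $R_{Sr,corr} = R_{Sr,raw} - \delta$. $\delta$ is a session
constant supplied by configuration; `estimate_delta()` estimates it as the
mean mass-88/mass-44 count ratio over an Sr-free reference region but is
never applied automatically. For synthetic scenarios the pipeline uses the
generator's true $\delta$, as one would use a session calibration.

`calibrate()` converts ion-count to molar ratios through a proportional
(through-origin) relation $M_{el} = a_{el} R_{el}$ --- the bundled
reference table of thirteen paired per-sample means is consistent with a
single multiplicative factor per element, and an intercept is not
identifiable from it. `fit_calibration()` estimates $a_{el}$ by
through-origin least squares with relative-error (1/x^2) weights, i.e. the
mean of per-sample molar/ion ratios: the ion ratios span two orders of
magnitude across samples and the calibration scatter is multiplicative, so
absolute-error weighting would let the largest samples dominate and
mispredict the small ones. The default relative accuracies are 20% (Na),
21% (Mg), 5% (Sr) and 4% (Ba); reported molar uncertainties combine the
per-coccolith precision ($CV_{corr}$) with these in quadrature, and no
calibrated value is more accurate than its calibration. K/Ca has no
calibration (the K content of the synthetic calcite standards is unknown)
and remains in ion-count units permanently; Ba results are flagged
low-precision when the counting error of the gated sums exceeds 0.25.

# Cohort statistics

Ratios are skewed towards high values, so all group-level inference uses
natural logarithms (natural, so growth rates come out in d^-1^ and the base
cancels everywhere else).

* `cv_decomposition()` contrasts the within-coccolith precision (the
  per-lith $CV_{corr}$) with the among-coccolith CV of $R_{el}$ within a
  sample; among-lith CVs above 1 are flagged rather than plotted.
* `anova_tukey()` runs one-way ANOVA on log ratios followed by Tukey's HSD
  on all pairs (studentized-range distribution; Tukey--Kramer for unequal
  n), with a compact letter display built by insert-and-absorb: groups
  share a letter iff their adjusted p is at least alpha. Per-lith values
  enter unweighted by their precision, and elements are tested separately.
  Exactly separated groups (zero within-group variance at floating-point
  resolution) get exact-separation letters with a warning.
* `correlation_matrix()` screens Pearson correlations of log ratios against
  per-sample covariates (salinity, alkalinity, temperature, nutrients),
  two-sided t-test p-values, significance flagged at p < 0.05 and no
  multiple-testing adjustment. Covariates are constant within a sample, so
  the effective replication is at the coccolith level --- a deliberate
  caveat carried in the documentation.
* `growth_rate()` is the OLS slope of log cell density against time.

# Validation sizes and what they show

The package's acceptance suite (and `scripts/acceptance.R`, which recomputes
the same quantities from scratch) runs at these problem sizes, chosen to
make Monte-Carlo error small against each tolerance while completing in
minutes on one core:

* Poisson-CV oracle: 200 blocks at 50/500 expected counts, 2000 replicates.
* Clean-scenario recovery: 128 x 128 px, 500 planes, 3 liths, 100 seeds;
  every recovered ratio is compared against the generator truth at 3
  combined-Poisson-SE per case.
* Contamination robustness: the salt scenario over 100 seeds, comparing the
  full treatment (contaminant-pixel exclusion, window screening, Ca gating)
  against the naive ratio over the uncorrected region; Sr/Ca serves as the
  negative control.
* Dimer correction: 200 seeds of a two-mass stack (true Sr/Ca 0.080,
  delta 0.01) measured on a geometry-defined interior region.
* Statistics: 1000 simulated null datasets for the family-wise error rate;
  adjusted p-values checked against an independent studentized-range
  implementation at 1e-6.

# Known limitations

* The Poisson correction is first-order in $1/n$; at very low counts per
  block (deep-sea Ba, for instance) the correction underestimates the
  counting floor by $O(1/n^2)$ terms. The low-precision flag is the guard.
* Threshold segmentation's Ca-noise selection bias (above) is accepted as
  negligible at per-coccolith precision; applications needing sub-0.1%
  accuracy should use fixed-geometry ROIs.
* The contaminant screen needs the contaminant to be laterally resolvable
  or depth-resolvable; a uniform, permanent film indistinguishable from the
  lith signature would pass through, as it would for any data-driven rule.
* Molar ratios inherit the calibration's matrix mismatch between synthetic
  and biogenic calcite; the stated 4--21% accuracies are lower bounds on
  the true uncertainty.
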