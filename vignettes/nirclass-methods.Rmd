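---
title: "Methods and design notes: on-device NIR cannabis classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes: on-device NIR cannabis classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirclass)
```

This vignette records the model, the assumptions, and the design
decisions behind `nirclass` — the things a maintainer or reviewer
would want to know that the function reference does not say.

## The classification problem

A handheld dual-module NIR sensor must decide, in the field and
without sample preparation, whether a cannabis sample contains more
than 0.4 wt% THC. The decision threshold is a *legal* construct, not a
spectroscopic one: the spectra of a 0.35 wt% and a 0.45 wt% sample are
nearly identical, so some decisions are intrinsically uncertain, and
the method is designed around that fact — it reports *unsuspicious* /
*suspicious* only when a calibrated posterior probability reaches
0.60, and *uncertain* otherwise. Potency regression is implemented
(`fit_potency_plsr()`) only to document why it is not the decision
engine: a few wt% of prediction error dwarfs the threshold.

## Pipeline and its assumptions

**Quality control** operates on raw intensity triplets, before any
absorbance computation, because its purpose is instrumental (sample
movement, poor sample presentation) rather than chemical. The movement
statistic is the mean over wavelengths of the across-scan standard
deviation, with the sample (n−1) convention — three scans are a sample
of the scan process. The instrument's real thresholds are not public;
the defaults here are anchored to the generator's stated world
(movement limit 40 counts = 5× the scan-noise sd, intensity floor
2000 counts = 10% of the white-reference level) and are config-exposed
(`qc.max_mean_sd`, `qc.min_mean_intensity`). Whether the movement
check should run on intensity or absorbance is not documented for the
original device; intensity was chosen here and both are reachable
through the API.

**Preprocessing** is a Savitzky–Golay filter (window 5 points, order
2, first derivative) followed by SNV. Two choices were genuinely open:

* *Edge handling.* The SG output keeps all 81 grid points by fitting
  the local polynomial to the truncated window at the two points on
  each edge (dropping the polynomial order if a truncated window gets
  too short). Keeping full length means wavelength-selection indices
  stay aligned with the grid. The alternative — truncating to 77
  points — would silently shift every interval boundary.
* *Derivative units.* The derivative is per index step, not per nm.
  On a uniform 5 nm grid these differ by a constant factor which the
  subsequent SNV removes, so the choice is cosmetic; it is recorded
  because it changes raw SG output values.

SNV uses the sample (n−1) standard deviation, the convention of common
chemometrics software. The composed pipeline is exactly invariant to
per-spectrum multiplicative scaling and additive offsets — the two
interferences the generator injects deliberately (scatter factor,
baseline), so the tests can verify the pipeline does what it is for.

**PLS** is NIPALS with X- and Y-deflation on mean-centered data,
collapsed to a regression vector. NIPALS (not SIMPLS) because
reference formulas for oracle comparison are ubiquitous and the
difference is numerically negligible for binary-response models. For a
binary PLS-DA, coding class 1 as +1 on a single response column is
equivalent to two-column coding, and the two per-class regression
vectors are sign mirrors — asserted in the tests.

**Cross-validation.** "90/10" is realized as 10-fold CV with a seeded
shuffle and venetian-blind assignment, stratified by class in
discriminant mode. Whether the original calibration used a single
90/10 split or full 10-fold is unknowable from the available
description; 10-fold uses all data and is deterministic given the
seed. The component count minimizes the out-of-fold misclassification
count, taking the smallest count among ties (parsimony). On synthetic
data the misclassification curve is flat near its minimum, so the
selected count is small (1–3) — the real device's six components
reflect the far messier real spectra.

**Outlier screening.** One pass: fit an initial CV-sized model,
compute Q residuals (squared residual of the orthogonal projection
onto the loading subspace) and Hotelling T² (scores scaled by training
score variances), remove calibration spectra exceeding *either* 95%
limit (Jackson–Mudholkar for Q, F-distribution scaling for T²), refit.
The original calibration removed 39 of 4260 spectra without stating a
rule or confidence level; 95% in either statistic is the common
default, and a single pass avoids iterative shrinkage of the
calibration set. With heavy-tailed synthetic scatter the screen
typically removes 5–10% of spectra.

**Interval selection.** Forward iPLS on 5-variable (25 nm) intervals:
score every interval alone by CV misclassification, seed with the
best, greedily add intervals while the criterion strictly improves,
preferring lower wavelengths on ties. Exhaustive subset search over 17
intervals is tractable but nonstandard; forward selection is what
practitioners run. The inner component count is chosen per candidate
subset by the same CV (up to `max_lv` = 8), since the original
coupling of iPLS to CV is not further specified. The selected regions
are *re-computed per training set*, never hard-coded: on the default
generator the packaging-dominated 1680–1735 nm region is excluded when
bag type varies independently of class, mirroring the behaviour
reported for the real device — but selection is data-driven, and under
some seeds a packaging-region interval can enter if it helps the model
cancel bag variance elsewhere. That is a property of iPLS, not a bug.

**Bayes calibration and the uncertainty zone.** Class-conditional
normal densities are fitted to the training predicted values; priors
default to training class proportions, with an `equal_priors` option
(the original description invokes Bayes' theorem without stating
priors; its histogram normalization hints at equal weights, so both
modes exist). Posteriors are computed in log space so they normalize
exactly even 50σ from both means. The verdict threshold is *p ≥ 0.60*:
the available description says "more than 60%" in one place and "at
least 60%" in another; ≥ was adopted and the discrepancy recorded. At
the exact boundary the choice is untestable on real data (posteriors
are continuous), but the rule must be deterministic.

**Fusion.** Red > yellow > green. Red dominance (any suspicious module
makes the device verdict suspicious) is explicit in the source
material; the yellow-vs-green cell is not readable from the text, so
yellow-dominates-green was chosen as the conservative option — mixed
evidence yields *uncertain*, consistent with the reported fused
uncertain fraction staying essentially equal to the per-module one.

## The synthetic world

The generator exists because the original spectra are not deposited.
It is a *stated world*, not a tuning knob: its defaults were fixed
once, from the published sample statistics where available and from
field-plausible magnitudes elsewhere.

| Parameter | Default | Why |
|---|---|---|
| Grid | 1550–1950 nm, 5 nm | the instrument's acquisition grid |
| THC class 1 | log-uniform 0.02–0.40 wt% | published sample range, threshold side |
| THC class 2 | log-uniform 0.45–24.38 wt% | published range; validation class 2 started at 0.45 |
| CBD class 1 / class 2 | log-uniform 1–18.69 / 0.02–2 wt% | chemotype structure, see below |
| Class balance | 42.1% / 57.9% | the published calibration split |
| White reference | ~20 000 counts, smooth | typical 16-bit detector headroom |
| Scan noise sd | 8 counts | SNR ≈ 2500 after 50-fold averaging |
| Scatter | lognormal sd 0.15 (multiplicative) + linear baseline sd 0.02 AU | particle-size/presentation effects SNV+derivative must remove |
| Module gain | lognormal sd 0.05 per module | module-to-module variation |
| Spot THC heterogeneity | lognormal sd 0.25 per spot | "significant" spot-to-spot discrepancy on flower buds |
| Moisture | uniform 0.05–0.15 | air-dry plant material |
| Bands | Gaussian, fictional positions | see below |

Two choices deserve emphasis:

* **Band positions are fictional.** Real cannabinoid band assignments
  in 1550–1950 nm exist in the literature but are not reproduced here;
  the generator only preserves the *structural* facts the pipeline
  relies on (PE/PP interference confined to 1680–1735 nm, water band
  above 1830 nm, cannabinoid bands overlapping but distinct). A green
  test therefore establishes that the *algorithm* behaves correctly on
  data with this structure — not that the model would transfer to real
  cannabis spectra.
* **CBD follows chemotype, not independence.** The first draft drew
  CBD independently of class over the full published range; that is
  chemically wrong (THC-rich drug-type plants are CBD-poor and vice
  versa — a 24 wt% THC, 18 wt% CBD sample does not exist) and it
  removed a correlation the real classifier almost certainly uses.
  The generator now draws class-1 CBD from 1–18.69 wt% and class-2
  CBD from 0.02–2 wt%. This makes the synthetic problem easier than
  the independent-CBD variant; the structural tests do not depend on
  it, and the end-to-end accuracy figures should be read as properties
  of this stated world.

Spot heterogeneity is multiplicative (`THC_spot = THC ×
lognormal(0, 0.25)`), which automatically makes the absolute spread
larger for high-THC samples — the mechanism behind the observation
that class-2 spectra of the same sample disagree more between spots.

What the generator does **not** model: Kubelka–Munk diffuse-reflection
physics, instrument line shape, wavelength-axis drift, temperature
effects, and non-Gaussian band shapes. None of these change what the
tests establish (algorithmic correctness), all of them matter for a
real calibration transfer.

## Numerical choices

* Grid divisibility tolerance 1e-9 nm; wavelengths are doubles.
* Absorbance is base-10 (`AU` convention); non-positive intensities
  are an error naming the offending wavelength.
* NIPALS stops a component when the Y block or the weight norm is
  numerically exhausted (`< .Machine$double.eps`); a model on a
  response orthogonal to X degrades to the zero regression vector and
  predicts the response mean.
* Rank-deficient CV folds extract fewer components than requested;
  the prediction then uses all extracted components.
* The Q limit uses Jackson–Mudholkar with the h0 exponent floored at
  1e-3 to survive near-degenerate residual spectra.
* Posterior normalization is exact to 1e-12 by construction
  (log-space); model JSON round trips reproduce predicted values to
  ~1e-15 relative (full-precision serialization).
* All randomness (fold shuffles, generator draws, holdout splits)
  derives from explicit seeds, and seeded code paths save and restore
  the caller's RNG state.

## Known limitations

* The published headline performance (70.4% correct / 19.0% wrong /
  10.6% uncertain per module on real validation data, ~81% accuracy
  excluding uncertain) was measured on a proprietary dataset and is
  **not** reproducible here; on the synthetic default world the
  pipeline performs better because the world is cleaner.
* The uncertainty rule calibrates only the *decision*; the posteriors
  themselves inherit any misfit of the two-Gaussian assumption (real
  predicted-value distributions are skewed for the wide class 2).
* Forward iPLS is greedy; it can miss synergistic interval pairs and
  its selection is seed-dependent near ties.
* QC thresholds are world-anchored defaults, not instrument constants;
  deploying against a real instrument requires re-deriving both from
  that instrument's noise floor.
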