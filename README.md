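# nirclass

On-device chemometrics for a handheld near-infrared (NIR) cannabis
classifier, implemented as an R package.

## The problem

Law-enforcement officers frequently encounter cannabis products that
cannot be told apart by appearance or odor: legal CBD-rich flower and
illegal THC-rich flower. Sending every sample to a chromatography lab
is slow and expensive, and potency estimation by portable NIR
spectroscopy (RMSEP of ~2 wt% THC) is far too imprecise to call a
0.4 wt% legal threshold. A classification approach works where
regression does not: a handheld sensor measures diffuse-reflectance
NIR spectra (1550–1950 nm, 5 nm steps, 81 points) through the sample's
transparent PE/PP bag at two spots simultaneously, classifies each
spectrum on the device, and shows a green / yellow / red verdict.

`nirclass` implements that device's entire evaluation chain for anyone
who wants to study, stress-test, or adapt the approach: forensic
chemometricians, instrument developers, and teaching.

## The method

For each sensor module, a measurement is a triplet of consecutive raw
intensity scans $I(\lambda)$:

1. **Quality control.** Movement check: the mean over $\lambda$ of the
   across-scan standard deviation must stay below a threshold;
   intensity check: mean intensity above a floor. Fail ⇒ re-measure.
2. **Absorbance.** $A(\lambda) = -\log_{10}(I/I_0)$ against a stored
   white reference $I_0$, after averaging the triplet.
3. **Preprocessing.** Savitzky–Golay first derivative (window 5,
   2nd-order polynomial) followed by Standard Normal Variate (SNV):
   removes additive baselines and multiplicative scatter.
4. **Wavelength selection.** Forward interval-PLS (iPLS) over
   17 contiguous 5-variable (25 nm) intervals, scored by 90/10
   cross-validated misclassification — this is what excludes the
   packaging-dominated 1680–1735 nm region and the water band above
   1830 nm.
5. **PLS-DA.** Mean-centered NIPALS PLS on the class code (+1 for
   class 1, THC ≤ 0.4 wt%; −1 for class 2), component count chosen by
   90/10 CV, after a single-pass removal of calibration outliers whose
   Q residual or Hotelling $T^2$ exceeds the 95% limits.
6. **Bayes calibration.** One normal distribution
   $\mathcal N(\mu_c, \sigma_c)$ per class is fitted to the training
   predicted values; posteriors
   $p_c = \pi_c \phi_c(y) / \sum_k \pi_k \phi_k(y)$ turn a predicted
   value into class probabilities. Verdicts need $p \ge 0.60$;
   anything less is *uncertain* (yellow).
7. **Fusion.** The two module verdicts combine with precedence
   red > yellow > green.

Because the original 305-sample spectral dataset is not public, the
package ships a synthetic generator (`simulate_dataset()`) that
emulates the data's statistical structure — Beer–Lambert Gaussian
bands for THC/CBD/matrix/water, PE/PP interference at 1680–1735 nm,
multiplicative scatter, per-module gains, triplet scans, and per-spot
THC heterogeneity — with known ground truth.

## Worked example

```r
library(nirclass)

train <- simulate_dataset(n_samples = 200, seed = 42)
model <- fit_plsda(train, plsda_config(seed = 42))
#> LVs: 3 | outliers removed: 27 | wavelengths kept: 15 of 81
#>   selected interval 5: 1650-1670 nm
#>   selected interval 13: 1850-1870 nm
#>   selected interval 7: 1700-1720 nm

test <- simulate_dataset(n_samples = 100, seed = 43)
classify(model, test$X[1, ])
#> first test spectrum (true THC 0.09 wt%):
#> y_pred = 0.646, p_class1 = 0.922, p_class2 = 0.078 -> "unsuspicious"

verdicts <- vapply(seq_len(nrow(test$X)),
                   function(i) classify(model, test$X[i, ])$verdict,
                   character(1))
summarize_outcomes(verdicts, encode_labels(test$meta$thc_wt_pct))
#> n = 200 spectra
#>   correct 87.0% | wrong 0.5% | uncertain 12.5%
#>   excluding uncertain (87.5% of spectra): correct 99.4% | wrong 0.6%
```

The predicted value `y_pred` is the score of the class-1 regression
vector: positive values lean legal, negative lean illegal. The
posteriors come from the two fitted class Gaussians; the verdict is
the winning class when its posterior reaches 0.60, otherwise
`"uncertain"`. `summarize_outcomes()` reports percentages over all
spectra and, separately, over the confidently classified subset.

A command-line front end wrapping the same functions lives at
`inst/cli/nirclass.R`:

```sh
Rscript inst/cli/nirclass.R simulate --config cfg.yaml --out train.csv
Rscript inst/cli/nirclass.R train    --train train.csv --model model.json
Rscript inst/cli/nirclass.R classify --model model.json --input field.csv --out verdicts.csv
Rscript inst/cli/nirclass.R evaluate --model model.json --input labeled.csv
```

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch at a
given seed — simulate a 200-sample calibration set and a 100-sample
validation set, calibrate the classifier, classify and fuse the
validation spectra, and print the outcome summary — then writes its
report JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope

Everything numerical the device computes is here. Hardware control,
Bluetooth/app protocol, and chromatographic reference methods are out
of scope; reference THC values are treated as given inputs. See
`vignettes/nirclass-methods.Rmd` for the model assumptions, the
generator's stated world, and known limitations.
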