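---
title: "Authenticating two-component coffee blends from NIR spectra"
author: "aquaNIR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Authenticating two-component coffee blends from NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaNIR)
```

## The problem

Robusta coffee is substantially cheaper than Arabica and is the usual
adulterant of "100% Arabica" products. Near-infrared (NIR) absorbance
spectroscopy in the 740–1700 nm range offers a rapid, non-destructive
route to authentication: overtone and combination bands of C–H, O–H and
N–H vibrations differ subtly but systematically between the varieties,
both in ground coffee and in the brewed liquid. The aquaphotomics view
goes one step further for aqueous extracts: the water matrix of the brew
acts as a mirror of the dissolved composition, so standardized
absorbances at a fixed catalog of water matrix coordinates (WAMACs)
form a water absorption spectral pattern (WASP) that tracks the
blending ratio.

`aquaNIR` implements this analysis chain as a tested, reusable package:
a synthetic spectra generator (real varietal datasets of this kind are
rarely public), the standard NIR preprocessing toolbox, PCA, a hybrid
PCA-LDA classifier with grouped cross-validation, NIPALS PLS regression
of the adulterant mass fraction, and classical aquagram computation.

## Data model

A `SpectraSet` (an S4 class extending `SummarizedExperiment`) holds an
N × P absorbance block on an evenly spaced wavelength grid plus
per-spectrum metadata: `variety`, `robusta_fraction` (% w/w), `form`
(ground/liquid), and the acquisition hierarchy `replicate` × `refill` ×
`scan`. Grid uniformity, fraction bounds and metadata completeness are
enforced by the class validity method, so every downstream module can
assume them. The default grid is 740–1700 nm in 2 nm steps (481
points); 2 nm is a package assumption — the characteristic wavelengths
of this literature are all even — not an instrument fact.

## The synthetic mixture generator

The generator defines the study conditions; everything quantitative in
the test suite is measured on its output.

Endmembers are Gaussian-peak spectra: both varieties share the broad
water/organic bands of a coffee extract (970, 1190, 1450 nm), while the
Robusta-like endmember adds absorbance at 908 and 954 nm (weakly
bound/free water and solvation shells) and at 1342, 1374, 1440 nm, and
the Arabica-like endmember at 1018–1060 nm (strongly hydrogen-bonded
water) and 1412, 1462, 1488 nm. Peak heights put the largest
between-class contrast near 0.1 AU, a realistic varietal contrast.

Blends follow Beer–Lambert linear mixing,
$A_f = (1 - f/100)\,A_{\mathrm{ara}} + (f/100)\,A_{\mathrm{rob}}$,
over the design levels 0.5, 1, 2, 3, 5, 10, 20, 35 % w/w plus pure
controls and two "marketed blend" test samples (B10, B30). The liquid
hierarchy is 3 replicates × 3 refills × 3 consecutive scans (12 sample
types × 27 = 324 spectra); ground coffee omits the refill step (108
spectra).

Each emitted scan is
$g\,A_f + o + t\,(\lambda - \lambda_{\mathrm{mid}}) + \varepsilon$:
gain $g$, offset $o$ and tilt $t$ are drawn once per refill —
consecutive scans of one refill share the physical presentation, which
is exactly what makes grouped cross-validation necessary — and
$\varepsilon$ is i.i.d. per point. Two calibrated presets are provided.
`"low"` (gain s.d. 0.002, offset 0.001 AU, tilt 2e-6 AU/nm, noise
5e-4 AU) keeps the point noise below 1% of the endmember contrast,
emulating a well-behaved powder measurement; `"realistic"` (0.01,
0.005 AU, 5e-6 AU/nm, 2e-3 AU) emulates liquid transflectance spectra
where scatter correction genuinely matters. No instrument noise
magnitudes are published for this application, so the presets were
chosen once, on the criterion that the qualitative behaviour of the
pipeline (pure classes separable; low fractions overlapping; ground
quantification cleaner than liquid) is reproduced; they are not fitted
to any instrument.

What the generator does *not* emulate: nonlinear detector response,
wavelength-dependent scatter, instrument line shape, temperature
perturbation of the water bands, or chemical variation within a
variety. Passing tests therefore demonstrate correctness of the
algorithms under the stated statistical structure, not performance on
any real spectrometer's data.

## Preprocessing

All steps compose through `applyChain()` and a compact chain syntax,
e.g. `"truncate:1300,1600|savgol:19,2,1|snv"`.

* **Truncation** to 800–1670 nm (noise reduction) or to the first
  (1300–1600 nm) / second (800–1100 nm) OH overtone.
* **Savitzky-Golay** smoothing/derivatives, degree-2 local polynomial,
  windows 11/17/19. Edge columns are dropped rather than extrapolated,
  so every retained point is a true centered fit; derivatives are per
  nm (divided by step^deriv), keeping regression vectors comparable
  across grids.
* **MSC** regresses each spectrum on a reference (default: mean of the
  block it is *fit* on) and inverts the affine fit. The fitted
  reference is a model artifact: cross-validation refits it on
  calibration rows only and reapplies it to validation rows, which is
  the leakage-safe convention.
* **SNV** standardizes each row to mean 0 and sample s.d. 1 (n−1
  denominator throughout the package, matching the aquagram's
  standardization).
* **Detrend** subtracts a per-row polynomial in wavelength (default
  degree 2, the classical NIR detrend).
* **Averaging** collapses scans, refills or replicates within sample
  type.

Averaging does not commute with row-wise transforms on noisy data (a
regression test documents this), so chain order is meaningful and is
recorded in the result's provenance metadata.

## PCA and PCA-LDA classification

PCA is mean-centering plus SVD; no column scaling (spectra share
units). Loading signs are fixed (largest-magnitude element positive) so
fitted models are platform-reproducible.

The classifier performs LDA with equal priors on the first NrPCs
scores; a spectrum goes to the class whose centroid is nearest in
Mahalanobis distance under the pooled within-class covariance. A small
ridge (1e-8 × trace/NrPCs, floored at 1e-12 so noiseless data remain
usable) stabilizes the inversion. NrPCs is chosen by grouped
cross-validation: among candidates whose validation accuracy is within
1 percentage point of the best, pick the smallest training–validation
gap, ties to fewer components. The 1-point tolerance is the package's
operationalization of a "best validation accuracy with minimal
train/val difference" rule and is exposed as a parameter.

Cross-validation is always group-aware — the scans and refills of one
replicate travel together — and stratified by sample type (replicates
shuffled deterministically under the scheme seed, dealt round-robin
over folds). *Recognition* accuracy is the mean calibration-set
accuracy over folds; *prediction* accuracy is the pooled validation-set
accuracy; confusion matrices pool validation assignments and are
row-normalized to percentages.

## PLS regression

NIPALS with a univariate response and mean-centering only. The
regression vector and intercept reproduce the latent-variable
prediction path to 1e-10 (both paths are implemented and
cross-checked). Cross-validation pools out-of-fold predictions into a
single PRESS: $R^2_{CV} = 1 - \mathrm{PRESS}/\mathrm{TSS}$ (TSS about
the global mean) and $\mathrm{RMSECV} = \sqrt{\mathrm{PRESS}/N}$, with
the component count selected at the global RMSECV minimum (ties to
fewer components; the source study does not report its count). The
canonical scheme for scan-replicated designs is leave-one-scan-triplet-
out: one fold per (sample type × replicate × refill).

Design notes: pooled rather than fold-averaged CV metrics (one PRESS
yields both numbers consistently); no y scaling; NIPALS chosen over
SIMPLS for transparency of the orthogonality invariants the tests
assert. Leave-group-out predictions carry a small shrinkage toward the
calibration mean (each calibration set slightly under-represents the
held-out level); on the low-noise ground design this bias is below
0.05 % w/w per level.

## Aquagrams

The classical aquagram: after a default pre-chain (truncate to the
overtone range, Savitzky-Golay window 19 order 2, MSC against the
mean), every wavelength is z-scored across *all rows passed in*, and
each group's mean z at each WAMAC is reported. WAMACs are the fixed
catalogs 890–1060 nm (11 coordinates, second overtone) and
1342–1512 nm (12, first overtone); lookup takes the nearest grid point
(lower on ties), and a WAMAC eaten by the filter edge-drop raises a
coverage error naming the wavelength. The literature also speaks of 12
characteristic *ranges* in the second overtone while listing 11
wavelengths; the catalog of 11 is used. Standardizing against the
displayed sample population (rather than pure-water reference spectra)
is the recorded choice; a reference-subtraction variant would be an
extension, not a change to this contract.

Because the z-scores are affine-invariant, adding a constant to all
spectra or scaling all by a positive factor leaves the pattern
unchanged (tested), and the count-weighted mean of group values is zero
at every WAMAC (a class invariant).

## The experiment suite

`runExperimentSuite(outDir, seed, ...)` chains the four experiments on
one generated dataset — pure-variety discrimination, mixture
classification with a Table-style confusion matrix, PLSR under both CV
schemes with the marketed blends first held out and then included, and
the two aquagram groupings — writing a metrics JSON and CSVs that are a
deterministic function of the seed.

## Numerical choices and problem sizes

Degenerate inputs fail loudly with named errors: uneven grids,
constant rows under SNV, near-zero MSC slopes (|b| < 1e-8), constant
responses or folds, classes absent from a training fold. Orthogonality
and idempotence invariants are asserted at 1e-8–1e-12.

The test suite measures its statistical properties on deliberately
compact designs — e.g. 5-level ground sets (63 spectra) over 20 seeds
for the unbiasedness trend, 50 label shuffles for the permutation null,
5 seeds for aquagram monotonicity — sizes chosen so each property is
measured with comfortable Monte-Carlo margin while the whole suite
stays quick to run.

## Limitations

Linear mixing is an idealization; real roast-dependent matrix effects
are nonlinear. The classifier is strictly linear (no QDA/SVM), the
regression univariate (no PLS2), and no automatic preprocessing search
is attempted — chains are configuration, mirroring how such pipelines
are reported. Accuracies obtained on the synthetic conditions
transfer to real instruments only to the extent that the noise model
does.
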