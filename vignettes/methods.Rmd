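---
title: "Methods: fluorescence state-transition, PAM and chloroplast-shape analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fluorescence state-transition, PAM and chloroplast-shape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluoroplast)
```

## Scope

`fluoroplast` implements the three quantitative assays used to phenotype
photosynthetic light acclimation and chloroplast morphology in green
macroalgae and kleptoplastic sea slugs, plus the statistical decision tree
that compares treatment groups, plus a synthetic-data generator that gives
every assay a recovery-testable input with analytic ground truth. This
vignette documents the models, the tunable parameters, and the numerical
and design choices behind them.

## 77 K emission spectra and the state-transition readout

At liquid-nitrogen temperature the two photosystems emit at separable
wavelengths: PSII at ~680–695 nm, PSI at ~710–730 nm. State transitions —
the migration of mobile LHCII antenna between the photosystems — therefore
show up as a change in the PSI/PSII emission ratio after light treatments
that preferentially excite one photosystem.

The processing chain is fixed, in this order:

1. **Resampling** to a uniform grid (linear interpolation, never
   extrapolating). Spectrometer exports are rarely uniform; smoothing
   assumes a uniform step.
2. **Smoothing** with a 4 nm centered running average. The window is
   inclusive at its edges (a point exactly 2 nm from the center is
   averaged in) and truncated at the spectrum ends; edge handling is a
   convention we had to fix, since a moving mean is underdetermined there.
3. **Baseline subtraction** at 800 nm. Chlorophyll emission has decayed to
   the instrument baseline by 800 nm; we subtract the *mean over
   798–802 nm* rather than the single 800 nm sample for robustness to
   single-pixel noise (the window truncates gracefully if the grid stops
   at 800). Negative values after subtraction are kept and flagged —
   clamping would bias the PSI statistic near zero.
4. **Normalization** to the PSII peak: the whole spectrum is divided by the
   maximum on 680–690 nm. Ties break toward the shorter wavelength, for
   determinism. Normalizing is idempotent and the resulting statistic is
   invariant to any positive rescaling of the raw counts.

The **normalized PSI fluorescence statistic** is the maximum of the
normalized spectrum on 710–730 nm. We use the window maximum rather than
the value at a fixed wavelength because emission maxima shift between
species, and some samples (notably *Bryopsis*-type spectra) lack a distinct
PSI peak altogether; in that case the window maximum is still well defined
and a `no_local_peak` flag is raised. A fixed-wavelength mode
(`psi_statistic(..., at_nm = )`) is exposed for sensitivity analyses.

The order of operations (smooth → baseline → normalize) is enforced
through a provenance record on the spectrum object: normalizing before
baseline subtraction, or subtracting a baseline from an already-normalized
spectrum, is an error rather than a silently different analysis.

### Self-absorption QC by dilution series

Concentrated powder samples re-absorb their own fluorescence, preferentially
in the region where chlorophyll absorbs (~680 nm), which inflates the
apparent PSI/PSII ratio. Samples are therefore measured at several
dilutions in optically neutral quartz powder. `qc_select_dilution()` walks
from the most concentrated to the most dilute member and selects the most
concentrated dilution whose PSI statistic agrees with the next more dilute
one within a relative tolerance (default 0.05 — the published criterion is
a visual "same shape", so the tolerance is explicit and configurable
here). If no adjacent pair agrees, the most dilute member still above a
PSII-signal noise floor is selected and a `self_absorption` flag raised;
a single-member series is selected with an `unverified` flag.

## PAM saturating-pulse parameters

From the dark reference (minimal `F0`, maximal `Fm`) and each
saturating-pulse record (steady-state `F`, pulse maximum `Fm'`):

* `Fv/Fm = (Fm − F0)/Fm` — maximum PSII quantum yield;
* `ΦPSII = (Fm' − F)/Fm'` — effective PSII yield;
* `NPQ = Fm/Fm' − 1` — non-photochemical quenching;
* `F0' = F0 / (Fv/Fm + F0/Fm')` — the standard estimate of the
  light-acclimated minimal fluorescence, written out explicitly here;
* `qL = ((Fm' − F)/(Fm' − F0')) · (F0'/F)` — fraction of open PSII
  centers (oxidized Q_A_): 1 at `F = F0'`, 0 at `F = Fm'`, both identities
  holding machine-exactly by construction;
* `rETR = 0.42 · ΦPSII · PPFD` — relative electron transport rate. The
  0.42 is the conventional plant-based estimate of the fraction of incident
  photons absorbed by PSII and is a named, configurable constant
  (`absorption_factor`), not a buried literal.

Negative NPQ and qL outside [0, 1] are reported raw with flags, never
silently clipped: they carry QC information (imperfect dark reference,
noisy level estimates).

Pulse extraction from a trace uses a 2 s pre-pulse mean for `F` and a 1 s
peak-window maximum for `Fm'` by default; instrument export granularity
varies, so both windows are parameters. A trace without a pulse in a dark
segment has no dark reference and is rejected — parameters that reference
`Fm` are undefined without one, so rapid-light-curve protocols measured
without dark acclimation must supply an explicit `(F0, Fm)` pair upstream.

**Rapid light curves**: replicates measured on a shared ladder of actinic
steps are combined by `build_light_curve()`. The group curve is truncated
before the first step at which any replicate's rETR is not positive
(per-replicate curves are kept in full) — the same convention used when
such curves are reported with a common positivity cutoff across replicates.

## Chloroplast shape analysis

The shape readout is the circularity `4π·Area/Perimeter²` (1 for a circle,
→ 0 for elongated objects), aggregated per biological replicate as the
median over all segmented objects; replicates, not objects, are the unit
of statistical analysis.

**Segmentation** is a classical pipeline: percentile intensity
normalization (recorded in provenance, replacing ad hoc
brightness/contrast adjustment), Gaussian smoothing, Otsu or fixed
thresholding, optional splitting of touching blobs by watershed on the
distance transform, minimum-area filtering, and border-object flagging.
A neural segmenter is deliberately out of scope — the scientific content
is the shape metric, not the detector — and externally produced label
masks can be re-measured directly (`measure_objects()` accepts any label
matrix), so published segmentations remain usable.

**Measurement.** Area is the pixel count times the pixel area. The
perimeter is the length of the 0.5 iso-contour of the object mask,
extracted marching-squares style (`grDevices::contourLines`) after a
σ = 1 px Gaussian pre-smoothing of the mask and followed by a 3-point
moving average of the contour vertices. The pre-smoothing matters: on a
*binary* mask the contour crossings sit at pixel midpoints and the
staircase inflates the perimeter of a true circle by ~6% (circularity
≈ 0.89; naive pixel-edge counting is worse, ≈ 0.79). With the sub-pixel
crossings the measured circularity of rasterized disks, squares and
ellipses is within ~0.02 of the analytic value at radii ≥ 10 px. Like any
fixed-scale estimator it has a sub-pixel error floor (~0.005 on disks), so
accuracy improves from the coarsest scale and then plateaus well inside
the ±0.03 band used by the recovery tests; measured circularity can
slightly exceed 1, and values above 1.02 are flagged. Because the
perimeter estimator differs in detail from any particular imaging
toolbox's, absolute circularities are comparable within this pipeline,
not guaranteed identical across software.

Border-touching objects are excluded from replicate summaries by default
(their perimeters are truncated by the field of view). In-focus region
selection is a user-supplied crop, not automated focus detection.

## Group statistics

`gated_compare()` implements the decision tree: Shapiro–Wilk normality per
group and Levene's test (classic mean-centered form, since the test is
named as Levene's) for variance homogeneity, all at α = 0.05. If every
assumption test passes: two-tailed Student's *t* for two groups (equal
variances — the gate has just vouched for them; Welch is an option) or
one-way ANOVA with Tukey's HSD post hoc for three or more. Otherwise:
Kruskal–Wallis with Dunn's post hoc (tie-corrected z tests on mean ranks).
The multiplicity adjustment for Dunn's p-values defaults to Holm —
conservative and standard — and is configurable; post-hoc tables are only
produced when the omnibus test is significant and more than two groups are
present. The gate is applied per comparison family, not globally. Groups
too small for Shapiro–Wilk (n < 3) or with zero variance are routed to the
non-parametric branch with a note.

`power_check()` gives a quick seeded estimate of the pipeline's power for
a given effect size, spread and replication.

## The synthetic-data generator

The generator exists so that every stage has an input with known truth;
its defaults encode the study conditions the pipeline is meant for.

**Spectra** are sums of Gaussian bands — PSII at 685 and 695 nm (σ 6 and
5 nm), PSI at 715 nm (σ 10 nm), default amplitudes 1000/600/550 counts
with a 50-count offset — on a 650–810 nm grid at 0.5 nm. State 2
multiplies the PSI amplitude by 2. Self-absorption is modelled as
attenuation of the emitted signal by `exp(-c·A(λ))`, with `A` a synthetic
chlorophyll-like absorption profile (main band at 678 nm; shipped as a
packaged table) and `c` proportional to sample concentration in dilution
series. The real phenomenon is radiative transfer in a scattering powder;
this single-pass attenuation reproduces its qualitative signature — the
680–690 nm region is suppressed far more than 710–730 nm, inflating the
apparent PSI statistic at high concentration — which is what the QC logic
needs, and no more. Ground truth records the pre-distortion band-sum
ratio.

**PAM traces** are built by inverting the analysis formulas: requested
NPQ(t) and qL(t) courses are converted to per-pulse `Fm'`, `F0'` and `F`
(the qL definition solved for `F` has the closed form
`F = Fm'·F0' / (qL·(Fm' − F0') + F0')`, the unique root in `(F0', Fm']`).
The steady-state level is held constant across each inter-pulse interval
at the next pulse's value, so noise-free extraction recovers every
ground-truth parameter to machine precision; no kinetic model of electron
transport is implied or intended. The first schedule segment must be dark
and pins `F0`/`Fm`. Noise is additive Gaussian, applied after
construction.

**Chloroplast scenes** place ellipses (lognormal equivalent radius,
configurable axis-ratio distribution, uniform orientation) by rejection
sampling under a minimum-separation constraint, rasterize them
(pixel-center-inside), blur, and add Gaussian or Poisson noise; the clean
label mask and per-object analytic truth (area `πab`, Ramanujan-II
perimeter, circularity) ride along. Default geometry — ~3 µm mean radius
at 0.2 µm/px (15 px), 512² fields — keeps objects comfortably above the
10 px radius where the perimeter estimator is accurate.

What the generator does *not* emulate: instrument spectral response and
wavelength calibration error, correlated (1/f) noise, fluorescence
kinetics within a pulse, out-of-focus light, clustered or touching
organelles in dense tissue, and real radiative transfer. Passing the
recovery tests therefore demonstrates correctness of the estimators under
clean, known-truth conditions — not robustness to every artifact of real
instruments; the QC flags and configurable windows are the handles for
real data.

## Problem sizes and determinism

Every stochastic default is seeded explicitly; identical configuration and
seed reproduce spectra, traces and scenes bit-identically. The recovery
tests use 5 replicates per group for spectral state detection (5% noise),
200-object scenes at 1200² px for shape-median recovery, 6 replicates per
group of 30-object scenes for shape separation, and 1000-replicate null
simulations per statistical branch — sizes chosen to hold Monte-Carlo
error well below the tolerances being checked while keeping the whole
suite runnable on a laptop in well under a minute per component.

## Known limitations

* The PSI statistic is a window maximum; for spectra with no PSI peak it
  measures the shoulder of PSII emission, and only the `no_local_peak`
  flag distinguishes the two situations.
* The dilution-agreement tolerance (0.05 relative) operationalizes a
  criterion that is visual in practice; different instruments may warrant
  a different value.
* Absolute circularity depends on the perimeter estimator; comparisons
  across software should be made on data re-measured with one estimator.
* The equal-variance *t*-test after a passed Levene gate is a modelling
  convention; Welch's form is available where that convention is not
  wanted.
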