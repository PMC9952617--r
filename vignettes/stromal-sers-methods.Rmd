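---
title: "Stromal SERS fingerprints for DCIS vs invasive breast cancer: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stromal SERS fingerprints: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sersstroma)
```

## The problem

Distinguishing ductal carcinoma in situ (DCIS) from invasive breast cancer
(IBC) in needle biopsies normally rests on a pathologist's reading of
HE-stained tissue. Surface-enhanced Raman spectroscopy (SERS) imaging of
fresh-frozen sections adds a biochemical axis: redox metabolites in the
tumour stroma leave band-resolved fingerprints, most prominently an
elevated polysulfide band near 480 cm⁻¹ and a depleted hypotaurine band
near 974 cm⁻¹ in invasive stroma — the spectroscopic face of the
desmoplastic reaction. `sersstroma` implements the full analysis chain
from raw hyperspectral cubes to patient-level calls: wavenumber
calibration, baseline correction, band integration, annotation joining,
differential-wavenumber discovery, mesh-level supervised classification
and mesh-ratio patient aggregation. Because the patient biopsies behind
such studies are not publicly available, the package ships a seeded
synthetic tissue-phantom generator that reproduces the statistical
structure the analysis relies on, so every stage is testable end to end.

## The synthetic generator

`make_phantom()` lays out an annotated lesion on a pixel grid: connected
cancer-nest blobs embedded in stroma, adipose patches at the margins and
a small normal-gland patch (defaults: 30 % nest, 50 % stroma, 15 % fat,
5 % gland). `render_cube()` turns a phantom into a hyperspectral cube.
Each pixel's spectrum is

* a smooth baseline — a cubic polynomial plus one broad Gaussian hump
  (centre 1100 cm⁻¹, SD 300 cm⁻¹, apex ≈ 40 a.u. on a ≈ 100 a.u.
  background), with coefficients drawn per pixel around per-patient
  means (20 % patient-level, 5 % pixel-level relative SD);
* Lorentzian marker bands (half-width at half-maximum 4 cm⁻¹) whose mean
  apex amplitudes depend on the pixel's (diagnosis, region) context,
  multiplied by a per-pixel log-normal *hotspot* factor (CV 0.25,
  emulating electromagnetic hotspot heterogeneity of the gold
  nanoparticle substrate) and a per-patient log-normal amplitude factor
  (CV 0.15 per band);
* a per-patient per-channel offset (SD 6 a.u., iid across channels) that
  gives each patient individual spectral fine structure — the noise
  floor of all per-patient tests, deliberately independent of image
  size; and
* additive channel noise (SD 8 a.u.).

The default library carries the 27 marker wavenumbers used as classifier
features. In stroma, DCIS-dominant bands have mean apex 100 a.u. against
55 a.u. in the other class (and vice versa for IBC-dominant bands),
which at the default patient-level variability is a ≈ 3 pooled-SD
between-class effect per band. Four bands are anchored DCIS-dominant
(382, 974, 1140, 1250 cm⁻¹) and 480 cm⁻¹ is anchored IBC-dominant; the
remaining 22 were assigned so the library totals 19 D-dominant and 8
I-dominant bands, with signs alternated among close neighbours
(e.g. the 576–696 cm⁻¹ run) so overlapping Lorentzian tails cancel
rather than blur adjacent bands together. The 722 cm⁻¹
purine-nucleotide band is a built-in negative control, equal in both
diagnoses. Peak width is 4 cm⁻¹ HWHM: the closest marker bands sit
16 cm⁻¹ apart, and at the instrument's 2 cm⁻¹ channel spacing this
width keeps neighbouring bands resolvable while remaining within the
physical range of SERS linewidths.

The default cohort (`cohort_config()`) is 14 DCIS and 32 IBC patients —
the clinical cohort's class sizes — each a 32 × 16 raw grid line-binned
by 2 to a 16 × 16 mesh grid, on a 240–1800 cm⁻¹ axis at 2 cm⁻¹ (the
axis starts at 240 rather than 300 cm⁻¹ so that the 256 cm⁻¹ marker
band lies on-grid). A configurable `calibration_shift` (default
+1 cm⁻¹) mislabels every cube's axis, giving the calibration stage real
work. One master seed drives independent child streams per patient and
per operation, so identical configurations are bit-reproducible.

What the generator does **not** emulate: tile seams and scanning
stripes, cosmic-ray spikes, anti-aliased or uncertain annotations,
spatial correlation of the background beyond the per-patient structure,
and any absolute intensity scale (SERS intensities are arbitrary units
throughout; only relative structure is meaningful). Passing tests
therefore demonstrate the correctness and calibration of the analysis
machinery under the stated noise model, not performance on real tissue.

## Preprocessing

**Calibration.** The silicon phonon line at 520 cm⁻¹ is located by
parabolic interpolation over the three channels around the maximum;
the cube's axis is shifted so the apex sits at exactly 520 cm⁻¹.
A recovered shift is accurate to well under half a channel. Because
each patient's estimated shift differs slightly, the pipeline then
resamples (linear interpolation) onto the cohort's canonical axis so
spectra share channel centres across patients; calibration is
idempotent to < 0.1 cm⁻¹.

**Baseline correction.** The vendor's baseline routine is proprietary,
so the package uses iteratively reweighted asymmetric least squares: a
Whittaker smoother with a second-order difference penalty
(`lambda = 5000`) in which channels above the current fit by more than
the spectrum's noise threshold are down-weighted to `p = 0.01`. The
threshold is 2.5 × a robust noise scale estimated once per spectrum
from second differences; when a genuine noise scale exists the peak
mask is dilated by 6 channels to cover band flanks. This construction
keeps the fit unbiased in two regimes that defeat the classical
fixed-asymmetry scheme: on noisy spectra the fit runs through the
middle of the noise band instead of its lower envelope, and on smooth
noiseless input it reproduces the baseline nearly exactly. The contract
is defined by truth recovery on synthetic cubes — pure baselines within
1 % of their range (noiseless), peak apexes within 5 % (noiseless) and
a median apex error below 10 % at the default noise — and those
tolerances are what the test suite enforces.

**Binning and band images.** Line binning averages `factor` × 1 pixel
groups along the scan axis (mean convention, so intensities stay
comparable across binning factors; the pixel pitch scales
accordingly). `band_image()` *sums* intensities over the closed window
`centre ± halfwidth` on channel centres — ±5 cm⁻¹ for imaging,
±10 cm⁻¹ for statistics and classifier features. Band integration is
linear and commutes with binning under the mean convention.

## Differential-wavenumber discovery

Tagged stromal spectra are averaged per patient; each channel is then
compared between 14 DCIS and 32 IBC patients with Welch's *t*-test
(unequal group sizes make the unequal-variance form the right default
even where a plain *t*-test would be conventional). A channel is
significant at `alpha = 0.05`; dominance is D where the DCIS mean is
higher, I where the IBC mean is higher.

Band-level peaks are collapsed from channel-level calls: significant
channels are clustered (gaps ≤ 10 cm⁻¹ merge), clusters shorter than 3
channels are discarded as isolated false positives, and within each
cluster the local maxima of a lightly smoothed |t| profile (9 cm⁻¹
running mean), thinned to a minimum separation of 10 cm⁻¹, are
reported. A reported apex must additionally be significant at
`peak_alpha = 2e-5` (|t| ≈ 5): run-level detection stays at `alpha`,
but band reporting demands strong evidence. On the shipped cohorts
genuine marker apexes carry |t| ≥ 6 while residual baseline artefacts
stay below |t| ≈ 4.5, so the two thresholds separate cleanly.

Discovery is two-pass (`discover_differential_bands()`). A first pass
corrects baselines and flags candidate channels; those channels,
dilated by 5, define one pooled peak mask shared by *every* patient,
and baselines are refit as a fixed-mask weighted Whittaker smooth. The
point is subtle but important: any baseline estimator that reacts to
peak amplitudes acquires a class-dependent bias wherever the two
classes carry different peak mass, which shows up as spurious weak
"differential" side lobes. With a fixed, class-independent mask the
correction is one linear operator applied to all patients, so it
cannot manufacture between-class differences; off-peak channels are
high-pass filtered toward zero and on-peak windows keep their true
contrasts. No multiple-testing correction is applied by default
(per-wavenumber significance is reported raw, matching practice);
a Benjamini–Hochberg option exists (`p_adjust = "BH"`).

## Mesh classification

Stromal pixels of the binned grid form the ROI mesh — one cell per
46.6 µm pixel — and each cell's 27 band intensities (±10 cm⁻¹ sums)
are the feature vector. Patients are randomly stratified into 4
class-balanced sets (with 46 patients that is 11–12 per set, not a
flat 10; the remainder policy is to spread all patients as evenly as
possible), one set held out for evaluation. Six families are trained —
L1-regularized logistic regression, RBF support vector machine, random
forest, gradient-boosted trees, k-nearest-neighbour and naive Bayes —
each by 3-fold cross-validation with a small default grid, selecting
the hyperparameters that *maximize* mean CV Cohen's kappa (selection by
chance-corrected agreement, robust to the ≈ 70/30 mesh imbalance).
Folds are patient-disjoint: mesh-level folding would leak patients, so
the conservative choice is built in and train/evaluation patient
overlap is a hard error, not a convention. Class-weighted training is
available but off by default. The CV report carries both the CV
metrics and, separately, the held-out evaluation metrics, since the
two answer different questions.

Permutation importance is the mean drop in kappa when one feature
column is shuffled (10 repeats), clipped at zero and normalized to unit
sum. Patient-level calls count each patient's meshes predicted IBC and
DCIS; the patient is called IBC if and only if the IBC mesh ratio
exceeds 0.5 (reported to 3 decimals).

## Numerical choices and degenerate inputs

* Welch test with zero variance in both groups: `p = 1` when means are
  equal (no evidence), `p = 0` otherwise; `n < 2` per group is an error.
* Cohen's kappa with degenerate marginals (`p_e = 1`) is defined as 0
  with a warning.
* Ties in patient aggregation (ratio exactly 0.5) resolve to DCIS — the
  call requires a majority for invasion.
* Baseline fitting caps at 50 reweighting iterations with a relative
  tolerance of 1e-6 and declares convergence once the peak mask is
  stable to within 0.5 % of channels; non-convergence warns and returns
  the best fit.
* The banded LDL' solver behind the Whittaker smoother is exact (it
  matches a dense solve to ~1e-10) and O(channels) per iteration.
* Grid coordinates are 0-based, column `x` / row `y`, pixel centres;
  masks share the binned grid by construction.

## Problem sizes

The shipped study conditions are deliberately desk-scale: 16 × 16 mesh
grids (≈ 127 stromal meshes per patient, ≈ 6100 meshes per cohort), 46
patients, 781 channels, 20 master seeds for the recovery study. These
sizes give the differential-recovery and classification checks their
stated power while keeping a full test run in minutes.

## Known limitations

Hard labels mean no partial-volume meshes, so mesh-level separability
is optimistic relative to real stroma; the generator's per-channel
patient offset is white, whereas real biological variability has
spectral structure; the baseline model is smooth by construction, so
the correction contracts say nothing about sharp substrate artefacts;
and the discovery procedure's apex-evidence threshold trades a small
risk of dropping a marginal band for specificity against
baseline-artefact side lobes — at very small effect sizes it will
undercount rather than overcount.
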