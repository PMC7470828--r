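---
title: "Quantifying TRP-channel function and expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying TRP-channel function and expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calciscope)
```

## The measurement problem

Sensory neurons of the dorsal root ganglion (DRG) detect noxious stimuli
through heat-activated TRP channels — TRPM3, TRPA1 and TRPV1. Two
complementary readouts quantify how inflammation changes these channels in
the neurons that innervate a treated paw:

* **Function**: GCaMP calcium imaging of intact DRGs and of nerve endings
  in skin flaps, under sequential application of channel-specific agonists
  (pregnenolone sulfate + CIM0216 for TRPM3; mustard oil for TRPA1;
  capsaicin for TRPV1) and a depolarising high-K⁺ solution, acquired as
  11-plane confocal z-stacks at 0.25 Hz.
* **Expression**: single-molecule fluorescent in situ hybridisation
  (RNAscope), where each fluorescent dot reports transcript signal and
  cells with ≥ 5 dots count as positive.

In both assays, neurons innervating the paw are identified by a
retrogradely transported label (WGA-AF647). `calciscope` implements the
complete quantification chain for both readouts, together with a
synthetic-data module that generates movies and slides with known ground
truth, so that every stage is testable as a parameter-recovery problem.

## Calcium-imaging preprocessing

A raw recording is a `T × Z × Y × X` stack. The pipeline
(`preprocess_movie()`) applies, in order:

1. **Z-averaging** over the 11 planes.
2. **Reference image**: the mean of the first 10 pre-stimulus frames; the
   count is configurable (`ref_frames`) but must not reach into the first
   stimulus window.
3. **Drift correction**: per-frame integer translation estimated by FFT
   cross-correlation against the reference. Integer shifts are the tested
   contract; subpixel motion is out of scope. Constant (information-free)
   frames get zero shift with a warning.
4. **Non-responsive mask**: the per-pixel temporal coefficient of
   variation (population SD over mean) is thresholded by Otsu's method on
   256 equal-width bins of the CV range, ties broken toward the lower
   threshold. Pixels below threshold are "non-responsive". CV is
   scale-free, so the mask is invariant under multiplicative intensity
   rescaling. Pixels whose temporal mean falls below ε = 10⁻⁶ × the image
   maximum (a scale-free guard) get CV 0 and are flagged.
5. **Background surface**: a bivariate polynomial of total degree ≤ 4
   (15 monomials `x^i y^j`, `i + j ≤ 4`) is fitted by least squares to the
   non-responsive pixels of the *time-averaged* image and subtracted from
   every frame. Fitting once to the temporal mean is a deliberate choice:
   the mask is defined by temporal statistics, so the model is temporal by
   construction, and a per-frame fit would absorb stimulus-locked signal.
   "Fourth order" is read as total degree ≤ 4, not degree 4 per axis;
   `degree` is configurable. Coordinates are affinely scaled to [−1, 1]
   before fitting — this changes nothing about the model span but keeps
   the normal equations well conditioned, which is what makes exact
   recovery of degree-4 truths (to ~10⁻¹² relative) possible.
6. **Normalisation**: F/F₀ or ΔF/F₀ = (F − F₀)/F₀ against the per-pixel
   reference baseline; pixels with F₀ ≤ ε are excluded and flagged.

## ROI extraction

**Somata (DRG mode).** Cells are either imported as a label mask —
mirroring visual identification in practice — or detected automatically as
bright disc-like blobs (difference-of-Gaussians band-pass, Otsu threshold,
watershed separation of touching cells, diameter filter). GCaMP-expressing
somata are visible at rest, which is what the generator's
`resting_contrast` parameter emulates.

**Nerve endings (skin mode).** Endings are not separable as cells; the
meaningful unit is a contiguous region of temporally correlated activity.
`detect_correlated_rois()` is a deterministic seed-and-grow segmenter:
seeds are temporally active pixels (SD above an Otsu threshold, or the
responsive complement of the preprocessing CV mask) whose mean Pearson
correlation with their *active* 8-neighbours exceeds `min_corr`
(default 0.8); regions grow by admitting frontier pixels whose correlation
with the region's mean trace is at least `min_corr`, strongest seed first,
and regions below `min_size_px` (default 10) are discarded. Restricting
the seed statistic to active neighbours is essential for thin branches
(1–3 px wide): their border pixels always abut uncorrelated background,
which would otherwise dilute the neighbour-mean correlation below any
usable threshold. The published analyses in this field often use CNMF-E
for this step; the full constrained matrix factorisation is deliberately
not re-implemented here — the segmenter keeps the same contract
(contiguous, temporally coherent, disjoint regions) while being
deterministic and parameter-sparse. Equivalence with any particular
CNMF-E parameterisation is not claimed.

**WGA classification.** An ROI is WGA⁺ iff its mean intensity in the WGA
channel strictly exceeds the background mean by more than five background
SDs. "Background" is all pixels outside every ROI after a 3-px dilation
(configurable); the strict inequality means boundary cells are negative.
The rule is not invariant to additive offsets (both the mean and the SD
enter), but is invariant to multiplicative rescaling of the channel.

## Responder classification

`call_response()` applies two criteria to each ROI trace and stimulus
window, both strict inequalities:

1. the peak of the baseline-subtracted ΔF/F₀ during stimulation exceeds
   5 × SD of the pre-stimulus window, and
2. the peak of the first derivative dF/dt during stimulation exceeds
   1 × SD of dF/dt over the pre-stimulus window.

The derivative is the first difference divided by the frame period, with
no smoothing — the minimal assumption; the criterion is what rejects slow
baseline ramps that could pass the peak test alone. The peak criterion is
applied to the baseline-subtracted trace (pre-window mean removed); a raw
F/F₀ mode is available (`baseline_subtract = FALSE`) since the convention
is genuinely ambiguous in the field. Both margins are reported for audit,
and a degenerate zero pre-stimulus SD is replaced by a small guard and
flagged. The per-stimulus baseline window is the stretch between the
previous window's end plus a recovery gap and the current onset, truncated
to the last 10 frames — reflecting designs with ~5 min wash-out between
stimuli.

Downstream accounting:

* **High-K⁺ exclusion** (DRG mode): ROIs failing the criterion on the K⁺
  window are flagged and removed from every downstream summary. Skin mode
  does not apply the exclusion or K⁺ normalisation, because nerve endings
  do not reliably respond to depolarisation even when agonist-responsive;
  skin readouts are area fractions instead.
* **K⁺ normalisation**: `peak_dff_norm = peak(stimulus) / peak(K⁺)` per
  non-excluded ROI.
* **Co-expression classes**: the subset of {M3, A1, V1} an ROI responds
  to — 8 classes including the empty set; class frequencies sum to 1 per
  group.
* **Responsive area** (skin): summed area of ROIs responding to each
  agonist (and to each exact class), divided by the imaged area.

## RNAscope quantification

Per slide: rolling-ball background subtraction (radius 1 µm), spot
detection at the 0.8 µm dot scale, a per-slide single-dot reference
intensity, cluster-to-dot correction, per-cell counting against supplied
cell masks (segmentation is manual in practice), and the ≥ 5-dot
positivity rule.

Numerical choices that deserve a note:

* The rolling-ball background is a grayscale opening with a disc
  structuring element, median-filtered afterwards. The median step matters:
  the shading being removed is smooth by assumption, while the raw opening
  acquires a local lift under compact bright blobs wider than a dot (i.e.
  clusters), which would bite into exactly the intensities the cluster
  correction depends on. A median window of ~4 ball radii rejects that
  lift and tracks a linear gradient without lag.
* Integrated intensity is the sum over an object's segmented component for
  singles and clusters alike, so the cluster/single ratio is
  self-consistent; measuring singles in a fixed disc and clusters over
  components would bias the ratio.
* The equivalent diameter is twice the intensity-weighted RMS radius,
  corrected analytically for the tail truncation introduced by the
  segmentation threshold. For an isolated Gaussian dot this estimator
  returns the nominal diameter regardless of brightness. A spot is a
  cluster when this diameter exceeds 1.5 × the dot diameter
  (`cluster_factor`, configurable — no community standard defines "single
  dot", so the factor is this package's choice and its sensitivity is
  exercised in the tests), or when its component carries ≥ 2 scale-matched
  intensity maxima (dots that overlap yet remain individually resolved —
  counting such a merged pair as one object would otherwise lose a dot).
* A cluster's equivalent count is its intensity divided by the slide's
  mean single-dot intensity, rounded to the nearest integer, minimum 1.
  The reference requires ≥ 5 singles per slide and is never pooled across
  slides; with fewer singles, cells are reported uncorrected and flagged.
* Spots are assigned to the cell whose mask contains their centroid pixel;
  spots outside all masks are reported in a background bin.

## Statistics

The group-comparison layer mirrors how such studies report results:

* `bootstrap_ratio_ci()` — the ratio of group means as a percentage with a
  percentile bootstrap CI (default 10,000 resamples, 95%), resampling each
  group independently. Percentile (not BCa) is the minimal reading of
  "bootstrapped CI"; the seed is a required, logged parameter and results
  are bit-reproducible. Resampling is at the cell level; animal-level
  resampling can be had by passing per-animal summaries instead. The known
  limitation — cells nested in animals are treated as independent — is
  inherited from the cell-level reporting convention itself.
* `shapiro_gate()` — normality gating; the non-parametric route is taken
  iff any compared group fails Shapiro–Wilk at α = 0.05 (the per-group
  rule is unstated in common practice; "any group fails" is the
  conservative choice). Untestable groups (n < 3, constant) force the
  non-parametric route with a flag.
* `kruskal_dunn()` — Kruskal–Wallis omnibus plus Dunn's pairwise z tests
  with tie correction, Holm-adjusted. Dunn's test is computed from the
  standard rank-statistic formula (no installed package provides it) and
  is checked against a full-permutation oracle at small n in the tests.
* `anova_holm_sidak()` — one-way ANOVA on per-animal values with pairwise
  t comparisons (pooled residual variance) under the Holm–Šidák step-down
  adjustment `1 − (1 − p₍ᵢ₎)^(m−i+1)`, monotonicity enforced; the smallest
  of three raw p = 0.01 gives 0.029701 exactly.
* `wilcoxon_paired()` — exact signed-rank distribution for n ≤ 25 without
  ties; zero differences dropped; six all-positive distinct differences
  give the exact one-sided p = 1/64 = 0.015625.

## What the generator emulates — and what it does not

`gen_soma_movie()`, `gen_skin_movie()` and `gen_rnascope_image()` produce
data with complete ground truth: cell/branch geometry, per-stimulus
response amplitudes programmed in units of the baseline noise SD,
stimulus-locked transients (instant rise, exponential decay, τ = 8 frames
at 0.25 Hz — kinetics in this range are visible in published traces but
not parameterised there, so τ is configurable), translational drift, a
polynomial background field within the span of the fitting model,
additive Gaussian noise (optionally Poisson-like), WGA channels at 10 ×
background-SD contrast for labelled cells, and RNAscope dots with known
per-cell counts and intensity-additive clusters.

Defaults were chosen once as plausible acquisition values — baseline 100
grey levels, noise SD 2, resting cell contrast 20 (structural SNR 10),
response amplitudes 10 × noise SD — since no numeric baselines or
amplitudes are available to calibrate against; they are free parameters of
the generator, not measurements.

Passing the recovery tests therefore shows that the pipeline inverts its
own generative model at realistic noise levels. It does not show
robustness to what the generator omits: optical PSF and z-attenuation,
photobleaching, non-rigid tissue motion, desensitisation between stimuli,
autofluorescence texture, or segmentation error in the supplied RNAscope
cell masks. Those are stated non-goals.

## Problem sizes and test design

The test suite and the acceptance script run everything at desk scale,
chosen as the package's own reproducible study conditions: 64–256 px
fields, 70–100 frame movies, 1,000 simulated traces for the responder
operating characteristics, 20-seed segmentation sweeps, 100-cell RNAscope
slides (25 px cell radius at 0.2 µm/px), 500 replicate bootstrap
experiments at 10,000 resamples, and 50 replicate 12-animal cohorts of 32
cells per animal (a stand-in for the hundreds of neurons scored per
ganglion in practice). Every expected value asserted in the tests is
either an arithmetic identity, a closed-form expectation of the generator,
or computed by an independent oracle (brute-force recomputation, exhaustive
threshold search, full permutation or sign enumeration) frozen alongside
the test.

## Known limitations

* Integer-only registration; subpixel drift below 1 px is uncorrected.
* The correlation segmenter assigns each pixel to one ROI; overlapping
  sources are out of scope.
* Cluster correction assumes intensity additivity; quenching or
  saturation in dense clusters would bias counts downward.
* Cell-level bootstrap CIs understate between-animal variability; the
  per-animal tables are retained precisely so animal-level analyses can
  be run instead.
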