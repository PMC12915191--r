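---
title: "Quantifying cytosolic payload delivery by single-particle tracking"
author: "payloadSPT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cytosolic payload delivery by single-particle tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(payloadSPT)
```

## The problem

Targeted nanocarriers — antibody-functionalized DNA origami structures
among them — promise to deliver a molecular payload across the plasma
membrane and release it in the cytosol. Bulk fluorescence readouts
cannot distinguish payload that is genuinely free in the cytosol from
payload stuck at the membrane or sequestered in endosomes. Live-cell
single-particle tracking (SPT) can: individual payload dyes are imaged
at high signal-to-noise in a near-TIRF (HILO) geometry, detected frame
by frame, linked into trajectories, and characterized by how they move
and where they are relative to the membrane.

`payloadSPT` implements that analysis chain as a reusable, fully tested
pipeline, together with a synthetic microscopy simulator that generates
ground-truth recordings so every stage can be validated quantitatively
without access to the original video data.

## The measurement model

### Acquisition geometry

The simulator's defaults mirror a dual-channel HILO acquisition: one
camera channel of 428 × 684 pixels covering 50 µm × 80 µm — hence a
pixel size of 0.117 µm (both 50/428 and 80/684 round to 0.117) — at
200 ms per frame, 16-bit. Emitters are rendered with the
pixel-integrated Gaussian point-spread-function model (erf differences
over pixel edges) rather than point sampling, so subpixel centroid
accuracy can be asserted exactly; Poisson shot noise is applied to the
expected photon image and Gaussian read noise added afterwards.

Emitter brightness is not something the recordings report, so it is a
free parameter of the simulator, not a fitted one. The default —
1500 photons per emitter per frame over a background of 100 photons per
pixel with 2 photons read noise — corresponds to a peak signal-to-noise
ratio of about 13 (see `peakSnr()`), a realistic value for a bright,
photostable dye imaged in HILO at 200 ms exposure, and comfortably
above the SNR 10 regime at which the detection benchmark is run.

A payload is rendered either as a single emitter (a cleaved dye
liberated in the cytosol) or as a cluster of four emitters on the
corners of a 2-px square (an intact four-dye payload). The 2-px
spacing is below the diffraction limit — the cluster still looks like
one Gaussian-ish blob — but its second moment is measurably larger:
moment additivity gives Rg² = Rg²(PSF) + s²/2 for side length s.

### Motion models

Four canonical diffusion modes are simulated, one per class reported by
trajectory-segmentation tools for intracellular transport:

* **normal** — Brownian motion, per-axis step variance 2·D·dt;
  MSD(τ) = 4Dτ, anomalous exponent α = 1.
* **directed** — Brownian motion plus a constant drift v·dt in a
  direction drawn uniformly per track (active transport); α → 2 when
  drift dominates.
* **confined** — Brownian steps reflected at the boundary of a disk of
  radius R (membrane-embedded or corralled particles); the MSD plateaus
  near R², so α → 0 at long lags.
* **subdiffusive** — fractional Brownian motion with Hurst exponent
  H ∈ (0, 0.5], generated by exact Davies–Harte circulant embedding of
  fractional Gaussian noise (crowded-cytosol motion). This choice has a
  clean oracle: α = 2H, so H = 0.25 must yield α = 0.5.

The literature the class taxonomy comes from does not prescribe a
generative model for "subdiffusive" or "confined"; fractional Brownian
motion and a reflecting disk are the standard choices with closed-form
expectations, which is exactly what a validation suite needs.

## The analysis chain

### Detection

Spots are found by a difference-of-Gaussians band-pass (σ and 2σ, with
σ the PSF width), 8-connected local-maximum search, and subpixel
refinement by intensity-weighted centroid in a window of radius
⌈3σ⌉. The local background is the median of the window's border ring.
Two shape descriptors are computed from the background-subtracted
second central moments M: the radius of gyration √tr M (σ√2 for an
isotropic Gaussian of width σ) and the eccentricity
√(1 − λ_min/λ_max), zero for a round spot.

Two numerical details matter in practice:

* Candidate maxima are pre-filtered on the band-pass response. A point
  emitter of integrated intensity I has a DoG peak of 0.3·I/(2πσ²);
  maxima below half the peak expected for a threshold-level emitter
  cannot survive the intensity cut, and dropping them early keeps the
  detector fast and starves out pure-noise candidates.
* Shape moments use a circular mask and a noise floor of two robust
  standard deviations above the background. The square window's corner
  pixels are the farthest from the centroid; with clipped-positive
  noise they dominate the second moment of dim spots and would bias the
  size of single dyes upward — enough, at realistic SNR, to obscure the
  single-versus-cluster size separation the analysis exists to measure.

The cleaved-payload population is expected to be *smaller* than the
intact four-dye population, and the package's population comparison
(`compareSizeEccentricity()`) tests exactly that, reporting KS p-values
and the direction of the median shift. For eccentricity the naive
expectation is that a single dye is *rounder*; the real-data direction
can differ, so the package reports the shift's direction rather than
asserting one.

### Linking

Frame-to-frame correspondence is solved as a minimum-total-distance
bipartite assignment (a Jonker–Volgenant-style shortest-augmenting-path
solver written for this package, verified against brute-force
permutation enumeration). Links beyond `maxDisplacement` (default 5
px/frame) are forbidden; a track may bridge up to `maxGap` missed
frames with its displacement budget scaled by (gap + 1). Unlinked spots
become singleton tracks, so spots are conserved. Per-frame-pair optimal
assignment is deterministic and entirely adequate at the sparse payload
densities this assay works at; no motion-model-aware (Kalman) linking
or merge/split handling is attempted.

The default minimum track length for exponent fitting is 20 frames:
the MSD fit uses up to 10 lags, and a 20-frame track supplies just
enough averaging per lag for the fit to be meaningful.

### MSD and the anomalous exponent

Each track's time-averaged MSD is the mean squared displacement over
all ordered observation pairs at each frame lag, up to a quarter of the
track length (`maxLagFraction = 0.25`); pairs spanning detection gaps
contribute at their true lag. The anomalous exponent α is the slope of
an ordinary least-squares fit of log MSD against log lag over the first
`min(10, n/4)` lags, and the intercept gives the generalized diffusion
coefficient through log(4·D). Unweighted log–log OLS over few early
lags is the field's default; nothing fancier is warranted by 20–50
frame tracks. Zero-valued MSD points are excluded with a warning, and
fits with fewer than three usable points are reported as failures, not
dropped silently.

### Diffusion-mode segmentation

A rolling window (default 30 frames, stride 5) is labeled by a fixed
rule set over three features: the window α, the straightness (net
displacement over path length), and a confinement ratio (maximum
pairwise squared distance over the MSD at the longest computed lag).
Rules, in order: *directed* if straightness > 0.6 and α > 1.4;
*confined* if the confinement ratio < 5.5 and α < 0.5; *subdiffusive*
if α < 0.7; else *normal*. Adjacent same-label windows merge into
segments, and a track's dominant class is the one covering the most
frames.

This is a deliberately transparent stand-in for neural
trajectory-segmentation tools over the same four classes; it is
calibrated only on this package's simulator and makes no claim of
reproducing any trained model's outputs. Two calibration notes:

* The confinement-ratio threshold is 5.5, not a value near 2: for a
  well-confined window the maximum pairwise distance approaches 2R
  while the MSD plateaus near R², so the ratio converges to ≈ 4 from
  above, while free-diffusion windows sit around 8–15. A cut at 5.5
  separates the two populations; a cut at 2 would reject essentially
  every genuinely confined window.
* At the study conditions (D = 0.1 µm²/s, 0.2 s/frame, 30-frame
  windows) the measured per-window accuracy is ≈ 100% for directed,
  ≈ 88% for confined, and ≈ 85% for normal tracks, with the residual
  confusion almost entirely normal→subdiffusive — the direction
  expected from the noise of short-window α estimates.

### Delivery-path classification

Payload fate is classified by explicit rules combining membrane
colocalization with the anomalous exponent. A spot is *on the membrane*
when the Euclidean distance transform of the membrane mask at its
rounded position is at most `d_mem` = 2 px (the colocalization distance
is not something a stained-membrane channel pins down more precisely
than the localization and mask errors, so it is a declared parameter).
The rules, in decision order:

1. membrane contact followed by sustained movement into the cell — at
   least 3 consecutive in-cell frames, rejecting boundary jitter —
   is *fast* if the post-membrane α > 0.8 and *slow* if α < 0.3;
   tracks with 0.3 ≤ α ≤ 0.8 are reported *unclassified* rather than
   forced into either class, since the rule set leaves that band open;
2. membrane residence longer than 10 frames with α < 0.3 and no
   subsequent departure is *attached*;
3. membrane residence longer than 10 frames followed by movement is
   *temporarily fixed*;
4. anything else is *unclassified*.

Residence is the longest consecutive membrane run. The exponent for
rule 1 is fitted on the sub-track after the last membrane frame when it
is long enough (≥ 10 observations), with a full-track fallback that is
flagged in the output; for membrane-resident tracks the full track *is*
the residence window, which is also the natural scope for the attached
rule's α. The first 5 post-membrane observations are excluded from the
fit when enough remain: the transit from membrane to cytosol is a short
directed relocation, and leaving it in biases the exponent of the
cytosolic phase upward — visibly so for strongly subdiffusive payloads,
which would otherwise leak into the unclassified band.

### Population statistics

Distributions are compared with the two-sided two-sample
Kolmogorov–Smirnov test (exact p for small samples, asymptotic
otherwise) and means with the two-sided unpaired t-test (Welch's form
by default; the pooled-variance variant sits behind a flag).
Significance bands follow the star convention: n.s. for p > 0.05, then
\*, \*\*, \*\*\*, \*\*\*\* at 0.05, 0.01, 0.001, 0.0001.

Colocalization of two segmented channels is computed natively: the
Pearson correlation of paired pixel intensities within an ROI (with
per-ROI reporting across a list of masks, since ROI-level heterogeneity
is itself informative), and Manders coefficients M1/M2 on
Otsu-thresholded (or fixed-threshold) masks — M1 the fraction of
channel A's intensity inside channel B's mask, M2 the converse. The
mask-based (segmented) form is used rather than threshold-free original
Manders, matching how payload/endosome overlap is quantified in
practice. ROI definitions are supplied by the user; the package does
not guess cell outlines for colocalization.

## The ground-truth scenario generator

`simulateScenario()` scripts payloads of the four delivery fates on a
circular cell (radius 150 px ≈ 17.5 µm — a realistic adherent-cell
scale — membrane band 4 px): *fast* payloads touch the membrane for 5
frames and then undergo directed transport into the cytosol; *slow*
payloads enter and then move as strongly subdiffusive fBm (H = 0.05);
*attached* payloads stay confined on the membrane for the whole
recording; *temporarily fixed* payloads sit for 15 frames and then
detach. In the cleavable condition, mobile payloads are single
emitters and membrane-resident ones four-dye clusters; the
non-cleavable condition keeps multiplicity 4 throughout.

"Fast" is scripted as directed transport rather than fast Brownian
motion deliberately: with 30–50-frame tracks, a free-diffusion track's
fitted α straddles the 0.8 cut often enough that a ground-truth "fast"
label would be unrecoverable in principle — precisely the ambiguity the
open 0.3–0.8 band acknowledges. Directed motion (α ≈ 2) and strong
subdiffusion (α ≈ 0.1) put the scripted classes far from both cuts, so
end-to-end misclassification measures pipeline error, not band overlap.

What the simulator does *not* emulate: photobleaching and blinking,
vesicle/endosome transport physics, 3-D defocus across the HILO sheet,
camera gain/EM noise beyond Gaussian read noise, and cell-shape
irregularity. Passing tests therefore demonstrate the correctness of
the computational chain under a faithful but idealized image model, not
performance on any particular biological recording.

## Problem sizes and reproducibility

The validation suite uses ensembles of 100–500 tracks of 200 steps for
exponent recovery (mean within 0.1 of theory), a 50-emitter frame at
peak SNR 10 for the detection benchmark (precision and recall ≥ 0.95
at a 2-px match radius), 500-spot populations for the single-vs-cluster
size comparison, and a 50-frame full-field two-channel scenario of 16
payloads for the end-to-end check (≥ 90% of payloads recover their true
path class). Every stochastic stage takes an explicit seed; identical
configuration and seed give byte-identical outputs, every output file
is stamped with the configuration's MD5 hash, and
`scripts/acceptance.R` recomputes all of the above from scratch.

## Known limitations

* The rule thresholds (straightness 0.6, confinement ratio 5.5, α cuts
  1.4/0.7/0.5) are calibrated on the simulator's motion models;
  recordings with different frame rates or diffusivities may need
  recalibration via `motionThresholds()`.
* Per-track α estimates from short tracks are noisy (sd ≈ 0.1 at 200
  frames, larger for shorter tracks); population statements should rest
  on distributions, not single-track values.
* The linker is globally greedy per frame pair; it does not revisit
  past assignments and will not resolve dense crossings that a
  multi-frame or motion-model-aware linker might.
* Eccentricity of a rendered four-dye cluster depends on the cluster's
  orientation and spacing relative to the pixel grid; only the size
  (Rg) direction is asserted in validation.
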