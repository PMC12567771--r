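---
title: "Simulating and segmenting multimodal MIR + autofluorescence tissue images"
author: "miraf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and segmenting multimodal MIR + autofluorescence tissue images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(miraf)
```

## The system being modelled

`miraf` simulates a label-free multimodal microscope for thin tissue
sections and the analysis chain that turns its raw images into a tissue
segmentation. The instrument has two optical paths sharing one axis:

* a **flying-spot mid-infrared (MIR) scanner** with four discrete laser
  lines — two *target* wavenumbers on the CH~2~ lipid (2928 cm^-1^) and NH
  protein (3352 cm^-1^) stretching bands, and two *reference* wavenumbers
  (3704 and 2792 cm^-1^) where tissue absorbs negligibly so that only
  scattering responds. The focused spot (≈22 µm at 1/e²) is rastered in
  20 µm steps natively, or 5 µm steps to push the effective resolution to
  about 10 µm;
* an **autofluorescence (AF) camera path**: ring-mounted LEDs (355–440 nm)
  excite endogenous fluorophores — collagen/elastin, flavins (FAD) and
  lipopigments (lipofuscin-like) — whose emission is selected by band-pass
  filters (400/10, 440/10, 550/40 nm) in front of a cooled CCD, at an
  effective sample-plane pitch of 4 µm.

Per band, transmission through a section of thickness $l$ follows the
Beer–Lambert law extended additively over species,

$$A(x, y; \nu) \;=\; \sum_s \varepsilon_s(\nu)\, c_s(x, y)\, l
  \;+\; B(x, y; \nu),$$

where $B$ is a scattering baseline. Detected counts are
$I = I_\mathrm{ref}\,10^{-\langle A\rangle_\mathrm{spot}}$ against the
bare reflective (gold) slide level $I_\mathrm{ref}$, with
$\langle\cdot\rangle_\mathrm{spot}$ the Gaussian-weighted spot average.
The analysis chain normalizes counts to $[0,1]$, converts to absorbance
against the gold reference, removes the scattering baseline by per-pixel
linear interpolation in wavenumber between the two reference-laser images,
upscales the MIR maps bicubically to the 4 µm AF grid, registers all
layers by phase correlation, z-scores each layer, and clusters the pixel
vectors with K-means (k = 5 by default), scoring segmentations with the
Davies–Bouldin index and comparing them across modalities with the
adjusted Rand index (ARI) after nearest-neighbour resampling, registration
and cropping. An FTIR-like modality (dense 10-band set, square-pixel box
averaging, ideal background subtraction, 6.25 or 25 µm pitch) serves as
the spectrally rich reference method.

Because no real acquisitions ship with the package, every experiment runs
on **synthetic phantoms with known ground truth**, which makes the whole
chain quantitatively testable: resolution claims against closed-form
modulation-transfer theory, the correction algebra against exact oracles,
and segmentation quality against the generating label map.

## The phantom generator

`generate_brain_phantom()` emulates a coronal brain section on a
reflective slide at a 2 µm ground-truth pitch (fine enough that the 4 µm
camera grid and the 5 µm raster comb never alias the truth). Five classes
are drawn: a background margin (bare slide), an elliptical gray-matter
bulk, two to three curved white-matter bands whose widths sweep the
5–100 µm structure range, a ventricle, and a reticular web of 5–20 µm
fine-structure elements inside gray matter (thresholded band-pass noise,
emulating protein-rich fiber bundles). The white-matter area fraction is
generator-calibrated to fall within 5–40 % of the frame.

Class composition follows the standard neurochemical picture: white
matter lipid-rich (myelin) with stronger FAD and collagen/elastin
autofluorescence; gray matter protein-rich with stronger lipopigment
autofluorescence; the ventricle watery and dim; the background empty.
Absolute concentrations are arbitrary units — no published calibration
exists for them — chosen **once** so that class mean vectors separate by
at least 3× the within-class standard deviation at the default texture
level (`cv = 0.1`), which is what makes the phantom clusterable by
design. Within-class texture is log-normal (positivity-preserving) with
unit mean, clipped to 1 ± 5 cv; `cv = 0` yields piecewise-constant
fields for oracle tests. The scattering baseline is a smooth, strictly
positive seeded field (correlation length ≥ 50 µm) scaled per class;
spectrally the baseline varies linearly in wavenumber, which makes the
two-reference correction exact in the noiseless limit — the simplest
model consistent with a slowly varying scattering background, and the one
that gives the correction algebra a sharp testable contract.

What the phantom does **not** emulate: anatomically faithful atlas
geometry, 3-D partial-volume effects through the section, spatially
correlated chemical texture, fluorophore photobleaching, and instrument
drift. Passing tests therefore validate the *algorithms* under known
ground truth, not biological realism of any particular tissue.

```{r phantom, eval = FALSE}
phantom <- generate_brain_phantom(phantom_config(seed = 1))
autoplot(phantom)
```

## Forward models and their conventions

**Spot profile.** Beam sizes are quoted as 1/e² diameters (the
beam-profiler convention), so the Gaussian sigma is $d/4$; for the 22 µm
spot, $\sigma = 5.5$ µm. The modulation transfer of the spot is then
$\mathrm{MTF}(f) = \exp(-2\pi^2\sigma^2 f^2)$, the closed form against
which the scan is verified at the 2 % level.

**Raster sampling.** The spot-averaged field is sampled on the raster
comb by bilinear interpolation of the finely blurred field; sample
positions start at the first pixel centre. Down-sampling a 5 µm-step scan
by 4 reproduces the 20 µm-step scan exactly (same comb, same blur), which
is the consistency contract of the super-sampling scheme.

**Detector noise** is additive zero-mean Gaussian with a default of 50
counts; counts are clipped (not wrapped) to the 16-bit range and kept as
floats — quantization is irrelevant at this noise level and would break
the 1e-9 round-trip oracle.

**AF spectra** are Gaussian approximations built from the published peak
positions and ranges (collagen/elastin 340/±15 nm excitation, 420 nm
emission; flavins dual 360/450 nm excitation, 525 nm emission;
lipopigments 450 nm excitation, broad 570 nm emission). A channel's
coupling to a fluorophore is the product of normalized excitation×LED and
emission×filter overlap integrals times the relative yield — closed-form
for Gaussians. Crosstalk is deliberate physics: every fluorophore feeds
every channel through these overlaps, which is why the package exposes
only relative count images and never absolute concentrations. The default
plan implements the four designed channels (two collagen/elastin, one
lipopigment, one flavin with dual illumination); the extra LEDs/filters of
the extended instrument inventory are accepted by the schema but not in
the default plan.

**Camera.** Per pixel, electrons are Poisson (signal + dark current) plus
Gaussian read noise; ADU counts are `round(e / gain)` clipped to the
16-bit range. The clip is applied in ADU so counts can never exceed
65535. The optical blur of the camera path is a 3 µm-FWHM Gaussian PSF,
the resolution bound of the magnifying optics; the 4 µm sample-plane
pitch absorbs the magnification.

## Numerical choices

* **Bicubic upscaling** uses the Keys cubic-convolution kernel
  (a = −0.5), separable, replicate-padded, output size rounded toward
  coverage; no installed package offers bicubic resampling on plain
  matrices, so it is implemented here and verified by round-trip oracles.
* **Registration** is phase correlation (cross-correlation computed in
  the frequency domain), integer peak first, then a locally upsampled
  discrete Fourier transform refines to 0.1 px. Cross-*modality*
  registration runs on gradient-magnitude images: an absorbance map and a
  fluorescence channel can be anti-correlated in intensity yet share
  edges, and intensity-domain correlation can lock onto a spurious offset
  in that case. Estimates larger than a quarter of the extent are treated
  as failures (the layers share a field of view by construction) and
  replaced by zero shift.
* **Scatter-corrected absorbances keep their negatives** under noise;
  clipping would bias cluster means. The absorbance floor is one count
  (1/65535).
* **Per-layer z-scoring** before clustering puts mixed-unit modalities on
  one Euclidean scale; it is the minimal choice that makes K-means
  meaningful across counts and absorbance units. The MIR layers entering
  clustering are the scatter-corrected target absorbances (a switch
  selects raw normalized intensities instead, for sensitivity analyses).
* **K-means**: k-means++ seeding, Lloyd iterations (via
  `stats::kmeans(algorithm = "Lloyd")`), best of 10 restarts, fully
  seeded. The alternative reading of "10 initialization iterations" — ten
  k-means++ candidate draws feeding a single run — is available as
  `init_method = "candidates"`; restarts are the default because they
  dominate it at negligible cost at these problem sizes. Assignment ties
  break toward the lowest centroid index, documented for reproducibility.
* **Label harmonization** solves the maximum-weight one-to-one assignment
  on the label contingency table exactly (permutation search, feasible to
  k = 8; greedy beyond), replacing the manual recoloring step a human
  would apply to match cluster maps across modalities.
* **Grating analysis**: modulation is estimated phase-insensitively as
  twice the Fourier-coefficient magnitude at the grating frequency over
  the profile mean, normalized by the square-wave fundamental 4/π so an
  unblurred target scores 1. Gratings are rendered with exact pixel-area
  coverage so the rendered duty cycle is unbiased at every frequency
  (point sampling at odd pixel-per-period counts would bias the mean by
  several percent). Frequencies beyond the raster Nyquist limit are
  reported as contrast 0 with an aliasing flag rather than measured from
  aliases. The resolvability threshold is 0.2 — "clearly visualized" is
  not otherwise quantified — and the 18-step ladder spans 1.25–250
  lp/mm with the named endpoints.

## The exact-recovery oracle

On a zero-texture, noiseless phantom the k = 5 segmentation must equal
the ground truth up to label permutation (ARI = 1). This contract is
meaningful only when every cube pixel samples a single tissue class, so
`ideal_multimodal_cube()` runs the full processing chain with an
aperture-free acquisition: point spot, raster step equal to the phantom
pitch, camera blur off, all noise off. Every algebraic stage (absorbance
conversion, scattering correction, channel couplings, z-scoring,
clustering, harmonization) is still exercised. With the instrument's real
22 µm spot, pixels at class boundaries are genuinely mixed — a background
pixel at the tissue rim carries a partial gray-matter signature and can
legitimately fall nearest to the dim ventricle centroid — so demanding
pixel-perfect recovery there would test the geometry of blending, not the
correctness of the chain. Finite-aperture fidelity is instead quantified
where it belongs: the grating resolution analysis and the
ordering-of-modalities experiment below.

## Experiments

`run_experiment()` mirrors the three study designs at desk scale
(default 512×512 ground-truth pixels ≈ 1×1 mm; the replicate studies use
256×256, sizes chosen to keep a full run in seconds on one CPU):

1. **Spectral richness**: FTIR-like segmentation with 10 vs 4 bands;
2. **Spatial resolution**: 6.25 vs 25 µm FTIR pitch, and 20 vs 10 µm MIR
   rastering;
3. **Multimodal fusion**: corrected MIR target layers upscaled to 4 µm
   plus the four AF channels in one cube.

Across 100 seeded replicate phantoms with default noise, the expected
ordering ARI(truth, multimodal) > ARI(truth, mir10) > ARI(truth, mir20)
and ARI(truth, ftir6.25) > ARI(truth, ftir25) holds in well over 90 % of
replicates; this reproduces, qualitatively, the published finding that
fusion recovers most of what the coarse MIR scan loses and that spatial
resolution dominates spectral richness. The absolute ARI values of the
original tissue experiments are not reproducible here — they depend on
real mouse-brain acquisitions that were never deposited — which is why
the package's acceptance is property- and simulation-based.

```{r experiment, eval = FALSE}
cfg <- run_config(seed = 1, modalities = c("mir20", "mir10", "multimodal"),
                  phantom = phantom_config(width = 256, height = 256))
report <- run_experiment(cfg)
tidy(report)
autoplot(report)
```

## Known limitations

* The scattering baseline is exactly linear in wavenumber, so the
  dual-reference correction is exact by construction; real baselines
  (Mie-type ripple, substrate interference) would leave residuals the
  package does not model.
* Absorbance is spot-averaged before the decadic exponential; at the
  contrast levels simulated the difference from intensity-domain
  averaging is far below the detector noise, but it is a modelling
  choice, made so the scan inverts exactly to the spot-averaged
  absorbance.
* AF spectra are single-Gaussian (per peak) caricatures; real emission
  tails would increase crosstalk.
* Registration covers translations only; the shared-path instrument
  design justifies this, and nonrigid residuals are out of scope.
* The Davies–Bouldin sweep can prefer k ≠ 5 on heavily blended cubes;
  the pipeline pins k = 5 by default, matching the anatomical reading of
  the five phantom classes.
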