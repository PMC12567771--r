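# miraf

Simulation and segmentation for multimodal mid-infrared (MIR) +
autofluorescence tissue imaging.

## What problem this addresses

Label-free chemical imaging of tissue sections faces a three-way trade-off
between speed, spatial resolution and chemical specificity. A four-laser
flying-spot MIR scanner maps lipid (CH₂, 2928 cm⁻¹) and protein (NH,
3352 cm⁻¹) absorption in seconds per cm² but resolves only ~20 µm (10 µm
with 5 µm super-sampled rastering); FTIR imaging is spectrally rich and
finer-pitched (6.25 µm) but takes hours; an autofluorescence camera sees
collagen/elastin, flavin (FAD) and lipopigment contrast at 4 µm in
seconds. Fusing the MIR and autofluorescence paths into one co-registered
data cube and clustering it promises FTIR-grade tissue segmentation —
gray matter, white matter, ventricle, fine fiber structure — at a small
fraction of the acquisition time.

Evaluating such a pipeline quantitatively requires ground truth that real
tissue never provides. `miraf` therefore implements the whole system as a
physics-based simulation on synthetic brain-section phantoms with known
labels, plus the complete processing and evaluation chain, so every claim
becomes a testable property. It is aimed at researchers developing or
benchmarking multimodal chemical-imaging pipelines.

## The model in brief

Per MIR band ν, with species concentrations $c_s$ and section thickness
$l$:

```
A(x,y;ν) = Σ_s ε_s(ν) c_s(x,y) l  +  scatter(x,y)·(b₀ + b₁ν)
counts   = clip( I_ref · 10^(−⟨A⟩_spot) + η, 0, 65535 )
```

where `⟨·⟩_spot` is a Gaussian spot average (1/e² diameter 22 µm, σ = d/4)
sampled on the raster comb and η is detector noise. The two reference
lasers (3704, 2792 cm⁻¹) see only the scattering baseline, so per-pixel
linear interpolation in wavenumber between them removes it from the target
bands. Autofluorescence channels couple each fluorophore through
closed-form Gaussian excitation×LED and emission×filter overlap integrals
into a CCD model with shot, dark and read noise. Processing: counts/65535
→ absorbance against the gold reference → scatter correction → bicubic
upscaling to the 4 µm grid → phase-correlation registration → per-layer
z-scoring → K-means (k-means++ seeding, 10 restarts, k = 5) →
Davies–Bouldin index and adjusted Rand index (after nearest-neighbour
resampling, registration and cropping) for evaluation.

## Worked example

```r
library(miraf)

cfg <- run_config(seed = 1, modalities = c("mir20", "mir10", "multimodal"),
                  phantom = phantom_config(width = 256, height = 256, seed = 1))
report <- run_experiment(cfg)
tidy(report)
#> # A tibble: 3 × 5
#>   modality   pitch     k davies_bouldin ari_truth
#>   <chr>      <dbl> <int>          <dbl>     <dbl>
#> 1 mir20          4     5          0.477     0.750
#> 2 mir10          4     5          0.440     0.828
#> 3 multimodal     4     5          0.557     0.881
```

One phantom is simulated through three acquisition modes and segmented
with k = 5. `ari_truth` is the adjusted Rand index of each segmentation
against the generating label map: the native 20 µm scan recovers the
gross anatomy (0.750), 5 µm rastering improves it (0.828), and fusing the
four autofluorescence channels recovers most of the remaining fine
structure (0.881) — the ordering the multimodal design exists to produce.
`autoplot(report)` charts it; `autoplot(report$segmentations$multimodal)`
draws the label map.

The resolution analysis scans binary line gratings through the simulated
spot and raster:

```r
gv <- run_grating_validation(spot = spot_profile(22), grid = raster_grid(5))
dplyr::filter(gv$curve, frequency %in% c(20, 40, 50, 63))
#>   frequency   contrast aliased
#> 1        20 0.7881     FALSE
#> 2        40 0.3841     FALSE
#> 3        50 0.2257     FALSE
#> 4        63 0.0922     FALSE
gv$limit
#> [1] 50
```

Modulation contrast follows the Gaussian-spot MTF; at the 0.2 threshold
the 5 µm-rastered 22 µm spot resolves up to 50 line pairs/mm (20 µm
bars), while 20 µm rastering is Nyquist-bound at 25 lp/mm.

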