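# ccquant

Quantitative assessment of the choriocapillaris (CC) from repeated
swept-source OCT angiography (SS-OCTA) en face images.

The CC — the dense capillary monolayer of the inner choroid — is notoriously
hard to image with commercial OCTA: at 10 µm/pixel sampling its capillary
mesh (mean intercapillary distance ~20–27 µm) is barely resolved, and a
single scan is dominated by multiplicative speckle, so flow deficits (FDs,
dark regions without detectable flow) cannot be measured reliably. `ccquant`
implements the full post-processing chain that makes CC quantification
workable on such data, for retinal-imaging researchers and image-analysis
method developers:

- **Registration and averaging** of repeated scans to the first scan, via a
  three-step cascade — translation → affine → cubic B-spline free-form
  deformation — each stage minimizing the mutual-information cost
  C = −I(I_F; I_M ∘ T_μ), followed by valid-pixel arithmetic averaging.
- **Quality metrics** across cumulative averages: global entropy (0–1),
  global standard deviation (0–255), local gray-level co-occurrence texture
  correlation, and PSNR against the full-stack average.
- **Intercapillary distance (ICD)** from the radially averaged 2-D power
  spectrum of a region (default 650 µm × 650 µm): the most prominent
  detrended peak in the 15–60 µm band is the mean capillary spacing.
- **Flow-deficit segmentation** by fuzzy c-means over pixel intensities with
  an explained-variance (99 %) elbow rule for the cluster count; the darkest
  cluster is the FD map; optional projection-artifact removal under a
  retinal-vessel mask.
- **Morphometric indices** of the FD population — density (FDD), number
  (FDN), mean size (FDS, µm²), aspect-ratio index (FDARI = mean M_i/N_i of
  the moments-equivalent ellipse axes), complexity index
  (FDCI = mean P_i²/(4π A_i)) — plus six functional maps (binary, perimeter,
  skeleton length, and per-component aspect-ratio / complexity / size maps).
- **A synthetic CC phantom generator** with complete ground truth (known
  spacing, known inter-scan motion, Gamma speckle, planted elliptical
  deficits), so every stage is validated against known truth.

## Worked example

```r
library(ccquant)

## a 1.28 mm synthetic CC scene: honeycomb mesh at 24 um spacing,
## 5% planted flow-deficit area
scene <- syntheticScene(c(128, 128), icdUm = 24, fdDensity = 0.05, seed = 1)

## three repeated "scans": known shifts + 2-look speckle
motions <- c(list(identityChain()),
             lapply(list(c(4, -3), c(-5, 2)),
                    function(s) TransformChain(translation = s)))
stack <- makeRepeatStack(scene, motions, looks = 2, seed = 1)

report <- runPipeline(stack, pipelineConfig(seed = 1, logLevel = "quiet"))
report$quality
report$indices
report$icd$icdUm
```

Output of this exact script:

```
  nAverage entropy  std textureCorr psnrDb
1        1   0.932 54.7      0.0357   16.1
2        2   0.911 41.6      0.0726   21.8
3        3   0.887 35.1      0.1013    Inf
  nAverage k    fdd  fdn fdsUm2 fdari fdci
1        1 8 0.1843 1134    266  1.53 1.03
2        2 8 0.1025  667    252  1.30 1.07
3        3 8 0.0707  352    329  1.17 1.11
ICD: 24.1 um (planted 24 um); planted FDD 0.049
```

Reading it: with more scans averaged, entropy and standard deviation fall
and texture correlation and PSNR rise (speckle suppression); the
flow-deficit density falls from a speckle-inflated 0.18 at a single scan
toward the planted truth of 0.049 (with five averages at 256×256 it lands
within ±0.02); the spectral ICD estimate recovers the generator's 24 µm
spacing to within one frequency bin. PSNR is `Inf` at the last level
because that level is its own reference.

A command-line wrapper with subcommands (`simulate`, `register-average`,
`quality`, `icd`, `segment`, `quantify`, `run`) is installed at
`inst/scripts/ccquant-cli.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/ccquant-cli.R", package="ccquant"))')" \
    simulate --outdir sim --n 5 --seed 1
```

## Package layout

- `R/` — S4 classes (`EnFaceImage`, `ImageStack`, `TransformChain`,
  `MembershipMap`, `FDBinaryMap`, `FDComponentSet`, `SyntheticScene`) and
  the module functions.
- `vignettes/cc-quantification-methods.Rmd` — the model, the numerical
  choices and their rationale, and known limitations.
- `tests/testthat/` — unit, property and end-to-end recovery tests.
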