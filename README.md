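# mitomorph

Whole-cell mitochondrial morphology phenotyping from fluorescence Z-stacks.

Mitochondria in a cell range from small ovoid fragments (**punctate**)
through short rods (**intermediate**) to long, branched networks
(**filamentous**), and the population-level mix of these shapes — the
cell's *mitochondrial phenotype* — tracks metabolic state and drug
response. `mitomorph` turns raw multi-slice fluorescence images into that
phenotype, for microscopists and computational biologists working with
cultured cells or scant clinical samples such as fine-needle aspirates.

The pipeline:

1. **All-in-focus fusion** — each pixel of the fused image is sampled from
   the slice maximizing a variance-of-Laplacian focus score (window 9 px),
   with majority smoothing of the selection map.
2. **Segmentation** — rolling-ball background subtraction (grayscale
   opening, disc radius 50 px), FFT band-pass passing 0.2–4 µm structures,
   adaptive local-mean thresholding (51 px window, robust automatic
   offset), binary open–close cleanup and 8-connected labelling inside a
   per-cell polygon ROI.
3. **Classification** — ten calibrated shape descriptors per object (area,
   perimeter, axis lengths, eccentricity, solidity, form factor
   4πA/P², skeleton length and branch points, aspect ratio), fed to a
   200-tree random forest; a transparent skeleton-length threshold rule
   (< 1 µm punctate, 1–4 µm intermediate, > 4 µm or branched filamentous)
   acts as fallback and cross-check.
4. **Population statistics** — per-cell class fractions, total
   mitochondrial area, density (mitochondrial area / cell area), the total
   morphology-change metric Σ|Δclass %| ∈ [0, 200], Friedman rank tests
   with exact permutation p-values, and Pearson correlation against
   external measurements (e.g. oxygen consumption rates).

A built-in simulator renders cells with known object classes through a
Gaussian-PSF defocus and Poisson/read-noise camera model, so the whole
chain is validated against generative ground truth — no external images
required.

## Worked example

```r
library(mitomorph)

# simulate one punctate-leaning cell and analyze it
spec <- simCellSpec(classMixture = c(0.6, 0.2, 0.2), objectCount = 30,
                    seed = 7)
sim  <- renderStack(list(spec), nSlices = 5)
seg  <- segmentCell(sim$stack, sim$rois[[1]])
objs <- classifyRuleBased(extractDescriptors(seg))
summarizeCell(objs, sim$rois[[1]])
```

```
   cellId n.punctate n.intermediate n.filamentous f.punctate f.intermediate
1 simcell         18              8             4        0.6      0.2666667
  f.filamentous nObjects totalAreaUm2 cellAreaUm2    density empty
1     0.1333333       30        55.85    1121.204 0.04981252 FALSE
```

The 30 placed objects are all recovered; the measured fractions
(60/27/13%) match the generative mixture (60/20/20%) to within sampling
noise of a 30-object draw, and density is total mitochondrial area divided
by the 19 µm-radius cell polygon's area.

Training and using the forest instead of the threshold rule:

```r
bench <- makeBenchmark(1000, mixture = c(1, 1, 1) / 3, seed = 1)
model <- trainClassifier(bench[!bench$missed, ], nTrees = 200, seed = 1)
model
#> MitoClassifier: 200 trees on 10 descriptors, OOB error 0.10%
objs  <- classifyObjects(model, extractDescriptors(seg))
```

`runSimulate()`, `runAnalyze()`, `runTrain()` and `runReport()` provide
file-level orchestration (TIFF stacks + ROI JSON in, CSV/PNG + a manifest
out); `inst/scripts/mitomorph.R` wraps them for shell use.

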