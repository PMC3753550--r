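# ApicalQuant

Quantitative image analysis of apical plasma-membrane remodelling during
*Drosophila* cellularization. In the first hour of embryogenesis the apical
surface, initially covered in villous protrusions, flattens while apical
endocytosis ramps up: endocytic structures multiply ~5-fold, Rab5-positive
apical endosomes ~3-fold, internalized cargo colocalizes extensively with
Rab5, and newly formed endosomes either persist apically or descend ~15 µm
basally toward the advancing cellularization furrow. ApicalQuant implements
the image-quantification pipelines behind each of those readouts, for
TIRF / confocal time-lapse data, together with seeded synthetic-movie
generators that provide ground truth for every stage.

## What it computes

* **Protrusion coverage** (`coverageTimeseries`) — per frame: bleach
  correction that fixes each frame's mean to the first frame; an oriented
  Mexican-hat filter bank, kernels G(u; σₓ) · R(v; σᵧ) with
  R(v) = (1 − v²/σᵧ²)·exp(−v²/2σᵧ²) across the ridge (defaults σₓ = 7,
  σᵧ = 1 px) rotated through θₖ = kπ/18; the per-pixel maximum over angles;
  Otsu segmentation of the positive responses with a robust noise floor;
  and the skeleton-pixel density of the segmented mask — the fractional
  surface coverage by protrusions. `ksCompare` contrasts conditions with an
  exact (exhaustively enumerated) small-sample two-sample KS test.
* **Puncta dynamics** (`punctaTimeseries`) — robust-background thresholding
  (trim 5% per intensity tail, mean + k·SD) and 8-connected spot detection
  per frame; counts and integrated intensities normalized to the mean of
  the first 20 frames. `countSubapicalStructures` counts structures in
  25 × 25 µm² ROIs across five z sections 0.2 µm apart.
* **Endosome tracking** (`linkDetections`, `filterTracks`,
  `classifyTracks`, `displacementProfile`) — per-frame-pair globally
  optimal gated assignment (max links, then minimum total displacement);
  tracks kept if they last ≥ 6 frames and originate within 5 µm of the
  apical surface; classified *descending* if their maximal depth passes
  5 µm, else *persistent*; per-stage depth statistics against the furrow
  front.
* **Colocalization** (`objectColocalization`) — fraction of reference-
  channel objects whose pixels overlap the partner-channel object mask by
  at least a configurable fraction (default 30%).
* **Synthetic scenes** (`genProtrusionMovie`, `genPunctaMovie`,
  `genTrackScene`, `genColocPair`) — seeded, bit-reproducible generators
  with truth tables, emulating retracting vs persistent protrusion fields,
  staged puncta regimes, descending/persistent particle scenes with a
  furrow schedule, and two-channel object sets with a known overlap
  fraction.

## Worked example

```r
library(ApicalQuant)

# a retracting (wild-type-like) protrusion movie with ground truth
movie <- genProtrusionMovie(protrusionMovieConfig(seed = 11))
cs <- coverageTimeseries(movie$stack, condition = "wt")
cor(frameTimes(cs), coverage(cs), method = "spearman")
#> [1] -0.9977772
range(coverage(cs))
#> [1] 0.005157471 0.048324585

# compare against a persistent (shibire-like) condition at the final frame
sh <- genProtrusionMovie(protrusionMovieConfig(profile = "persistent",
                                               seed = 14))
cs2 <- coverageTimeseries(sh$stack, condition = "shibire")
ksCompare(coverage(cs)[41:60], coverage(cs2)[41:60])$statistic
#> [1] 1
```

The Spearman ρ ≈ −0.998 says measured coverage falls almost monotonically
as protrusions retract (from ~4.8% of the field to ~0.5%), while the
persistent condition stays near its initial coverage, so the two
conditions separate completely (KS D = 1).

```r
pair <- genColocPair(colocPairConfig(overlapFraction = 0.8, seed = 3))
res <- objectColocalization(
  getFrame(pair$ref, 1), getFrame(pair$partner, 1),
  colocParams(refParams = robustBackgroundParams(kSd = 3),
              partnerParams = robustBackgroundParams(kSd = 3), minArea = 5)
)
res$percentPositive
#> [1] 80
```

A command-line front end wrapping the same functions is installed at
`system.file("scripts", "apicalquant.R", package = "ApicalQuant")`, with
subcommands `simulate`, `flatten`, `puncta`, `count-subapical`, `track`
and `coloc`, each driven by a YAML run configuration (see
`defaultRunConfig()`).

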