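---
title: "ApicalQuant: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ApicalQuant: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ApicalQuant quantifies apical plasma-membrane remodelling during
*Drosophila* cellularization from fluorescence time-lapse imaging: the
retraction of villous protrusions (apical flattening), the concurrent rise
of endocytic puncta and sub-apical structures, the colocalization of
internalized cargo with Rab5, and the basal descent of apically born
endosomes relative to the cellularization furrow. This vignette explains
each model, the parameters that matter, and the choices made where the
design was genuinely open.

# Data model

An `ImageStack` is a `T x Y x X` (or `T x Z x Y x X`) non-negative
intensity array with explicit calibration: `pixelSizeUm` (µm/px),
`frameIntervalS` (s) and, for z-resolved stacks, `zSpacingUm` (µm).
Calibration is never inferred from files — acquisitions do not reliably
carry it — so it always comes from the user (or a YAML run configuration,
`loadRunConfig()`). The axis convention is T first, then optional Z, then
Y, then X; in sagittal views the row index increases from apical to basal.
Pixel indices are 0-based internally; every reported position or distance
is in micrometres. On disk, stacks are 16-bit unsigned-integer multi-page
TIFFs (the camera ADU convention), which round-trips integer-valued stacks
exactly.

# Protrusion coverage

The flattening readout is the fraction of the apical field covered by the
*skeleton* of segmented protrusions, computed per frame as:

1. **Bleach correction.** Every frame is multiplied by
   `mean(frame 1) / mean(frame t)`, fixing each frame's mean intensity to
   the initial image. This is exact (checked to 1e-9 relative) and assumes
   the field-averaged signal would otherwise be stationary — reasonable
   while the membrane stays within the evanescent field.
2. **Oriented Mexican-hat filter bank.** The ridge detector at orientation
   θ is the separable product of a Gaussian of scale σₓ along the ridge
   axis *u* and a Ricker (Mexican-hat) profile of scale σᵧ across it:
   `G(u; σx) · (1 − v²/σy²) exp(−v²/(2σy²))`. Defaults σₓ = 7 px,
   σᵧ = 1 px select bright, thin, elongated structures — protrusions a
   pixel or two wide and tens of pixels long. After discrete sampling the
   kernel is shifted to exact zero mean, so flat regions give exactly zero
   response. The interval [0, π) is sampled at 18 orientations (10°
   steps, configurable), finer than the orientation spread of protrusions;
   ridges are undirected, so π-periodicity suffices. Correlation uses
   reflective (mirror) padding, computed by FFT with the kernel spectra
   precomputed once per movie; reflective padding avoids dark-edge
   artifacts that would otherwise inflate the background class.
3. **Orientation MIP and segmentation.** The per-pixel maximum over the
   angle-indexed response stack enhances protrusions of any orientation.
   The mask is `MIP > max(t_otsu, t_floor)`, where `t_otsu` is the Otsu
   threshold of the *positive* response histogram (256 bins, exhaustive
   between-class-variance search) and `t_floor = median + 4·MAD` of the
   full response. The floor replaces the background rejection an
   interactively trained pixel classifier would learn: Otsu always splits
   a histogram, so on a structure-free frame it would label a sizeable
   fraction of pure noise as foreground, while genuine ridge responses sit
   far above the robust noise band (on the synthetic study conditions the
   Otsu threshold is ~2x the floor whenever protrusions are present, so
   the floor only engages on near-empty frames). A constant response
   yields an empty mask; a constant *positive* response is thresholded at
   half its value so a clean two-valued response segments exactly.
4. **Skeleton coverage.** Coverage is the number of skeleton pixels
   (Zhang–Suen thinning, implemented in C++ and cross-checked against an
   independent R implementation) divided by the frame's pixel count. The
   skeleton makes the readout insensitive to protrusion thickness and
   out-of-focus halo; since the published definition of "area covered by
   protrusions" is ambiguous between skeleton length and mask area, the
   binary-mask area fraction is emitted alongside as a secondary column.

Conditions are compared with a two-sample KS test, `ksCompare`. For
`n·m ≤ 100` the two-sided p-value is computed exactly by enumerating all
`choose(n+m, n)` assignments of the pooled sample (correct under ties);
larger samples use the asymptotic KS distribution. At n = m = 3 — three
embryos per condition — the smallest achievable exact p is 2/20 = 0.1,
attained at complete separation (D = 1); that floor, not a tiny asymptotic
p, is the honest small-sample statement of condition separation.

# Puncta quantification

Spot segmentation uses **robust-background thresholding**: sort the pixel
intensities, discard the lowest and highest `trim_fraction` (default 5%,
counts rounded down), and set the threshold to mean + `k`·SD of the
retained pixels, with the *population* SD for oracle-exact testability.
Detection takes 8-connected components above threshold with area in
`[min_area, max_area]` px (defaults 2–200, spanning diffraction-limited
puncta to small vacuoles at 0.1–0.2 µm/px sampling) and reports centroids
(µm), areas, integrated intensities and an eccentricity column for
optional tubule/vesicle splitting downstream.

The per-operation defaults (`trim = 0.05`, `k = 2`, area ≥ 2) follow the
published description of the method. For the *pipeline runs on the
synthetic study conditions* — shot-noise-limited images with a Gaussian
PSF of σ = 1.5 px — the analysis configuration is `k = 3` and
`min_area = 5`: mean + 2 SD sits at the ~2–5% tail of pixel noise, so on
a 512² frame it admits thousands of noise pixels whose chance doublets
would swamp real spots, whereas k = 3 is the standard 3σ detection limit,
and 5 px is about half the above-half-maximum area (≈ 2π ln2 σ² ≈ 10 px)
of the PSF, below which a detection cannot be a resolved spot. Both are
ordinary, configurable analysis choices, not changes to the method.

Counts and integrated intensities are normalized by the mean of the first
20 frames (the early-cellularization baseline); the normalized series
therefore averages exactly 1 over the baseline window and is invariant to
global intensity rescaling. Movies shorter than the baseline are refused.

Sub-apical structures are counted in square ROIs of 25 × 25 µm² (625 µm²),
independently in five z sections 0.2 µm apart — per-section counts, no
cross-z merging, matching how such counts are made manually — and each
ROI reports the mean over its sections.

# Endosome tracking

Detections (frame, y, x in µm) are linked frame pair by frame pair with a
globally optimal one-to-one assignment: among pairs within a hard gate
(default 2 µm/frame), the assignment maximizes the number of links and,
among those, minimizes total Euclidean displacement. This is solved as a
maximum-weight bipartite matching with edge weights `C − d` where
`C > (min(n,m)+1)·gate`, so cardinality strictly dominates cost. There is
no gap closing: a missed detection terminates the track, keeping the
6-frame minimum-duration criterion meaningful as *continuous*
detectability. Linking is invariant to the ordering of detections within
a frame (detections are canonically sorted first).

Filters and classification use inclusive boundaries: tracks are kept if
duration ≥ 6 frames and origin depth ≤ 5 µm below the apical reference
(a 6-frame track and an exactly-5-µm origin both pass; one ulp past 5 µm
fails), and a kept track is *descending* if its maximal depth exceeds
5 µm, else *persistent*. "Displacement" is the maximal depth below the
apical reference — the quantity that distinguishes descent past the
apical band — with the net start-to-end displacement emitted as a
secondary column. The apical reference is a configured depth or, from an
image, the intensity-weighted mean row of the brightest 1% of pixels in
frame 1 (the apical membrane dominates sagittal views); the furrow front
is an input series (configuration or generator truth), not detected from
images. `displacementProfile` assigns each track to the stage window
containing its first frame and reports n, mean and population SD of
maximal depth per window and class, next to the mean furrow depth.

# Colocalization

Both channels are segmented with the same robust-background + detection
machinery; a reference object is *positive* when at least
`overlap_fraction_min` (default 0.3) of its pixels fall on the partner
object mask. The published assessment was by eye; 30% pixel overlap is a
deliberately permissive, explicit surrogate, and the per-object overlap
fractions are emitted so any other criterion can be re-applied post hoc.
A Manders M1 column (reference intensity fraction over the partner mask)
is included as a pixel-weighted cross-check. Analysis is single-plane, as
in single-plane confocal quantification.

# Synthetic study conditions

Each generator is a pure function of (configuration, seed): identical
inputs give bit-identical outputs (`withr::with_seed`). Ground truth is
computed on the noiseless latent structure — for coverage, on the latent
binary protrusion mask — never on rendered pixels. The camera model is
`Poisson(gain·signal)/gain + N(0, read SD)`, clamped at zero and
quantized to integer ADU: the standard sCMOS/EMCCD approximation.

* **Protrusion movies** (default T = 60 at 40 s/frame ≈ the ~40 min of
  cellularization; 256² px at 0.16 µm/px): thin anti-aliased line
  segments (lognormal length, mean 2 µm), blurred with a 1-px Gaussian
  PSF over a static textured membrane background (level 100 ADU, 5%
  texture), amplitude 400 ADU (peak ridge SNR ≈ 10), multiplicative
  bleaching `exp(−0.005·t)` applied before noise. Under the wild-type
  profile the protrusion count decays exponentially from 150 to 10% of
  its initial value by the last frame; the persistent profile (the
  dynamin-blocked phenotype) keeps it constant. Protrusions are
  resampled each frame — they are highly dynamic structures.
* **Puncta movies** (default 512² px): Poisson births at a
  piecewise-constant stage schedule over the early/mid/late thirds of the
  movie (multipliers 1/3/5 for the fivefold regime; 1/2/3 for the
  threefold one), lifetime 3 frames, Gaussian PSF σ = 1.5 px, peak
  120 ADU over background 100 (peak SNR ≈ 10). Births begin
  `lifetime − 1` frames before the movie so occupancy is stationary from
  frame 1. The 512² field (82 × 82 µm at the default sampling) keeps
  early-stage occupancy near 48 objects — large enough for per-frame
  occupancies to concentrate — while leaving late-stage frames below the
  crowding regime where spot merging would bias counts. With `zPlanes >
  1` the generator renders independent object sets per z section for
  per-section counting.
* **Track scenes** (T = 100; 40 µm deep × 50 µm wide): particles are born
  within 4.5 µm of the apical reference (inside the 5-µm origin filter
  with margin for the 0.1-µm detection jitter); 70% descend at
  1 µm/frame to a target depth ~ N(15, 2²) µm (truncated at 6 µm) and
  terminate, the rest random-walk (step SD 0.3 µm) reflected within the
  band for ≥ 6 frames. Births stop 30 frames before the end so descents
  complete within the recording; stage windows for profile analysis
  accordingly span the birth-active first 70 frames. The furrow deepens
  linearly from 0 to 30 µm. The descending fraction 0.7 is an
  order-of-magnitude choice — no measured fraction exists — and is
  configurable. Detection tables carry a `true_track_id` column that the
  tracker must ignore.
* **Colocalization pairs**: exactly `n = 100` non-overlapping Gaussian
  blobs (σ = 2 px, ≥ 12 px centre separation, rejection-sampled with an
  explicit infeasible-packing error) in the reference channel;
  `floor(f·n)` of them duplicated at identical positions in the partner
  channel plus 30 partner-only distractors at disjoint positions, so the
  truth contains exactly `floor(f·n)` positives by construction.

What the generators do *not* emulate: evanescent-field depth decay and
TIRF shadowing, optical sectioning cross-talk, motion blur, spatially
varying background drift, protrusion curvature and branching, endosome
splitting/merging, and detection dropout. Passing the recovery tests
therefore demonstrates that the pipelines measure what they claim under a
faithful noise and geometry model — not that they are robust to every
artifact of real acquisitions.

# Numerical choices and degenerate inputs

Kernels are exactly zero-mean after discretization; FFT correlation is
verified against direct looped correlation to ~1e-14. Otsu uses 256
fixed-width bins and exhaustive search; a zero-range positive response is
thresholded at half its value; an all-constant response yields an empty
mask. The KS permutation p-value counts `D_perm ≥ D_obs − 1e-12` to be
safe against float equality. Thresholding uses the population SD and
floor-rounded trim counts so a sorted-list oracle reproduces it exactly.
Assignment ties in linking are broken deterministically by the canonical
detection ordering. Boundary semantics (≥ 6 frames, ≤ 5 µm origin,
> 5 µm descent) are tested at one ulp. Empty detection sets, empty masks,
zero-rate generators and zero-mean frames all either return well-defined
empty results or fail with a named error, as documented per function.

# Problem sizes used by the test-suite

The suite exercises the full study conditions: six 60-frame 256²
protrusion movies through the complete coverage pipeline; ten 60-frame
512² puncta movies across both stage regimes plus five-section z-stacks;
sixteen tracking scenes (exact, jittered and boundary cases); and thirty
two-channel pairs at three overlap fractions. Oracle checks run the
robust threshold against brute force on 1,000 random arrays, the exact KS
test against full enumeration for every sample-size pair with n·m ≤ 36,
and the C++ thinning against an independent R implementation on 100
random masks. `scripts/acceptance.R` re-runs the same conditions
end-to-end from a single command-line seed.

# Known limitations

* Equivalence with interactively trained segmentation (and with
  commercial tracker output) is not claimed; the deterministic
  replacements are documented contracts instead.
* Coverage compares conditions at n = 3, where the exact KS p-value
  cannot go below 0.1; claims of astronomically small p-values require
  pixel-scale sample sizes that conflate pixels with replicates.
* Counts in crowded fields are biased low by object merging (no
  declumping); the synthetic defaults stay below that regime and real
  data approaching it would need a declumping step.
* Tracking assumes continuous detectability (no gap closing) and no
  merge/split events; the minimum-duration filter semantics depend on it.
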