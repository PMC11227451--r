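---
title: "Methods: allele-level DNA/RNA FISH image analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-level DNA/RNA FISH image analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters and numerical choices
behind `hifishr`. It is the package's own account of its methods; every
empirical statement here is one the test suite or `scripts/acceptance.R`
computes.

## The measurement problem

Combined DNA/RNA FISH marks a gene locus (DNA probe, one spot per allele)
and its nascent transcript (intron-targeted RNA probe, one spot per
actively transcribing allele) in the same nucleus. In a high-throughput
plate format the data are 16-bit, maximum-projected 2D fields in three
channels — DAPI, DNA probe, RNA probe — at a pixel size of 0.108 µm.
Two acquisition designs exist:

* **simultaneous**: one hybridization, one imaging round, all three
  channels in register by construction;
* **sequential**: RNA is imaged first, the DNA probe hybridized
  afterwards, and the plate re-imaged; the two rounds are related by an
  unknown, essentially rigid translation that must be estimated before
  DNA and RNA spots can be compared.

The pipeline's end product is an allele table: per DNA spot, the minimum
2D Euclidean distance to an RNA spot of the same cell, an activity class,
and a normalized radial nuclear position, plus per-cell spot-count
summaries.

## Registration model

The inter-round displacement is modeled as a pure integer-pixel
translation — no rotation, scaling or non-rigid terms — estimated from the
DAPI channel, whose textured nuclei provide the shared high-intensity
features the correlation locks onto. For images $A$ (DNA round) and $B$
(RNA round),

$$C(\Delta r, \Delta c) = \sum_{r,c} A(r,c)\, B(r+\Delta r,\, c+\Delta c),$$

summed over overlapping pixels only, is evaluated for all
$|\Delta| \le$ `max_shift` (default 50 px, generous for plate re-mounting
drift on a 1024–2048 px field). The implementation zero-pads and uses
FFTs; `method = "direct"` evaluates the defining sum and the two agree to
relative 1e−9 (tested). Ties at the peak resolve to the smallest
displacement magnitude, then row-major order; a constant correlation map
is an error rather than an arbitrary zero shift.

Sign convention: the returned `TranslationVector` is defined
*operationally* as the vector whose application (`apply_translation`,
content moved by `+v`, zero-filled boundary) maximizes overlap with the
reference image. A round-trip property test (shift a scene, re-noise,
estimate, undo) enforces this; 100/100 random shifts with $|\Delta|\le 20$
on moderately noisy 512² DAPI fields are recovered exactly.

The registration quality score is the Pearson correlation of the two DAPI
images over their overlap at the estimated shift, in $[-1, 1]$. Fields
below `min_quality` (default 0.3) are excluded and counted; uncorrelated
noise pairs score near 0, correct registrations of real scenes above 0.9.
Raw (unnormalized) correlation is the default; `normalized = TRUE`
subtracts image means first, which helps under uneven illumination. The
displacement bound and the failure criterion are deliberately exposed as
configuration, since neither has a single principled value.

## Nucleus segmentation, morphometrics, QC

The default segmenter is a classical baseline: Gaussian smoothing
(`smooth_sigma_px = 8`) → Otsu threshold → hole filling → morphological
closing/opening with a disc brush (`mask_smooth_radius = 15` px) →
Euclidean-distance-transform watershed to split touching nuclei →
removal of objects under `min_area_px`. Heavy smoothing is intentional:
DAPI chromatin texture otherwise leaves ragged outlines that depress
circularity for correctly found nuclei. Any external segmenter can
replace the baseline by passing its label mask through `external_mask`;
the QC, radial and downstream stages are agnostic to the mask's origin.

Per nucleus we report area, equivalent circular diameter
$2\sqrt{A/\pi}$, perimeter, centroid and circularity
$4\pi A / P^2$. The perimeter uses a Crofton-style estimator — chord
counts along rows, columns and both diagonals, $P = \tfrac{\pi}{4}(N_h +
N_v + (N_{d1}+N_{d2})/\sqrt{2})$ — because naive boundary-pixel counting
overestimates $P$ enough to make a circularity threshold of 0.95
unreachable even for ideal discs. With this estimator a rasterized disc
of radius 50 px scores ≈ 0.99 (tested); very small labels (a few pixels)
can exceed 1, which is harmless since the size filter removes them.

QC flags (never deletes) nuclei with equivalent diameter < 10 µm **or**
circularity < 0.95. Two interpretation choices are worth stating:
"smaller than 10 microns" is read as equivalent *diameter* (an area of
10 µm² would exclude almost nothing), and the two criteria are treated as
independent exclusion rules — a small-but-round object is still excluded,
since either anomaly indicates a segmentation error. Border-touching
nuclei are retained. Both thresholds are configurable.

## Radial position

Per nucleus — independently of its neighbors — the Euclidean distance
transform of its binary mask is rescaled so the deepest pixel maps to 0
and the boundary pixels map exactly to 1, and subtracted accordingly:
radial position 0 is the nuclear center, 1 the periphery. Standard
distance transforms give boundary *foreground* pixels the value 1 (one
unit from background), not 0; the rescaling uses the per-nucleus min and
max so this off-by-one cannot tilt the scale. On a disc of radius $R$ the
coordinate is linear in the distance $d$ from the center — equal to
$d/R$ within 0.04 at $d/R \in \{0, .25, .5, .75, 1\}$ — and uniformly
placed points average $2/3$ (area weighting favors the periphery), both
verified against the rasterized geometry. Each nucleus is normalized
separately, so a small nucleus spans the same 0–1 range as a large one.

## Spot detection

FISH signals are compact, approximately Gaussian blobs of scale ~1–2 px
at 0.108 µm/px. Detection is by scale-normalized Laplacian of Gaussian:
candidates are 8-neighborhood local maxima of the negated response above a
threshold, pruned by non-maximum suppression within `min_separation_px`
(default 3), and refined to the intensity-weighted centroid of the
locally background-subtracted raw image in a $(2\lceil 2\sigma\rceil+1)^2$
window. Sub-pixel refinement matters: at 0.108 µm/px, a half-pixel error
is 0.054 µm against a 1.0 µm decision radius; measured localization RMSE
on the default simulated plate is well under 0.5 px.

The default threshold is absolute on the LoG response
(`spot_threshold = 2000` for the simulator's acquisition settings, where
true spots respond around 10⁴ and the noise floor tops out near 500); an
adaptive mode thresholds at `median + k·MAD` per image. The original
acquisition software tunes these per plate with visual feedback, so both
semantics are explicit parameters here rather than hidden heuristics.
Spots are assigned to the nucleus label under their nearest integer
pixel — no tolerance ring for spots just outside a mask — and spots over
background are dropped and counted (`detected = retained + dropped` is
asserted per field and channel).

## Allele-level analysis

Per cell and channel, spot counts are binned `0 / 1 / 2 / >=3`; the
expression class follows the RNA count (0 silent, 1 monoallelic,
2 biallelic, ≥3 multi). Cells are *selected* for allele analysis when
they pass QC, have exactly two DNA spots, and at most two RNA spots —
more of either indicates detection artifacts or segmentation faults.
RNA spots need only lie in a nucleus to be counted; no proximity to a DNA
spot is required for counting.

For each DNA spot of a selected cell, the minimum 2D Euclidean distance
to the cell's RNA spots (in µm) determines the class: `active` if
strictly below 1.0 µm, `inactive` otherwise, and `no_transcription` with
a missing distance when the cell has no RNA spot at all. The boundary is
strict: exactly 1.0 µm is inactive. Distances are 2D because the inputs
are maximum projections; no z term exists.

Radial distributions of active versus inactive alleles are compared with
the two-sided two-sample Kolmogorov–Smirnov test (asymptotic p-values via
`stats::ks.test`; the test suite cross-checks the D statistic against a
brute-force sup-ECDF computation). Because it is ambiguous whether
"inactive" should include alleles of cells with no RNA spot at all, the
report computes both versions: active vs inactive, and active vs
(inactive + no_transcription). No multiple-testing correction is applied;
p-values are reported raw. Count histograms are reported over all
QC-passing cells, while the activity analysis runs on selected cells only.

## The simulator: what it emulates, and what it does not

`simulate_plate()` renders square fields with elliptical nuclei
(semi-minor axis 5.5–7.5 µm, axis ratio ≤ 1.3, uniformly oriented,
non-overlapping with a small margin), a smooth DAPI profile plus low-pass
chromatin-like texture (the registration features), two Gaussian DNA
spots per nucleus strictly inside the ellipse, and RNA spots for active
alleles placed uniformly within 0–0.8 µm of their DNA spot — inside the
1.0 µm calling radius with margin; the offset range can be widened to
straddle the threshold for stress tests. Expression classes are drawn per
cell (silent/monoallelic/biallelic = 0.66/0.26/0.064 by default,
renormalized), matching how monoallelic and biallelic cells are reported
for a lowly expressed gene. False-positive RNA spots are Poisson per
nucleus (default rate 0.03), standing in for the few percent of cells
with more transcription sites than alleles seen in real screens; no
generative model for them is established, so the rate is an honest knob.
Camera noise is Poisson shot noise plus Gaussian read noise, applied
independently per imaging round; sequential mode translates the noiseless
scene by an integer truth shift (zero-filled), then re-noises.

Deliberately not modeled: optics-accurate PSFs, camera-specific noise
calibration, 3D structure, cell-cycle state, touching or overlapping
nuclei, autofluorescence and illumination gradients. Consequently,
passing tests demonstrate the *algorithms* are correct under controlled
conditions — they do not certify performance on real microscope images,
where segmentation and per-plate threshold tuning dominate difficulty.

Determinism: each field's RNG stream is derived from the configuration
seed and the field's plate coordinates, so any field can be regenerated
in isolation, and a config re-run reproduces the plate bit for bit. The
analysis path itself contains no randomness.

## Problem sizes and numerical choices

The validation suite uses a default plate of 1024² fields with 25 nuclei
each — dense enough to be realistic (about a third of the field area is
nuclear), small enough that a whole-plate run with several hundred nuclei
completes in a couple of minutes on one core. Statistical checks use 700
nuclei (expression-fraction recovery, three binomial standard errors),
100 random shifts (registration recovery), 10⁴ points (radial mean), and
40 seeded replicates (KS null calibration). The KS calibration runs at
the allele-record level — truth geometries rasterized by
`truth_label_mask()` with radial positions read off `radial_map()` —
since activity-independent placement is a property of the generator, and
rendering plus re-detecting 40 plates would only re-exercise stages
validated elsewhere.

Degenerate inputs have defined behavior: a blank DAPI image yields an
empty mask (not an error); a single-pixel nucleus has radial position 0;
a cell with no RNA spots gets `NA` distances; an all-constant correlation
map errors; negative distances error. Images are validated as
single-plane on load — z-stacks must be collapsed with `max_project()`
first, matching real-time projection at acquisition.

## Known limitations

* The classical segmenter needs contrast between nuclei and background
  and will merge heavily overlapping nuclei; the adapter hook exists
  precisely so a learned segmenter can take over on real data.
* Activity calling inherits the 1.0 µm rule's blind spot: an inactive
  allele within 1.0 µm of the *other* allele's RNA signal is called
  active. The simulator reproduces this intrinsic ambiguity; it is a
  property of the method, not of the implementation.
* Integer-pixel registration leaves up to half a pixel (0.054 µm) of
  systematic offset between rounds; negligible against the 1.0 µm radius
  but a real limit for finer colocalization questions.
* Asymptotic KS p-values are approximate for small allele counts; the
  null calibration shows the rejection rate stays near nominal at the
  group sizes a plate produces.
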