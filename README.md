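# hifishr

Allele-level analysis of high-throughput DNA/RNA FISH (HiFISH) plate
images in R.

In a diploid nucleus, a gene is present as two alleles. Labeling the locus
with a DNA FISH probe and its nascent transcript with an intron-targeted
RNA FISH probe makes it possible to ask, allele by allele, whether the gene
is being transcribed and where the allele sits in the nucleus. `hifishr`
implements the image-analysis side of that experiment for multiwell-plate
screens: hundreds of fields, three channels (DAPI, DNA probe, RNA probe),
acquired either in one hybridization round (simultaneous DNA/RNA FISH) or
in two rounds that must first be registered to each other (sequential
FISH).

## What the pipeline computes

1. **Registration** (sequential mode). The translation between the RNA
   round and the DNA round is estimated from the DAPI channel at the peak
   of the cross-correlation
   `C(Δr, Δc) = Σ A(r, c) · B(r + Δr, c + Δc)`
   over a bounded displacement search, and applied to the RNA image with
   zero-filled boundaries. An FFT path accelerates the search and is
   checked against the defining double sum.
2. **Nucleus segmentation and QC.** A classical baseline (Gaussian
   smoothing → Otsu threshold → hole filling → distance-transform
   watershed → small-object removal) produces a label mask; any external
   segmenter (e.g. a deep-learning model) can be plugged in through
   `external_mask`. Nuclei with equivalent diameter < 10 µm or circularity
   `4π·area/perimeter² < 0.95` are flagged as segmentation errors.
3. **Spot detection.** FISH signals are detected as local maxima of a
   scale-normalized Laplacian-of-Gaussian response, refined to sub-pixel
   positions by intensity-weighted centroids, and assigned to the nucleus
   under them; spots over background are dropped and counted.
4. **Radial position.** Per nucleus, the Euclidean distance transform of
   its mask is normalized so the nuclear center maps to 0 and the
   periphery to 1 — a size-free radial coordinate for every spot.
5. **Allele activity.** Cells with exactly two DNA spots and at most two
   RNA spots are selected; each DNA spot is classified from its minimum
   Euclidean distance to an RNA spot of the same cell: `active`
   (< 1.0 µm), `inactive` (≥ 1.0 µm), `no_transcription` (no RNA spot in
   the cell, distance `NA`). Radial distributions of active versus
   inactive alleles are compared with a two-sided two-sample
   Kolmogorov–Smirnov test.

A fully ground-truthed synthetic plate simulator (`simulate_plate()`)
renders DAPI/DNA/RNA fields with configurable expression fractions, noise,
and inter-round shifts, so every stage above is testable without a
microscope.

## Worked example

```r
library(hifishr)

cfg <- simulation_config(n_fields = 2, nuclei_per_field = 25, seed = 11)
sim <- simulate_plate(cfg, wells = "A01", out_dir = "demo_plate",
                      mode = "simultaneous")
res <- run_pipeline(sim$manifest)
print(res)
#> HiFISH pipeline run (simultaneous mode)
#>   cells: 50 segmented, 38 QC-pass, 38 selected
#>   expression (selected cells): silent 60.5%, mono 31.6%, bi 7.9%, multi 0.0%
#>   alleles: active 21.1%, inactive 18.4%, no transcription 60.5%
#>   radial, active vs inactive: Two-sample KS: D = 0.2500, p = 0.7391 (n = 16 vs 14)
#>   radial mean +- sd: active 0.52 +- 0.21, inactive 0.57 +- 0.14
write_results(res$tables, "demo_results")
```

Reading the output: 50 nuclei were segmented and 38 passed morphometric
QC and the two-DNA-spot selection; of those, 60.5% showed no
transcription site (silent), 31.6% one (monoallelic) and 7.9% two
(biallelic). At the allele level, 21.1% of DNA spots had an RNA signal
within 1.0 µm. The KS comparison of radial positions (0 = nuclear center,
1 = periphery) finds no positional difference between active and inactive
alleles (p = 0.74) — as expected here, since the simulator places alleles
independently of activity.

The same run is available from a shell:

```sh
Rscript inst/cli/hifish.R simulate --out demo_plate --seed 11 \
    --n-fields 2 --nuclei-per-field 25
Rscript inst/cli/hifish.R analyze --manifest demo_plate/manifest.csv \
    --out demo_results
Rscript inst/cli/hifish.R report --results demo_results --out demo_report
```

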