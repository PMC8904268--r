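# occuscore

Quantifying cell-population shifts in the developing lung, two ways:

1. **Marker-gene scoring of bulk transcriptomes.** Fetal tracheal
   occlusion (TO) — a surgical therapy evaluated for congenital
   diaphragmatic hernia — expands the airway basal cell population
   (roughly 1.5% → 2.5% of lung cells). With only bulk RNA-seq of whole
   lung available, the shift is detectable through cell-type marker
   genes: for gene *g* and group *k*, the relative expression is
   *r(g,k) = median FPKM in k / median FPKM in control*, and a cell
   type's panel of marker ratios is summarized (median) and compared
   across groups with Kruskal–Wallis + Dunn (≥ 3 groups) or the exact
   Wilcoxon rank-sum test (2 groups).
2. **Calibrated quantification of marker-positive nuclei.** In
   fluorescence sections, nuclei are segmented (Otsu threshold, hole
   fill, 8-connected labelling, size gate), the marker channel is
   thresholded at the 99.9th percentile of a negative-control image, and
   each nucleus is called positive under a localization-aware rule
   (nuclear / cytoplasmic / apical). The readout is
   *positive nuclei / total nuclei*.

The package also implements the associated read-count and
differential-expression gates (all-samples and k-of-n dialects; padj < α
strict, |FC| ≥ t inclusive), self-contained tie-corrected rank statistics,
and seeded synthetic-data generators — bulk expression as noisy linear
mixtures of cell-type profiles with known mixing proportions, and
microscopy fields of disk-like nuclei with known positive fractions — so
every stage is validated against ground truth. A `markers derive` /
`score bulk` / `filter de` / `quantify images` / `simulate *` command-line
interface is included (`inst/exec/occuscore`).

Who it is for: researchers tracking relative cell-type abundance in bulk
tissue RNA-seq against a control group, and anyone needing a reproducible,
negative-control-calibrated percent-positive-nuclei measurement.

## Worked example

```r
library(occuscore)

# bulk: the default scenario simulates the measured basal expansion
# (1.5% -> 2.5%, 6 samples/group, 20 markers for each of 11 cell types)
sim <- simulate_bulk(bulk_sim_params(seed = 7))
rel <- relative_expression(group_medians(sim$expr, sim$design), "control")
panel <- compare_panel(score_cell_types(rel, sim$truth$signatures),
                       alpha = 0.05)
panel
#> cell_type_score_panel: 11 cell types x 2 groups (control = control)
#>   basal              (20 genes) control=1, TO=1.61  [KW p=7.35e-09; sig vs control: TO]
#>   club               (20 genes) control=1, TO=0.981  [KW p=0.563]
#>   ciliated           (20 genes) control=1, TO=0.97  [KW p=0.247]
#>   goblet             (20 genes) control=1, TO=0.916  [KW p=0.0828]
#>   AT1                (20 genes) control=1, TO=0.989  [KW p=1]
#>   ...

# images: 512x512 field, 50 nuclei, nuclear marker on 25% of them
isim <- simulate_image(image_sim_params(positive_fraction = 0.25, seed = 7))
cal <- calibrate_marker_threshold(isim$negative_control)  # 99.9% quantile
quantify_image(isim$image, cal)
#> quant_result: 13/50 nuclei positive (26.0%)
```

The basal panel's summary ratio (1.61) is the median over its 20 marker
genes of group-median expression relative to control — near the
pure-marker closed form 0.025/0.015 = 1.67, slightly diluted by background
expression — and the only cell type flagged significant, as simulated. The
image result recovers the simulated positive count exactly
(round(0.25 × 50) = 13, half away from zero).

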