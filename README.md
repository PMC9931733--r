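# aqpolar

Spatial-transcriptomics analysis of astrocyte endfoot mRNA polarization.

Aquaporin-4 (AQP4) is normally concentrated at the perivascular endfeet of
astrocytes; in Alzheimer's-model (APP/PS1) mice this polarization is lost.
On a Visium-style spot lattice the endfoot compartment of a perivascular
astrocyte falls into the adjacent vessel-containing (blood–brain-barrier,
BBB) spot, so the endfoot share of a gene's transcripts can be estimated
per astrocyte as the **gene ratio**

    R = b / (a + b),   maximized over adjacent BBB spots,

where `a` is the count in the astrocyte (AC) spot and `b` the count in a
neighboring BBB spot. `aqpolar` is for researchers who want to compute and
stress-test this statistic and the workflow around it:

* **Gating** — AC spots (`Gfap > 0 & Aqp4 > 0`), BBB spots
  (`Pecam1 > 0 & Flt1 > 0`), CSF-facing region exclusions, configurable
  double-positive policy.
* **Hex-lattice pairing** — Space Ranger array coordinates, neighbors
  `(r, c±2)` and `(r±1, c±1)`, AC spots without a BBB neighbor dropped.
* **Polarization** — per-AC gene ratios, group means, fold changes,
  one-way ANOVA + LSD post hoc, ratio–ratio Pearson fits.
* **AEG screening cascade** — astrocyte markers (reference fold change
  > 100) → astrocyte endfoot genes (ratio > 0 in > 60% of perivascular
  AC) → AD-related AEGs (mean-ratio fold change deviating from 1 by
  > 0.15).
* **Gene-set scores** — binned-control module scores (24 expression bins,
  100 controls per set gene) with thresholded group comparison.
* **Statistics** — BH adjustment, rank-sum DE screen (|FC| > 1.5,
  adjusted p < 0.05), 2^(−ΔΔCT) qPCR fold changes; all oracle-tested.
* **Immunofluorescence** — CD31 vessel (lumen-enclosing ring) detection,
  top-1% AQP4 masks, and the proportion of vessels coated on more than a
  quarter of their perimeter.
* **Synthetic data** — a ground-truth Visium-like tissue generator
  (known per-gene endfoot allocation π per group) and a two-channel
  fluorescence-field generator, so the whole pipeline is testable
  offline.

File formats: MatrixMarket + features/barcodes TSV + tissue positions CSV
bundles (`load_bundle`/`write_bundle`), GMT gene sets (`read_gmt`), 16-bit
two-channel TIFF + JSON annotations (`read_if_field`/`write_if_field`),
TSV outputs with a JSON run manifest (`save_results`).

## Worked example

The demo generates three synthetic samples (WT, APP/PS1, APP/PS1+MOX) in
which the true WT endfoot share of *Aqp4* is 0.7, reduced by a factor
0.66 in APP/PS1 and partially restored (0.9) under treatment, then runs
the full pipeline:

```r
library(aqpolar)
out <- run_demo(seed = 42)
subset(out$summary, gene == "Aqp4")
#>         group   n mean_ratio fold_change  anova_p lsd_p_vs_ref
#> 1     APP/PS1 240      0.451       0.653 9.85e-42     1.61e-41
#> 2 APP/PS1+MOX 240      0.613       0.887 9.85e-42     3.32e-06
#> 3          WT 240      0.691       1.000 9.85e-42           NA
```

The recovered mean ratios (0.691, 0.451, 0.613) track the planted
allocations (0.70, 0.462, 0.63), the fold changes recover the planted
effects (0.66, 0.9), and both group differences are detected (ANOVA and
LSD vs WT). The screening cascade and the truth table are returned
alongside:

```r
out$screen
#> AEG screening cascade:
#>   markers:         12
#>   AEGs:            12
#>   AD-related AEGs: 12
truth_summary(out$truth, "APP/PS1", "WT")[1, ]
#>   gene fold_change
#> 1 Aqp4        0.66
```

(All 12 default candidate genes are planted with the same disease effect,
so all 12 are correctly called AD-related; the screening acceptance check
uses 200 candidates of which only 20 are affected.)

For the immunofluorescence arm:

```r
f  <- generate_if_field(10, c(rep(0.3, 6), rep(0.1, 4)), noise_sd = 0, seed = 5)
vs <- detect_vessels(f$cd31)
quantify_coating(vs, top_percent_mask(f$aqp4, 1))
#> vessel coating: 10 vessels; proportion coated = 0.600 (threshold 0.25, radial probe, radius 3 px)
```

Six of ten vessels were constructed with 30% of their perimeter coated
(above the quarter rule) and four with 10%, so the coated proportion is
exactly 0.6.

## Package layout

* `R/synth.R`, `R/vesselcoat.R` — synthetic tissue / fluorescence
  generators and the coating quantifier
* `R/spotio.R` — bundle, GMT, TIFF and results I/O
* `R/gating.R`, `R/polarization.R`, `R/aegscreen.R`, `R/genescore.R`,
  `R/stats.R` — the analysis stages
* `R/pipeline.R` — `analysis_config()`, `run_pipeline()`, `run_demo()`
* `vignettes/aqpolar-methods.Rmd` — the model, its assumptions, and every
  numerical design choice
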