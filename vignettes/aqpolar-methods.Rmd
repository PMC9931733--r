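---
title: "Quantifying astrocyte endfoot mRNA polarization from spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying astrocyte endfoot mRNA polarization from spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqpolar)
```

## The problem

Aquaporin-4 (AQP4) water channels are normally concentrated — "polarized" —
at the perivascular endfeet of astrocytes, the terminal processes that wrap
brain capillaries. Loss of this polarization accompanies Alzheimer's-type
pathology and impairs perivascular clearance. Because *Aqp4* mRNA is
transported into the endfoot for local translation, the *spatial*
distribution of the transcript itself carries a signal: on a Visium-style
spot lattice (spots ~55 µm, pitch ~100 µm), the endfoot compartment of a
perivascular astrocyte falls into the neighboring vessel-containing spot
rather than the astrocyte-body spot.

`aqpolar` turns that observation into a measurable statistic and ships the
complete workflow around it: spot gating, lattice pairing, the gene-ratio
statistic with group comparisons, an endfoot-gene screening cascade,
gene-set scoring, the supporting statistics, and an immunofluorescence
quantifier for the protein-level counterpart. A synthetic-data generator
with known ground truth makes every stage testable without any external
download.

## Spot gating

Perivascular astrocyte (**AC**) candidates are spots with *Gfap* > 0 **and**
*Aqp4* > 0 on **raw counts**; blood-brain-barrier (**BBB**) spots have
*Pecam1* > 0 and *Flt1* > 0. Detection thresholds of zero on raw counts are
deliberate: ">0" is a detection call, and normalization could only turn
detected transcripts into fractions, never change positivity.

Regions facing the cerebrospinal fluid — glia limitans, ependyma, choroid
plexus — express astrocyte markers without being perivascular, so they are
excluded from the AC gate (choroid plexus also from the BBB gate). The
exclusion list is a configurable set of free-string region labels, not a
hard-coded anatomy.

A spot can pass both gates. The default `overlap_policy = "bbb"` assigns it
to the barrier compartment and removes it from AC: counting the same spot
as both its own astrocyte body and another astrocyte's endfoot target would
double-count transcripts sitting in the BBB spot. `"ac"` and `"drop"` are
available for sensitivity analyses.

## Lattice adjacency

Spots sit on a hexagonal lattice in Space Ranger array coordinates, where
the six neighbors of `(r, c)` are `(r, c±2)` and `(r±1, c±1)`. Adjacency is
defined by this rule — one lattice step by default — rather than by a
micrometer radius; pixel coordinates (100 µm pitch) are carried along as
metadata and a test verifies that the rule coincides with
minimal-pixel-distance neighbors. One step is the conservative reading of
"adjacent" given that astrocyte processes span roughly twice the spot
pitch; `max_steps` widens the radius in whole steps, counted on the ideal
lattice so a missing intermediate spot does not break two-step adjacency.
An AC spot with no BBB neighbor is not perivascular and is dropped.

## The gene ratio

For an AC spot with count $a$ of a gene and an adjacent BBB spot with
count $b$, the gene ratio is

$$ R = \frac{b}{a + b} \in [0, 1], $$

maximized over the AC spot's BBB neighbors (an astrocyte reaches the
vessel it actually touches; the maximum picks the strongest endfoot
signal). $R$ estimates the fraction of the astrocyte's transcripts in the
endfoot compartment. Properties that the test suite enforces: $R$ is
non-decreasing in any $b$, non-increasing in $a$, invariant to common
scaling, and adding a neighbor never decreases it.

Three numerical choices matter:

* **Raw counts within the pair.** The two spots sit adjacent on the same
  section and capture area; their capture efficiencies are as comparable
  as spatial data allows, and a ratio of raw counts is then a direct
  binomial-allocation estimate. A depth-normalization flag exists but is
  off by default, since dividing by total spot depth would re-introduce
  composition effects from unrelated genes.
* **0/0 is undefined, not zero.** An astrocyte in which the gene is
  detected in neither compartment carries no information about
  *allocation*; imputing 0 would bias the polarization estimate downward
  exactly for low-expression genes. Dropped records are counted in a QC
  attribute.
* **Ties** in the neighbor maximum resolve to the lowest barcode, so
  outputs are byte-stable.

Group summaries report per-gene means, the fold change of group mean over
the reference (WT) mean, one-way ANOVA across groups, and LSD pairwise
p-values against the reference. Records are pooled across samples by
default — the reported quantity is a property of the astrocyte population —
with `per_sample = TRUE` available to average within samples first when
samples, not astrocytes, are the experimental unit.

## The AEG screening cascade

Three nested stages, each with the strict inequalities of the filter
definitions:

1. **Astrocyte markers**: genes whose astrocyte mean expression in a
   vascular cell-type reference exceeds 100-fold the largest mean among
   the other BBB cell types. A cell type that never expresses a gene would
   make the fold change divide by zero, so zero denominators are replaced
   by a small pseudo-mean (10⁻⁶ of the table maximum): a perfectly
   astrocyte-specific gene should pass the screen, not crash it.
2. **Astrocyte endfoot genes (AEGs)**: markers whose gene ratio is
   positive in strictly more than 60% of perivascular astrocytes.
   "Endfoot-positive" is implemented as ratio > 0 — any detected endfoot
   signal. The denominator is the total perivascular AC population of the
   reference (WT) group, so astrocytes in which the gene is undetected
   count as endfoot-negative; using the WT population keeps the gene
   definition independent of disease state (both choices are arguments).
3. **AD-related AEGs**: AEGs whose disease-group mean-ratio fold change
   deviates from 1 by strictly more than 0.15. The deviation is unsigned
   by default — the rule as stated is symmetric, and on real data
   reductions dominate anyway — with `direction = "down"` available.

The chain AD-related ⊆ AEGs ⊆ markers holds by construction, and raising
any stage threshold can only shrink that stage's output.

## Gene-set (module) scores

Per spot, the score is the mean log-normalized expression of the set genes
minus the mean over expression-matched control genes: counts are
depth-normalized to 10,000 per spot and log1p-transformed, genes are
ranked by average expression and cut into 24 equal-frequency bins, and
each set gene draws 100 controls from its own bin (seeded). Controls are
drawn **without replacement, capped at the bin size**: when a bin is
smaller than the control count the whole bin serves as the control pool,
which makes small-panel scoring deterministic and exactly reproducible by
hand (the test suite exploits this). Binning breaks ties by gene id, so
scores are invariant to the order of genes in the panel and in the set.

The thresholded comparison retains spots with score strictly above a
cutoff (0.8 by default, config-exposed since no principled value exists)
and runs ANOVA + LSD on the retained scores; `-Inf` gives the unfiltered
comparison.

## Statistics

The primitives are thin, contract-checked wrappers over the standard
machinery: one-way ANOVA (with exact closed-form guards for the
zero-variance and identical-group corners, where the fitted F would
otherwise be floating-point fuzz), LSD pairwise t tests on the pooled
within-group mean square, Benjamini–Hochberg adjustment, Pearson
correlation with a least-squares line, and a Wilcoxon rank-sum
differential-expression screen with the |FC| > 1.5 and adjusted p < 0.05
filter. "|FC| > 1.5" is two-sided on the log scale, and a complete
knockout (fold change 0 or ∞) passes the magnitude rule. Each primitive is
tested against an independent brute-force implementation (explicit sums of
squares, step-up by hand, closed-form Pearson sums) to 10⁻¹⁰ on random
instances, and the ANOVA null rejection rate is calibrated at the nominal
5% over 1000 simulations.

## Immunofluorescence vessel coating

Vessels are the vacuole-like structures in the CD31 channel: connected
CD31-positive components enclosing a lumen of at least `min_lumen_px`
pixels (filled blobs are rejected). Vessel detection thresholds at half
the channel maximum by default; the top-1% intensity rule applies to
**AQP4 positivity**, implemented as strictly above the 99th percentile of
the whole field (so a uniform channel yields an empty mask and ties at
the threshold are excluded).

A vessel is "coated" when strictly more than a quarter of its
outer-perimeter pixels are supported by nearby AQP4 signal. The pairing of
perimeter pixels to AQP4 pixels is the one genuinely open design choice
here. An isotropic disk probe (any AQP4 pixel within `pairing_radius_px`)
bleeds tangentially around the ends of a coated arc by roughly the probe
radius on each side, which distorts the perimeter fraction by several
pixels. The default is therefore a **radial-sector probe**: an AQP4 pixel
supports perimeter pixel *p* only if it lies within the pairing radius
*and* within 0.75 px of the outward radial line through *p*. This measures
"how much of the perimeter has AQP4 immediately outside it", recovers
constructed coverage fractions to within one perimeter-pixel quantum, and
is monotone in the radius; `pairing_mode = "disk"` restores the isotropic
probe. A quadrant-style reading of the quarter rule can be emulated by
comparing per-vessel fractions rather than the built-in flag.

The field protocol samples six 0.2 mm × 0.2 mm regions (seeded, without
overlap), assigns vessels to regions by centroid, and reports per-region
proportions with their mean alongside the whole-field proportion.

## The synthetic generator

`generate_tissue()` emulates exactly the structure the analysis consumes:

* a hex lattice with contiguous region bands (including a choroid-plexus
  band to exercise the exclusions);
* vessel spots expressing *Pecam1*/*Flt1*, each paired with exactly one
  fresh neighboring astrocyte spot expressing *Gfap*/*Aqp4*. Placement
  forbids a second vessel adjacent to an existing astrocyte, so each
  generated astrocyte has exactly one vessel neighbor and the expected
  observed ratio equals the allocation parameter analytically; the
  analysis-side max-over-neighbors rule is still exercised by the gating
  of double-positive spots;
* per candidate gene and group, a pair-total expected count (default 10)
  split between the vessel spot (fraction π) and the astrocyte spot
  (1 − π), then negative-binomial noise (size 10 by default; variance =
  µ + µ²/size, Poisson at `Inf`). In the Poisson limit the conditional
  distribution of the vessel count given the pair total is binomial(π),
  so the mean observed ratio converges to π exactly; at size 10 the
  residual bias is below 0.01 for the default parameters;
* marker counts floored at 1 wherever their allocated mean is positive,
  so generated spots always pass their own gates (a gene allocated π = 1
  correctly leaves its astrocyte counts at zero);
* background genes expressed everywhere with baseline means log-spaced
  from 0.5 to 20 — a realistic dynamic range that makes expression-bin
  control matching meaningful — plus a 5% sprinkling of non-perivascular
  astrocytes, placed away from vessels, to exercise the
  no-BBB-neighbor drop;
* geometry and counts are drawn from separate derived seeds, so the
  placement is invariant to the count-model parameters and pre-noise pair
  totals do not depend on π.

The default group structure **is** the study condition the package is
demonstrated under: WT endfoot share π = 0.7 for *Aqp4*, a multiplicative
disease effect δ = 0.66 (APP/PS1) and a treatment effect δ′ = 0.9
(APP/PS1+MOX), i.e. a partial restoration. The generator returns a truth
table (gene × group, expected ratio = π) so recovery is checked against
ground truth, not against itself.

What the generator does **not** emulate: brain anatomy beyond region
labels, realistic whole-transcriptome covariance, segmentation-scale cell
mixing within spots, or image optics (the fluorescence fields are
geometric annuli with optional Gaussian noise). Passing tests therefore
demonstrate that the estimators recover their targets under the stated
allocation model — not that the biological effect sizes in any real tissue
match these defaults.

The companion `generate_if_field()` paints annular CD31 vessels and AQP4
on a contiguous arc of each vessel's outer perimeter covering exactly the
requested pixel fraction, choosing the arc split so the default radial
probe recovers exactly the painted pixels.

## Problem sizes and reproducibility

The packaged checks run at the sizes the estimators need rather than at
atlas scale: ratio recovery and the screening cascade use three groups of
2000 perivascular astrocytes (a 210 × 230 lattice per sample), score
calibration uses 100 random 20-gene sets on a 1000-spot sample, the null
calibration uses 1000 simulated ANOVA instances, and the
immunofluorescence check uses ten constructed vessels. Every random stage
takes an explicit seed; `run_pipeline()` writes stage tables plus a
manifest (configuration, seed, row counts, no timestamps) so a rerun with
the same inputs is byte-identical.

## Known limitations

* A spot is larger than a capillary: endothelial transcripts and endfoot
  transcripts share the BBB spot, so the gene ratio is a compartment
  allocation estimate, not a subcellular measurement, and genes expressed
  by endothelium inflate their own "endfoot" share. The marker-screen
  stage (astrocyte-specific 100-fold enrichment) exists precisely to keep
  such genes out of the AEG candidate list.
* The ratio is descriptive; no transport mechanism is inferred.
* Pooled-record tests treat astrocytes as independent; spatial
  autocorrelation within a section would make the reported p-values
  anticonservative on real data (the per-sample mode is the conservative
  alternative).
* The screening thresholds (100-fold, 60%, 0.15-fold) are the field's
  stated filter values, not optimized quantities; sensitivity/FDR checks
  verify the cascade logic under the generator's conditions only.

```{r demo, eval = FALSE}
out <- run_demo(seed = 42)
subset(out$summary, gene == "Aqp4")
out$screen
```
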