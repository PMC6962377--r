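---
title: "Methods: quantifying glioblastoma cell responses to low compressive solid stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying glioblastoma cell responses to low compressive solid stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechanomir)
```

## Background

Uninhibited growth of a glioblastoma (GBM) inside the rigid skull compresses
the tumour and the surrounding parenchyma. This compressive solid stress
(CSS) is largest at the tumour border and decays radially, so the invasive
cells occupying the centimetre-scale margin around a resection cavity — the
region where most recurrences arise — experience low stresses, on the order
of tens of pascals. `mechanomir` implements the downstream quantification
for an *in vitro* model of that niche, in which GBM cell lines (LN229,
U251) are compressed at 13–115 Pa and three readouts are taken: collective
migration in a wound-healing gap assay, single-cell morphology, and the
transcriptomic response culminating in a miRNA–mRNA pathway interaction
analysis.

The package operates on tabular or image inputs that emulate what the wet
lab produces (segmented areas, per-cell shape tables, an expression table
with fold changes and FDR, per-miRNA pathway/target exports). A
synthetic-data module generates all of these with known ground truth, so
every stage is testable end to end without raw microscopy or array data.

## Wound closure

For a gap of initial cell-free area $A_i$ and final area $A_f$,

$$\mathrm{WC} = \frac{A_i - A_f}{A_i},$$

a unitless fraction that is invariant to the area scale. Because migration
varies day to day, conditions are analysed as matched pairs against their
same-day control:

$$\Delta \mathrm{WC} = \overline{\mathrm{WC}_{exp} - \mathrm{WC}_{ctrl}},$$

reported in percentage points. `differential_closure()` tests the paired
differences with a one-sided t-test (direction: more closure than control)
and flags significance at $\alpha = 0.05/5 = 0.01$, Bonferroni-corrected
for the five condition-versus-control comparisons of a pressure series.
The test runs on the raw paired differences; normalising closures first
would entangle the day effect the pairing exists to remove. Pairing is by
explicit replicate id, never row order. The derived convenience
`fold_increase()` converts a control closure and a differential closure
into the "x-fold more gap closed" figure.

Segmentation of the cell-free area (`segment_cell_free_area()`) is a
deliberately plain recipe: global Otsu threshold on intensity,
morphological closing with a 3-pixel disc, connected components, largest
dark region. The upstream study performed this step interactively in an
image tool without recording parameters, so the package fixes one
documented, deterministic recipe and isolates it behind a single function
where alternatives can be swapped in. On synthetic pairs the recipe
recovers generator truth areas to within ~1%, and the end-to-end pipeline
recovers generator closures within ±2 percentage points.

## Aspect-ratio morphometrics

Cell shape is summarised by the aspect ratio (AR), the major/minor axis
ratio of the moment-equivalent ellipse (`measure_shapes()`); AR = 1 is a
perfect circle, and cells with AR ≥ 2 are called elongated
(`percent_elongated()`). Objects touching the image border are excluded
automatically; dividing cells cannot be recognised from a mask alone, so
they are accepted as a pre-set exclusion flag in tabular input.

Since AR ≥ 1 by construction, distributions are modelled on the shifted
variable $x = \mathrm{AR} - 1$ as a one- or two-component lognormal
mixture:

$$f(x) = \sum_{i} \frac{a_i}{x\,\sigma_i\sqrt{2\pi}}
  \exp\!\left(-\frac{(\ln x - \mu_i)^2}{2\sigma_i^2}\right),$$

whose component peak sits at

$$m = e^{\mu - \sigma^2} + 1 .$$

`fit_ar_pdf()` fits the mixture to a density histogram by unweighted least
squares. Numerical choices, each of which mattered in practice:

* **Binning** (`ar_histogram()`): fixed width 0.1 AR from 1 to the 99.5th
  percentile. A fixed width keeps SSE comparable across conditions; the
  upper trim stops a handful of extreme cells from dictating the support.
* **Bin-averaged model evaluation**: the model predicts each bin's CDF
  increment divided by the bin width — the quantity a density histogram
  estimates — rather than the density at the bin midpoint. Midpoint
  evaluation biases sharply peaked components at this bin width, and the
  resulting lack of fit is exactly what a spurious second component would
  absorb.
* **Initialisation**: method-of-moments on the binned sample for one term;
  a 2-means split of $\log x$ for two terms; five jittered multistarts;
  bounds $a \in [0, 2]$, $\sigma \in [0.01, 2]$. The best converged start
  by SSE wins, making the fit deterministic for a given histogram.
* **Model selection** (`select_model()`): the fits are compared by SSE
  (on a shared histogram the R² ranking is the same comparison restated).
  Three extra parameters reduce SSE even on pure noise, so the 2-term
  model must pass an extra-sum-of-squares F-test at a deliberately
  conservative $\alpha = 10^{-3}$, and its minor component must carry at
  least 5% of the scale weight — a subpopulation below that is a blip,
  not a population, and unweighted least squares is otherwise happy to
  park an ultra-narrow component on a single noisy bin.
* **Degenerate inputs**: zero-variance histograms, fewer than 8 bins, or
  fewer than 50 cells raise a fit error; if only the 2-term fit fails,
  `fit_ar_mixture()` falls back to the 1-term model with a warning.
* **Relevance**: a fitted secondary mode below AR = 2
  (`flag_relevant_secondary()`) describes rounded cells and is not treated
  as an elongated subpopulation, mirroring how sub-threshold secondary
  peaks are discounted in the source analysis.

A known limitation: the least-squares objective is unweighted (residual
variance actually scales with bin density), which on heavy-tailed unimodal
samples can admit a weak, sub-threshold second component. These are
exactly the fits the relevance flag discounts, so downstream conclusions
about elongated subpopulations are unaffected.

## Differential-expression filtering

`filter_de()` applies the triple threshold used to call differential
expression from the upstream array console: $p < 0.05$, FDR $< 0.05$,
$|\mathrm{FC}| > 2$, all strict. Fold changes use the signed convention
(magnitude ≥ 1, sign giving direction). Both the p and FDR gates are
exposed as arguments because the upstream reporting is ambiguous about
whether the coding-gene list was additionally gated on raw p; the default
applies both. FDR is consumed, never computed here — the package emulates
a finished multiple-testing step, it does not redo it.
`split_by_type()` partitions survivors into coding genes and precursor
miRNAs (the unit of the interaction analysis), routing unknown types to
`other` with a warning.

## miRNA–mRNA pathway interaction analysis

For each differentially regulated precursor miRNA, a pathway/target export
(emulating a per-miRNA pathway-database download) lists enriched pathways
with an enrichment p-value and the miRNA's target genes in each pathway.
`score_interactions()` cross-references these exports with the DE mRNA
list and scores each (miRNA, pathway) node:

* **intersection** — the export's enrichment p is below 0.05. The
  significance call is read from the export, as supplied by the database,
  not recomputed.
* **percent overlap** — differentially regulated targets as a percentage
  of all targets in the pathway: how *many* of the miRNA's levers in that
  pathway moved.
* **cumulative absolute FC** — the summed $|\mathrm{FC}|$ of the
  differentially regulated targets: how *hard* they moved. Because the
  upstream filter enforces $|\mathrm{FC}| > 2$, this is always at least
  twice the DE-target count.

Duplicate export rows consolidate before scoring: identical
(miRNA, pathway, database) rows merge by target-set union and minimum
enrichment p, then multi-database listings collapse to one node per
(miRNA, pathway). Reported miRNA ids pass through substitution rules
(`apply_substitutions()`) first, mapping host-gene entries (`*-HG`) and
precursor variants with identical mature sequences onto the ids pathway
databases index.

Pathways are assigned to one of seven functional groups — Cancer,
Motility, DNA Repair, Cell Cycle, Apoptosis, Miscellaneous, Canonical —
by ordered inclusion/exclusion keyword rules (`pathway_group_rules()`,
`classify_pathway()`). Rule order and the DNA Repair exclusion of
"signaling" ensure, e.g., that an "ATM signaling network" pathway is
Canonical while "ATM-dependent DNA damage response" is DNA Repair;
Miscellaneous is the guaranteed fallback, so classification is total and
stable. The shipped keyword sets are reconstructions from the pathway
names cited in the source analysis (its full criteria table is
supplementary material); the rules are an ordinary tibble a lab can
version and edit.

Group summaries (`aggregate_interactions()`) average node values over
*all* nodes, zeros included — a pathway a miRNA targets whose targets did
not move still counts — which is what keeps group means small and
comparable across groups of different sizes. Group differences are tested
with one-way ANOVA plus Tukey–Kramer HSD at $\alpha = 0.05$
(`compare_interaction_groups()`). Heat-map matrices for the three metric
views are exported with deterministic ordering (miRNAs grouped by GBM
relevance when annotated; pathways blocked by functional group) via
`export_heatmaps()` and plotted with `plot_interaction_heatmap()`.

## The synthetic-data generators

The generators define the conditions under which the package is tested.

**Condition presets** (`condition_presets()`) encode ten conditions (five
per cell line). The aspect-ratio mixtures are built by inverting the mode
formula, $\mu = \ln(m - 1) + \sigma^2$, from each condition's published
peak locations; the two quoted secondary variances ($\sigma^2 = 10^{-4}$
at 23 Pa, $1.5\times10^{-3}$ at 47 Pa) are used verbatim. The remaining
dispersions and weights are not published; they are fixed, documented
constants chosen once so that conditions with a published elongated-cell
fraction reproduce it exactly in expectation (LN229 agar 21.0%, LN229
23 Pa 39.1%, U251 115 Pa 5.8%; the U251 control uses the U251-average
33.0%), with moderate dispersions (σ ≈ 0.6 for LN229, up to ≈ 1.2 for the
heavier-tailed U251 line) elsewhere. Wound-closure fractions for
conditions without a published value are plausible fixed constants.
All randomness flows through explicit seed arguments (default 42).

**Wound pairs** (`simulate_wound_pair()`) are 1000×1000 px (configurable)
grayscale images at 1.61 µm/px — a 4× objective class — with a vertical
dark band of the requested width over a bright speckled lawn, plus sparse
debris/dark-pixel noise that the morphological cleanup must remove. The
final band width is rounded so the true area ratio equals
$1 - \mathrm{closure}$ up to one pixel of rounding, and truth areas are
recorded in a sidecar.

**Expression sets** (`simulate_expression_set()`) contain exactly `n_de`
true positives (|FC| uniform above 2, p and FDR below 0.05) among nulls
built to fail the triple filter by either a small fold change or a
non-significant FDR. **Pathway databases** (`simulate_pathway_db()`) mint
pathway names from group-specific keyword pools (asserting the classifier
round-trip at generation time), attach one of four source-database labels,
and draw target lists from the supplied feature universe.

What the generators do *not* emulate — and therefore what passing tests do
not show about real data: real microscopy artifacts (uneven illumination,
out-of-focus debris, ragged wound edges), probe-level array noise and the
correlation structure of real transcriptomes, real pathway-database
content and its version drift, and curved or textured wound boundaries.
Published heat-map grand totals and extreme node values depend on the real
microarray and database version and are deliberately out of reach; the
package instead verifies the scoring machinery against brute-force oracles
on synthetic databases.

## Problem sizes and reproducibility

The shipped tests run the morphometric recovery at the study's own scale —
n = 2000 cells per sample, 20 seeds across all ten presets (median
secondary-mode error < 0.1 AR at 23 Pa; selected-model R² ≥ 0.91 in ≥ 90%
of runs) — and the wound pipeline on 400×400 px images, sizes chosen to
exercise every code path at full statistical fidelity while keeping a
complete run in tens of seconds. `run_pipeline()` writes every table with
a provenance header (package version, seed, configuration hash) and is
byte-reproducible for a fixed configuration and seed.
`scripts/acceptance.R` recomputes the headline quantities (the 23 Pa
secondary mode and the minimum fit R² across presets) from scratch.
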