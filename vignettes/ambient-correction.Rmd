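---
title: "Ambient RNA correction for per-sample sc-DGE: model, thresholds, and the simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ambient RNA correction for per-sample sc-DGE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastcar)
library(dplyr)
```

## The contamination model and what the correction assumes

Droplet scRNA-seq partitions a cell suspension that always contains
cell-free mRNA released by lysed cells during dissociation. Every droplet —
with or without a cell — captures a sample of this ambient pool. Two
consequences follow:

* **Empty droplets are pure soup.** Libraries with very low total UMI
  counts contain no cell; their counts are draws from the ambient pool at
  the per-droplet capture rate. They are a direct, per-sample measurement
  of the contamination.
* **Every cell carries the same soup.** A cell library is the superposition
  of native expression and an ambient draw of about the same size as an
  empty droplet's.

The correction implemented here uses the first fact to undo the second.
For one sample, with `thE` the empty-library UMI ceiling and `frAA` the
contamination-chance gate:

1. Ambient libraries: all libraries with total UMI $\le$ `thE`
   (inclusive).
2. Per gene $g$: $gMax^g = \max_j \; counts[g, j]$ over ambient libraries
   $j$, and $frC^g$ = fraction of ambient libraries with $counts[g, j] > 0$.
3. If $frC^g >$ `frAA` (strictly) and $gMax^g > 0$, then for every cell
   $c$: $counts'[g, c] = \max(0,\; counts[g, c] - gMax^g)$.

The estimator is deliberately an upper envelope: $gMax$ is the largest
ambient draw seen across (typically tens of thousands of) empty droplets,
so subtracting it removes essentially the whole ambient component from
every cell. The cost is bounded — at most $gMax$ real counts per cell per
gated gene — and is negligible exactly where the method is meant to act:
genes whose native expression in their own cell type is an order of
magnitude above the soup level, but whose soup level differs between
samples and would otherwise drive false between-group differences in
non-expressing cell types.

Assumptions worth stating explicitly:

* all cell libraries are equally likely to contain ambient RNA (no
  per-cell contamination fraction is estimated, unlike SoupX/CellBender);
* lysed-cell mRNA is the only source of counts a cell does not express
  (barcode swapping is out of scope);
* the correction is *per sample*: soup composition is sample-specific, so
  multi-sample studies loop over samples and never pool ambient profiles;
* correction is applied to the user-supplied cell matrix, profiling to the
  full/raw matrix. Cell Ranger's *filtered* matrix cannot be profiled —
  the empty droplets have been removed from it. Passing one matrix for
  both roles is permitted and simply corrects every library in it.

## The two parameters

**`empty_threshold` (thE), UMIs per library, default 100.** Libraries at
or below it are ambient. 100 is the conventional default; the useful value
is dataset-specific and the package treats its choice as a diagnostic
workflow rather than an estimation problem (below). Above about 500 the
package warns: lowly-expressing live cells (T cells are the classic case)
start entering the "ambient" set, which inflates their genes' $gMax$ and
can erase those genes from the whole matrix.

**`contamination_chance` (frAA), fraction in [0, 1], default 0.005.** The
gate mirrors the minimum-expressing-fraction cut-offs of sc-DGE methods: a
gene seen in fewer than 5 of each 1000 ambient libraries cannot reach the
expressing-fraction threshold of the downstream test as contamination, so
correcting it would only cost signal. Matching `frAA` to the downstream
tool's cut-off keeps the corrected gene set exactly as large as it needs
to be.

Boundary semantics are pinned down in code and tests: threshold selection
is *inclusive* (a library with exactly `thE` UMIs is ambient), the gate is
*strict* (a gene at exactly `frC == frAA` is not corrected), and a gene
never seen in the ambient libraries is never corrected regardless of the
gate.

## Threshold selection diagnostics

The package does not auto-select `thE`; the procedure is a judgement call
that trades removal of likely-contaminating transcripts against loss of
everything else, and it is kept visual/tabular:

* `profile_removal_grid()` computes, for a grid of candidate thresholds
  (default 0–500 in steps of 25, covering the range up to the warning
  ceiling), the $gMax$ and $frC$ every gene would have. $gMax$ and the
  ambient library count are non-decreasing along the grid by construction,
  which the tests assert.
* `gene_removal_summary()` contrasts, for one gene and one candidate
  threshold, the per-cell count distribution by cell type before and after
  subtracting the implied $gMax$ — the numeric substrate of the usual
  violin diagnostic. A good threshold mostly flattens the gene in
  non-expressing types while leaving the expressing type high.
* `suggest_threshold()` is a convenience flag, clearly labelled heuristic:
  the smallest grid point at which a named gene's $gMax$ reaches its
  upper-quartile count in named non-expressing cell types. It encodes the
  "remove about as much as non-expressing cells show" rule of thumb and is
  no substitute for looking at the tables.
* `ambient_report()` is report-only mode: the full per-gene soup profile
  (with a rank by total ambient counts), computed without touching the
  matrix, for annotating downstream DGE results instead of correcting.

`pseudobulk_aggregate()` sums cell counts per (sample, cell type), the
unit on which between-group DGE runs and on which the contamination
manifests; `plot_pseudobulk_heatmap()` places the per-sample ambient
profile next to the cell types it contaminates.

## The simulator

Every quantitative claim the test suite and `scripts/acceptance.R` make is
computed on simulated data with exact ground truth, so the generative
model matters. `simulation_config()` defaults describe one realistic
sample and are treated as the study conditions, not tuning knobs:

* 600 genes; 8 cell types with 5 exclusive marker genes each (markers
  carry 50% of their type's expression mass), a 60-gene housekeeping block
  expressed in all types (35%), and the remainder spread thinly and
  ubiquitously. The housekeeping block exists so over-correction of
  commonly expressed genes is exercisable.
* 250 cells per type (2,000 cells) with lognormal total depth, location
  1,000 UMIs, `sdlog` 0.2.
* The ambient pool is the lysis-weighted mixture of the type profiles
  (equal weights by default).
* Each cell's depth is split binomially into a native and an ambient part
  (`contamination_fraction`, default 0.1), then multinomially into genes
  from the type profile and the pool respectively — counts stay integers
  and the native/ambient decomposition is exact per entry.
* 20,000 empty droplets draw Poisson depths and pool-multinomial counts.
  The two steps are generated in the equivalent factorised form —
  independent Poisson counts per gene with mean
  `empty_depth_mean * pool probability` — which is distributionally
  identical and vectorises.
* `empty_depth_mean` defaults to `contamination_fraction * cell_depth_mean`
  (100 UMIs): a droplet's soup capture does not depend on whether it holds
  a cell, so the empty-droplet depth *is* the per-cell ambient load. This
  consistency is not cosmetic — it is the regime in which the empties' max
  is a sound envelope for cells' ambient content. (An early draft of the
  generator used half that depth; the corrected fold changes then failed
  to shrink reliably, because the empties systematically under-sampled the
  soup relative to deep cells. The depth is now derived, not set.)
* Everything is deterministic given `seed`; per-sample draws in a study
  use fixed offsets from it.

What the simulator does **not** emulate: transcriptome-scale gene counts
and realistic expression calibration (600 genes, three expression tiers),
doublets, UMI/PCR errors, barcode swapping, or cell types absent from the
cell calls but present in the soup. One structural consequence shows up in
every simulated run: with a deep ambient pool and only 600 genes, *every*
gene clears the default `frC` gate, so the whole matrix loses a few counts
per cell — on a real 20,000–30,000-gene transcriptome the gate passes only
a small ambient-dominated subset. Passing tests therefore demonstrate the
correctness and behaviour of the algorithm under its assumptions, not its
end-to-end effect on any particular real dataset.

## The recovery study

The headline check (`tests/testthat/test-acceptance.R`, reproduced by
`scripts/acceptance.R`) simulates the false-positive scenario directly: two
groups of 6 samples, identical native expression, with one cell type's
lysis weight raised from 0.125 to 0.3 in group A's ambient mixture — so
that type's 5 marker genes contaminate group A more. Per sample the
correction runs with `thE` at the *empty-depth ceiling*,
`qpois(1 - 1e-5, empty_depth_mean)` (about 144), and `frAA = 0.005`.
Measured against ground truth, over 20 replicates at fixed seeds:

* the share of ambient-derived marker counts removed from non-expressing
  cell types (attribution within a cell is ambient-first);
* the share of native marker counts lost from the expressing type;
* how often the mean |log2 fold change| of the shifted markers, in pooled
  non-expressing pseudo-bulk CPM between groups (0.5 pseudo-count),
  shrinks after correction.

The problem sizes (20 replicates × 12 samples × 22,000 droplets × 600
genes) keep the full study a few minutes on one CPU.

## Numerical and implementation choices

* Integer arithmetic throughout; no scaling or normalisation. Corrected
  matrices from other tools may be real-valued: the reader accepts `real`
  MatrixMarket files and rounds half-to-even with a warning.
* Sparse all the way down (`Matrix::dgCMatrix`). Clamped subtraction only
  touches stored entries of gated genes — a stored zero stays zero — so the
  correction causes no fill-in and never densifies.
* MatrixMarket triplets are 1-based on disk (the standard), genes-as-rows
  (the Cell Ranger convention); a `transposed` reader option accepts the
  other orientation but the in-memory contract is always genes × libraries.
  Both the v2 (`genes.tsv`) and v3 (`features.tsv.gz`) dialects are read;
  writing is always v3. `Matrix::writeMM` degrades an all-ones matrix to
  `pattern` format; the writer restores explicit values so the on-disk
  type is always `integer`.
* Duplicate gene *symbols* are retained (IDs are the key); duplicate gene
  IDs are an error. Gene axes are matched by identity (same IDs, same
  order) between the profiling and correction matrices, and the first
  discordant position is reported on mismatch.
* Zero ambient libraries is a defined state, not an error: warning, all
  zero profile, correction a no-op. An empty threshold grid is an error.
* The per-gene bookkeeping (`counts_removed`, `cells_affected`,
  `cells_zeroed`) satisfies an exact conservation law — total counts before
  minus after equals the summed removals — asserted on every random test
  instance.
* The CLI writes corrected matrices to a temporary directory and renames on
  success, so a failed run leaves no partial matrix. Exit codes: 0 ok,
  1 usage, 2 data/format, 3 internal.

## Known limitations

Subtracting a per-gene constant is blunt by design: it removes the same
amount from every cell, so cells with above-envelope ambient draws retain a
small residue and lowly-expressing cells of a gated gene can be zeroed.
There is no per-cell contamination estimate, no probabilistic background
model, and no handling of barcode swapping. The threshold has no
closed-form optimum; the diagnostics make the trade-off visible but the
choice stays with the analyst. Genes with enormous `gMax` but `frC` below
the gate are — by construction — never corrected, and no override is
provided.
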