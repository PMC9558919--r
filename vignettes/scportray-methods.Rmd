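---
title: "Portraying single-cell expression landscapes with self-organizing maps"
author: "scportray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Portraying single-cell expression landscapes with self-organizing maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scportray)
```

## The method

scportray stratifies large single-cell RNA-seq data sets by the combinatorial
activation of co-expression modules. The workflow has five stages.

**1. Meta-cell downsampling.** Training a SOM on gene profiles over a hundred
thousand cells is wasteful: nearby cells are near-replicates. Cells are
therefore partitioned three times — an unsupervised base clustering
(k-means on the top principal components by default; any external partition
can be injected), a split of each cluster by sample of origin, and a
refinement k-means inside each (cluster, sample) set with
`k = max(1, round(n / cells_per_metacell))`. Each refinement centroid — the
mean normalized expression of its member cells — is a *meta-cell*. By
construction a meta-cell never mixes samples, size-weighted meta-cell means
reproduce the global gene means exactly, and the data shrink by roughly the
target factor (default 100).

**2. SOM training.** Each gene's profile over the meta-cells is centered to
zero mean (the differential-expression convention of the portraits) and a
rectangular planar SOM is trained on these profiles with batch updates: per
epoch every gene is assigned to its best-matching unit (BMU, minimal
Euclidean distance) and every unit's weight vector becomes the
neighborhood-weighted mean of the gene profiles under a Gaussian kernel over
grid distance. The kernel width anneals geometrically from `cols/2` to
`sigma_end` (default 0.5). Weights are initialized on the plane of the first
two principal components, which makes training fully deterministic. After
the annealed epochs, batch updates continue at `sigma_end` until the
assignment is a fixed point (at most `max_converge` extra iterations): this
convergence phase guarantees that the stored weight of a unit is consistent
with exactly the genes finally mapped to it, which the upscaling stage
relies on. Each unit is a *meta-gene*; the grid default is 40 x 40 = 1,600
meta-genes, chosen so that with genome-scale inputs (about 20,000 genes) a
meta-gene summarizes on the order of ten genes.

**3. Portraits and spot modules.** An entity's *portrait* is its meta-gene
vector minus a reference mean, reshaped onto the grid; red regions are
over-expressed relative to the reference, blue under-expressed. Spot-module
extraction selects, in every portrait, the units reaching 90% of that
portrait's maximum (`threshold_fraction = 0.9`); the union of selected units
over all portraits is decomposed into 8-neighborhood connected areas. A spot
is a region of *correlated* meta-genes, and two distinct spots can be
grid-adjacent, so each connected area is further segmented: the peak unit of
every portrait seeds a spot, seeds whose weight profiles correlate at least
`split_correlation = 0.9` count as the same spot, and the remaining units
are flooded (in decreasing order of summary over-expression) onto the
adjacent seed group with the most similar profile. The 0.9 correlation
threshold sits in a wide safe band: secondary peaks inside one spot
correlate above 0.95 with the main peak, while peaks of functionally
distinct spots correlate near or below zero. Segments smaller than
`min_units = 3` units are discarded as single-pixel noise. Module genes are
the genes mapped to member units, so modules are disjoint gene sets by
construction. Letters A, B, C, ... are assigned by row-major scan order of
the module centroids. Functional annotation tests each (module, gene set)
pair with a right-tailed Fisher exact test (hypergeometric upper tail) over
a caller-supplied universe.

**4. Upscaling.** The SOM summarizes meta-cells, but the analysis needs
single-cell resolution. For every non-empty unit a support-vector
regression (linear kernel, epsilon-insensitive loss with the tube scaled to
the target spread; a least-squares variant is available behind the same
interface) is fitted on the meta-cells, from the unit's member-gene
expression (centered by the meta-cell gene means) to the unit's weight
vector. Single-gene units pass their centered gene value through directly;
empty units inherit the predictor of the nearest non-empty unit (ties to
the lower unit index). Applying the predictors to any cell yields its full
meta-gene vector — and hence its portrait — without retraining the SOM.
Because the predictors are linear, averaging predictions over a meta-cell's
member cells approximates predicting at the centroid, so cell-level
predictions are consistent with the meta-cell landscape.

**5. Module activation patterns (PATs).** Per-cell module expression is the
mean normalized expression over the module's genes. Each module column is
centered across cells and divided by sigma, the standard deviation of the
pooled centered matrix. A module is activated in a cell when its level
exceeds 0.5 sigma; the cell is a *major* PAT when every activated module
also exceeds 1 sigma (uppercase label, e.g. "B D"), a *minor* PAT otherwise
(lowercase, "b d"), and "none" when nothing is activated. Letters within a
label are ordered by the modules' overall activation frequency. Labels
carried by strictly fewer than 0.5% of all cells are dissolved into "none"
(at the reference scale of 133,405 cells this cutoff is 667 cells). Group
comparisons use right-tailed Fisher exact tests on PAT frequencies, and the
*PAT flow* graph greedily balances over-represented PATs of one group
against the most similar (Euclidean distance between PAT mean
module-expression vectors) under-represented PATs of the other, always
expanding the largest remaining surplus, until the differential frequencies
are exhausted.

Marker-based cell typing and cell-cycle phase calling run alongside: a cell
is positive for a marker iff it has any signal (count > 0, matching the
read-based definition of receptor-construct positivity), and phase scores
subtract expression-matched control means from signature means, with S/G2M
called only for positive scores (the signatures cannot separate G0 from G1,
so non-cycling cells default to G1).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `scale`, `log_base` | 1e4, e | library-size target and log base of normalization |
| `cells_per_metacell` | 100 | target meta-cell size; the ~100x downsampling factor |
| `rows`, `cols` | 40, 40 | SOM grid (1,600 meta-genes) |
| `epochs`, `sigma_start`, `sigma_end` | 100, cols/2, 0.5 | batch-SOM schedule (grid units) |
| `threshold_fraction` | 0.90 | spot selection, fraction of a portrait's maximum |
| `min_units` | 3 | minimal spot size in units |
| `split_correlation` | 0.9 | seed-profile correlation above which peaks merge |
| `major_sigma`, `minor_sigma` | 1.0, 0.5 | PAT activation thresholds in pooled-sigma units |
| `rare_fraction` | 0.005 | rare-PAT rejection fraction |
| `n_bins`, `n_ctrl` | 25, 100 | cell-cycle control matching window and sample size |

## The synthetic benchmark

`generate_dataset()` emulates a multi-sample experiment with known ground
truth, so that every downstream stage is testable without external
downloads. Counts are negative-binomial (`variance = mu + 0.1 mu^2`) with
gene baselines drawn log-normally; the background uses `lognormal(log 0.5,
1.5)` — the heavy tail reproduces the wide expression range of real
transcriptomes, and matters because expression-matched control scoring
presumes peers at any signature's expression level. Five disjoint 40-gene
modules are planted in 2,000 genes; module member genes draw baselines
around per-module levels (1, 0.7, 0.5, 0.35 for the population modules and
4 for the cycling module), reflecting that real modules differ strongly in
absolute expression with proliferation machinery among the strongest, and
that membership of a gene expressed near zero would not be a recoverable
planted fact. Four populations (fractions 0.4/0.3/0.2/0.1) each activate
one module at fold-change 4; the fifth module is activated in a 40%
"cycling" subset of every population, which makes its per-cell expression
bimodal. Eight samples split into two groups, with the first population's
frequency halved in group B — the planted signal for the enrichment and
flow-graph machinery.

The generator does **not** emulate batch effects, doublets, ambient RNA, or
empirically fitted dropout; passing tests therefore demonstrate the
machinery's correctness and sensitivity under clean planted structure, not
robustness to those artifacts.

## Numerical choices and degenerate inputs

* Cluster-count rule `k = max(1, round(n / target))`, with `k = n` reducing
  meta-cells to single cells and `k = 1` to the group mean.
* SOM determinism: PCA-plane initialization; assignment ties broken by the
  lower unit index; units with negligible neighborhood mass keep their
  previous weights.
* A portrait with a non-positive maximum contributes no units to spot
  selection (logged, not an error); constant genes keep all-zero profiles.
* Pooled sigma of zero (a constant module-expression matrix) is a contract
  error; the score tie `s = g2m > 0` resolves to G2M to keep phase
  assignment total.
* Rare-PAT rejection is strict: a label is dissolved iff its count is
  strictly below `rare_fraction x n_cells`, which reproduces the 667-cell
  cutoff at the 133,405-cell reference scale and leaves a label holding
  exactly the boundary count intact.
* Cell-cycle controls are drawn from an expression-centered window (about
  one `n_bins`-th of the eligible genes, at least `n_ctrl`) over genes
  outside both signatures; sampling is seeded, and scores are invariant to
  gene order.
* Flow balancing breaks distance ties by PAT label order, making the graph
  reproducible; group frequencies are computed over classified cells
  ("none" excluded) by default.

## Design choices where the design was open

* **Pooled sigma** (one standard deviation over all modules x cells after
  per-module centering) rather than per-module sigma: the pooled reading
  keeps the activation levels of strongly and weakly varying modules on one
  scale; a per-module option exists (`pooled_sigma = FALSE`).
* **Rejection before tier reporting**: rare labels are dissolved on their
  combined counts, then tiers are summarized; the order is configurable in
  principle but the reported tier partition always covers all cells.
* **Saddle segmentation of connected over-expression areas** (the
  `split_correlation` step): plain connected components cannot yield
  adjacent-but-distinct modules, yet adjacent distinct modules are the
  rule, not the exception, on organized maps — co-regulated programs land
  side by side. Setting `split_correlation > 1` restores plain components.
* **Greedy largest-surplus-first flow matching** with Euclidean similarity
  between PAT centroids: a concrete, deterministic instance of iterative
  balancing; exact transport would change edge weights little at the
  frequency scales involved but costs determinism of interpretation.
* **Lettering by centroid scan order**: any stable rule works; scan order
  makes letters reproducible across reruns of the same map.

## Problem sizes used by the test suite

The suite and the acceptance script exercise the full pipeline at 2,000
genes x 5,000 cells with a 20 x 20 map, 60 epochs, base clustering k = 16
and 100 cells per meta-cell (about 128 meta-cells), which keeps a five-seed
sweep under a few minutes while preserving every structural property the
method relies on; unit tests use smaller constructed fixtures with
closed-form or brute-force oracles.

## Known limitations

* Spot recovery depends on the map's island placement; with several
  mutually exclusive programs plus one shared (cycling) program, a
  particular seed can still fuse one module pair when their islands touch
  and their profiles correlate above `split_correlation` at the seam.
* The upscaling fidelity guarantee concerns non-empty units; empty units
  inherit a neighbor's predictor and track that neighbor's weights by
  design.
* Phase calling inherits the calibration limits of signature-minus-control
  scoring; the G1 class absorbs G0 cells, and scores near zero are
  sensitive to the control pool's composition.
* The 2-D embedding of PAT centroids (for PAT maps) is exported data; no
  embedding algorithm is bundled.
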