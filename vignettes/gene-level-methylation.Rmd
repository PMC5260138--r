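---
title: "Gene-level methylation profiles from WGBS: model, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-level methylation profiles from WGBS: model, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methtable)
library(dplyr)
```

## The problem

Whole-genome bisulfite sequencing (WGBS) reports, for every cytosine in a
genome, how many mapped reads called it methylated (read as C) and how many
called it unmethylated (converted to T). In plants, methylation is tracked in
three sequence contexts — CG, CHG and CHH (H = A, C or T) — because distinct
enzymatic pathways maintain each. A single *Arabidopsis*-scale methylome is
tens of millions of per-cytosine records; most comparative questions a bench
scientist asks, however, are phrased at the gene level: *is the promoter of
this gene more CHH-methylated in the mutant?*

`methtable` reduces a per-cytosine report to six numbers per gene — the
average methylation level of the **promoter** and the **gene body** in each
of the three contexts — and provides the downstream operations this reduction
enables: differentially methylated gene (DMG) selection between conditions,
cutoff filtering, gene-list set algebra, hypergeometric term enrichment, and
single-linkage clustering for heatmaps.

## The estimator

The methylation level of one cytosine $i$ is the non-converted read fraction

$$ C_i = \frac{\#\,\text{reads C}}{\#\,\text{reads C} + \#\,\text{reads T}}, $$

and the level of a region $X$ (a promoter or a gene body, in one context) is
the **unweighted arithmetic mean** over its qualifying sites

$$ \bar{C}_X = \frac{\sum_{i \in X} C_i}{\sum_{i \in X} 1}. $$

This is deliberately *not* the pooled-count ratio
$\sum C / \sum (C + T)$: pooling would let one deeply covered cytosine
dominate the region. The two estimators differ whenever coverage is
heterogeneous, and the test suite checks they are distinguished. The pooled
variant remains available behind `pooled = TRUE` for users who want
read-weighted averages.

Two filters make the average trustworthy:

* **Coverage filter** — a site only qualifies with at least `min_coverage = 4`
  mapped reads. Below that, $C_i$ is too noisy to average.
* **Site-count filter** — a region's level is only reported when at least
  `min_sites = 5` sites qualify; otherwise the measurement is `NaN`.
  Averaging five observations bounds the influence of any single cytosine at
  20%.

The `NaN` rule is exact and two-sided: a measurement is `NaN` *iff* its
qualifying-site count is below the threshold, and that count is reported
alongside every measurement (`n_pmt_CG`, ...). The site-count filter counts
*qualifying* sites, i.e. it is applied after the coverage filter; counting
before would let uncovered cytosines satisfy the requirement.

With per-site binomial reads this estimator is consistent: its standard
error is approximately $\sqrt{\bar p (1-\bar p) / (k \bar c)}$ for $k$ sites
at mean coverage $\bar c$, and the suite verifies that ≥95% of estimates on
simulated data fall within four such standard errors of the simulated truth.

## Compartments

The **gene body** is the full annotated `gene` feature span; no exon/intron
distinction is made. The **promoter** runs from 2500 bp upstream to 500 bp
downstream of the transcription start site, strand-aware (on `-` genes the
TSS is the feature end and the offsets mirror). Consequences of this
definition, chosen once and applied everywhere:

* The promoter's downstream 500 bp overlaps the start of the gene body;
  overlap is intentional (proximal-promoter methylation straddles the TSS).
* Promoters are clamped at coordinate 1. No upper clamp is applied, because
  no chromosome-length source is required; sites cannot exist beyond the
  chromosome end, so an over-extended promoter merely gains no sites.
* Cytosines on **both strands** contribute to a region regardless of the
  gene's strand — a CG dyad is two observations. Watson/Crick origin is kept
  in the site table (`strand`), but region membership is by position only.

Promoter measurements of structural RNA genes (rRNA, tRNA, snRNA, snoRNA,
miRNA, ...) and transposable elements are reported as `NaN` with a site count
of zero: "promoter" is not a meaningful compartment for these biotypes, and
TE methylation dynamics would otherwise dominate promoter summaries. Their
gene-body measurements are kept. The exclusion list
(`default_excluded_biotypes()`) is configurable.

## Input dialects and the mtable

Two per-cytosine report dialects are read: the 8-column BS-Seeker2 CGmap
(which omits uncovered sites; strand is encoded as the Watson-strand
nucleotide C/G) and the 7-column Bismark genome-wide cytosine report (which
keeps uncovered sites; coverage is the sum of the two count columns). Both
parse to the same site table, and the suite demands that the two encodings
of one methylome produce **byte-identical** mtables.

The mtable output is a 7-column TSV — `gene_id` plus `pmt_CG`, `pmt_CHG`,
`pmt_CHH`, `gene_CG`, `gene_CHG`, `gene_CHH` — with levels at 4 decimal
places and undefined cells as the literal `NaN`. A header line is written
(and checked on read); headerless files are accepted with `header = FALSE`.
Writing is deterministic, so repeated runs are diff-able.

## Downstream operations

**DMGs.** Two pools of datasets (conditions) are compared on one
measurement. A gene is evaluable only when the measurement is defined in
*every* member of both pools — the default guards against a pool mean driven
by a single replicate, and `require_complete = FALSE` relaxes it. Pool values
are unweighted means over members; a gene is selected when
$|\bar m_B - \bar m_A| \ge \Delta$ (inclusive, so boundary genes are kept)
with the sign matching the requested direction. The conventional
demonstration criterion $\Delta = 0.15$ is the default. No statistical test
is attached: the deliberate contract is a transparent, deterministic delta
filter; a deviation of 0.1 in a measurement built from $k \ge 5$ sites means
roughly 10% of the observed cytosines changed state.

**Threshold selection** keeps genes at-or-beyond a cutoff (`>=` / `<=`,
inclusive) in at least one or in all datasets; `NaN` never satisfies a
cutoff, so `mode = "all"` rejects genes undefined anywhere.

**Set algebra.** Venn decomposition for 2–4 sets partitions the union into
$2^k - 1$ signature regions (signatures are 1/0 strings in input-set order),
and a small expression language (`|`, `&`, `-`, parentheses) produces new
lists with the expression recorded as provenance. The suite verifies the
partition property and that every expression equals the union of its
satisfying Venn cells.

**Enrichment.** For a test list with $m$ annotated members in a background
of $N$ annotated genes and a term covering $n$ of them, the probability of
observing exactly $x$ list members in the term is hypergeometric:

$$ p(x \mid N, m, n) = \frac{\binom{m}{x}\binom{N-m}{n-x}}{\binom{N}{n}}. $$

The reported p-value is the **upper tail** $\sum_{k \ge x} p(k)$ — a point
probability is not an over-representation measure, and the tail is the
universal convention this pmf feeds. The pmf itself stays exposed for
verification. Two open choices were settled as follows: the background $N$
is the number of *annotated* genes (not all genome genes), because
unannotated genes cannot contribute to any term and would deflate every
p-value uniformly (configurable by supplying a wider annotation table); and
Benjamini–Hochberg adjusted p-values are computed and reported in their own
column but do not drive the raw-p cutoff, which reproduces the classic
cutoff behaviour. Coefficients are computed in log space (`lchoose`), so
genome-scale $N$ cannot overflow. Test genes missing from the background are
dropped with a diagnostic count — a mismatched identifier universe is a data
property, not an error.

**Clustering.** Heatmap presentation clusters genes and datasets
independently with single linkage over Euclidean distance — the
cluster–cluster distance is the minimum pairwise member distance, which
makes merge heights non-decreasing and exactly equal to the sorted edge
weights of the minimum spanning tree (the suite uses both an $O(n^3)$
re-scanning reference and an MST oracle). Ties are broken deterministically
toward the pair containing the lowest original item index, and the leaf
order keeps the lower-indexed cluster on the left, so results are
reproducible across platforms. `NaN` handling is complete-case by default
(genes undefined in any dataset are dropped and counted) because a heatmap
cell cannot display `NaN`; a fill-value alternative exists behind
`na_policy = "fill"`. No leaf-order optimization is applied — the order is
the one the merges induce. Trees serialize to Newick with branch lengths
encoding height differences, so root-to-leaf path length equals the final
merge height. Datasets are clustered on the prepared (selected, NaN-free)
matrix, not the full gene universe: the heatmap should group conditions by
the genes it actually displays.

## The simulator

`simulate_methylome()` exists so every operation is testable against known
truth without downloads. It emulates:

* a toy annotation (default 50 genes, 2 chromosomes, gene bodies 1–3 kb,
  spaced so promoters never collide), including deterministic edge cases —
  a promoter clamped at coordinate 1, a transposable element and an rRNA
  gene;
* per-cell truth: for each gene × compartment × context, a true probability
  drawn from a Beta distribution centred on the context mean
  (CG 0.65, CHG 0.30, CHH 0.08 — the plant pattern of high CG, intermediate
  CHG, low CHH; concentration 30 gives genes individuality);
* sites at 8/8/30 per kb for CG/CHG/CHH (≈10k sites for 50 genes), coverage
  Poisson with mean 10, methylated counts binomial at the cell's truth;
* both dialects of the same site set, with zero-coverage sites present only
  in the cytosine report, as the real tools behave.

Passing `cell_p` from one run into another seed simulates a **replicate
library** of the same biological condition: gene-level truth is shared while
site placement and reads are redrawn.

What it does **not** emulate — and what passing tests therefore do not show
about real data: no real sequence (context tokens are drawn, not read from a
genome, so context-density correlations with GC content are absent), no
spatial autocorrelation of methylation along the chromosome, no bisulfite
conversion failure or mapping bias, uniform coverage rather than
mappability-structured coverage, and no overlapping or nested gene models.
The estimator is exercised under idealized binomial noise; on real data the
same code runs, but its error is bounded by data quality, not by these
tests.

## Numerical and scale choices

* Levels are serialized at 4 decimals; round-trip identity is tested at that
  precision. Internally everything is double precision; oracle comparisons
  use 1e−12 tolerances.
* `min_coverage` is floored at 1: a zero-coverage site has no defined level.
* The delta and cutoff comparisons are inclusive (`>=`), documented at each
  call site, so a gene exactly on the boundary is selected.
* Test problem sizes were chosen to exercise the estimator at study scale
  while keeping the default suite fast: profile oracles run on ten 50-gene
  (~10k-site) methylomes, parameter recovery on twenty, hypergeometric
  enumeration exhaustively for backgrounds of 5/9/12 plus sampled cases to
  20, a 10^5-draw resampling check at N = 200, and clustering oracles on
  matrices up to 12 items over 20 seeds.

## Known limitations

* Gene bodies are whole feature spans; transcript-aware summaries (exonic
  methylation, alternative TSSs) are out of scope.
* DMG selection is a deterministic filter; it makes no claim of statistical
  significance and is not a DMR caller.
* GO term ancestry is not propagated; the enrichment background is exactly
  the supplied annotation table.
* Venn decomposition stops at four sets, matching the display convention it
  serves.
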