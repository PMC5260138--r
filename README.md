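# methtable

Gene-level DNA methylation profiles from whole-genome bisulfite sequencing
(WGBS), and the downstream analyses those profiles enable.

## What it is for

A WGBS experiment resolves into millions of per-cytosine records — in plants,
separately for the CG, CHG and CHH sequence contexts (H = A, C or T), each
maintained by a distinct enzymatic pathway. `methtable` is for researchers
who want to work at the gene level instead: it reduces a per-cytosine report
(BS-Seeker2 **CGmap** or Bismark **cytosine report**) plus a GTF annotation
to a compact tab-delimited **mtable** with six measurements per gene —
promoter and gene-body average methylation in each context — and then
operates on those tables:

* **DMG selection** — differentially methylated genes between two dataset
  pools by a level-difference criterion;
* **threshold selection** — genes above/below a methylation cutoff in
  any/all datasets;
* **gene-list set algebra** — Venn region decomposition for up to four sets
  and Boolean combinations;
* **enrichment** — hypergeometric over-representation of GO/KEGG-style
  annotation terms;
* **2D clustering** — single-linkage Euclidean clustering of genes and
  datasets for heatmaps;
* **simulation** — a synthetic methylome generator with ground truth, so the
  entire workflow runs and is testable with no external data.

## The model

The methylation level of cytosine *i* is the non-converted read fraction

```
C_i = (# reads C) / (# reads C + # reads T)
```

and a gene-level measurement is the unweighted mean of `C_i` over the
qualifying sites of a compartment (promoter = TSS −2500..+500 strand-aware;
gene body = the annotated feature span) in one context. A site qualifies
with coverage ≥ 4 reads; a measurement is reported only when ≥ 5 sites
qualify, otherwise it is `NaN`. Promoter measurements of structural-RNA and
transposable-element genes are suppressed.

Enrichment uses the upper-tail hypergeometric probability

```
p(x | N, m, n) = C(m, x) C(N−m, n−x) / C(N, n),   p-value = Σ_{k ≥ x} p(k)
```

with `N` annotated background genes, `m` annotated test-list members, `n`
the term size and `x` the overlap. Clustering is agglomerative single
linkage (minimum pairwise Euclidean distance between clusters) with
deterministic tie-breaking.

See the methods vignette (`vignettes/gene-level-methylation.Rmd`) for the
assumptions, filters, and design decisions in full.

## Worked example

Simulate a control methylome, build its mtable through the pipeline entry
point, then compare against a mutant that retains only 20% of each gene's
CHH methylation (an RdDM-defective condition simulated as a replicate
sharing the control's CG/CHG truth):

```r
library(methtable)

sim <- simulate_methylome(sim_config(seed = 7), dir = tempfile())
res <- run_mtable(sim$cgmap, sim$gtf, "demo.mtable")
res$summary
#> # A tibble: 6 × 3
#>   measurement n_usable pct_usable
#>   <chr>          <int>      <dbl>
#> 1 pmt_CG            41         82
#> 2 pmt_CHG           41         82
#> 3 pmt_CHH           41         82
#> 4 gene_CG           48         96
#> 5 gene_CHG          50        100
#> 6 gene_CHH          50        100
```

82% of promoters and ≥96% of gene bodies are measurable: the other genes
either carry an excluded biotype (promoter cells) or lack five covered
sites. The profiles show the plant pattern — CG high, CHG intermediate,
CHH low:

```r
head(res$profiles[, 1:7], 5)
#> # A tibble: 5 × 7
#>   gene_id    pmt_CG pmt_CHG  pmt_CHH gene_CG gene_CHG gene_CHH
#>   <chr>       <dbl>   <dbl>    <dbl>   <dbl>    <dbl>    <dbl>
#> 1 SIMG00001   0.576   0.320   0.0218   0.621    0.314   0.0337
#> 2 SIMG00002 NaN     NaN     NaN        0.758    0.354   0.137
#> 3 SIMG00003 NaN     NaN     NaN        0.602    0.318   0.0801
#> 4 SIMG00004   0.619   0.278   0.0565   0.520    0.289   0.0353
#> 5 SIMG00005 NaN     NaN     NaN        0.646    0.422   0.0999
```

DMG selection on gene-body CHH at the conventional Δ = 0.15:

```r
truth <- sim$cell_p
truth$p[truth$context == "CHH"] <- 0.2 * truth$p[truth$context == "CHH"]
mut <- simulate_methylome(sim_config(seed = 8), dir = tempfile(), cell_p = truth)
run_mtable(mut$cgmap, mut$gtf, "mut.mtable")

dmgs <- select_dmgs(read_mtable("demo.mtable"), read_mtable("mut.mtable"),
                    "gene_CHH", delta = 0.15)
dmgs
#> # A tibble: 4 × 4
#>   gene_id   mean_a mean_b   diff
#>   <chr>      <dbl>  <dbl>  <dbl>
#> 1 SIMG00013  0.185 0.0291 -0.156
#> 2 SIMG00032  0.205 0.0256 -0.179
#> 3 SIMG00040  0.201 0.0333 -0.168
#> 4 SIMG00045  0.204 0.028  -0.176
```

The four selected genes are exactly the control genes with enough CHH
methylation to lose 0.15 of it; `diff` is the signed mutant-minus-control
difference. A `gene_set` made from `dmgs` feeds `venn_regions()`,
`combine_sets()`, `enrich()` and, via `prepare_matrix()` +
`cluster_heatmap()`, the clustered heatmap (`autoplot()` renders it).

A shell entry point wrapping these functions as subcommands
(`simulate`, `mtable`, `dmg`, `threshold`, `venn`, `enrich`, `cluster`)
is installed at `system.file("cli", "methtable.R", package = "methtable")`.

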