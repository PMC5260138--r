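# Per-site methylation levels and the six per-gene region averages.
#
# The gene-level estimator is deliberately simple: the level of one cytosine
# is the fraction of non-converted reads C/(C+T); the level of a region is
# the unweighted arithmetic mean of per-site levels over qualifying sites
# (context match, position inside the interval, coverage >= min_coverage),
# reported only when at least min_sites sites qualify, otherwise NaN.

#' Derive a strand-aware promoter interval around a TSS
#'
#' On the `+` strand the promoter is `[tss - upstream, tss + downstream]`;
#' on the `-` strand the mirror `[tss - downstream, tss + upstream]`. The
#' start is clamped at coordinate 1. All arguments are vectorized.
#'
#' @param tss 1-based transcription start site coordinate(s).
#' @param strand `"+"` or `"-"` per gene.
#' @param upstream,downstream Promoter extent in bp (defaults 2500 / 500).
#' @return A tibble with integer columns `start` and `end`.
#' @export
#' @examples
#' derive_promoter(10000, "+")  # [7500, 10500]
#' derive_promoter(10000, "-")  # [9500, 12500]
#' derive_promoter(100, "+")    # clamped to [1, 600]
derive_promoter <- function(tss, strand, upstream = 2500, downstream = 500) {
  if (any(!strand %in% c("+", "-"))) {
    abort(sprintf(
      "unknown strand token '%s' (expected '+' or '-')",
      strand[which(!strand %in% c("+", "-"))[1L]]
    ))
  }
  if (any(tss < 1)) abort("TSS coordinates must be >= 1")
  start <- ifelse(strand == "+", tss - upstream, tss - downstream)
  end <- ifelse(strand == "+", tss + downstream, tss + upstream)
  tibble(start = as.integer(pmax(1, start)), end = as.integer(end))
}

#' Per-cytosine methylation level
#'
#' The methylation level of one cytosine is the fraction of reads reporting
#' it as methylated, `n_methylated / n_total` (the C / (C + T) read ratio of
#' bisulfite sequencing). Sites with zero coverage have no defined level and
#' must be filtered out before calling.
#'
#' @param sites A data frame of cytosine sites with columns `n_methylated`
#'   and `n_total` (as produced by [read_cgmap()] / [read_cx_report()]).
#' @return The input as a tibble with a `level` column appended.
#' @export
#' @examples
#' site_level(tibble::tibble(n_methylated = c(0, 5, 1), n_total = c(7, 5, 4)))
site_level <- function(sites) {
  if (any(sites$n_total == 0L)) {
    abort("site with zero coverage has undefined methylation level; filter first")
  }
  as_tibble(sites) |>
    mutate(level = .data$n_methylated / .data$n_total)
}

#' Average methylation level of one genomic interval
#'
#' Qualifying sites are those on the given chromosome with matching context,
#' position within `[start, end]` (inclusive, both strands), and coverage
#' `n_total >= min_coverage`. When at least `min_sites` sites qualify, the
#' returned level is the unweighted mean of their per-site levels; otherwise
#' the level is `NaN`. The qualifying-site count is returned either way.
#'
#' @param sites A cytosine site table (see [read_cgmap()]).
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive interval bounds.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param min_coverage Minimum read coverage for a site to qualify (default 4).
#' @param min_sites Minimum number of qualifying sites for a defined level
#'   (default 5).
#' @param pooled If `TRUE`, use the pooled-count ratio
#'   `sum(C) / sum(C + T)` instead of the mean of per-site levels. Off by
#'   default: the estimator of record weights every site equally.
#' @return A one-row tibble with columns `level` and `n_sites`.
#' @export
summarize_region <- function(sites, chrom, start, end, context,
                             min_coverage = 4, min_sites = 5, pooled = FALSE) {
  if (start > end) {
    abort(sprintf("invalid interval: start %d > end %d", start, end))
  }
  min_coverage <- max(1L, as.integer(min_coverage))
  q <- sites[
    sites$chrom == chrom & sites$context == context &
      sites$pos >= start & sites$pos <= end &
      sites$n_total >= min_coverage,
    , drop = FALSE
  ]
  k <- nrow(q)
  level <- if (k >= min_sites) {
    if (pooled) sum(q$n_methylated) / sum(q$n_total)
    else mean(q$n_methylated / q$n_total)
  } else {
    NaN
  }
  tibble(level = level, n_sites = as.integer(k))
}

#' Build gene-level methylation profiles (the mtable rows)
#'
#' Computes, for every gene, the six measurements `pmt_CG`, `pmt_CHG`,
#' `pmt_CHH`, `gene_CG`, `gene_CHG`, `gene_CHH`: the average methylation
#' level of the promoter and gene-body intervals in each sequence context,
#' under the coverage and site-count filters of [summarize_region()].
#' Promoter measurements of genes whose biotype is in
#' `excluded_promoter_biotypes` (RNA genes and transposable elements by
#' default) are forced to `NaN` with a site count of 0; their gene-body
#' measurements are kept. Genes on chromosomes absent from the site table
#' get all-`NaN` profiles.
#'
#' @param sites A cytosine site table (see [read_cgmap()]).
#' @param genes A gene-model table (see [read_gene_models()]).
#' @param min_coverage,min_sites,pooled As in [summarize_region()].
#' @param excluded_promoter_biotypes Biotypes whose promoter cells are
#'   suppressed; see [default_excluded_biotypes()].
#' @return A tibble with one row per gene (input order): `gene_id`, the six
#'   measurement columns in mtable order, and six `n_*` columns holding the
#'   qualifying-site count behind each measurement.
#' @export
build_profiles <- function(sites, genes, min_coverage = 4, min_sites = 5,
                           excluded_promoter_biotypes = default_excluded_biotypes(),
                           pooled = FALSE) {
  min_coverage <- max(1L, as.integer(min_coverage))
  chrom_levels <- unique(c(genes$chrom, sites$chrom))
  covered <- sites[sites$n_total >= min_coverage, , drop = FALSE]
  s_gr <- GenomicRanges::GRanges(
    factor(covered$chrom, levels = chrom_levels),
    IRanges::IRanges(covered$pos, width = 1L)
  )

  cells_for <- function(starts, ends) {
    q_gr <- GenomicRanges::GRanges(
      factor(genes$chrom, levels = chrom_levels),
      IRanges::IRanges(starts, ends)
    )
    hits <- GenomicRanges::findOverlaps(q_gr, s_gr)
    tibble(
      gene_id = genes$gene_id[S4Vectors::queryHits(hits)],
      context = covered$context[S4Vectors::subjectHits(hits)],
      n_methylated = covered$n_methylated[S4Vectors::subjectHits(hits)],
      n_total = covered$n_total[S4Vectors::subjectHits(hits)]
    ) |>
      group_by(.data$gene_id, .data$context) |>
      summarise(
        n_sites = dplyr::n(),
        level = if (pooled) sum(.data$n_methylated) / sum(.data$n_total)
                else mean(.data$n_methylated / .data$n_total),
        .groups = "drop"
      ) |>
      mutate(level = replace(as.numeric(.data$level),
                             .data$n_sites < min_sites, NaN)) |>
      tidyr::complete(
        gene_id = genes$gene_id,
        context = contexts(),
        fill = list(n_sites = 0L, level = NaN)
      )
  }

  widen <- function(cells, prefix) {
    lv <- tidyr::pivot_wider(
      cells[, c("gene_id", "context", "level")],
      names_from = "context", values_from = "level",
      names_glue = paste0(prefix, "_{context}")
    )
    ns <- tidyr::pivot_wider(
      cells[, c("gene_id", "context", "n_sites")],
      names_from = "context", values_from = "n_sites",
      names_glue = paste0("n_", prefix, "_{context}")
    )
    left_join(lv, ns, by = "gene_id")
  }

  pmt <- widen(cells_for(genes$promoter_start, genes$promoter_end), "pmt")
  body <- widen(cells_for(genes$body_start, genes$body_end), "gene")

  out <- tibble(gene_id = genes$gene_id, biotype = genes$biotype) |>
    left_join(pmt, by = "gene_id") |>
    left_join(body, by = "gene_id")

  excl <- out$biotype %in% excluded_promoter_biotypes
  for (ctx in contexts()) {
    out[[paste0("pmt_", ctx)]][excl] <- NaN
    out[[paste0("n_pmt_", ctx)]][excl] <- 0L
  }
  out$biotype <- NULL
  cols <- c("gene_id", mtable_measurements(), paste0("n_", mtable_measurements()))
  out[, cols]
}
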