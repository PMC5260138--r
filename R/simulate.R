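# Synthetic methylome generator.
#
# Emits a coherent toy dataset: a GTF gene annotation, a ground-truth site
# table, and the same methylome serialized in both per-cytosine dialects
# (CGmap omits uncovered sites, the cytosine report keeps them, exercising
# both parser behaviours). No real sequence is synthesized: each site carries
# a context token drawn at generation time, and the dinucleotide/trinucleotide
# columns are filled consistently with that token — downstream code only ever
# reads the token.

#' Configuration for the synthetic methylome
#'
#' The defaults describe a small plant-like study: 50 genes on 2 chromosomes,
#' CG methylation high, CHG intermediate, CHH low (per-cell truth is drawn
#' from a Beta distribution around the context mean, concentration
#' `gene_concentration`, so genes differ), cytosine densities of 8/8/30
#' sites per kb for CG/CHG/CHH, and per-site read coverage drawn from a
#' Poisson with mean `mean_depth` (default 10).
#'
#' @param seed RNG seed; all outputs are deterministic given the seed.
#' @param n_chroms,n_genes Genome shape.
#' @param gene_length Two-element range of gene-body lengths (bp).
#' @param promoter_upstream,promoter_downstream Promoter offsets (bp).
#' @param p_true Named per-context true methylation means, either a single
#'   vector applied to both compartments or a list with elements `promoter`
#'   and `gene_body`.
#' @param gene_concentration Beta concentration of the per-cell jitter
#'   around the context mean; `Inf` disables jitter (cells get the mean
#'   exactly, including degenerate 0/1).
#' @param sites_per_kb Named per-context cytosine densities.
#' @param mean_depth Mean per-site read coverage (Poisson).
#' @param biotype_props Named biotype proportions for gene assignment.
#' @param edge_cases Include deterministic edge cases: a gene whose promoter
#'   clamps at coordinate 1, one transposable element and one rRNA gene.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 2,
                       n_genes = 50,
                       gene_length = c(1000, 3000),
                       promoter_upstream = 2500,
                       promoter_downstream = 500,
                       p_true = c(CG = 0.65, CHG = 0.30, CHH = 0.08),
                       gene_concentration = 30,
                       sites_per_kb = c(CG = 8, CHG = 8, CHH = 30),
                       mean_depth = 10,
                       biotype_props = c(protein_coding = 0.84,
                                         transposable_element = 0.08,
                                         miRNA = 0.04, rRNA = 0.04),
                       edge_cases = TRUE) {
  if (!is.list(p_true)) p_true <- list(promoter = p_true, gene_body = p_true)
  for (comp in c("promoter", "gene_body")) {
    p <- p_true[[comp]]
    if (is.null(p) || !all(contexts() %in% names(p))) {
      abort("p_true must name probabilities for CG, CHG and CHH")
    }
    if (any(p < 0 | p > 1)) abort("p_true probabilities must lie in [0, 1]")
  }
  if (!all(contexts() %in% names(sites_per_kb)) || any(sites_per_kb <= 0)) {
    abort("sites_per_kb must be positive for CG, CHG and CHH")
  }
  if (n_genes < 1 || n_chroms < 1) abort("need at least one gene and chromosome")
  if (length(gene_length) != 2L || gene_length[1L] > gene_length[2L] ||
      gene_length[1L] < 200) {
    abort("infeasible gene_length range (need min >= 200, min <= max)")
  }
  if (mean_depth <= 0) abort("mean_depth must be positive")
  expected_min_sites <- min(sites_per_kb) * gene_length[1L] / 1000
  if (expected_min_sites < 1) {
    abort("infeasible density/length combination: < 1 expected site per gene body")
  }
  if (abs(sum(biotype_props) - 1) > 1e-8 || any(biotype_props < 0)) {
    abort("biotype_props must be non-negative and sum to 1")
  }
  structure(
    list(
      seed = seed, n_chroms = n_chroms, n_genes = n_genes,
      gene_length = gene_length,
      promoter_upstream = promoter_upstream,
      promoter_downstream = promoter_downstream,
      p_true = p_true, gene_concentration = gene_concentration,
      sites_per_kb = sites_per_kb, mean_depth = mean_depth,
      biotype_props = biotype_props, edge_cases = edge_cases
    ),
    class = "sim_config"
  )
}

draw_cell_p <- function(mean_p, concentration) {
  if (!is.finite(concentration) || mean_p <= 0 || mean_p >= 1) {
    return(mean_p)
  }
  rbeta(1L, mean_p * concentration, (1 - mean_p) * concentration)
}

cgmap_dinuc <- c(CG = "CG", CHG = "CA", CHH = "CT")
cx_trinuc <- c(CG = "CGA", CHG = "CAG", CHH = "CTA")

#' Simulate a methylome and serialize it in both report dialects
#'
#' Generates gene models, per-cytosine ground truth (true per-site
#' methylation probability, realized binomial read counts), and writes a GTF
#' annotation plus the identical site set in the CGmap and cytosine-report
#' dialects. Zero-coverage sites appear in the cytosine report only, as the
#' emitting tools behave. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if missing); defaults to a fresh
#'   temporary directory.
#' @param cell_p Optional per-cell truth override: a tibble with columns
#'   `gene_id`, `region` (`"promoter"`/`"gene_body"`), `context` and `p`, as
#'   returned in the `cell_p` element of a previous run. Supplying the truth
#'   of one run to another seed simulates a replicate library of the same
#'   biological condition: gene-level methylation probabilities are shared
#'   while site placement and read sampling vary.
#' @return A list with file paths (`gtf`, `cgmap`, `cx_report`), the `genes`
#'   model table (same shape as [read_gene_models()] output), the `sites`
#'   ground-truth tibble (site table columns plus `gene_id`, `region`,
#'   `p_true`), the per-cell truth `cell_p`, and the `config`.
#' @export
simulate_methylome <- function(config = sim_config(), dir = tempfile("simmeth"),
                               cell_p = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config$seed)

  up <- config$promoter_upstream
  down <- config$promoter_downstream
  max_len <- config$gene_length[2L]
  slot <- up + down + max_len + 1000L
  n <- config$n_genes
  gene_id <- sprintf("SIMG%05d", seq_len(n))
  chrom <- paste0("Chr", ((seq_len(n) - 1L) %% config$n_chroms) + 1L)
  slot_idx <- ((seq_len(n) - 1L) %/% config$n_chroms)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  len <- sample(seq(config$gene_length[1L], config$gene_length[2L]), n, replace = TRUE)
  biotype <- sample(names(config$biotype_props), n, replace = TRUE,
                    prob = config$biotype_props)

  slot_start <- 3000L + slot_idx * slot
  body_start <- ifelse(strand == "+", slot_start + up, slot_start)
  body_end <- body_start + len - 1L

  if (config$edge_cases && n >= 3L) {
    # gene 1: promoter clamps at coordinate 1
    strand[1L] <- "+"
    body_start[1L] <- 800L
    body_end[1L] <- body_start[1L] + len[1L] - 1L
    chrom[1L] <- "Chr1"
    biotype[c(2L, 3L)] <- c("transposable_element", "rRNA")
  }

  tss <- ifelse(strand == "+", body_start, body_end)
  prom <- derive_promoter(tss, strand, up, down)

  genes <- tibble(
    gene_id = gene_id, biotype = biotype, chrom = chrom, strand = strand,
    body_start = as.integer(body_start), body_end = as.integer(body_end),
    promoter_start = prom$start, promoter_end = prom$end
  )

  # promoter-only flank (the upstream part not overlapping the body)
  flank_start <- ifelse(strand == "+", prom$start, body_end + 1L)
  flank_end <- ifelse(strand == "+", body_start - 1L, prom$end)

  lookup_p <- NULL
  if (!is.null(cell_p)) {
    lookup_p <- setNames(
      cell_p$p,
      paste(cell_p$gene_id, cell_p$region, cell_p$context, sep = "\r")
    )
  }

  site_rows <- vector("list", n)
  cell_rows <- vector("list", n)
  for (g in seq_len(n)) {
    regions <- list(
      promoter = c(flank_start[g], flank_end[g]),
      gene_body = c(body_start[g], body_end[g])
    )
    rows <- list()
    cells <- list()
    for (region in names(regions)) {
      r <- regions[[region]]
      if (r[1L] > r[2L]) next
      rlen <- r[2L] - r[1L] + 1L
      counts <- vapply(contexts(), function(ctx) {
        rpois(1L, config$sites_per_kb[[ctx]] * rlen / 1000)
      }, integer(1L))
      total <- sum(counts)
      if (total == 0L || total > rlen) next
      pos <- sort(sample(seq(r[1L], r[2L]), total))
      ctx <- sample(rep(contexts(), times = counts))
      p_cell <- if (is.null(lookup_p)) {
        vapply(contexts(), function(cc) {
          draw_cell_p(config$p_true[[region]][[cc]], config$gene_concentration)
        }, double(1L))
      } else {
        setNames(unname(lookup_p[
          paste(gene_id[g], region, contexts(), sep = "\r")
        ]), contexts())
      }
      if (any(is.na(p_cell))) {
        abort(sprintf("cell_p override lacks entries for gene %s / %s",
                      gene_id[g], region))
      }
      cells[[region]] <- tibble(
        gene_id = gene_id[g], region = region, context = contexts(),
        p = unname(p_cell)
      )
      p_site <- p_cell[ctx]
      cov <- rpois(total, config$mean_depth)
      meth <- rbinom(total, cov, p_site)
      rows[[region]] <- tibble(
        chrom = chrom[g], pos = pos,
        strand = sample(c("+", "-"), total, replace = TRUE),
        context = ctx,
        n_methylated = meth, n_total = cov,
        gene_id = gene_id[g], region = region, p_true = unname(p_site)
      )
    }
    site_rows[[g]] <- bind_rows(rows)
    cell_rows[[g]] <- bind_rows(cells)
  }
  sites <- bind_rows(site_rows) |>
    arrange(.data$chrom, .data$pos)
  cell_truth <- bind_rows(cell_rows)

  paths <- list(
    gtf = file.path(dir, "sim.gtf"),
    cgmap = file.path(dir, "sim.cgmap"),
    cx_report = file.path(dir, "sim.CX_report.txt")
  )

  gtf_lines <- sprintf(
    "%s\tsimulate\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_biotype \"%s\";",
    genes$chrom, genes$body_start, genes$body_end, genes$strand,
    genes$gene_id, genes$biotype
  )
  readr::write_lines(gtf_lines, paths$gtf)

  covered <- sites[sites$n_total > 0L, , drop = FALSE]
  cgmap_lines <- sprintf(
    "%s\t%s\t%d\t%s\t%s\t%.4f\t%d\t%d",
    covered$chrom, ifelse(covered$strand == "+", "C", "G"), covered$pos,
    covered$context, cgmap_dinuc[covered$context],
    covered$n_methylated / covered$n_total,
    covered$n_methylated, covered$n_total
  )
  readr::write_lines(cgmap_lines, paths$cgmap)

  cx_lines <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t%s",
    sites$chrom, sites$pos, sites$strand, sites$n_methylated,
    sites$n_total - sites$n_methylated, sites$context,
    cx_trinuc[sites$context]
  )
  readr::write_lines(cx_lines, paths$cx_report)

  c(paths, list(genes = genes, sites = sites, cell_p = cell_truth,
                config = config))
}

#' Simulate a gene-to-term annotation table
#'
#' Assigns genes to synthetic terms for exercising the enrichment module.
#' Term memberships are drawn uniformly from `gene_ids`; optionally one term
#' (`enriched_term`) preferentially samples from `enriched_genes`, planting a
#' detectable over-representation signal.
#'
#' @param gene_ids Background gene identifiers.
#' @param n_terms Number of terms.
#' @param term_size Two-element range of genes per term.
#' @param enriched_genes Optional gene ids concentrated into the first term.
#' @param seed RNG seed.
#' @return A list with `annotations` (tibble: `gene_id`, `term_id`) and
#'   `term_labels` (tibble: `term_id`, `label`).
#' @export
simulate_annotations <- function(gene_ids, n_terms = 15, term_size = c(5, 40),
                                 enriched_genes = NULL, seed = 1) {
  set.seed(seed)
  term_id <- sprintf("TERM%03d", seq_len(n_terms))
  rows <- lapply(seq_len(n_terms), function(i) {
    k <- sample(seq(term_size[1L], min(term_size[2L], length(gene_ids))), 1L)
    members <- if (i == 1L && !is.null(enriched_genes)) {
      pool <- intersect(enriched_genes, gene_ids)
      unique(c(
        sample(pool, min(k, length(pool))),
        sample(gene_ids, max(0L, k - length(pool)))
      ))
    } else {
      sample(gene_ids, k)
    }
    tibble(gene_id = members, term_id = term_id[i])
  })
  # every background gene gets at least one annotation so N spans gene_ids
  ann <- bind_rows(rows)
  missing <- setdiff(gene_ids, ann$gene_id)
  if (length(missing) > 0L) {
    ann <- bind_rows(ann, tibble(
      gene_id = missing,
      term_id = sample(term_id, length(missing), replace = TRUE)
    ))
  }
  list(
    annotations = distinct(arrange(ann, .data$term_id, .data$gene_id)),
    term_labels = tibble(
      term_id = term_id,
      label = sprintf("synthetic process %03d", seq_len(n_terms))
    )
  )
}
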