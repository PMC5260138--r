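# Readers and writers for the per-cytosine report dialects, gene annotation
# and the mtable gene-profile format.

# Parse a character field to integer, aborting with the original file line
# number of the first non-integer value.
parse_int_field <- function(x, field, line_no) {
  out <- suppressWarnings(as.integer(x))
  bad <- which(is.na(out) | !grepl("^[0-9]+$", x))
  if (length(bad) > 0L) {
    abort(sprintf(
      "line %d: %s '%s' is not a non-negative integer",
      line_no[bad[1L]], field, x[bad[1L]]
    ))
  }
  out
}

split_report_lines <- function(path, n_fields, dialect) {
  lines <- readr::read_lines(path)
  keep <- nzchar(lines)
  line_no <- which(keep)
  if (length(line_no) == 0L) {
    return(list(fields = matrix(character(), ncol = n_fields), line_no = integer()))
  }
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != n_fields)) {
    bad <- which(nf != n_fields)[1L]
    abort(sprintf(
      "line %d: expected %d tab-delimited fields for %s, found %d",
      line_no[bad], n_fields, dialect, nf[bad]
    ))
  }
  list(
    fields = matrix(unlist(parts), ncol = n_fields, byrow = TRUE),
    line_no = line_no
  )
}

check_context_field <- function(ctx, line_no) {
  bad <- which(!ctx %in% contexts())
  if (length(bad) > 0L) {
    abort(sprintf(
      "line %d: unknown cytosine context token '%s' (expected CG, CHG or CHH)",
      line_no[bad[1L]], ctx[bad[1L]]
    ))
  }
  ctx
}

check_counts <- function(n_methylated, n_total, line_no) {
  bad <- which(n_methylated > n_total)
  if (length(bad) > 0L) {
    abort(sprintf(
      "line %d: methylated count %d exceeds total count %d",
      line_no[bad[1L]], n_methylated[bad[1L]], n_total[bad[1L]]
    ))
  }
  invisible(NULL)
}

#' Read a BS-Seeker2 CGmap per-cytosine report
#'
#' CGmap files carry one covered cytosine per line in 8 tab-delimited fields:
#' chromosome, Watson-strand nucleotide (`C` for a Watson cytosine, `G` for a
#' Crick cytosine), 1-based position, context (`CG`/`CHG`/`CHH`), dinucleotide
#' context, methylation level, methylated read count, and total read count.
#' The level field is redundant with the two counts and is ignored. Lines with
#' zero total coverage are dropped. Gzip-compressed files are accepted.
#'
#' @param path Path to a CGmap file (optionally `.gz`).
#' @return A tibble of cytosine sites with columns `chrom`, `pos`, `strand`
#'   (`"+"` for Watson cytosines, `"-"` for Crick), `context`, `n_methylated`,
#'   `n_total`.
#' @seealso [read_cx_report()] for the Bismark dialect.
#' @export
#' @examples
#' f <- tempfile(fileext = ".cgmap")
#' writeLines(c("Chr1\tC\t1002\tCG\tCG\t0.75\t3\t4",
#'              "Chr1\tG\t1003\tCG\tCG\t0.0\t0\t6"), f)
#' read_cgmap(f)
read_cgmap <- function(path) {
  parsed <- split_report_lines(path, 8L, "CGmap")
  m <- parsed$fields
  ln <- parsed$line_no
  if (length(ln) == 0L) {
    return(empty_sites())
  }
  nuc <- m[, 2L]
  bad <- which(!nuc %in% c("C", "G"))
  if (length(bad) > 0L) {
    abort(sprintf(
      "line %d: nucleotide field '%s' is neither C nor G", ln[bad[1L]], nuc[bad[1L]]
    ))
  }
  ctx <- check_context_field(m[, 4L], ln)
  pos <- parse_int_field(m[, 3L], "position", ln)
  n_meth <- parse_int_field(m[, 7L], "methylated count", ln)
  n_total <- parse_int_field(m[, 8L], "total count", ln)
  check_counts(n_meth, n_total, ln)
  tibble(
    chrom = m[, 1L],
    pos = pos,
    strand = ifelse(nuc == "C", "+", "-"),
    context = ctx,
    n_methylated = n_meth,
    n_total = n_total
  ) |>
    filter(.data$n_total > 0L)
}

#' Read a Bismark genome-wide cytosine report (CX_report)
#'
#' CX_report files carry one cytosine per line (covered or not) in 7
#' tab-delimited fields: chromosome, 1-based position, strand (`+`/`-`),
#' methylated read count, unmethylated read count, context, and trinucleotide
#' context. The total coverage is the sum of the two count fields. Sites with
#' zero coverage are retained by the parser (the coverage filter in
#' [build_profiles()] removes them). Gzip-compressed files are accepted.
#'
#' @param path Path to a cytosine report (optionally `.gz`).
#' @return A tibble of cytosine sites; see [read_cgmap()] for columns.
#' @export
#' @examples
#' f <- tempfile(fileext = ".CX_report.txt")
#' writeLines(c("Chr1\t1002\t+\t3\t1\tCG\tCGA",
#'              "Chr1\t900\t-\t0\t0\tCHH\tCTA"), f)
#' read_cx_report(f)
read_cx_report <- function(path) {
  parsed <- split_report_lines(path, 7L, "CX_report")
  m <- parsed$fields
  ln <- parsed$line_no
  if (length(ln) == 0L) {
    return(empty_sites())
  }
  strand <- m[, 3L]
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad) > 0L) {
    abort(sprintf(
      "line %d: strand field '%s' is neither + nor -", ln[bad[1L]], strand[bad[1L]]
    ))
  }
  ctx <- check_context_field(m[, 6L], ln)
  pos <- parse_int_field(m[, 2L], "position", ln)
  n_meth <- parse_int_field(m[, 4L], "methylated count", ln)
  n_unmeth <- parse_int_field(m[, 5L], "unmethylated count", ln)
  tibble(
    chrom = m[, 1L],
    pos = pos,
    strand = strand,
    context = ctx,
    n_methylated = n_meth,
    n_total = n_meth + n_unmeth
  )
}

empty_sites <- function() {
  tibble(
    chrom = character(), pos = integer(), strand = character(),
    context = character(), n_methylated = integer(), n_total = integer()
  )
}

#' Read gene models from a GTF annotation
#'
#' Extracts `gene` feature rows and derives, for each gene, the gene-body
#' interval (the full feature span) and a strand-aware promoter interval
#' around the transcription start site (TSS; the feature start on `+` genes,
#' the feature end on `-` genes). Promoter offsets default to 2500 bp upstream
#' and 500 bp downstream of the TSS, so the promoter overlaps the first 500 bp
#' of the gene body. Promoters are clamped at coordinate 1; no upper clamp is
#' applied (chromosome lengths are not required).
#'
#' @param path Path to a GTF file with `gene` features carrying `gene_id`
#'   (and, when present, `gene_biotype`) attributes.
#' @param promoter_upstream,promoter_downstream Promoter extent in bp upstream
#'   and downstream of the TSS.
#' @return A tibble with one row per gene: `gene_id`, `biotype` (`"unknown"`
#'   when the annotation has none), `chrom`, `strand`, `body_start`,
#'   `body_end`, `promoter_start`, `promoter_end` (1-based, inclusive).
#' @export
read_gene_models <- function(path, promoter_upstream = 2500,
                             promoter_downstream = 500) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0L) {
    abort("no gene features found in GTF annotation")
  }
  gene_id <- as.character(gr$gene_id)
  if (any(is.na(gene_id) | !nzchar(gene_id))) {
    abort("GTF gene feature without a gene_id attribute")
  }
  dup <- unique(gene_id[duplicated(gene_id)])
  if (length(dup) > 0L) {
    abort(sprintf("duplicate gene_id in annotation: %s", dup[1L]))
  }
  biotype <- if ("gene_biotype" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$gene_biotype)
  } else {
    rep(NA_character_, length(gr))
  }
  biotype[is.na(biotype) | !nzchar(biotype)] <- "unknown"
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    abort(sprintf(
      "gene %s has unknown strand '%s'",
      gene_id[which(!strand %in% c("+", "-"))[1L]],
      strand[which(!strand %in% c("+", "-"))[1L]]
    ))
  }
  body_start <- BiocGenerics::start(gr)
  body_end <- BiocGenerics::end(gr)
  tss <- ifelse(strand == "+", body_start, body_end)
  prom <- derive_promoter(tss, strand, promoter_upstream, promoter_downstream)
  tibble(
    gene_id = gene_id,
    biotype = biotype,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    strand = strand,
    body_start = as.integer(body_start),
    body_end = as.integer(body_end),
    promoter_start = prom$start,
    promoter_end = prom$end
  )
}

mtable_header <- function() c("gene_id", mtable_measurements())

#' Write and read the mtable gene-profile format
#'
#' The mtable is a tab-delimited text file with one header line
#' (`gene_id pmt_CG pmt_CHG pmt_CHH gene_CG gene_CHG gene_CHH`) and one row
#' per gene. Levels are serialized with 4 decimal places; undefined
#' measurements are written as the literal `NaN`. `read_mtable(write_mtable(x))`
#' reproduces `x` at the serialized precision. Writing is deterministic:
#' repeated writes of the same profiles are byte-identical.
#'
#' @param profiles A data frame with a `gene_id` column and the six
#'   measurement columns (extra columns, e.g. site counts, are ignored).
#' @param path Output (or input) path; `.gz` is handled transparently.
#' @param header For `read_mtable()`, whether the file carries the header
#'   line. Headerless files are accepted with `header = FALSE`, in which case
#'   the canonical column order is assumed.
#' @return `write_mtable()` returns `path` invisibly; `read_mtable()` returns
#'   a tibble of profiles.
#' @export
#' @examples
#' p <- tibble::tibble(gene_id = "G1", pmt_CG = 0.5, pmt_CHG = NaN,
#'                     pmt_CHH = 0, gene_CG = 1, gene_CHG = 0.25, gene_CHH = NaN)
#' f <- tempfile(fileext = ".mtable")
#' write_mtable(p, f)
#' read_mtable(f)
write_mtable <- function(profiles, path) {
  miss <- setdiff(mtable_header(), names(profiles))
  if (length(miss) > 0L) {
    abort(sprintf("profiles lack mtable column(s): %s", paste(miss, collapse = ", ")))
  }
  rows <- if (nrow(profiles) == 0L) {
    character()
  } else {
    cells <- vapply(mtable_measurements(), function(mn) {
      v <- as.numeric(profiles[[mn]])
      ifelse(is.na(v), "NaN", sprintf("%.4f", v))
    }, character(nrow(profiles)))
    if (nrow(profiles) == 1L) cells <- matrix(cells, nrow = 1L)
    paste(profiles$gene_id, apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  }
  readr::write_lines(c(paste(mtable_header(), collapse = "\t"), rows), path)
  invisible(path)
}

#' @rdname write_mtable
#' @export
read_mtable <- function(path, header = TRUE) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (header) {
    if (length(lines) == 0L ||
        !identical(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]], mtable_header())) {
      abort(sprintf(
        "mtable header mismatch: expected '%s'",
        paste(mtable_header(), collapse = "\t")
      ))
    }
    lines <- lines[-1L]
  }
  if (length(lines) == 0L) {
    out <- c(list(gene_id = character()),
             setNames(rep(list(double()), 6L), mtable_measurements()))
    return(as_tibble(out))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 7L)) {
    bad <- which(nf != 7L)[1L]
    abort(sprintf(
      "mtable row '%s': expected 7 fields, found %d",
      parts[[bad]][1L], nf[bad]
    ))
  }
  m <- matrix(unlist(parts), ncol = 7L, byrow = TRUE)
  vals <- m[, -1L, drop = FALSE]
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & vals != "NaN", arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "mtable row '%s': cell '%s' is neither numeric nor NaN",
      m[bad[1L, 1L], 1L], vals[bad[1L, 1L], bad[1L, 2L]]
    ))
  }
  num[is.na(num)] <- NaN
  out <- as_tibble(setNames(
    c(list(m[, 1L]), lapply(seq_len(6L), function(j) num[, j])),
    mtable_header()
  ))
  out
}
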