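# Readers/writers: the two per-cytosine dialects, GTF gene models, mtable.

write_tmp <- function(lines, ext = ".txt") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("CGmap lines map to sites with strand from the nucleotide column", {
  f <- write_tmp(c(
    "Chr1\tC\t1002\tCG\tCG\t0.75\t3\t4",
    "Chr1\tG\t1003\tCG\tCG\t0.0\t0\t6",
    "Chr2\tC\t50\tCHH\tCT\t0.5\t1\t2",
    "Chr2\tC\t60\tCHG\tCA\t0\t0\t0" # zero coverage: dropped
  ))
  s <- read_cgmap(f)
  expect_equal(nrow(s), 3L)
  expect_equal(s$strand, c("+", "-", "+"))
  expect_equal(s$pos, c(1002L, 1003L, 50L))
  expect_equal(s$n_methylated, c(3L, 0L, 1L))
  expect_equal(s$n_total, c(4L, 6L, 2L))
  expect_equal(s$context, c("CG", "CG", "CHH"))
})

test_that("CGmap parse errors name the offending line", {
  bad_cols <- write_tmp(c("Chr1\tC\t1\tCG\tCG\t0\t0\t4", "Chr1\tC\t2\tCG"))
  expect_error(read_cgmap(bad_cols), "line 2.*8 tab-delimited fields")
  bad_ctx <- write_tmp("Chr1\tC\t1\tCpG\tCG\t0\t0\t4")
  expect_error(read_cgmap(bad_ctx), "line 1.*context token 'CpG'")
  bad_int <- write_tmp("Chr1\tC\t1\tCG\tCG\t0\tx\t4")
  expect_error(read_cgmap(bad_int), "line 1.*'x'")
  bad_counts <- write_tmp("Chr1\tC\t1\tCG\tCG\t0\t5\t4")
  expect_error(read_cgmap(bad_counts), "line 1.*exceeds")
})

test_that("cytosine-report lines sum counts and keep uncovered sites", {
  f <- write_tmp(c(
    "Chr1\t1002\t+\t3\t1\tCG\tCGA",
    "Chr1\t900\t-\t0\t0\tCHH\tCTA"
  ))
  s <- read_cx_report(f)
  expect_equal(nrow(s), 2L)
  expect_equal(s$n_total, c(4L, 0L))
  expect_equal(s$n_methylated, c(3L, 0L))
  expect_equal(s$strand, c("+", "-"))
  expect_error(
    read_cx_report(write_tmp("Chr1\t1\t*\t0\t0\tCG\tCGA")),
    "line 1.*strand"
  )
})

test_that("the two dialect encodings of one methylome parse identically", {
  sim <- simulate_methylome(sim_config(seed = 11, n_genes = 12))
  a <- read_cgmap(sim$cgmap)
  b <- read_cx_report(sim$cx_report)
  b <- b[b$n_total > 0L, ]
  key <- function(s) {
    with(s[order(s$chrom, s$pos), ],
         paste(chrom, pos, strand, context, n_methylated, n_total))
  }
  expect_identical(key(a), key(b))
  # counts identical to the simulator's ground truth
  truth <- sim$sites[sim$sites$n_total > 0L, ]
  expect_identical(key(a), key(truth))
})

test_that("gene models derive strand-aware, clamped promoters from the GTF", {
  f <- write_tmp(c(
    "Chr1\tsrc\tgene\t10000\t12000\t.\t+\t.\tgene_id \"Gp\"; gene_biotype \"protein_coding\";",
    "Chr1\tsrc\tgene\t20000\t22000\t.\t-\t.\tgene_id \"Gm\"; gene_biotype \"miRNA\";",
    "Chr2\tsrc\tgene\t1000\t3000\t.\t+\t.\tgene_id \"Gc\";"
  ), ext = ".gtf")
  g <- read_gene_models(f)
  expect_equal(g$gene_id, c("Gp", "Gm", "Gc"))
  # '+' gene: promoter is TSS-2500 .. TSS+500
  expect_equal(unlist(g[1, c("promoter_start", "promoter_end")], use.names = FALSE),
               c(7500L, 10500L))
  # '-' gene: TSS is the feature end, offsets mirrored
  expect_equal(unlist(g[2, c("promoter_start", "promoter_end")], use.names = FALSE),
               c(21500L, 24500L))
  # lower clamp at coordinate 1
  expect_equal(unlist(g[3, c("promoter_start", "promoter_end")], use.names = FALSE),
               c(1L, 1500L))
  expect_equal(g$biotype, c("protein_coding", "miRNA", "unknown"))
})

test_that("GTF reader rejects empty and duplicated annotations", {
  no_genes <- write_tmp(
    "Chr1\tsrc\texon\t1\t10\t.\t+\t.\tgene_id \"G1\";",
    ext = ".gtf"
  )
  expect_error(read_gene_models(no_genes), "no gene features")
  dup <- write_tmp(c(
    "Chr1\tsrc\tgene\t1\t10\t.\t+\t.\tgene_id \"G1\";",
    "Chr1\tsrc\tgene\t20\t30\t.\t+\t.\tgene_id \"G1\";"
  ), ext = ".gtf")
  expect_error(read_gene_models(dup), "duplicate gene_id.*G1")
})

test_that("mtable round-trips at serialized precision, including NaN cells", {
  profiles <- tibble::tibble(
    gene_id = c("G1", "G2", "G3"),
    pmt_CG = c(0.12345, NaN, 1),
    pmt_CHG = c(0, NaN, 0.5),
    pmt_CHH = c(NaN, NaN, 0.3333),
    gene_CG = c(0.9, NaN, 0.0001),
    gene_CHG = c(0.25, NaN, 0),
    gene_CHH = c(1, NaN, NaN)
  )
  f <- withr::local_tempfile(fileext = ".mtable")
  write_mtable(profiles, f)
  lines <- readLines(f)
  expect_equal(lines[1], "gene_id\tpmt_CG\tpmt_CHG\tpmt_CHH\tgene_CG\tgene_CHG\tgene_CHH")
  expect_equal(lines[3], "G2\tNaN\tNaN\tNaN\tNaN\tNaN\tNaN")
  back <- read_mtable(f)
  for (mn in c("pmt_CG", "pmt_CHG", "pmt_CHH", "gene_CG", "gene_CHG", "gene_CHH")) {
    expect_equal(back[[mn]], round(profiles[[mn]], 4))
  }
  expect_true(all(is.nan(unlist(back[2, -1]))))
})

test_that("mtable writing is deterministic and handles empty collections", {
  set.seed(42)
  profiles <- random_mtable(sprintf("G%03d", 1:200))
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_mtable(profiles, f1)
  write_mtable(profiles, f2)
  expect_identical(readLines(f1), readLines(f2))

  f3 <- withr::local_tempfile()
  write_mtable(profiles[0, ], f3)
  expect_equal(length(readLines(f3)), 1L) # header only
  expect_equal(nrow(read_mtable(f3)), 0L)
})

test_that("mtable reader rejects malformed files with informative messages", {
  f <- write_tmp(c("gene\tbad\theader"))
  expect_error(read_mtable(f), "header mismatch")
  f2 <- write_tmp(c(
    "gene_id\tpmt_CG\tpmt_CHG\tpmt_CHH\tgene_CG\tgene_CHG\tgene_CHH",
    "G1\t0.1\t0.2\toops\t0.4\t0.5\t0.6"
  ))
  expect_error(read_mtable(f2), "row 'G1'.*'oops'")
  # headerless files accepted with the flag
  f3 <- write_tmp("G1\t0.1\t0.2\tNaN\t0.4\t0.5\t0.6")
  back <- read_mtable(f3, header = FALSE)
  expect_equal(back$gene_id, "G1")
  expect_true(is.nan(back$pmt_CHH))
})

test_that("parsed sites always satisfy 0 <= n_methylated <= n_total", {
  sim <- simulate_methylome(sim_config(seed = 5, n_genes = 10))
  for (s in list(read_cgmap(sim$cgmap), read_cx_report(sim$cx_report))) {
    expect_true(all(s$n_methylated >= 0L))
    expect_true(all(s$n_methylated <= s$n_total))
  }
})
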