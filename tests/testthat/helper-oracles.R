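# Independent reference implementations used as oracles. These deliberately
# share no code path with the package: plain per-gene filtering loops, an
# O(n^3) agglomeration that rescans member pairs, and exhaustive subset
# enumeration for the hypergeometric model.

# Loop-based gene-profile reference: one vector scan per (gene, compartment,
# context) cell, no overlap machinery.
naive_profiles <- function(sites, genes, min_coverage = 4, min_sites = 5,
                           excluded = default_excluded_biotypes()) {
  measurements <- c("pmt_CG", "pmt_CHG", "pmt_CHH",
                    "gene_CG", "gene_CHG", "gene_CHH")
  out <- data.frame(gene_id = genes$gene_id)
  for (mn in measurements) out[[mn]] <- NaN
  for (mn in measurements) out[[paste0("n_", mn)]] <- 0L
  for (gi in seq_len(nrow(genes))) {
    for (comp in c("pmt", "gene")) {
      if (comp == "pmt" && genes$biotype[gi] %in% excluded) next
      lo <- if (comp == "pmt") genes$promoter_start[gi] else genes$body_start[gi]
      hi <- if (comp == "pmt") genes$promoter_end[gi] else genes$body_end[gi]
      for (ctx in c("CG", "CHG", "CHH")) {
        keep <- sites$chrom == genes$chrom[gi] &
          sites$context == ctx &
          sites$pos >= lo & sites$pos <= hi &
          sites$n_total >= min_coverage
        k <- sum(keep)
        mn <- paste0(comp, "_", ctx)
        out[[paste0("n_", mn)]][gi] <- k
        if (k >= min_sites) {
          out[[mn]][gi] <- mean(sites$n_methylated[keep] / sites$n_total[keep])
        }
      }
    }
  }
  out
}

# Brute-force pairwise-pool DMG scan with explicit per-gene loops.
naive_dmgs <- function(pool_a, pool_b, measurement, delta,
                       direction = "both") {
  universe <- sort(unique(unlist(
    lapply(c(pool_a, pool_b), function(d) d$gene_id)
  )))
  hits <- character()
  for (g in universe) {
    va <- vapply(pool_a, function(d) {
      i <- match(g, d$gene_id)
      if (is.na(i)) NaN else d[[measurement]][i]
    }, double(1))
    vb <- vapply(pool_b, function(d) {
      i <- match(g, d$gene_id)
      if (is.na(i)) NaN else d[[measurement]][i]
    }, double(1))
    if (any(is.na(va)) || any(is.na(vb))) next
    dd <- mean(vb) - mean(va)
    ok <- abs(dd) >= delta && switch(direction,
      both = TRUE, hyper = dd > 0, hypo = dd < 0
    )
    if (ok) hits <- c(hits, g)
  }
  hits
}

# O(n^3) single-linkage reference: keeps explicit member lists and rescans
# all member pairs with its own Euclidean distance at every step.
naive_single_linkage_heights <- function(m) {
  euclid <- function(a, b) sqrt(sum((a - b)^2))
  clusters <- lapply(seq_len(nrow(m)), identity)
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf
    bi <- bj <- NA_integer_
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dmin <- Inf
        for (a in clusters[[i]]) {
          for (b in clusters[[j]]) {
            dmin <- min(dmin, euclid(m[a, ], m[b, ]))
          }
        }
        if (dmin < best) {
          best <- dmin
          bi <- i
          bj <- j
        }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# Exact hypergeometric pmf by exhaustive enumeration: all C(N, n) draws of
# the class from the background, counting test-set members in each.
enum_hypergeom_pmf <- function(x, N, m, n) {
  if (n == 0L) {
    return(as.numeric(x == 0L))
  }
  draws <- utils::combn(N, n)
  counts <- colSums(draws <= m) # background items 1..m are the test set
  mean(counts == x)
}

enum_hypergeom_tail <- function(x, N, m, n) {
  if (n == 0L) {
    return(as.numeric(x <= 0L))
  }
  draws <- utils::combn(N, n)
  counts <- colSums(draws <= m)
  mean(counts >= x)
}

# Convenience: a tiny deterministic site table spanning one chromosome.
make_sites <- function(pos, context = "CG", n_methylated, n_total,
                       chrom = "Chr1", strand = "+") {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), strand = strand,
    context = context,
    n_methylated = as.integer(n_methylated),
    n_total = as.integer(n_total)
  )
}

make_gene <- function(gene_id = "G1", biotype = "protein_coding",
                      chrom = "Chr1", strand = "+",
                      body_start = 1000L, body_end = 3000L,
                      promoter_upstream = 2500, promoter_downstream = 500) {
  tss <- if (strand == "+") body_start else body_end
  prom <- derive_promoter(tss, strand, promoter_upstream, promoter_downstream)
  tibble::tibble(
    gene_id = gene_id, biotype = biotype, chrom = chrom, strand = strand,
    body_start = as.integer(body_start), body_end = as.integer(body_end),
    promoter_start = prom$start, promoter_end = prom$end
  )
}

# Random mtable-shaped profile table for compare/cluster tests.
random_mtable <- function(gene_ids, nan_frac = 0.1) {
  vals <- lapply(1:6, function(i) {
    v <- runif(length(gene_ids))
    v[runif(length(gene_ids)) < nan_frac] <- NaN
    v
  })
  names(vals) <- c("pmt_CG", "pmt_CHG", "pmt_CHH",
                   "gene_CG", "gene_CHG", "gene_CHH")
  tibble::as_tibble(c(list(gene_id = gene_ids), vals))
}
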