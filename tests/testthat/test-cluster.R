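# Single-linkage clustering, matrix preparation and heatmap assembly.

test_that("matrix preparation drops incomplete genes and reports the count", {
  ids <- c("G1", "G2", "G3")
  a <- random_mtable(ids, nan_frac = 0)
  b <- random_mtable(ids, nan_frac = 0)
  a$gene_CG[2] <- NaN
  mat <- prepare_matrix(list(x = a, y = b), "gene_CG")
  expect_equal(dim(mat$values), c(2L, 2L))
  expect_equal(mat$n_dropped, 1L)
  expect_false("G2" %in% rownames(mat$values))
  # fill policy keeps the gene
  mat2 <- prepare_matrix(list(x = a, y = b), "gene_CG",
                         na_policy = "fill", fill_value = 0)
  expect_equal(nrow(mat2$values), 3L)
  expect_equal(mat2$values["G2", "x"], 0)
  # cells equal the mtable cells verbatim
  expect_equal(mat$values["G1", "x"], a$gene_CG[1])
  expect_equal(mat$values["G3", "y"], b$gene_CG[3])
})

test_that("an all-NaN measurement cannot be clustered", {
  ids <- c("G1", "G2", "G3")
  a <- random_mtable(ids, nan_frac = 0)
  b <- random_mtable(ids, nan_frac = 0)
  a$pmt_CHH <- NaN
  expect_error(prepare_matrix(list(a = a, b = b), "pmt_CHH"), "too small")
  expect_error(prepare_matrix(list(a = a), "gene_CG"), ">= 2 datasets")
})

test_that("identical items merge at distance zero", {
  m <- rbind(c(0.2, 0.4), c(0.2, 0.4), c(0.9, 0.9))
  d <- single_linkage(m)
  expect_equal(d$merges$height[1], 0)
  expect_equal(sort(c(d$merges$a[1], d$merges$b[1])), c(-2L, -1L))
})

test_that("1-D points at 0, 1, 3 merge at heights 1 then 2", {
  d <- single_linkage(matrix(c(0, 1, 3), ncol = 1))
  expect_equal(d$merges$height, c(1, 2))
  # single linkage: d({0,1},{3}) = min(|3-1|, |3-0|) = 2
  expect_equal(d$merges$a, c(-1L, 1L))
  expect_equal(d$merges$b, c(-2L, -3L))
})

test_that("merge heights equal the naive reference and the MST edge weights", {
  skip_if_not_installed("igraph")
  set.seed(51)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    m <- matrix(runif(n * 3), ncol = 3)
    d <- single_linkage(m)
    expect_equal(d$merges$height, naive_single_linkage_heights(m),
                 tolerance = 1e-12)
    # single-linkage heights are the sorted MST edge weights
    g <- igraph::graph_from_adjacency_matrix(as.matrix(dist(m)),
                                             mode = "undirected",
                                             weighted = TRUE)
    mst_w <- sort(igraph::E(igraph::mst(g))$weight)
    expect_equal(sort(d$merges$height), mst_w, tolerance = 1e-12)
    # monotone merges
    expect_true(all(diff(d$merges$height) >= -1e-12))
  }
})

test_that("flat clusterings agree with hclust single linkage", {
  set.seed(52)
  partition_key <- function(labels) {
    split(seq_along(labels), labels) |>
      lapply(paste, collapse = ",") |>
      unlist() |>
      sort() |>
      paste(collapse = "|")
  }
  for (rep in 1:10) {
    n <- sample(5:10, 1)
    m <- matrix(runif(n * 2), ncol = 2)
    d <- single_linkage(m)
    hc <- hclust(dist(m), method = "single")
    for (h in unique(c(d$merges$height / 2, d$merges$height + 1e-9))) {
      mine <- cut_dendrogram(d, h)
      ref <- cutree(hc, h = h)
      expect_equal(partition_key(mine), partition_key(ref))
    }
  }
})

test_that("item order permutations preserve the merge-height multiset", {
  set.seed(53)
  m <- matrix(runif(8 * 3), ncol = 3, dimnames = list(paste0("r", 1:8), NULL))
  h0 <- sort(single_linkage(m)$merges$height)
  for (i in 1:5) {
    perm <- sample(8)
    expect_equal(sort(single_linkage(m[perm, ])$merges$height), h0,
                 tolerance = 1e-12)
  }
})

test_that("planted two-block structure is contiguous in leaf order", {
  set.seed(54)
  for (rep in 1:5) {
    lo <- matrix(runif(10 * 4, 0.0, 0.15), ncol = 4)
    hi <- matrix(runif(8 * 4, 0.75, 0.95), ncol = 4)
    m <- rbind(lo, hi)
    rownames(m) <- paste0("g", seq_len(nrow(m)))
    ord <- single_linkage(m)$order
    block <- ord <= 10
    # one contiguous run of each block
    expect_lte(sum(diff(block) != 0), 1L)
  }
})

test_that("2D heatmap clustering reorders by both leaf orders", {
  set.seed(55)
  ids <- sprintf("G%02d", 1:12)
  mtabs <- list(a = random_mtable(ids, 0), b = random_mtable(ids, 0),
                c = random_mtable(ids, 0))
  mat <- prepare_matrix(mtabs, "gene_CHH")
  hm <- cluster_heatmap(mat)
  expect_equal(rownames(hm$values), rownames(mat$values)[hm$row_tree$order])
  expect_equal(colnames(hm$values), colnames(mat$values)[hm$col_tree$order])
  expect_equal(sort(as.vector(hm$values)), sort(as.vector(mat$values)))
  g <- glance(hm$row_tree)
  expect_equal(g$n_leaves, 12L)
  expect_equal(g$n_merges, 11L)
})

test_that("replicate datasets join before diverging ones in the column tree", {
  # two control replicates around one mean, three shifted mutants
  set.seed(56)
  ids <- sprintf("G%02d", 1:40)
  base <- runif(40, 0.1, 0.3)
  mk <- function(center, noise = 0.02) {
    out <- random_mtable(ids, 0)
    out$gene_CHH <- pmin(1, pmax(0, center + rnorm(40, 0, noise)))
    out
  }
  mtabs <- list(ctl1 = mk(base), ctl2 = mk(base),
                mut1 = mk(base + 0.4), mut2 = mk(base + 0.45),
                mut3 = mk(base + 0.5))
  ct <- single_linkage(prepare_matrix(mtabs, "gene_CHH"), on = "cols")
  first <- ct$merges[1, ]
  expect_setequal(c(first$a, first$b), c(-1L, -2L))
})

test_that("newick serialization preserves linkage heights", {
  skip_if_not_installed("ape")
  set.seed(57)
  m <- matrix(runif(6 * 3), ncol = 3, dimnames = list(paste0("g", 1:6), NULL))
  d <- single_linkage(m)
  tr <- ape::read.tree(text = as_newick(d))
  expect_setequal(tr$tip.label, paste0("g", 1:6))
  # root-to-tip path length equals the final merge height for every tip
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  expect_equal(unname(depths), rep(max(d$merges$height), 6), tolerance = 1e-6)
})

test_that("heatmap files round-trip through disk", {
  set.seed(58)
  ids <- sprintf("G%02d", 1:8)
  mtabs <- list(a = random_mtable(ids, 0), b = random_mtable(ids, 0))
  hm <- cluster_heatmap(prepare_matrix(mtabs, "pmt_CG"))
  dir <- withr::local_tempdir()
  write_heatmap(hm, dir)
  mat <- readr::read_tsv(file.path(dir, "matrix.tsv"), show_col_types = FALSE)
  expect_equal(mat$gene_id, rownames(hm$values))
  expect_true(file.exists(file.path(dir, "row_tree.nwk")))
  p <- autoplot(hm)
  expect_s3_class(p, "ggplot")
})
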