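# Single-linkage hierarchical clustering with Euclidean distance over the
# gene x dataset methylation matrix, for heatmap presentation.
#
# The agglomeration is authored here (with a deterministic tie-break: among
# equally distant pairs, the pair containing the lowest original item index
# wins) rather than delegated, so merge records and leaf order are fully
# specified; stats::hclust and minimum-spanning-tree orderings serve as
# independent cross-checks in the test suite.

#' Assemble a clustering-ready methylation matrix
#'
#' Collects one measurement across several datasets into a genes x datasets
#' matrix. Genes with an undefined (`NaN`) or missing value in any dataset
#' are dropped under the default complete-case policy (`na_policy =
#' "drop_genes"`); `na_policy = "fill"` substitutes `fill_value` instead.
#'
#' @param mtables A named list of mtable profile tables (see
#'   [read_mtable()]); at least two.
#' @param measurement One of the six measurement names.
#' @param genes Optional gene subset (a `gene_set`, character vector, or
#'   data frame with `gene_id`) applied before NaN handling.
#' @param na_policy `"drop_genes"` (default) or `"fill"`.
#' @param fill_value Replacement level under `na_policy = "fill"`.
#' @return An object of class `meth_matrix`: a list with `values` (numeric
#'   matrix, gene rownames, dataset colnames), `measurement` and
#'   `n_dropped`.
#' @export
prepare_matrix <- function(mtables, measurement, genes = NULL,
                           na_policy = c("drop_genes", "fill"),
                           fill_value = 0) {
  na_policy <- match.arg(na_policy)
  check_measurement(measurement)
  ds <- as_mtable_list(mtables, "dataset")
  if (length(ds) < 2L) abort("matrix too small to cluster: need >= 2 datasets")
  vals <- measurement_matrix(ds, measurement)
  if (!is.null(genes)) {
    keep_ids <- as_gene_set(genes)$genes
    vals <- vals[rownames(vals) %in% keep_ids, , drop = FALSE]
  }
  incomplete <- apply(vals, 1L, function(r) any(is.na(r)))
  if (na_policy == "drop_genes") {
    n_dropped <- sum(incomplete)
    vals <- vals[!incomplete, , drop = FALSE]
  } else {
    n_dropped <- 0L
    vals[is.na(vals)] <- fill_value
  }
  if (nrow(vals) < 2L || ncol(vals) < 2L) {
    abort(sprintf(
      "matrix too small to cluster: %d gene(s) x %d dataset(s) after NaN handling",
      nrow(vals), ncol(vals)
    ))
  }
  structure(
    list(values = vals, measurement = measurement, n_dropped = n_dropped),
    class = "meth_matrix"
  )
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf(
    "<meth_matrix> %s: %d genes x %d datasets (%d gene(s) dropped as incomplete)\n",
    x$measurement, nrow(x$values), ncol(x$values), x$n_dropped
  ))
  invisible(x)
}

item_matrix <- function(x, on) {
  m <- if (inherits(x, "meth_matrix")) x$values else as.matrix(x)
  if (on == "cols") m <- t(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("item", seq_len(nrow(m)))
  m
}

#' Single-linkage agglomerative clustering
#'
#' Clusters the rows (or columns) of a methylation matrix by Euclidean
#' distance with single linkage: the distance between two clusters is the
#' minimum pairwise distance between their members, so merge heights are
#' non-decreasing. Ties are broken deterministically in favour of the pair
#' containing the lowest original item index (then the lowest index on the
#' other side). The leaf order is induced by the merges, with the
#' lower-indexed cluster kept on the left.
#'
#' @param x A `meth_matrix` from [prepare_matrix()] or a plain numeric
#'   matrix (items in rows).
#' @param on `"rows"` (default) or `"cols"`: which axis to cluster.
#' @return An object of class `meth_dendrogram`: a list with `merges`
#'   (tibble with `step`, `a`, `b`, `height`; negative entries are leaves by
#'   original index, positive entries earlier merge steps), `order` (leaf
#'   indices), `labels`, `n`, and `on`.
#' @export
#' @examples
#' m <- matrix(c(0, 1, 3), ncol = 1)
#' single_linkage(m)$merges  # (1,2) at height 1, then with 3 at height 2
single_linkage <- function(x, on = c("rows", "cols")) {
  on <- match.arg(on)
  m <- item_matrix(x, on)
  n <- nrow(m)
  if (n < 2L) abort("need at least 2 items to cluster")

  D <- as.matrix(dist(m))
  diag(D) <- Inf
  active <- rep(TRUE, n)
  cluster_min <- seq_len(n)      # lowest original index per active cluster
  node_id <- -seq_len(n)         # merge-record label (hclust convention)
  leaves <- as.list(seq_len(n))  # ordered leaves per active cluster

  rec_a <- integer(n - 1L)
  rec_b <- integer(n - 1L)
  rec_h <- double(n - 1L)

  for (step in seq_len(n - 1L)) {
    act <- which(active)
    sub <- D[act, act, drop = FALSE]
    dmin <- min(sub)
    hit <- which(sub == dmin, arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    ci <- act[hit[, 1L]]
    cj <- act[hit[, 2L]]
    key1 <- pmin(cluster_min[ci], cluster_min[cj])
    key2 <- pmax(cluster_min[ci], cluster_min[cj])
    pick <- order(key1, key2)[1L]
    i <- ci[pick]
    j <- cj[pick]
    # keep the cluster containing the lower original index on the left
    if (cluster_min[j] < cluster_min[i]) {
      tmp <- i; i <- j; j <- tmp
    }
    rec_a[step] <- node_id[i]
    rec_b[step] <- node_id[j]
    rec_h[step] <- dmin
    leaves[[i]] <- c(leaves[[i]], leaves[[j]])
    D[i, ] <- pmin(D[i, ], D[j, ])
    D[, i] <- D[i, ]
    D[i, i] <- Inf
    D[j, ] <- Inf
    D[, j] <- Inf
    active[j] <- FALSE
    cluster_min[i] <- min(cluster_min[i], cluster_min[j])
    node_id[i] <- step
  }

  root <- which(active)
  structure(
    list(
      merges = tibble(step = seq_len(n - 1L), a = rec_a, b = rec_b, height = rec_h),
      order = leaves[[root]],
      labels = rownames(m),
      n = n,
      on = on
    ),
    class = "meth_dendrogram"
  )
}

#' @export
print.meth_dendrogram <- function(x, ...) {
  cat(sprintf(
    "<meth_dendrogram> single linkage over %d %s; merge heights %.4g .. %.4g\n",
    x$n, x$on, min(x$merges$height), max(x$merges$height)
  ))
  invisible(x)
}

#' @export
tidy.meth_dendrogram <- function(x, ...) x$merges

#' @export
glance.meth_dendrogram <- function(x, ...) {
  tibble(
    n_leaves = x$n,
    n_merges = nrow(x$merges),
    max_height = max(x$merges$height)
  )
}

#' Convert a single-linkage dendrogram to an hclust object
#'
#' @param x A `meth_dendrogram`.
#' @return A `stats::hclust` object (usable with `plot()` and `cutree()`).
#' @export
as_hclust <- function(x) {
  stopifnot(inherits(x, "meth_dendrogram"))
  structure(
    list(
      merge = cbind(x$merges$a, x$merges$b),
      height = x$merges$height,
      order = x$order,
      labels = x$labels,
      method = "single",
      dist.method = "euclidean"
    ),
    class = "hclust"
  )
}

#' Flat clusters from a dendrogram at a height cut
#'
#' Items joined by merges at height `<= h` share a cluster label.
#'
#' @param x A `meth_dendrogram`.
#' @param h Height threshold.
#' @return Integer cluster memberships (labelled by item), numbered by
#'   first appearance.
#' @export
cut_dendrogram <- function(x, h) {
  stopifnot(inherits(x, "meth_dendrogram"))
  parent <- seq_len(x$n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  # union-find over merges under the cut
  node_members <- vector("list", nrow(x$merges))
  get_members <- function(id) if (id < 0L) -id else node_members[[id]]
  for (s in seq_len(nrow(x$merges))) {
    node_members[[s]] <- c(get_members(x$merges$a[s]), get_members(x$merges$b[s]))
    if (x$merges$height[s] <= h) {
      mm <- node_members[[s]]
      r <- find(mm[1L])
      for (i in mm[-1L]) parent[find(i)] <- r
    }
  }
  roots <- vapply(seq_len(x$n), find, integer(1L))
  labels <- setNames(match(roots, unique(roots)), x$labels)
  labels
}

#' Two-dimensional clustering for heatmap presentation
#'
#' Clusters genes (rows) and datasets (columns) independently by
#' single-linkage Euclidean distance and reorders the matrix by both leaf
#' orders.
#'
#' @param x A `meth_matrix` from [prepare_matrix()].
#' @return An object of class `meth_heatmap`: a list with `row_tree` and
#'   `col_tree` (`meth_dendrogram`s), `values` (the reordered matrix) and
#'   `measurement`.
#' @export
cluster_heatmap <- function(x) {
  stopifnot(inherits(x, "meth_matrix"))
  row_tree <- single_linkage(x, on = "rows")
  col_tree <- single_linkage(x, on = "cols")
  structure(
    list(
      row_tree = row_tree,
      col_tree = col_tree,
      values = x$values[row_tree$order, col_tree$order, drop = FALSE],
      measurement = x$measurement
    ),
    class = "meth_heatmap"
  )
}

newick_escape <- function(x) gsub("[ ,;:()\\[\\]]", "_", x)

#' Serialize a dendrogram as a Newick tree
#'
#' Branch lengths encode linkage heights: each child branch spans the
#' difference between its parent's merge height and its own (leaves sit at
#' height 0), so root-to-leaf path lengths equal the final merge height.
#'
#' @param x A `meth_dendrogram`.
#' @return A Newick string (terminated with `;`).
#' @export
as_newick <- function(x) {
  stopifnot(inherits(x, "meth_dendrogram"))
  node_str <- function(id) {
    if (id < 0L) {
      list(str = newick_escape(x$labels[-id]), height = 0)
    } else {
      a <- node_str(x$merges$a[id])
      b <- node_str(x$merges$b[id])
      h <- x$merges$height[id]
      list(
        str = sprintf("(%s:%g,%s:%g)", a$str, h - a$height, b$str, h - b$height),
        height = h
      )
    }
  }
  paste0(node_str(nrow(x$merges))$str, ";")
}

#' Write a clustered heatmap to disk
#'
#' Writes the reordered matrix as TSV (`matrix.tsv`, first column `gene_id`)
#' and the two dendrograms as Newick trees (`row_tree.nwk`,
#' `col_tree.nwk`).
#'
#' @param x A `meth_heatmap` from [cluster_heatmap()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_heatmap <- function(x, dir) {
  stopifnot(inherits(x, "meth_heatmap"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mat <- as_tibble(x$values, rownames = "gene_id")
  readr::write_tsv(mat, file.path(dir, "matrix.tsv"), progress = FALSE)
  readr::write_lines(as_newick(x$row_tree), file.path(dir, "row_tree.nwk"))
  readr::write_lines(as_newick(x$col_tree), file.path(dir, "col_tree.nwk"))
  invisible(dir)
}

#' Heatmap plot of a 2D-clustered methylation matrix
#'
#' @param object A `meth_heatmap` from [cluster_heatmap()].
#' @param ... Unused.
#' @return A ggplot object with rows and columns in dendrogram leaf order.
#' @export
autoplot.meth_heatmap <- function(object, ...) {
  df <- as_tibble(object$values, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "dataset", values_to = "level")
  df$gene_id <- factor(df$gene_id, levels = rev(rownames(object$values)))
  df$dataset <- factor(df$dataset, levels = colnames(object$values))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dataset, y = .data$gene_id,
                                   fill = .data$level)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#f7fbff", high = "#67000d",
                                 limits = c(0, 1), name = object$measurement) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}
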