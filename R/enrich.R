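# Hypergeometric over-representation analysis of a gene list against a
# gene -> term annotation table.
#
# The model: drawing n genes (the annotation class) from a background of N
# annotated genes of which m belong to the test list, the probability of
# exactly x list members in the class is
#   p(x | N, m, n) = C(m, x) C(N - m, n - x) / C(N, n),
# and the enrichment p-value is the upper tail sum_{k >= x} p(k | N, m, n).
# Binomial coefficients are computed in log space so genome-scale N is safe.

check_hypergeom_args <- function(x, N, m, n) {
  ints <- c(x, N, m, n)
  if (any(ints < 0) || any(ints != round(ints))) {
    abort("hypergeometric parameters must be non-negative integers")
  }
  if (any(x > m) || any(m > N) || any(n > N)) {
    abort("hypergeometric parameters violate 0 <= x <= m <= N, 0 <= n <= N")
  }
  # x below the support floor max(0, n - (N - m)) is simply impossible and
  # yields probability 0 rather than an error (lchoose returns -Inf there)
  invisible(NULL)
}

#' Hypergeometric probability mass function
#'
#' Exact probability of observing `x` test-set genes in an annotation class
#' when `n` class genes are drawn from a background of `N` annotated genes,
#' `m` of which are in the test set:
#' `C(m, x) * C(N - m, n - x) / C(N, n)`. Vectorized over `x`.
#'
#' @param x Number of test-set genes in the class.
#' @param N Background size (annotated genes).
#' @param m Test-set size (annotated members).
#' @param n Class size in the background.
#' @return Probability value(s).
#' @export
#' @examples
#' hypergeom_pmf(5, N = 10, m = 5, n = 5)  # 1 / choose(10, 5) = 1/252
hypergeom_pmf <- function(x, N, m, n) {
  check_hypergeom_args(x, N, m, n)
  exp(lchoose(m, x) + lchoose(N - m, n - x) - lchoose(N, n))
}

#' @rdname hypergeom_pmf
#' @description `hypergeom_tail()` is the upper-tail enrichment p-value
#'   `P(X >= x) = sum_{k = x}^{min(m, n)} p(k | N, m, n)`.
#' @export
hypergeom_tail <- function(x, N, m, n) {
  if (length(x) != 1L) abort("hypergeom_tail expects a single x")
  k <- x:min(m, n)
  # restrict to the support: k >= max(0, n - (N - m))
  k <- k[k >= max(0L, n - (N - m))]
  if (length(k) == 0L) return(0)
  p <- sum(exp(lchoose(m, k) + lchoose(N - m, n - k) - lchoose(N, n)))
  min(1, p)
}

#' Read a two-column gene-to-term annotation table
#'
#' A neutral carrier for GO/KEGG-style exports: tab-delimited with two
#' columns, gene id and term id. A header row named `gene_id`/`term_id` is
#' recognized and skipped; duplicate pairs are dropped.
#'
#' @param path Path to the annotation TSV (optionally `.gz`).
#' @return A tibble with columns `gene_id` and `term_id`.
#' @export
read_annotation_table <- function(path) {
  tab <- readr::read_tsv(
    path,
    col_names = c("gene_id", "term_id"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(tab) > 0L && identical(unname(unlist(tab[1L, ])), c("gene_id", "term_id"))) {
    tab <- tab[-1L, , drop = FALSE]
  }
  distinct(tab)
}

#' Hypergeometric enrichment of a gene list
#'
#' Tests every annotation term for over-representation in a gene list
#' against the background of all annotated genes, using the upper-tail
#' hypergeometric probability. Only terms with at least one test-set member
#' are tested; results at or below `p_cutoff` are returned sorted by
#' p-value, then term id. A Benjamini-Hochberg adjusted p-value is reported
#' in its own column (computed over all tested terms) but does not drive the
#' `p_cutoff` selection. Test-set genes absent from the annotation
#' background are dropped and counted in the `n_dropped` attribute, not
#' treated as an error.
#'
#' @param genes A `gene_set`, character vector, or data frame with a
#'   `gene_id` column — the list to test.
#' @param annotations Gene-to-term annotation: a data frame with columns
#'   `gene_id` and `term_id` (see [read_annotation_table()]).
#' @param term_labels Optional data frame with columns `term_id` and `label`.
#' @param p_cutoff Raw p-value cutoff for reporting (default 0.05).
#' @return A tibble of class `meth_enrichment` with columns `term_id`,
#'   `label` (if labels were given), `x` (test-set genes in the class), `m`
#'   (annotated test-set size), `n` (class size), `N` (background size),
#'   `p_value` and `p_adjust`. Attributes `n_background`, `n_test_annotated`,
#'   `n_dropped` and `n_terms_tested` summarize the run; see
#'   [glance.meth_enrichment()].
#' @export
enrich <- function(genes, annotations, term_labels = NULL, p_cutoff = 0.05) {
  ids <- as_gene_set(genes)$genes
  if (length(ids) == 0L) abort("empty test gene list")
  if (!all(c("gene_id", "term_id") %in% names(annotations))) {
    abort("annotations must carry gene_id and term_id columns")
  }
  ann <- distinct(as_tibble(annotations)[, c("gene_id", "term_id")])
  background <- unique(ann$gene_id)
  N <- length(background)
  in_bg <- ids %in% background
  m <- sum(in_bg)
  n_dropped <- length(ids) - m
  if (m == 0L) abort("no annotated genes in list")
  if (n_dropped > 0L) {
    inform(sprintf(
      "%d of %d test genes are not in the annotation background and were dropped",
      n_dropped, length(ids)
    ))
  }
  test <- ids[in_bg]
  per_term <- ann |>
    group_by(.data$term_id) |>
    summarise(
      n = dplyr::n(),
      x = sum(.data$gene_id %in% test),
      .groups = "drop"
    ) |>
    filter(.data$x >= 1L)
  n_tested <- nrow(per_term)
  p <- vapply(
    seq_len(n_tested),
    function(i) hypergeom_tail(per_term$x[i], N, m, per_term$n[i]),
    double(1L)
  )
  res <- per_term |>
    mutate(m = m, N = N, p_value = p, p_adjust = p.adjust(p, method = "BH")) |>
    filter(.data$p_value <= p_cutoff) |>
    arrange(.data$p_value, .data$term_id) |>
    select("term_id", "x", "m", "n", "N", "p_value", "p_adjust")
  if (!is.null(term_labels)) {
    lab <- as_tibble(term_labels)[, c("term_id", "label")]
    res <- left_join(res, distinct(lab), by = "term_id") |>
      relocate("label", .after = "term_id")
  }
  structure(
    res,
    class = c("meth_enrichment", class(res)),
    n_background = N,
    n_test_annotated = m,
    n_dropped = n_dropped,
    n_terms_tested = n_tested
  )
}

#' @export
tidy.meth_enrichment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "meth_enrichment")
  attr(out, "n_background") <- NULL
  attr(out, "n_test_annotated") <- NULL
  attr(out, "n_dropped") <- NULL
  attr(out, "n_terms_tested") <- NULL
  as_tibble(out)
}

#' One-row summary of an enrichment run
#'
#' @param x A `meth_enrichment` result from [enrich()].
#' @param ... Unused.
#' @return A tibble with the background size, annotated test-set size,
#'   dropped-gene count, number of terms tested and number reported.
#' @export
glance.meth_enrichment <- function(x, ...) {
  tibble(
    n_background = attr(x, "n_background"),
    n_test_annotated = attr(x, "n_test_annotated"),
    n_dropped = attr(x, "n_dropped"),
    n_terms_tested = attr(x, "n_terms_tested"),
    n_enriched = nrow(x)
  )
}

#' Bar chart of enriched terms
#'
#' @param object A `meth_enrichment` result.
#' @param top Maximum number of terms to show (by ascending p-value).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meth_enrichment <- function(object, top = 20, ...) {
  df <- as_tibble(tidy(object)) |> head(top)
  lab <- if ("label" %in% names(df)) df$label else df$term_id
  df$term <- factor(lab, levels = rev(lab))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_value), y = .data$term)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(
      x = expression(-log[10] ~ p),
      y = NULL,
      title = "Hypergeometric term enrichment"
    ) +
    ggplot2::theme_minimal()
}
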