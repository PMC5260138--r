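# Gene selection by methylation values: the pairwise pool comparison (DMGs)
# and the cutoff workflow (mC threshold).

as_mtable_list <- function(x, what) {
  if (is.data.frame(x)) x <- list(x)
  if (!is.list(x) || length(x) == 0L) {
    abort(sprintf("%s must be a non-empty mtable data frame or list of them", what))
  }
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    names(x) <- paste0(what, "_", seq_along(x))
  }
  if (anyDuplicated(names(x))) {
    abort(sprintf("%s member names must be unique", what))
  }
  for (d in x) {
    if (!all(c("gene_id", mtable_measurements()) %in% names(d))) {
      abort(sprintf("%s member is not an mtable profile table", what))
    }
  }
  x
}

# Matrix of one measurement across datasets over the union gene universe;
# genes absent from a dataset carry NaN.
measurement_matrix <- function(datasets, measurement) {
  universe <- sort(unique(unlist(lapply(datasets, function(d) d$gene_id))))
  vals <- matrix(
    NaN, length(universe), length(datasets),
    dimnames = list(universe, names(datasets))
  )
  for (j in seq_along(datasets)) {
    d <- datasets[[j]]
    vals[match(d$gene_id, universe), j] <- d[[measurement]]
  }
  vals
}

apply_gene_filters <- function(result, genes, biotypes, chroms) {
  if (is.null(biotypes) && is.null(chroms)) {
    return(result)
  }
  if (is.null(genes)) {
    abort("biotype/chromosome filters require a `genes` gene-model table")
  }
  meta <- genes[match(result$gene_id, genes$gene_id), , drop = FALSE]
  keep <- rep(TRUE, nrow(result))
  if (!is.null(biotypes)) keep <- keep & meta$biotype %in% biotypes
  if (!is.null(chroms)) keep <- keep & meta$chrom %in% chroms
  keep[is.na(keep)] <- FALSE
  result[keep, , drop = FALSE]
}

#' Select differentially methylated genes between two dataset pools
#'
#' Each pool is one experimental condition holding one or more datasets
#' (loaded mtable profile tables; see [read_mtable()]). A gene is evaluable
#' when its chosen measurement is defined (non-`NaN`) in every member of both
#' pools (set `require_complete = FALSE` to average over the available
#' members instead). The pool value is the unweighted mean over members, and
#' a gene is selected when `|mean_b - mean_a| >= delta` with the sign
#' matching `direction` (`"hyper"`: pool B above pool A; `"hypo"`: below;
#' `"both"`: either). The comparison is inclusive, so boundary genes are
#' selected. Optional biotype/chromosome allow-lists are applied afterward.
#'
#' @param pool_a,pool_b An mtable tibble or (optionally named) list of them.
#' @param measurement One of the six measurement names, e.g. `"gene_CHH"`.
#' @param delta Minimum absolute level difference in `[0, 1]` (default 0.15,
#'   the conventional demonstration criterion).
#' @param direction `"both"`, `"hyper"` or `"hypo"`.
#' @param genes Optional gene-model table supplying `biotype` and `chrom`
#'   for the filters.
#' @param biotypes,chroms Optional allow-lists applied after selection.
#' @param require_complete Require the measurement to be defined in every
#'   pool member (default) rather than averaging available members.
#' @return A tibble with one row per selected gene: `gene_id`, `mean_a`,
#'   `mean_b` and the signed difference `diff` (`mean_b - mean_a`).
#' @export
select_dmgs <- function(pool_a, pool_b, measurement, delta = 0.15,
                        direction = c("both", "hyper", "hypo"),
                        genes = NULL, biotypes = NULL, chroms = NULL,
                        require_complete = TRUE) {
  direction <- match.arg(direction)
  check_measurement(measurement)
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0 || delta > 1) {
    abort("delta must be a single level difference in [0, 1]")
  }
  a <- as_mtable_list(pool_a, "pool_a")
  b <- as_mtable_list(pool_b, "pool_b")
  vals <- measurement_matrix(c(a, b), measurement)
  ia <- seq_along(a)
  ib <- length(a) + seq_along(b)
  pool_mean <- function(cols) {
    sub <- vals[, cols, drop = FALSE]
    if (require_complete) rowMeans(sub) else rowMeans(sub, na.rm = TRUE)
  }
  mean_a <- pool_mean(ia)
  mean_b <- pool_mean(ib)
  diff <- mean_b - mean_a
  evaluable <- !is.na(mean_a) & !is.na(mean_b)
  selected <- evaluable & abs(diff) >= delta &
    switch(direction, both = TRUE, hyper = diff > 0, hypo = diff < 0)
  out <- tibble(
    gene_id = rownames(vals)[selected],
    mean_a = unname(mean_a[selected]),
    mean_b = unname(mean_b[selected]),
    diff = unname(diff[selected])
  )
  apply_gene_filters(out, genes, biotypes, chroms)
}

#' Select genes above or below a methylation cutoff
#'
#' Selects genes whose chosen measurement is at or beyond a cutoff in at
#' least one (`mode = "any"`) or in every one (`mode = "all"`) of the given
#' datasets. `side = "above"` means `value >= cutoff`; `"below"` means
#' `value <= cutoff` (both inclusive). `NaN` never satisfies the cutoff, so
#' under `mode = "all"` a gene undefined in any dataset is not selected.
#'
#' @param datasets An mtable tibble or (optionally named) list of them.
#' @param measurement One of the six measurement names.
#' @param cutoff Methylation level cutoff in `[0, 1]`.
#' @param side `"above"` or `"below"`.
#' @param mode `"any"` (at least one dataset) or `"all"` (every dataset).
#' @inheritParams select_dmgs
#' @return A tibble with `gene_id` and one value column per dataset.
#' @export
select_by_threshold <- function(datasets, measurement, cutoff,
                                side = c("above", "below"),
                                mode = c("any", "all"),
                                genes = NULL, biotypes = NULL, chroms = NULL) {
  side <- match.arg(side)
  mode <- match.arg(mode)
  check_measurement(measurement)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0 || cutoff > 1) {
    abort("cutoff must be a single methylation level in [0, 1]")
  }
  ds <- as_mtable_list(datasets, "dataset")
  vals <- measurement_matrix(ds, measurement)
  sat <- if (side == "above") vals >= cutoff else vals <= cutoff
  sat[is.na(sat)] <- FALSE
  selected <- if (mode == "any") rowSums(sat) > 0L else rowSums(sat) == ncol(sat)
  out <- bind_cols(
    tibble(gene_id = rownames(vals)[selected]),
    as_tibble(vals[selected, , drop = FALSE])
  )
  apply_gene_filters(out, genes, biotypes, chroms)
}
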