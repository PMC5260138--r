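# Gene-list bookkeeping: named gene sets, Venn region decomposition for up
# to four sets, and a small Boolean expression language over set names.

#' Named gene sets
#'
#' A gene set is a named, de-duplicated collection of gene identifiers with
#' a free-text provenance describing the operation that produced it.
#' `as_gene_set()` converts character vectors, data frames carrying a
#' `gene_id` column (e.g. [select_dmgs()] output), and gene sets themselves.
#'
#' @param genes Character vector of gene ids (duplicates are dropped,
#'   first-seen order kept).
#' @param name Set name.
#' @param provenance Free-text description of the producing operation.
#' @return An object of class `gene_set`.
#' @export
#' @examples
#' gene_set(c("AT1G01010", "AT1G01020"), name = "demo")
gene_set <- function(genes, name = "gene_set", provenance = NA_character_) {
  genes <- as.character(genes)
  genes <- genes[nzchar(genes) & !is.na(genes)]
  structure(
    list(name = name, genes = unique(genes), provenance = provenance),
    class = "gene_set"
  )
}

#' @rdname gene_set
#' @param x Object to convert.
#' @param ... Passed to [gene_set()].
#' @export
as_gene_set <- function(x, ...) UseMethod("as_gene_set")

#' @export
as_gene_set.gene_set <- function(x, ...) x

#' @export
as_gene_set.character <- function(x, ...) gene_set(x, ...)

#' @export
as_gene_set.data.frame <- function(x, ...) {
  if (!"gene_id" %in% names(x)) {
    abort("data frame has no gene_id column to convert to a gene set")
  }
  gene_set(x$gene_id, ...)
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  if (!is.na(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Read and write one-id-per-line gene lists
#'
#' The plain-text interchange format for gene lists: one gene identifier per
#' line, no header. Blank lines are ignored on read.
#'
#' @param path File path.
#' @param name Set name (defaults to the file name).
#' @param x A `gene_set` or character vector.
#' @return `read_gene_list()` returns a `gene_set`; `write_gene_list()`
#'   returns `path` invisibly.
#' @export
read_gene_list <- function(path, name = basename(path)) {
  ids <- readr::read_lines(path)
  gene_set(ids[nzchar(ids)], name = name,
           provenance = sprintf("read from %s", basename(path)))
}

#' @rdname read_gene_list
#' @export
write_gene_list <- function(x, path) {
  readr::write_lines(as_gene_set(x)$genes, path)
  invisible(path)
}

normalize_set_list <- function(sets) {
  if (!is.list(sets) || is.data.frame(sets)) {
    abort("sets must be a list of gene sets or id vectors")
  }
  sets <- lapply(sets, function(s) as_gene_set(s)$genes)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    nm <- names(sets) %||% rep("", length(sets))
    nm[!nzchar(nm)] <- paste0("set", which(!nzchar(nm)))
    names(sets) <- nm
  }
  if (anyDuplicated(names(sets))) abort("set names must be unique")
  sets
}

#' Decompose up to four gene sets into Venn regions
#'
#' Partitions the union of 2-4 gene sets into the `2^k - 1` disjoint Venn
#' regions. Each region is identified by a signature: a string of 1/0 flags,
#' one per input set in input order (`"110"` = in the first two sets, not
#' the third). Every gene of the union falls in exactly one region.
#'
#' @param sets A named list of 2 to 4 gene sets (or id vectors).
#' @return A tibble with one row per signature (empty regions included):
#'   `signature`, `sets` (comma-joined member set names), `n_genes`, and a
#'   `genes` list-column of the member ids.
#' @export
#' @examples
#' venn_regions(list(A = c("g1", "g2"), B = c("g2", "g3")))
venn_regions <- function(sets) {
  sets <- normalize_set_list(sets)
  k <- length(sets)
  if (k < 2L || k > 4L) {
    abort(sprintf("Venn decomposition supports 2 to 4 sets, got %d", k))
  }
  uni <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) uni %in% s, logical(length(uni)))
  if (length(uni) == 1L) member <- matrix(member, nrow = 1L)
  sig_of_gene <- apply(member, 1L, function(r) paste(as.integer(r), collapse = ""))
  combos <- expand.grid(rep(list(c(0L, 1L)), k))[, k:1, drop = FALSE]
  sigs <- apply(combos, 1L, paste, collapse = "")
  sigs <- sigs[sigs != strrep("0", k)]
  sigs <- sigs[order(sigs, decreasing = TRUE)]
  genes_by_sig <- lapply(sigs, function(s) uni[sig_of_gene == s])
  tibble(
    signature = sigs,
    sets = vapply(sigs, function(s) {
      paste(names(sets)[strsplit(s, "")[[1L]] == "1"], collapse = ",")
    }, character(1L)),
    n_genes = lengths(genes_by_sig),
    genes = genes_by_sig
  )
}

# --- Boolean expression language over set names ------------------------------
# Grammar (left-associative):
#   expr   := term  { ('|' | '-') term }
#   term   := factor { '&' factor }
#   factor := NAME | '(' expr ')'
# '|' union, '&' intersection, '-' difference.

tokenize_set_expr <- function(expression) {
  chars <- strsplit(expression, "")[[1L]]
  tokens <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
    } else if (ch %in% c("|", "&", "-", "(", ")")) {
      tokens[[length(tokens) + 1L]] <- list(type = ch, text = ch, pos = i)
      i <- i + 1L
    } else if (grepl("^[A-Za-z0-9_.]$", ch)) {
      j <- i
      while (j <= length(chars) && grepl("^[A-Za-z0-9_.]$", chars[j])) j <- j + 1L
      tokens[[length(tokens) + 1L]] <- list(
        type = "NAME",
        text = paste(chars[i:(j - 1L)], collapse = ""),
        pos = i
      )
      i <- j
    } else {
      abort(sprintf("unexpected character '%s' at position %d in set expression", ch, i))
    }
  }
  tokens
}

#' Combine gene sets with a Boolean expression
#'
#' Evaluates an expression over named gene sets using `|` (union), `&`
#' (intersection), `-` (difference) and parentheses, e.g.
#' `"(A | B) - C"`. `&` binds tighter than `|` and `-`, which associate left
#' to right. The result carries the expression text as its provenance.
#'
#' @param sets A named list of gene sets (or id vectors).
#' @param expression A Boolean expression string over the set names.
#' @return A `gene_set` holding the ids of the combination.
#' @export
#' @examples
#' combine_sets(list(A = c("g1", "g2"), B = c("g2", "g3")), "A & B")
combine_sets <- function(sets, expression) {
  sets <- normalize_set_list(sets)
  tokens <- tokenize_set_expr(expression)
  if (length(tokens) == 0L) abort("empty set expression")
  idx <- 1L

  peek <- function() if (idx <= length(tokens)) tokens[[idx]] else NULL
  advance <- function() {
    tok <- tokens[[idx]]
    idx <<- idx + 1L
    tok
  }

  parse_factor <- function() {
    tok <- peek()
    if (is.null(tok)) {
      abort(sprintf("set expression ends unexpectedly at position %d", nchar(expression) + 1L))
    }
    if (tok$type == "NAME") {
      advance()
      if (!tok$text %in% names(sets)) {
        abort(sprintf("unknown set name '%s' at position %d", tok$text, tok$pos))
      }
      return(sets[[tok$text]])
    }
    if (tok$type == "(") {
      advance()
      val <- parse_expr()
      close_tok <- peek()
      if (is.null(close_tok) || close_tok$type != ")") {
        abort(sprintf("unbalanced parenthesis opened at position %d", tok$pos))
      }
      advance()
      return(val)
    }
    abort(sprintf("expected a set name or '(' at position %d, found '%s'", tok$pos, tok$text))
  }

  parse_term <- function() {
    val <- parse_factor()
    while (!is.null(peek()) && peek()$type == "&") {
      advance()
      val <- intersect(val, parse_factor())
    }
    val
  }

  parse_expr <- function() {
    val <- parse_term()
    while (!is.null(peek()) && peek()$type %in% c("|", "-")) {
      op <- advance()
      rhs <- parse_term()
      val <- if (op$type == "|") union(val, rhs) else setdiff(val, rhs)
    }
    val
  }

  result <- parse_expr()
  if (idx <= length(tokens)) {
    tok <- tokens[[idx]]
    abort(sprintf("unexpected token '%s' at position %d in set expression", tok$text, tok$pos))
  }
  gene_set(result, name = expression, provenance = expression)
}
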