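#' Read a gene-set library from GMT
#'
#' Each line: term, description, then member genes, tab-separated. Gene
#' symbols are upper-cased and duplicates within a set are removed; empty
#' descriptions are tolerated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (term -> gene set), with the
#'   file's base name stored in attribute `name`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stopf("GMT parse error at line %d: expected >= 3 tab-separated fields", i)
    }
    term <- parts[1]
    genes <- unique(toupper(parts[-(1:2)][nzchar(parts[-(1:2)])]))
    if (length(genes) == 0) {
      stopf("GMT parse error at line %d: term '%s' has no genes", i, term)
    }
    if (term %in% names(sets)) {
      stopf("GMT parse error at line %d: duplicate term '%s'", i, term)
    }
    sets[[term]] <- genes
  }
  structure(sets, name = sub("\\.gmt$", "", basename(path)))
}

#' Write a gene-set library to GMT
#'
#' @param library Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(library, path) {
  lines <- purrr::imap_chr(as.list(library), function(genes, term) {
    paste(c(term, "na", genes), collapse = "\t")
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Hypergeometric over-representation test against a gene-set library
#'
#' For each term, computes the one-sided upper-tail hypergeometric p-value
#' `P(X >= k)` for drawing `k` term genes in a query of size `n` from a
#' universe of size `N` containing `K` term genes (term sets are first
#' intersected with the universe). This is the Fisher-exact
#' over-representation statistic; Benjamini-Hochberg adjusted p-values are
#' appended. Terms with zero overlap are still reported.
#'
#' Gene symbols are case-folded to upper case throughout. The default
#' universe is the union of all library genes and the query.
#'
#' @param query Character vector of query genes.
#' @param library Gene-set library (named list, as from [read_gmt()]).
#' @param universe Optional character vector; defaults to the union of all
#'   library genes and the query.
#' @return Tibble `term, k, K, n, N, p_value, p_adjusted, neg_log10_p,
#'   overlap_genes` (list column), sorted as returned by [rank_terms()]
#'   input order (library order).
#' @export
fisher_enrich <- function(query, library, universe = NULL) {
  if (length(query) == 0) abort("query gene set is empty")
  query <- unique(toupper(query))
  lib <- purrr::map(as.list(library), ~ unique(toupper(.x)))
  if (is.null(universe)) {
    universe <- union(unlist(lib, use.names = FALSE), query)
  }
  universe <- unique(toupper(universe))
  if (length(universe) == 0) abort("universe is empty")
  if (!all(query %in% universe)) {
    stopf("query gene(s) outside the universe: %s",
          paste(head(setdiff(query, universe), 3), collapse = ", "))
  }
  N <- length(universe)
  n <- length(query)
  if (length(lib) == 0) {
    return(tibble(term = character(), k = integer(), K = integer(),
                  n = integer(), N = integer(), p_value = numeric(),
                  p_adjusted = numeric(), neg_log10_p = numeric(),
                  overlap_genes = list()))
  }
  purrr::imap(lib, function(genes, term) {
    term_in_universe <- intersect(genes, universe)
    K <- length(term_in_universe)
    overlap <- intersect(query, term_in_universe)
    k <- length(overlap)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(term = term, k = k, K = K, n = n, N = N, p_value = p,
           overlap_genes = list(sort(overlap)))
  }) |>
    bind_rows() |>
    mutate(p_adjusted = bh_adjust(.data$p_value),
           neg_log10_p = -log10(.data$p_value)) |>
    select("term", "k", "K", "n", "N", "p_value", "p_adjusted",
           "neg_log10_p", "overlap_genes")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates that all p-values lie in (0, 1] and applies the BH step-up
#' procedure (`adj_i = min_{j>=i} p_(j) * m / j`, capped at 1), returning
#' values in the input order.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Rank enrichment results and keep the top terms
#'
#' Sorts by p-value ascending, breaking ties by larger overlap then
#' alphabetical term, and returns the first `top` rows.
#'
#' @param results Tibble from [fisher_enrich()].
#' @param top Number of terms to keep (default 10).
#' @return Ranked tibble with at most `top` rows.
#' @export
rank_terms <- function(results, top = 10) {
  if (nrow(results) == 0) return(results)
  results |>
    arrange(.data$p_value, desc(.data$k), .data$term) |>
    head(top)
}
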