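#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn .env
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join bind_rows distinct pull n across desc row_number
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats hclust dist cutree phyper p.adjust rnorm rbinom sd
#'   setNames na.omit
#' @importFrom utils head combn
NULL

# Single user-facing seed fanned out to named substreams so each stage can be
# regenerated independently; offsets keep every derived seed < 2^31.
substream_seed <- function(seed, stream) {
  offsets <- c(matrix = 0L, phenotypes = 1L, gmt = 2L, folds = 3L,
               regions = 4L, pipeline = 5L)
  if (!stream %in% names(offsets)) {
    abort(paste0("unknown RNG substream: ", stream))
  }
  (as.integer(seed) %% 1000000000L) * 2L + offsets[[stream]]
}

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    stopf("`%s` must be a single integer >= %d (got %s)", name, min,
          paste(x, collapse = ","))
  }
  invisible(as.integer(x))
}

check_fraction <- function(x, name, lo = 0, hi = 1, open = FALSE) {
  ok <- length(x) == 1L && is.finite(x) &&
    if (open) (x > lo && x < hi) else (x >= lo && x <= hi)
  if (!ok) {
    stopf("`%s` must be a number in %s%g, %g%s (got %s)", name,
          if (open) "(" else "[", lo, hi, if (open) ")" else "]",
          paste(x, collapse = ","))
  }
  invisible(as.numeric(x))
}

# Convert a wide expression tibble (gene_id + one column per region) to a
# numeric matrix with gene ids as rownames.
expr_to_matrix <- function(expr) {
  stopifnot(is.data.frame(expr), "gene_id" %in% names(expr))
  m <- as.matrix(expr[setdiff(names(expr), "gene_id")])
  if (!is.numeric(m)) abort("expression values must be numeric")
  rownames(m) <- expr$gene_id
  m
}

matrix_to_expr <- function(m) {
  dplyr::bind_cols(tibble(gene_id = rownames(m)), as_tibble(m))
}
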