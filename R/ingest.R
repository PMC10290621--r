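#' Read a gene-by-region expression-energy matrix from TSV
#'
#' The file must have a header row of region identifiers, a first column
#' named `gene_id`, and optionally an `experiment_id` column when several
#' ISH experiments exist per gene. Replicate experiments are collapsed to
#' one profile per gene with [collapse_replicates()]. When a
#' `gene_whitelist` is given, genes absent from the file are reported as
#' missing (never fabricated) and retained genes follow whitelist order.
#'
#' @param path TSV file path.
#' @param gene_whitelist Optional character vector of gene ids to keep.
#' @return A list with `expression` (tibble: `gene_id` + numeric region
#'   columns) and `report` (list: `requested_genes`, `retained_genes`,
#'   `missing_genes`, `collapsed_replicates`).
#' @export
read_expression_matrix <- function(path, gene_whitelist = NULL) {
  if (!file.exists(path)) stopf("expression file not found: %s", path)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    .default = readr::col_character()
  ), progress = FALSE)
  if (!"gene_id" %in% names(raw)) {
    abort("malformed header: first column must be `gene_id`")
  }
  has_exp <- "experiment_id" %in% names(raw)
  value_cols <- setdiff(names(raw), c("gene_id", "experiment_id"))
  if (length(value_cols) == 0) abort("malformed header: no region columns")

  for (cn in value_cols) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(v) & !is.na(raw[[cn]]))
    if (length(bad)) {
      stopf("non-numeric cell at row %d, column %s: '%s'",
            bad[1], cn, raw[[cn]][bad[1]])
    }
    neg <- which(v < 0)
    if (length(neg)) {
      stopf("negative expression energy at row %d, column %s: %s",
            neg[1], cn, raw[[cn]][neg[1]])
    }
    raw[[cn]] <- v
  }

  if (has_exp) {
    collapsed <- collapse_replicates(raw)
    expr <- collapsed$expression
    reps <- collapsed$experiments_per_gene
  } else {
    if (anyDuplicated(raw$gene_id)) {
      stopf("duplicate gene rows after collapsing: %s",
            raw$gene_id[duplicated(raw$gene_id)][1])
    }
    expr <- raw
    reps <- setNames(rep(1L, nrow(raw)), raw$gene_id)
  }

  if (is.null(gene_whitelist)) {
    requested <- expr$gene_id
    missing <- character()
  } else {
    requested <- gene_whitelist
    missing <- setdiff(gene_whitelist, expr$gene_id)
    expr <- expr[match(intersect(gene_whitelist, expr$gene_id), expr$gene_id), ]
  }
  report <- list(requested_genes = length(requested),
                 retained_genes = nrow(expr),
                 missing_genes = missing,
                 collapsed_replicates = as.list(reps))
  stopifnot(report$retained_genes + length(report$missing_genes) ==
              report$requested_genes)
  list(expression = as_tibble(expr), report = report)
}

#' Collapse replicate ISH experiments to one profile per gene
#'
#' Keeps, for each gene, the experiment with the largest total energy across
#' regions; ties are broken by the lexicographically smallest
#' `experiment_id`. Deterministic and idempotent.
#'
#' @param rows Tibble with `gene_id`, `experiment_id`, and numeric region
#'   columns.
#' @return List with `expression` (one row per gene, `experiment_id`
#'   dropped) and `experiments_per_gene` (named integer vector).
#' @export
collapse_replicates <- function(rows) {
  stopifnot(all(c("gene_id", "experiment_id") %in% names(rows)))
  value_cols <- setdiff(names(rows), c("gene_id", "experiment_id"))
  totals <- rowSums(as.matrix(rows[value_cols]))
  picked <- rows |>
    mutate(.total = totals) |>
    group_by(.data$gene_id) |>
    arrange(desc(.data$.total), .data$experiment_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup()
  counts <- table(rows$gene_id)
  # preserve first-appearance gene order of the input
  picked <- picked[match(unique(rows$gene_id), picked$gene_id), ]
  list(expression = picked |> select(-".total", -"experiment_id"),
       experiments_per_gene = setNames(as.integer(counts[unique(rows$gene_id)]),
                                       unique(rows$gene_id)))
}

#' Read a CAN region list from CSV
#'
#' Expects columns `region_id, acronym, can_role` with `can_role` in
#' `{feedforward, feedback}` (the two arms of central autonomic control:
#' cortical/limbic feedforward drive vs brainstem reflex feedback).
#'
#' @param path CSV file path.
#' @return Tibble `region_id, acronym, can_role`.
#' @export
read_region_set <- function(path) {
  if (!file.exists(path)) stopf("region file not found: %s", path)
  reg <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("region_id", "acronym", "can_role")
  if (!all(need %in% names(reg))) {
    stopf("region CSV must have columns %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(reg$region_id)) {
    stopf("duplicate region_id: %s", reg$region_id[duplicated(reg$region_id)][1])
  }
  bad <- setdiff(unique(reg$can_role), c("feedforward", "feedback"))
  if (length(bad)) stopf("unknown can_role value: %s", bad[1])
  as_tibble(reg[need])
}

#' Subset an expression matrix to a region set
#'
#' Restricts columns to the listed regions, in region-set order. Under
#' `strict = TRUE` a listed region missing from the matrix is an error;
#' otherwise it is dropped with a warning. Idempotent.
#'
#' @param expr Expression tibble (`gene_id` + region columns).
#' @param regions Region tibble as from [read_region_set()].
#' @param strict Error (rather than warn) on regions absent from the matrix.
#' @return Expression tibble restricted and reordered to the region set.
#' @export
subset_regions <- function(expr, regions, strict = FALSE) {
  if (nrow(regions) == 0) abort("region set is empty")
  have <- setdiff(names(expr), "gene_id")
  missing <- setdiff(regions$region_id, have)
  if (length(missing)) {
    if (strict) stopf("region %s not in matrix", missing[1])
    warn(paste0("dropping ", length(missing),
                " region(s) absent from the matrix: ",
                paste(missing, collapse = ", ")))
  }
  keep <- intersect(regions$region_id, have)
  if (length(keep) == 0) abort("no listed region is present in the matrix")
  expr[c("gene_id", keep)]
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()] for collapsed (one row per gene)
#' matrices; values and orders round-trip exactly.
#'
#' @param expr Expression tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  readr::write_tsv(expr, path)
  invisible(path)
}
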