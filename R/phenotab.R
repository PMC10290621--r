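# Closed vocabulary of ECG/echo parameters appearing in the knockout table.
# Order matters for the lexer: longest / most specific names first so e.g.
# "HR_TTE" and "HRV" are matched before "HR".
pheno_params <- c("QTc Dispersion", "QTc_dispersion", "HR_TTE", "rMSSD",
                  "LVIDd", "LVIDs", "HRV", "QTc", "QRS", "HR", "RR", "PQ",
                  "PR", "ST")

pheno_canonical <- c("QTc Dispersion" = "QTc_dispersion",
                     "QTc_dispersion" = "QTc_dispersion",
                     "HR_TTE" = "HR_TTE", "rMSSD" = "rMSSD",
                     "LVIDd" = "LVIDd", "LVIDs" = "LVIDs", "HRV" = "HRV",
                     "QTc" = "QTc", "QRS" = "QRS", "HR" = "HR", "RR" = "RR",
                     "PQ" = "PQ", "PR" = "PR", "ST" = "ST")

pheno_display <- c(QTc_dispersion = "QTc Dispersion", HR_TTE = "HR_TTE",
                   rMSSD = "rMSSD", LVIDd = "LVIDd", LVIDs = "LVIDs",
                   HRV = "HRV", QTc = "QTc", QRS = "QRS", HR = "HR",
                   RR = "RR", PQ = "PQ", PR = "PR", ST = "ST")

#' Parse an ECG phenotype string in the knockout-table dialect
#'
#' Tokenizes strings such as `"HR ↑ HRV↓"`, `"PQ ↓,HR ↑,PR ↓"` or
#' `"HR ↓ (F),HR ↑ (M)"`: each up/down arrow binds to the nearest preceding
#' comma-separated parameter list (so `"HR, RR ↑"` yields both `HR up` and
#' `RR up`), an immediately following `(F)`/`(M)` marks a sex-specific
#' phenotype, and the literal `"No"` denotes no ECG phenotype. Arrow glyph
#' variants (`↑↓`, `^`, `v` are not accepted — only the Unicode arrows) and
#' unknown parameter names raise a parse error naming the fragment.
#'
#' @param raw Non-empty phenotype string.
#' @return Tibble of tokens: `parameter` (canonical name, e.g.
#'   `QTc_dispersion`), `direction` (`up`/`down`), `sex` (`any`/`F`/`M`).
#'   Zero rows for `"No"`.
#' @export
parse_phenotype_string <- function(raw) {
  if (length(raw) != 1 || is.na(raw) || !nzchar(trimws(raw))) {
    abort("phenotype string must be non-empty")
  }
  s <- trimws(raw)
  if (identical(toupper(s), "NO")) {
    return(tibble(parameter = character(), direction = character(),
                  sex = character()))
  }
  param_re <- paste0("(", paste(gsub(" ", "[ ]", pheno_params), collapse = "|"),
                     ")")
  tokens <- list()
  pos <- 1L
  nch <- nchar(s)
  pending <- character()
  last_group <- 0L  # index into tokens of last closed group, for sex binding
  push_group <- function(dir) {
    if (length(pending) == 0) {
      stopf("parse error near position %d: arrow with no preceding parameter",
            pos)
    }
    tokens[[length(tokens) + 1L]] <<- list(params = pending, dir = dir,
                                           sex = "any")
    last_group <<- length(tokens)
    pending <<- character()
  }
  while (pos <= nch) {
    rest <- substr(s, pos, nch)
    if (grepl("^[,[:space:]]+", rest)) {
      pos <- pos + attr(regexpr("^[,[:space:]]+", rest), "match.length")
      next
    }
    m <- regexpr(paste0("^", param_re), rest)
    if (m == 1L) {
      hit <- regmatches(rest, m)
      pending <- c(pending, pheno_canonical[[hit]])
      last_group <- 0L
      pos <- pos + attr(m, "match.length")
      next
    }
    ch2 <- substr(rest, 1, 1)
    if (ch2 == "↑" || ch2 == "↓") {
      push_group(if (ch2 == "↑") "up" else "down")
      pos <- pos + 1L
      next
    }
    m <- regexpr("^\\((F|M)\\)", rest)
    if (m == 1L) {
      if (last_group == 0L) {
        stopf("parse error: sex marker '%s' not preceded by an arrow",
              regmatches(rest, m))
      }
      tokens[[last_group]]$sex <- sub("[()]", "",
                                      gsub("[()]", "", regmatches(rest, m)))
      pos <- pos + attr(m, "match.length")
      next
    }
    frag <- substr(rest, 1, min(12, nchar(rest)))
    stopf("unrecognized phenotype fragment: '%s'", frag)
  }
  if (length(pending)) {
    stopf("parse error: parameter(s) %s have no direction arrow",
          paste(pending, collapse = ", "))
  }
  purrr::map(tokens, function(g) {
    tibble(parameter = g$params, direction = g$dir, sex = g$sex)
  }) |>
    bind_rows() |>
    distinct()
}

#' Serialize phenotype tokens back to the table dialect
#'
#' Inverse of [parse_phenotype_string()] up to token-set identity:
#' re-parsing the serialized string recovers exactly the same tokens.
#'
#' @param tokens Token tibble (`parameter, direction, sex`).
#' @return A single phenotype string; `"No"` for zero tokens.
#' @export
serialize_phenotype_tokens <- function(tokens) {
  if (nrow(tokens) == 0) return("No")
  purrr::pmap_chr(tokens, function(parameter, direction, sex) {
    paste0(pheno_display[[parameter]], " ",
           if (direction == "up") "↑" else "↓",
           if (sex != "any") paste0(" (", sex, ")") else "")
  }) |> paste(collapse = ",")
}

#' Read a per-gene phenotype table
#'
#' Expects a TSV with columns `gene_id, ecg_phenotype, behavior_phenotype,
#' npd_annotation`. ECG strings are parsed into tokens; a gene's
#' neuropsychiatric-disease status is `limited_or_none` exactly when the
#' annotation field equals the literal `"Limited or no NPD annotations"`,
#' otherwise `annotated`.
#'
#' @param path TSV path. Defaults to the packaged transcription of the
#'   study's 32-gene feedforward candidate table.
#' @return Tibble `gene_id, ecg_phenotype, tokens` (list column),
#'   `behavior_phenotype, npd_annotation, npd_status`.
#' @export
read_phenotype_table <- function(path = system.file("extdata",
                                                    "table1_phenotypes.tsv",
                                                    package = "canprio")) {
  if (!file.exists(path)) stopf("phenotype table not found: %s", path)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("gene_id", "ecg_phenotype", "behavior_phenotype", "npd_annotation")
  if (!all(need %in% names(tab))) {
    stopf("phenotype TSV must have columns %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$gene_id)) {
    stopf("duplicate gene_id in phenotype table: %s",
          tab$gene_id[duplicated(tab$gene_id)][1])
  }
  tab |>
    mutate(tokens = purrr::map(.data$ecg_phenotype, parse_phenotype_string),
           npd_status = ifelse(.data$npd_annotation ==
                                 "Limited or no NPD annotations",
                               "limited_or_none", "annotated")) |>
    select("gene_id", "ecg_phenotype", "tokens", "behavior_phenotype",
           "npd_annotation", "npd_status")
}

# parameters equivalent under a filter criterion: heart rate is measured
# both on the surface ECG (HR) and by transthoracic echo (HR_TTE); rMSSD is
# a vagally mediated HRV statistic, so HRV criteria match either.
criterion_params <- function(parameter) {
  switch(parameter,
         HR = c("HR", "HR_TTE"),
         HRV = c("HRV", "rMSSD"),
         parameter)
}

#' Filter genes by an ECG phenotype criterion
#'
#' A gene matches when any of its tokens matches the criterion. The `HR`
#' criterion matches both `HR` and `HR_TTE` tokens and the `HRV` criterion
#' matches both `HRV` and `rMSSD` tokens (each pair measures the same
#' physiological quantity). Under `sex_mode = "any"` sex-specific tokens
#' count (a male-only heart-rate increase still matches).
#'
#' @param table Phenotype tibble from [read_phenotype_table()].
#' @param parameter Criterion parameter (e.g. `"HR"`, `"HRV"`); `NULL`
#'   matches every gene.
#' @param direction `"up"` or `"down"`; ignored when `parameter` is `NULL`.
#' @param sex_mode `"any"`, `"F"`, or `"M"`.
#' @return Tibble `gene_id, matched_tokens` (serialized string of the
#'   matching tokens), one row per matching gene, in table order.
#' @export
filter_by_phenotype <- function(table, parameter = NULL, direction = "up",
                                sex_mode = c("any", "F", "M")) {
  sex_mode <- match.arg(sex_mode)
  if (is.null(parameter)) {
    return(tibble(gene_id = table$gene_id,
                  matched_tokens = purrr::map_chr(table$tokens,
                                                  serialize_phenotype_tokens)))
  }
  if (!parameter %in% unname(pheno_canonical)) {
    stopf("unknown phenotype parameter: %s", parameter)
  }
  if (!direction %in% c("up", "down")) {
    stopf("direction must be 'up' or 'down' (got %s)", direction)
  }
  params <- criterion_params(parameter)
  hits <- purrr::map(table$tokens, function(tok) {
    sel <- tok$parameter %in% params & tok$direction == direction &
      (sex_mode == "any" | tok$sex %in% c("any", sex_mode))
    tok[sel, , drop = FALSE]
  })
  keep <- purrr::map_lgl(hits, ~ nrow(.x) > 0)
  tibble(gene_id = table$gene_id[keep],
         matched_tokens = purrr::map_chr(hits[keep],
                                         serialize_phenotype_tokens))
}

#' Classify genes by neuropsychiatric-disease annotation status
#'
#' Partitions the given genes into `annotated` (any literature NPD
#' association recorded) and `limited_or_none` (annotation field is the
#' literal "Limited or no NPD annotations"); genes absent from the table
#' are reported as `unknown` rather than an error.
#'
#' @param table Phenotype tibble from [read_phenotype_table()].
#' @param genes Character vector of gene ids.
#' @return Tibble `gene_id, npd_status` with status in
#'   `{annotated, limited_or_none, unknown}`, in input order.
#' @export
annotate_npd <- function(table, genes) {
  status <- table$npd_status[match(genes, table$gene_id)]
  tibble(gene_id = genes,
         npd_status = ifelse(is.na(status), "unknown", status))
}
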