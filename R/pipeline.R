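#' Assemble a pipeline configuration
#'
#' Collects the file paths and stage parameters for a full end-to-end run.
#' `config` may also be loaded from YAML or JSON with
#' [read_pipeline_config()].
#'
#' @param matrix Expression TSV path.
#' @param regions Region CSV path.
#' @param genes Optional path to a one-id-per-line gene whitelist.
#' @param gmt Named character vector/list of GMT library paths (may be
#'   empty to skip enrichment).
#' @param phenotypes Optional phenotype TSV path (omit to skip the filter
#'   stage).
#' @param out_dir Output directory for stage artifacts.
#' @param k_min,k_max Silhouette search range for biclustering.
#' @param rfe An [rfe_config()].
#' @param top_hub Number of hub genes to extract.
#' @param enrich_top Number of enriched terms reported per library/cluster.
#' @param filters List of phenotype criteria, each
#'   `list(parameter=, direction=)`; default: increased heart rate and
#'   decreased heart-rate variability.
#' @param strict_regions Error on regions listed but absent from the matrix.
#' @param seed Integer seed for the whole run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix, regions, genes = NULL, gmt = character(),
                            phenotypes = NULL, out_dir = tempfile("canprio"),
                            k_min = 2, k_max = 10, rfe = rfe_config(),
                            top_hub = 99, enrich_top = 10,
                            filters = list(list(parameter = "HR",
                                                direction = "up"),
                                           list(parameter = "HRV",
                                                direction = "down")),
                            strict_regions = FALSE, seed = 1L) {
  structure(list(matrix = matrix, regions = regions, genes = genes,
                 gmt = gmt, phenotypes = phenotypes, out_dir = out_dir,
                 k_min = k_min, k_max = k_max, rfe = rfe,
                 top_hub = top_hub, enrich_top = enrich_top,
                 filters = filters, strict_regions = strict_regions,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path Config file; top-level keys mirror [pipeline_config()]
#'   arguments (`rfe` as a nested mapping of [rfe_config()] arguments).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (!is.null(raw$rfe)) raw$rfe <- do.call(rfe_config, raw$rfe)
  do.call(pipeline_config, raw)
}

stage_error <- function(stage, e) {
  stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
}

#' Run the full prioritization pipeline
#'
#' Executes ingest, biclustering, multiclass SVM-RFE, enrichment and the
#' phenotype filter in order, writing each stage's artifacts under
#' `config$out_dir` before the next stage starts. Identical config + seed
#' gives byte-identical summaries (wall-clock timing is logged to the
#' console, not stored in the summary).
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return A list of class `can_run_summary` with per-stage counts, the
#'   fitted objects, and the seed.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  # stage 1: ingest
  whitelist <- NULL
  if (!is.null(config$genes)) {
    if (!file.exists(config$genes)) {
      stopf("pipeline stage 'ingest' failed: gene list not found: %s",
            config$genes)
    }
    whitelist <- readLines(config$genes)
  }
  ing <- tryCatch({
    res <- read_expression_matrix(config$matrix, whitelist)
    regions <- read_region_set(config$regions)
    res$expression <- subset_regions(res$expression, regions,
                                     strict = config$strict_regions)
    res$regions <- regions
    res
  }, error = function(e) stage_error("ingest", e))
  jsonlite::write_json(ing$report, file.path(config$out_dir, "ingest_report.json"),
                       auto_unbox = TRUE)
  say("ingest: %d/%d genes retained over %d regions", ing$report$retained_genes,
      ing$report$requested_genes, ncol(ing$expression) - 1)

  # stage 2: bicluster
  bic <- tryCatch(bicluster(ing$expression, ing$regions,
                            k_min = config$k_min, k_max = config$k_max),
                  error = function(e) stage_error("bicluster", e))
  labels_tbl <- tidy(bic)
  readr::write_tsv(labels_tbl, file.path(config$out_dir, "cluster_labels.tsv"))
  readr::write_tsv(bind_rows(
    mutate(bic$genes$silhouette_by_k, axis = "genes"),
    mutate(bic$regions$silhouette_by_k, axis = "regions")),
    file.path(config$out_dir, "silhouette_profile.tsv"))
  write_linkage_newick(bic$genes$tree,
                       file.path(config$out_dir, "gene_tree.nwk"))
  write_linkage_newick(bic$regions$tree,
                       file.path(config$out_dir, "region_tree.nwk"))
  say("bicluster: gene k = %d, region k = %d", bic$genes$k, bic$regions$k)

  # stage 3: mSVM-RFE
  gene_names <- gene_cluster_name_vector(bic)
  rfe_cfg <- config$rfe
  rfe_cfg$seed <- config$seed
  rfe <- tryCatch(run_msvm_rfe(bic$zscored, bic$regions$labels,
                               gene_names, rfe_cfg),
                  error = function(e) stage_error("msvm_rfe", e))
  readr::write_tsv(rfe$ranking, file.path(config$out_dir, "rfe_ranking.tsv"))
  hubs <- top_hub_genes(rfe, min(config$top_hub, nrow(rfe$ranking)))
  readr::write_tsv(hubs$hub_genes, file.path(config$out_dir, "hub_genes.tsv"))
  say("rfe: %d runs, top %d hub genes (%s)", rfe$n_runs,
      nrow(hubs$hub_genes),
      paste(names(hubs$partition), hubs$partition, sep = ":", collapse = ", "))

  # stage 4: enrichment (per gene cluster x library)
  enrich <- list()
  if (length(config$gmt)) {
    enrich <- tryCatch({
      universe_genes <- labels_tbl$id[labels_tbl$axis == "genes"]
      out <- list()
      for (lib_name in names(config$gmt)) {
        lib <- read_gmt(config$gmt[[lib_name]])
        universe <- union(unlist(lib, use.names = FALSE),
                          toupper(universe_genes))
        for (cl in sort(unique(na.omit(labels_tbl$cluster_name[
          labels_tbl$axis == "genes"])))) {
          qry <- labels_tbl$id[labels_tbl$axis == "genes" &
                                 labels_tbl$cluster_name %in% cl]
          res <- fisher_enrich(qry, lib, universe) |>
            rank_terms(config$enrich_top) |>
            mutate(library = lib_name, gene_cluster = cl)
          out[[paste(lib_name, cl, sep = ".")]] <- res
        }
      }
      out
    }, error = function(e) stage_error("enrichment", e))
    enr_tbl <- bind_rows(enrich) |>
      mutate(overlap_genes = purrr::map_chr(.data$overlap_genes, paste,
                                            collapse = ";"))
    readr::write_tsv(enr_tbl, file.path(config$out_dir, "enrichment.tsv"))
    say("enrichment: %d term rows across %d library x cluster queries",
        nrow(enr_tbl), length(enrich))
  }

  # stage 5: phenotype filter
  candidates <- NULL
  if (!is.null(config$phenotypes)) {
    candidates <- tryCatch({
      tab <- read_phenotype_table(config$phenotypes)
      hits <- purrr::map(config$filters, function(f) {
        filter_by_phenotype(tab, f$parameter, f$direction)
      }) |> bind_rows() |> distinct(.data$gene_id, .keep_all = TRUE)
      left_join(hits, annotate_npd(tab, hits$gene_id), by = "gene_id")
    }, error = function(e) stage_error("phenotype_filter", e))
    readr::write_tsv(candidates, file.path(config$out_dir, "candidates.tsv"))
    say("phenotype filter: %d candidate genes", nrow(candidates))
  }

  summary <- structure(list(
    seed = config$seed,
    genes_requested = ing$report$requested_genes,
    genes_retained = ing$report$retained_genes,
    n_regions = ncol(ing$expression) - 1,
    dropped_zero_variance = length(bic$dropped_rows),
    gene_k = bic$genes$k,
    region_k = bic$regions$k,
    gene_cluster_sizes = as.list(table(bic$genes$labels)),
    rfe_runs = rfe$n_runs,
    hub_genes = nrow(hubs$hub_genes),
    hub_partition = as.list(hubs$partition),
    enrichment_queries = length(enrich),
    filtered_candidates = if (is.null(candidates)) NA_integer_
                          else nrow(candidates),
    bicluster = bic, rfe = rfe, hubs = hubs, enrichment = enrich,
    candidates = candidates, ingest_report = ing$report
  ), class = "can_run_summary")

  scalars <- summary[c("seed", "genes_requested", "genes_retained",
                       "n_regions", "dropped_zero_variance", "gene_k",
                       "region_k", "gene_cluster_sizes", "rfe_runs",
                       "hub_genes", "hub_partition", "enrichment_queries",
                       "filtered_candidates")]
  jsonlite::write_json(scalars, file.path(config$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  summary
}

# named vector gene_id -> cluster name (or numeric label when unnamed)
gene_cluster_name_vector <- function(bic) {
  lab <- bic$genes$labels
  if (!is.null(bic$gene_cluster_names)) {
    setNames(unname(bic$gene_cluster_names[as.character(lab)]), names(lab))
  } else {
    setNames(as.character(lab), names(lab))
  }
}
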