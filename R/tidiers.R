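#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a biclustering result
#'
#' One row per clustered item on both axes, with cluster index and (for
#' genes, when region roles were available) the feedforward/feedback
#' cluster name.
#'
#' @param x A `can_bicluster` object.
#' @param ... Unused.
#' @return Tibble `axis, id, cluster, cluster_name`.
#' @method tidy can_bicluster
#' @export
tidy.can_bicluster <- function(x, ...) {
  gene_names <- if (!is.null(x$gene_cluster_names)) {
    unname(x$gene_cluster_names[as.character(x$genes$labels)])
  } else NA_character_
  bind_rows(
    tibble(axis = "genes", id = names(x$genes$labels),
           cluster = unname(x$genes$labels), cluster_name = gene_names),
    tibble(axis = "regions", id = names(x$regions$labels),
           cluster = unname(x$regions$labels), cluster_name = NA_character_)
  )
}

#' One-row summary of a biclustering result
#'
#' @param x A `can_bicluster` object.
#' @param ... Unused.
#' @return Tibble with chosen k and peak mean silhouette per axis, plus the
#'   number of zero-variance genes dropped before clustering.
#' @method glance can_bicluster
#' @export
glance.can_bicluster <- function(x, ...) {
  tibble(gene_k = x$genes$k,
         gene_silhouette = max(x$genes$silhouette_by_k$mean_silhouette),
         region_k = x$regions$k,
         region_silhouette = max(x$regions$silhouette_by_k$mean_silhouette),
         dropped_rows = length(x$dropped_rows))
}

#' Tidy an mSVM-RFE result
#'
#' @param x A `can_rfe` object.
#' @param ... Unused.
#' @return The per-gene ranking tibble (`gene_id, selection_frequency,
#'   mean_elimination_step, rank, cluster`).
#' @method tidy can_rfe
#' @export
tidy.can_rfe <- function(x, ...) x$ranking

#' One-row summary of an mSVM-RFE result
#'
#' @param x A `can_rfe` object.
#' @param ... Unused.
#' @return Tibble with run count, fold structure, stop size and feature
#'   count.
#' @method glance can_rfe
#' @export
glance.can_rfe <- function(x, ...) {
  tibble(n_runs = x$n_runs,
         n_folds = x$config$n_folds,
         n_repeats = x$config$n_repeats,
         stop_n = x$config$stop_n,
         n_features = nrow(x$ranking),
         total_selections = sum(x$ranking$selection_frequency))
}

#' One-row summary of a pipeline run
#'
#' @param x A `can_run_summary` object.
#' @param ... Unused.
#' @return Tibble of the stage counts recorded in the run summary.
#' @method glance can_run_summary
#' @export
glance.can_run_summary <- function(x, ...) {
  tibble(seed = x$seed,
         genes_requested = x$genes_requested,
         genes_retained = x$genes_retained,
         n_regions = x$n_regions,
         gene_k = x$gene_k,
         region_k = x$region_k,
         rfe_runs = x$rfe_runs,
         hub_genes = x$hub_genes,
         filtered_candidates = x$filtered_candidates)
}

#' @export
print.can_bicluster <- function(x, ...) {
  cat("Biclustering of", length(x$genes$labels), "genes x",
      length(x$regions$labels), "regions\n")
  cat("  gene clusters:  k =", x$genes$k,
      if (!is.null(x$gene_cluster_names))
        paste0("(", paste(x$gene_cluster_names, collapse = ", "), ")"), "\n")
  cat("  region clusters: k =", x$regions$k, "\n")
  invisible(x)
}

#' @export
print.can_rfe <- function(x, ...) {
  cat("mSVM-RFE:", x$n_runs, "runs,", nrow(x$ranking), "features,",
      "stop size", x$config$stop_n, "\n")
  print(head(x$ranking, 10))
  invisible(x)
}

#' @export
print.can_run_summary <- function(x, ...) {
  cat("Pipeline run (seed", paste0(x$seed, "):"), "\n")
  print(glance(x))
  invisible(x)
}
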