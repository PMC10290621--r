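#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_vline labs facet_wrap coord_flip theme_minimal
#' @export
ggplot2::autoplot

#' Silhouette profile plot for a biclustering
#'
#' Mean silhouette width against candidate cluster number for both axes,
#' with the chosen k marked — the diagnostic behind the cluster-number
#' choice.
#'
#' @param object A `can_bicluster` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot can_bicluster
#' @export
autoplot.can_bicluster <- function(object, ...) {
  prof <- bind_rows(
    mutate(object$genes$silhouette_by_k, axis = "genes",
           chosen = .data$k == object$genes$k),
    mutate(object$regions$silhouette_by_k, axis = "regions",
           chosen = .data$k == object$regions$k)
  )
  ggplot(prof, aes(x = .data$k, y = .data$mean_silhouette)) +
    geom_line() +
    geom_point(aes(colour = .data$chosen), show.legend = FALSE) +
    facet_wrap(~axis, scales = "free_y") +
    labs(x = "number of clusters", y = "mean silhouette width") +
    theme_minimal()
}

#' Selection-frequency plot for an mSVM-RFE ranking
#'
#' @param object A `can_rfe` object.
#' @param top_n Number of top-ranked genes shown.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot can_rfe
#' @export
autoplot.can_rfe <- function(object, top_n = 30, ...) {
  d <- head(object$ranking, top_n)
  d$gene_id <- factor(d$gene_id, levels = rev(d$gene_id))
  ggplot(d, aes(x = .data$gene_id, y = .data$selection_frequency,
                fill = .data$cluster)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "runs selecting the gene (of final feature sets)",
         fill = "gene cluster") +
    theme_minimal()
}

#' Bar chart of top enriched terms
#'
#' Terms ordered by -log10 p-value, the usual over-representation readout.
#'
#' @param results Tibble from [fisher_enrich()] (optionally already passed
#'   through [rank_terms()]).
#' @param top Number of terms displayed.
#' @return A ggplot.
#' @export
plot_enrichment <- function(results, top = 10) {
  d <- rank_terms(results, top)
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot(d, aes(x = .data$term, y = .data$neg_log10_p)) +
    geom_col(fill = "steelblue") +
    coord_flip() +
    labs(x = NULL, y = expression(-log[10](italic(p)))) +
    theme_minimal()
}
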