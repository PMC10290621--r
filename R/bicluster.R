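#' Z-score expression rows
#'
#' Standardizes each gene row to mean 0 and sample (n-1) standard deviation 1
#' across regions, the per-row scaling used for the clustered heat map.
#' Zero-variance rows cannot be standardized and are dropped (recorded in
#' `dropped_rows`).
#'
#' @param expr Expression tibble (`gene_id` + numeric region columns).
#' @return List with `zscored` (tibble, same layout) and `dropped_rows`
#'   (character vector of zero-variance gene ids).
#' @export
zscore_rows <- function(expr) {
  m <- expr_to_matrix(expr)
  if (ncol(m) < 2) abort("z-scoring needs at least 2 regions")
  sds <- apply(m, 1, sd)
  dropped <- rownames(m)[sds == 0 | !is.finite(sds)]
  keep <- setdiff(rownames(m), dropped)
  if (length(keep) == 0) abort("all rows have zero variance")
  z <- (m[keep, , drop = FALSE] - rowMeans(m[keep, , drop = FALSE])) /
    sds[keep]
  list(zscored = matrix_to_expr(z), dropped_rows = dropped)
}

#' Ward minimum-variance linkage over genes or regions
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on
#' Euclidean distances between profiles (the dissimilarity-squaring "D2"
#' variant, equivalent to classical Ward on the raw observations; merge
#' heights are on the distance scale). `axis = "genes"` clusters rows,
#' `axis = "regions"` clusters columns of the z-scored matrix.
#'
#' @param zscored Z-scored expression tibble (from [zscore_rows()]).
#' @param axis `"genes"` or `"regions"`.
#' @return An `hclust` object whose labels are gene or region ids.
#' @export
ward_linkage <- function(zscored, axis = c("genes", "regions")) {
  axis <- match.arg(axis)
  m <- expr_to_matrix(zscored)
  if (axis == "regions") m <- t(m)
  if (nrow(m) < 2) stopf("need at least 2 %s to cluster", axis)
  if (anyNA(m) || any(!is.finite(m))) abort("matrix contains NaN/NA values")
  hclust(dist(m, method = "euclidean"), method = "ward.D2")
}

#' Cut a linkage tree into k clusters with canonical labels
#'
#' Removes the k-1 highest merges and relabels the resulting groups 1..k in
#' order of first appearance along the tree's leaf ordering, so labels are
#' reproducible across platforms.
#'
#' @param tree An `hclust` object.
#' @param k Number of clusters, `1 <= k <=` number of leaves.
#' @return Named integer vector of cluster labels.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1 || k > n) stopf("k must be in [1, %d] (got %s)", n, k)
  raw <- cutree(tree, k = k)
  first_seen <- unique(raw[tree$order])
  relab <- match(raw, first_seen)
  setNames(as.integer(relab), names(raw))
}

#' Select the number of clusters by average silhouette width
#'
#' For each k in `[k_min, k_max]` cuts the tree and computes the mean
#' silhouette width over items using Euclidean distances; the chosen k
#' maximizes the mean, with ties going to the smallest k.
#'
#' @param zscored Z-scored expression tibble.
#' @param tree `hclust` tree over the same axis.
#' @param axis `"genes"` or `"regions"`.
#' @param k_min,k_max Search range (`k_max` capped at n items - 1).
#' @return A list of class `can_clustering`: `axis`, `k`, `labels` (named
#'   integer vector), `silhouette_by_k` (tibble `k, mean_silhouette`),
#'   `tree`.
#' @export
silhouette_select_k <- function(zscored, tree, axis = c("genes", "regions"),
                                k_min = 2, k_max = 10) {
  axis <- match.arg(axis)
  m <- expr_to_matrix(zscored)
  if (axis == "regions") m <- t(m)
  n <- nrow(m)
  if (n < 3) abort("silhouette selection needs at least 3 items")
  if (k_max > n - 1) k_max <- n - 1
  if (k_min < 2 || k_min > k_max) stopf("invalid k range [%d, %d]", k_min, k_max)
  d <- dist(m, method = "euclidean")
  ks <- seq.int(k_min, k_max)
  mean_sil <- purrr::map_dbl(ks, function(k) {
    lab <- cut_tree(tree, k)[rownames(m)]
    mean(cluster::silhouette(lab, d)[, "sil_width"])
  })
  best <- ks[which.max(mean_sil)]  # which.max takes the first => smallest k
  structure(list(axis = axis,
                 k = best,
                 labels = cut_tree(tree, best)[rownames(m)],
                 silhouette_by_k = tibble(k = ks, mean_silhouette = mean_sil),
                 tree = tree),
            class = "can_clustering")
}

#' Bicluster an expression matrix over genes and regions
#'
#' Full row/column clustering stage: z-scores gene rows, builds Ward trees
#' over genes and over regions, and selects each axis's cluster count by
#' average silhouette width. When a region set with autonomic roles is
#' supplied, gene clusters are additionally named by contrast of mean
#' z-scored expression in feedforward vs feedback regions: the cluster(s)
#' relatively higher in feedforward regions are labelled `FF-ANS`, the rest
#' `FB-ANS` (with `-2`, `-3` suffixes if several clusters share a side).
#'
#' @param expr Expression tibble (raw energies; z-scoring is internal).
#' @param regions Optional region tibble with `region_id, can_role`.
#' @param k_min,k_max Silhouette search range for both axes.
#' @return A list of class `can_bicluster`: `genes` and `regions`
#'   ([silhouette_select_k()] results), `zscored`, `dropped_rows`,
#'   `gene_cluster_names` (named character vector, present when `regions`
#'   had roles).
#' @export
bicluster <- function(expr, regions = NULL, k_min = 2, k_max = 10) {
  zs <- zscore_rows(expr)
  gene_tree <- ward_linkage(zs$zscored, "genes")
  region_tree <- ward_linkage(zs$zscored, "regions")
  genes <- silhouette_select_k(zs$zscored, gene_tree, "genes", k_min, k_max)
  regs <- silhouette_select_k(zs$zscored, region_tree, "regions", k_min, k_max)

  cluster_names <- NULL
  if (!is.null(regions) && "can_role" %in% names(regions)) {
    z <- expr_to_matrix(zs$zscored)
    ff <- intersect(regions$region_id[regions$can_role == "feedforward"],
                    colnames(z))
    fb <- intersect(regions$region_id[regions$can_role == "feedback"],
                    colnames(z))
    if (length(ff) && length(fb)) {
      contrast <- purrr::map_dbl(seq_len(genes$k), function(cl) {
        rows <- names(genes$labels)[genes$labels == cl]
        mean(z[rows, ff, drop = FALSE]) - mean(z[rows, fb, drop = FALSE])
      })
      side <- ifelse(contrast >= 0, "FF-ANS", "FB-ANS")
      # disambiguate multiple clusters on one side by contrast rank
      for (s in unique(side)) {
        idx <- which(side == s)
        if (length(idx) > 1) {
          ord <- order(-abs(contrast[idx]))
          side[idx[ord][-1]] <- paste0(s, "-", seq_along(idx[-1]) + 1)
        }
      }
      cluster_names <- setNames(side, seq_len(genes$k))
    }
  }
  structure(list(genes = genes, regions = regs,
                 zscored = zs$zscored, dropped_rows = zs$dropped_rows,
                 gene_cluster_names = cluster_names),
            class = "can_bicluster")
}

#' Export a linkage tree as Newick
#'
#' Writes the dendrogram with merge heights converted to branch lengths, so
#' external tree viewers can display the clustering.
#'
#' @param tree An `hclust` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_linkage_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
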