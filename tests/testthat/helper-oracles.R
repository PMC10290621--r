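# Independent oracles, deliberately implemented with different primitives
# than the package code paths they check.

# Brute-force Ward agglomerator: at each step exhaustively evaluates every
# cluster pair and merges the one with the smallest within-cluster
# sum-of-squares increase dWSS = |A||B|/(|A|+|B|) * ||mean_A - mean_B||^2.
# Heights are reported on the distance scale, sqrt(2 * dWSS). Returns the
# merge heights and the partition after each merge (as lists of leaf-name
# sets) for order-insensitive comparison.
oracle_ward <- function(x) {
  stopifnot(!is.null(rownames(x)))
  clusters <- lapply(rownames(x), function(id) id)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- NULL
    best_cost <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        a <- x[clusters[[i]], , drop = FALSE]
        b <- x[clusters[[j]], , drop = FALSE]
        d2 <- sum((colMeans(a) - colMeans(b))^2)
        cost <- nrow(a) * nrow(b) / (nrow(a) + nrow(b)) * d2
        if (cost < best_cost - 1e-15) {
          best_cost <- cost
          best <- c(i, j)
        }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, sqrt(2 * best_cost))
    partitions <- c(partitions, list(lapply(clusters, sort)))
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a partition given as a label vector: sorted list of
# sorted member-name sets
canonical_partition <- function(labels) {
  parts <- split(names(labels), labels)
  parts <- lapply(parts, sort)
  unname(parts[order(vapply(parts, `[`, "", 1))])
}

# hypergeometric upper tail P(X >= k) by direct enumeration with choose()
oracle_hyper_p <- function(N, K, n, k) {
  i <- seq(k, min(K, n))
  if (k > min(K, n)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# adjusted Rand index from the pair-counting formula
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / total
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# small planted dataset in the shape run_msvm_rfe consumes: samples x
# features matrix (regions as rows) plus class labels
planted_training_set <- function(n_genes, n_regions, k_classes,
                                 n_informative, signal, noise_sd, seed) {
  sim <- simulate_expression(synthetic_config(
    n_genes = n_genes, n_regions = n_regions,
    k_region_clusters = k_classes, k_gene_clusters = k_classes,
    n_informative_genes = n_informative,
    signal = signal, noise_sd = noise_sd, seed = seed))
  list(sim = sim,
       x = t(log(canprio:::expr_to_matrix(sim$expression))),
       classes = stats::setNames(sim$regions$region_cluster,
                                 sim$regions$region_id))
}
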