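#' Configuration for the synthetic expression-energy generator
#'
#' Describes a gene-by-brain-region expression-energy dataset with planted
#' block structure: `k_region_clusters` column classes (emulating the seven
#' CAN region clusters), `k_gene_clusters` row groups (emulating the
#' feedforward / feedback gene clusters), and `n_informative_genes` genes
#' whose log-scale mean is shifted by `signal` in exactly one region class
#' ("on" / "off" pattern). Energies are log-normal: `exp(block_mean + noise)`,
#' matching the non-negative, right-skewed character of in situ hybridization
#' expression energies.
#'
#' Defaults mirror the study scale: 418 genes with ECG knockout phenotypes
#' profiled over 47 central-autonomic-network regions falling into 7 region
#' clusters and 2 gene clusters.
#'
#' @param n_genes,n_regions Matrix dimensions.
#' @param k_region_clusters Planted number of region (column) classes.
#' @param k_gene_clusters Planted number of gene (row) groups.
#' @param n_informative_genes Genes carrying class-specific signal; the rest
#'   share a single mean across all regions.
#' @param signal Log-scale mean offset between "on" and "off" blocks.
#' @param noise_sd Log-scale Gaussian noise standard deviation.
#' @param seed Integer seed; all draws derive from it via fixed substreams.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 418, n_regions = 47,
                             k_region_clusters = 7, k_gene_clusters = 2,
                             n_informative_genes = n_genes,
                             signal = 2, noise_sd = 0.4, seed = 1L) {
  check_count(n_genes, "n_genes")
  check_count(n_regions, "n_regions")
  check_count(k_region_clusters, "k_region_clusters")
  check_count(k_gene_clusters, "k_gene_clusters")
  check_count(n_informative_genes, "n_informative_genes", min = 0L)
  if (n_informative_genes > n_genes) {
    stopf("`n_informative_genes` (%d) exceeds `n_genes` (%d)",
          n_informative_genes, n_genes)
  }
  if (k_region_clusters > n_regions) {
    stopf("`k_region_clusters` (%d) exceeds `n_regions` (%d)",
          k_region_clusters, n_regions)
  }
  if (k_gene_clusters > n_genes) {
    stopf("`k_gene_clusters` (%d) exceeds `n_genes` (%d)",
          k_gene_clusters, n_genes)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stopf("`noise_sd` must be >= 0 (got %s)", paste(noise_sd, collapse = ","))
  }
  check_count(seed, "seed", min = 0L)
  structure(list(n_genes = as.integer(n_genes),
                 n_regions = as.integer(n_regions),
                 k_region_clusters = as.integer(k_region_clusters),
                 k_gene_clusters = as.integer(k_gene_clusters),
                 n_informative_genes = as.integer(n_informative_genes),
                 signal = as.numeric(signal),
                 noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# split n items into k contiguous groups as even as possible (sizes differ <= 1)
even_split <- function(n, k) sort(rep(seq_len(k), length.out = n))

#' Simulate a gene-by-region expression-energy matrix with planted structure
#'
#' Generates a strictly positive matrix `exp(block_mean + N(0, noise_sd))`.
#' Each informative gene is "on" (mean shifted up by `signal` on the log
#' scale) in exactly one planted region class; the on-class is tied to the
#' gene's planted gene cluster so gene groups are distinguishable. Region
#' classes are assigned a feedforward or feedback autonomic role (first gene
#' cluster's classes are feedforward) so downstream cluster naming can be
#' exercised.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements:
#'   * `expression` — tibble, `gene_id` + one numeric column per region;
#'   * `truth` — tibble `gene_id, gene_cluster, informative, on_class`;
#'   * `regions` — tibble `region_id, acronym, can_role, region_cluster`
#'     (the planted ground truth; `can_role` is `feedforward`/`feedback`).
#' @export
#' @examples
#' sim <- simulate_expression(synthetic_config(n_genes = 40, n_regions = 20,
#'                                             k_region_clusters = 4, seed = 3))
#' dim(sim$expression)
simulate_expression <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must be created with synthetic_config()")
  }
  c2 <- config
  gene_ids <- sprintf("gene%04d", seq_len(c2$n_genes))
  region_ids <- sprintf("R%03d", seq_len(c2$n_regions))

  region_class <- even_split(c2$n_regions, c2$k_region_clusters)
  gene_cluster <- even_split(c2$n_genes, c2$k_gene_clusters)
  informative <- seq_len(c2$n_genes) <= c2$n_informative_genes

  # region classes split as evenly as possible across gene clusters; the
  # classes owned by gene cluster g are the candidate "on" classes for its
  # informative genes
  class_owner <- even_split(c2$k_region_clusters, c2$k_gene_clusters)

  base_mean <- 1
  withr::with_seed(substream_seed(c2$seed, "matrix"), {
    on_class <- rep(NA_integer_, c2$n_genes)
    for (g in seq_len(c2$k_gene_clusters)) {
      own <- which(class_owner == g)
      idx <- which(informative & gene_cluster == g)
      if (length(idx)) {
        on_class[idx] <- rep(own, length.out = length(idx))
      }
    }
    mu <- matrix(base_mean, nrow = c2$n_genes, ncol = c2$n_regions)
    for (i in which(informative)) {
      mu[i, region_class == on_class[i]] <- base_mean + c2$signal
    }
    noise <- matrix(rnorm(c2$n_genes * c2$n_regions, sd = c2$noise_sd),
                    nrow = c2$n_genes)
    energies <- exp(mu + noise)
  })
  dimnames(energies) <- list(gene_ids, region_ids)

  role <- ifelse(class_owner[region_class] == 1L, "feedforward", "feedback")
  list(
    expression = matrix_to_expr(energies),
    truth = tibble(gene_id = gene_ids,
                   gene_cluster = gene_cluster,
                   informative = informative,
                   on_class = on_class),
    regions = tibble(region_id = region_ids,
                     acronym = region_ids,
                     can_role = role,
                     region_cluster = region_class)
  )
}

#' Simulate a per-gene ECG phenotype table
#'
#' Draws increased-heart-rate (`HR ↑`) and decreased-heart-rate-variability
#' (`HRV ↓`) annotations independently per gene as Bernoulli draws, writing
#' phenotype strings in the same dialect as the packaged knockout table so
#' they round-trip through [parse_phenotype_string()]. Genes with neither
#' annotation carry the literal "No".
#'
#' @param genes Character vector of gene identifiers (non-empty).
#' @param fraction_hr_up,fraction_hrv_down Per-gene probabilities in `[0,1]`.
#' @param fraction_npd Probability that a gene carries a (generic) human
#'   neuropsychiatric disease annotation rather than the literal
#'   "Limited or no NPD annotations".
#' @param seed Integer seed.
#' @return Tibble `gene_id, ecg_phenotype, behavior_phenotype, npd_annotation`.
#' @export
simulate_phenotypes <- function(genes, fraction_hr_up = 0.3,
                                fraction_hrv_down = 0.1,
                                fraction_npd = 0.3, seed = 1L) {
  if (length(genes) == 0) abort("`genes` must be a non-empty character vector")
  check_fraction(fraction_hr_up, "fraction_hr_up")
  check_fraction(fraction_hrv_down, "fraction_hrv_down")
  check_fraction(fraction_npd, "fraction_npd")
  n <- length(genes)
  withr::with_seed(substream_seed(seed, "phenotypes"), {
    hr_up <- rbinom(n, 1, fraction_hr_up) == 1
    hrv_down <- rbinom(n, 1, fraction_hrv_down) == 1
    npd <- rbinom(n, 1, fraction_npd) == 1
    behav <- sample(c("Hyperactivity", "Decreased prepulse inhibition",
                      "Decreased thigmotaxis", "No"), n, replace = TRUE)
  })
  ecg <- purrr::map2_chr(hr_up, hrv_down, function(a, b) {
    parts <- c(if (a) "HR ↑", if (b) "HRV ↓")
    if (length(parts) == 0) "No" else paste(parts, collapse = ",")
  })
  tibble(gene_id = genes,
         ecg_phenotype = ecg,
         behavior_phenotype = behav,
         npd_annotation = ifelse(npd, "Neuropsychiatric disease association",
                                 "Limited or no NPD annotations"))
}

#' Simulate a gene-set library (GMT) with one planted perfect term
#'
#' Draws `n_terms` random gene sets from `genes` with sizes uniform in
#' `set_size_range`. When `query` is supplied a term named `PLANTED_QUERY`
#' equal to exactly that set is appended, so its over-representation p-value
#' is minimal by construction.
#'
#' @param n_terms Number of random terms (0 allowed: empty library).
#' @param genes Gene universe to draw from.
#' @param set_size_range Length-2 integer range of set sizes.
#' @param query Optional character vector (subset of `genes`) planted as its
#'   own term.
#' @param seed Integer seed.
#' @return A gene-set library: named list of character vectors with attribute
#'   `name`, as returned by [read_gmt()].
#' @export
simulate_gmt <- function(n_terms, genes, set_size_range = c(5, 25),
                         query = NULL, seed = 1L) {
  check_count(n_terms, "n_terms", min = 0L)
  if (length(set_size_range) != 2 || any(set_size_range < 1)) {
    abort("`set_size_range` must be two positive integers")
  }
  if (max(set_size_range) > length(genes)) {
    stopf("set size %d exceeds gene universe size %d",
          max(set_size_range), length(genes))
  }
  if (!is.null(query) && !all(query %in% genes)) {
    abort("`query` must be a subset of `genes`")
  }
  withr::with_seed(substream_seed(seed, "gmt"), {
    sets <- purrr::map(seq_len(n_terms), function(i) {
      size <- sample(seq(set_size_range[1], set_size_range[2]), 1)
      sort(sample(genes, size))
    })
  })
  names(sets) <- if (n_terms > 0) sprintf("TERM_%03d", seq_len(n_terms)) else character()
  if (!is.null(query)) sets[["PLANTED_QUERY"]] <- toupper(sort(unique(query)))
  sets <- purrr::map(sets, ~ unique(toupper(.x)))
  structure(sets, name = "synthetic_library")
}

#' Write a synthetic study bundle to disk
#'
#' Materializes one simulated dataset as the plain-text files the ingestion
#' stage consumes: expression TSV, region CSV, phenotype TSV, GMT library,
#' and a ground-truth JSON.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if absent).
#' @param n_terms Number of random GMT terms.
#' @return Invisibly, a named list of the file paths written.
#' @export
write_synthetic_bundle <- function(config = synthetic_config(), dir,
                                   n_terms = 20) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_expression(config)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    regions = file.path(dir, "regions.csv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    gmt = file.path(dir, "library.gmt"),
    truth = file.path(dir, "truth.json")
  )
  write_expression_matrix(sim$expression, paths$expression)
  readr::write_csv(sim$regions[c("region_id", "acronym", "can_role")],
                   paths$regions)
  pheno <- simulate_phenotypes(sim$truth$gene_id, seed = config$seed)
  readr::write_tsv(pheno, paths$phenotypes)
  planted <- sim$truth$gene_id[sim$truth$informative &
                                 sim$truth$gene_cluster == 1]
  lib <- simulate_gmt(n_terms, sim$truth$gene_id,
                      set_size_range = c(5, max(5, config$n_genes %/% 10)),
                      query = head(planted, 10), seed = config$seed)
  write_gmt(lib, paths$gmt)
  jsonlite::write_json(list(gene_cluster = as.list(setNames(sim$truth$gene_cluster,
                                                            sim$truth$gene_id)),
                            region_cluster = as.list(setNames(sim$regions$region_cluster,
                                                              sim$regions$region_id)),
                            informative = sim$truth$gene_id[sim$truth$informative]),
                       paths$truth, auto_unbox = TRUE)
  invisible(paths)
}
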