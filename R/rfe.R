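#' Configuration for multiclass SVM recursive feature elimination
#'
#' Defaults reproduce the study protocol: 4 stratified folds with all
#' combinations of 3 folds as training sets, 50 repetitions (200 runs),
#' 10% of remaining features eliminated per iteration down to a stop size
#' of 15, linear C-classification SVMs at cost 0.01.
#'
#' @param n_folds Folds per repeat (>= 2).
#' @param n_repeats Repetitions of the fold split.
#' @param elimination_fraction Fraction of remaining features removed per
#'   iteration, in (0, 1).
#' @param stop_n Final feature-set size per run (>= 1).
#' @param svm_cost Soft-margin cost for the linear SVMs.
#' @param seed Integer seed for the stratified shuffles.
#' @return A list of class `rfe_config`.
#' @export
rfe_config <- function(n_folds = 4, n_repeats = 50,
                       elimination_fraction = 0.10, stop_n = 15,
                       svm_cost = 0.01, seed = 1L) {
  check_count(n_folds, "n_folds", min = 2L)
  check_count(n_repeats, "n_repeats")
  check_fraction(elimination_fraction, "elimination_fraction", open = TRUE)
  check_count(stop_n, "stop_n")
  check_fraction(svm_cost, "svm_cost", lo = 0, hi = Inf, open = TRUE)
  check_count(seed, "seed", min = 0L)
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 elimination_fraction = as.numeric(elimination_fraction),
                 stop_n = as.integer(stop_n),
                 svm_cost = as.numeric(svm_cost),
                 seed = as.integer(seed)),
            class = "rfe_config")
}

#' Build a repeated stratified fold plan over samples
#'
#' For each repeat, samples are shuffled within class (seeded) and dealt
#' round-robin to folds, continuing one global fold pointer across classes
#' so overall fold sizes differ by at most 1 and per-class occupancy differs
#' by at most 1. Training sets enumerate all (n_folds - 1)-subsets of folds,
#' i.e. leave-one-fold-out, giving `n_folds` training sets per repeat and
#' `n_repeats * n_folds` runs in total.
#'
#' @param sample_classes Named vector/factor: class label per sample id.
#' @param config An [rfe_config()].
#' @return Tibble with one row per training set: `repeat_id, fold_left_out,
#'   run_id, train_ids` (list column of sample ids).
#' @export
make_fold_plan <- function(sample_classes, config = rfe_config()) {
  ids <- names(sample_classes)
  if (is.null(ids)) abort("`sample_classes` must be named by sample id")
  cls <- split(ids, as.character(sample_classes))
  sizes <- lengths(cls)
  if (any(sizes < 2)) {
    bad <- names(sizes)[sizes < 2][1]
    stopf(paste0("class %s has %d member; stratified folds with ",
                 "all-but-one-fold training cannot guarantee class presence"),
          bad, sizes[[bad]])
  }
  nf <- config$n_folds
  plans <- withr::with_seed(substream_seed(config$seed, "folds"), {
    purrr::map(seq_len(config$n_repeats), function(rep_i) {
      fold_of <- integer(0)
      ptr <- 0L
      for (cl in names(cls)) {
        members <- sample(cls[[cl]])
        f <- ((ptr + seq_along(members) - 1L) %% nf) + 1L
        ptr <- (ptr + length(members)) %% nf
        fold_of <- c(fold_of, setNames(f, members))
      }
      fold_of
    })
  })
  out <- purrr::imap(plans, function(fold_of, rep_i) {
    purrr::map(seq_len(nf), function(left_out) {
      tibble(repeat_id = rep_i, fold_left_out = left_out,
             train_ids = list(names(fold_of)[fold_of != left_out]))
    }) |> bind_rows()
  }) |> bind_rows()
  out$run_id <- seq_len(nrow(out))
  out[c("run_id", "repeat_id", "fold_left_out", "train_ids")]
}

#' Score features by squared weights of pairwise linear SVMs
#'
#' Fits a one-vs-one soft-margin linear SVM for every pair of classes
#' present in the training set and scores each feature as the sum over
#' pairwise classifiers of the squared weight-vector coefficient — the
#' standard SVM-RFE importance criterion. Higher means more important.
#'
#' @param x Numeric matrix, samples x features (column names = feature ids).
#' @param y Class label per sample.
#' @param cost SVM soft-margin cost.
#' @return Named numeric vector of scores, one per feature.
#' @export
rank_features_by_weights <- function(x, y, cost = 0.01) {
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) abort("training set must contain >= 2 classes")
  if (all(apply(x, 2, function(v) length(unique(v)) == 1))) {
    abort("degenerate training set: all features constant")
  }
  score <- setNames(numeric(ncol(x)), colnames(x))
  for (pair in utils::combn(classes, 2, simplify = FALSE)) {
    sel <- y %in% pair
    fit <- e1071::svm(x = x[sel, , drop = FALSE], y = factor(y[sel]),
                      type = "C-classification", kernel = "linear",
                      cost = cost, scale = FALSE)
    w <- as.numeric(crossprod(fit$coefs, fit$SV))
    score <- score + w^2
  }
  score
}

#' One recursive feature-elimination run
#'
#' Starting from all features, repeatedly scores features with
#' [rank_features_by_weights()] and removes the `m` lowest-scoring, where
#' `m = min(max(1, ceiling(elimination_fraction * n_remaining)),
#' n_remaining - stop_n)`, stopping when exactly `stop_n` features remain.
#' Score ties are broken by removing the lexicographically larger feature
#' id first, making runs fully deterministic.
#'
#' @param x Training matrix, samples x features.
#' @param y Class labels.
#' @param config An [rfe_config()].
#' @return List: `final_features` (character, length `stop_n`),
#'   `elimination_step` (named integer; iteration at which each feature was
#'   removed, 0 for survivors), `n_iterations`.
#' @export
rfe_single_run <- function(x, y, config = rfe_config()) {
  feats <- colnames(x)
  if (length(feats) <= config$stop_n) {
    stopf("need more than stop_n = %d features (got %d)",
          config$stop_n, length(feats))
  }
  step_of <- setNames(integer(length(feats)), feats)
  remaining <- feats
  iter <- 0L
  while (length(remaining) > config$stop_n) {
    iter <- iter + 1L
    sc <- rank_features_by_weights(x[, remaining, drop = FALSE], y,
                                   cost = config$svm_cost)
    m <- min(max(1L, ceiling(config$elimination_fraction * length(remaining))),
             length(remaining) - config$stop_n)
    # lowest score first; ties -> lexicographically larger id removed first
    ord <- order(sc, -rank(names(sc)))
    drop <- names(sc)[ord][seq_len(m)]
    step_of[drop] <- iter
    remaining <- setdiff(remaining, drop)
  }
  list(final_features = remaining, elimination_step = step_of,
       n_iterations = iter)
}

#' Multiclass SVM-RFE hub-gene ranking over repeated stratified folds
#'
#' Runs [rfe_single_run()] on every training set of the fold plan (samples
#' are brain regions, classes are region-cluster labels, features are
#' genes) and aggregates: `selection_frequency` counts the runs whose final
#' set contains the gene; `mean_elimination_step` averages the iteration at
#' which the gene was removed, with survivors scored as last iteration + 1
#' so that surviving ranks latest. Genes are ranked by frequency
#' (descending), then mean elimination step (descending), then gene id.
#'
#' @param zscored Z-scored expression tibble (genes x regions).
#' @param region_labels Named vector: region-cluster label per region id.
#' @param gene_cluster_labels Optional named vector: gene-cluster label (or
#'   name) per gene id, carried into the ranking.
#' @param config An [rfe_config()].
#' @return A list of class `can_rfe`: `ranking` (tibble `gene_id,
#'   selection_frequency, mean_elimination_step, rank, cluster`), `runs`
#'   (tibble of per-run final feature sets), `n_runs`, `config`.
#' @export
run_msvm_rfe <- function(zscored, region_labels, gene_cluster_labels = NULL,
                         config = rfe_config()) {
  z <- expr_to_matrix(zscored)
  x_all <- t(z)  # samples (regions) x features (genes)
  if (!all(rownames(x_all) %in% names(region_labels))) {
    abort("`region_labels` must cover every region in the matrix")
  }
  cls <- region_labels[rownames(x_all)]
  plan <- make_fold_plan(cls, config)

  runs <- purrr::pmap(plan, function(run_id, repeat_id, fold_left_out,
                                     train_ids) {
    res <- rfe_single_run(x_all[train_ids, , drop = FALSE], cls[train_ids],
                          config)
    tibble(run_id = run_id, repeat_id = repeat_id,
           fold_left_out = fold_left_out,
           final_features = list(res$final_features),
           n_iterations = res$n_iterations,
           elimination_step = list(res$elimination_step))
  }) |> bind_rows()

  genes <- colnames(x_all)
  freq <- setNames(integer(length(genes)), genes)
  step_sum <- setNames(numeric(length(genes)), genes)
  for (i in seq_len(nrow(runs))) {
    st <- runs$elimination_step[[i]]
    last <- runs$n_iterations[i]
    st[st == 0L] <- last + 1L  # survivors count as eliminated last
    step_sum <- step_sum + st[genes]
    f <- runs$final_features[[i]]
    freq[f] <- freq[f] + 1L
  }
  ranking <- tibble(gene_id = genes,
                    selection_frequency = as.integer(freq[genes]),
                    mean_elimination_step = step_sum[genes] / nrow(runs)) |>
    arrange(desc(.data$selection_frequency),
            desc(.data$mean_elimination_step), .data$gene_id) |>
    mutate(rank = row_number())
  ranking$cluster <- if (!is.null(gene_cluster_labels)) {
    as.character(gene_cluster_labels[ranking$gene_id])
  } else NA_character_
  structure(list(ranking = ranking, runs = runs, n_runs = nrow(runs),
                 config = config),
            class = "can_rfe")
}

#' Extract the top hub genes, partitioned by gene cluster
#'
#' @param rfe A `can_rfe` object from [run_msvm_rfe()].
#' @param top_n Number of hub genes to extract (default 99, the study's
#'   choice).
#' @return List: `hub_genes` (tibble, first `top_n` rows of the ranking)
#'   and `partition` (named integer vector of counts per gene cluster;
#'   sums to `top_n`).
#' @export
top_hub_genes <- function(rfe, top_n = 99) {
  if (top_n <= 0) abort("`top_n` must be positive")
  n <- nrow(rfe$ranking)
  if (top_n > n) stopf("`top_n` (%d) exceeds number of genes (%d)", top_n, n)
  hubs <- rfe$ranking[seq_len(top_n), ]
  part <- table(hubs$cluster, useNA = "ifany")
  list(hub_genes = hubs,
       partition = setNames(as.integer(part), names(part)))
}
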