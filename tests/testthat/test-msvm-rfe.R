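test_that("fold plans are stratified, balanced, and enumerate leave-one-fold-out", {
  classes <- setNames(rep(1:7, times = c(7, 7, 7, 7, 7, 6, 6)),
                      sprintf("R%02d", 1:47))
  cfg <- rfe_config(n_folds = 4, n_repeats = 50, seed = 3)
  plan <- make_fold_plan(classes, cfg)
  expect_equal(nrow(plan), 200)
  expect_equal(plan$run_id, 1:200)

  # reconstruct fold sizes for one repeat from the four training sets
  rep1 <- plan[plan$repeat_id == 1, ]
  fold_members <- lapply(1:4, function(f) {
    setdiff(names(classes), rep1$train_ids[[which(rep1$fold_left_out == f)]])
  })
  sizes <- sort(lengths(fold_members), decreasing = TRUE)
  expect_equal(sizes, c(12, 12, 12, 11))
  # per-class occupancy differs by at most 1 across folds
  for (cl in unique(classes)) {
    occ <- vapply(fold_members,
                  function(m) sum(classes[m] == cl), integer(1))
    expect_lte(max(occ) - min(occ), 1)
  }

  # class sizes all multiples of n_folds -> identical class composition
  classes8 <- setNames(rep(1:2, each = 8), sprintf("S%02d", 1:16))
  plan8 <- make_fold_plan(classes8, rfe_config(n_folds = 4, n_repeats = 1))
  folds8 <- lapply(1:4, function(f) {
    setdiff(names(classes8), plan8$train_ids[[which(plan8$fold_left_out == f)]])
  })
  comps <- lapply(folds8, function(m) as.vector(table(classes8[m])))
  expect_true(all(vapply(comps, identical, logical(1), comps[[1]])))

  single <- setNames(c(1, 1, 2), c("a", "b", "c"))
  expect_error(make_fold_plan(single, cfg), "class 2 has 1 member")
})

test_that("pairwise SVM weight scores separate signal from noise symmetrically", {
  set.seed(21)
  y <- rep(c("a", "b"), each = 10)
  x <- cbind(f1 = ifelse(y == "a", 1, -1),
             f2 = rnorm(20, sd = 1e-3))
  rownames(x) <- sprintf("s%02d", 1:20)
  sc <- rank_features_by_weights(x, y, cost = 1)
  expect_gt(sc[["f1"]], sc[["f2"]])

  # a duplicated feature column receives an equal share of the weight
  x3 <- cbind(x, f1copy = x[, "f1"])
  sc3 <- rank_features_by_weights(x3, y, cost = 1)
  expect_lt(abs(sc3[["f1"]] - sc3[["f1copy"]]), 1e-9)

  expect_error(rank_features_by_weights(cbind(f1 = rep(1, 4)),
                                        c("a", "a", "b", "b")),
               "degenerate")
  expect_error(rank_features_by_weights(x, rep("a", 20)), ">= 2 classes")
})

test_that("the elimination schedule follows ceil-with-clamp down to the stop size", {
  set.seed(7)
  y <- rep(c("a", "b"), each = 6)
  make_x <- function(p) {
    x <- matrix(rnorm(12 * p), 12, p,
                dimnames = list(sprintf("s%02d", 1:12),
                                sprintf("f%03d", seq_len(p))))
    x[, 1] <- x[, 1] + ifelse(y == "a", 3, -3)  # keep it non-degenerate
    x
  }
  cfg <- rfe_config(elimination_fraction = 0.1, stop_n = 15, svm_cost = 1)

  run20 <- rfe_single_run(make_x(20), y, cfg)
  expect_length(run20$final_features, 15)
  # 20 -> 18 -> 16 -> 15: removals of 2, 2, 1 across three iterations
  expect_equal(as.vector(table(run20$elimination_step[run20$elimination_step > 0])),
               c(2, 2, 1))
  expect_equal(run20$n_iterations, 3)

  run16 <- rfe_single_run(make_x(16), y, cfg)
  expect_equal(run16$n_iterations, 1)
  expect_length(run16$final_features, 15)

  expect_error(rfe_single_run(make_x(15), y, cfg), "more than stop_n")
})

test_that("selection frequency is conserved and runs are seed-deterministic", {
  ts <- planted_training_set(n_genes = 40, n_regions = 18, k_classes = 3,
                             n_informative = 6, signal = 3, noise_sd = 0.3,
                             seed = 31)
  zs <- zscore_rows(ts$sim$expression)
  for (cfg in list(rfe_config(n_folds = 3, n_repeats = 2, stop_n = 5, seed = 1),
                   rfe_config(n_folds = 2, n_repeats = 3, stop_n = 8, seed = 2))) {
    rfe <- run_msvm_rfe(zs$zscored, ts$classes, config = cfg)
    expect_equal(rfe$n_runs, cfg$n_folds * cfg$n_repeats)
    expect_equal(sum(rfe$ranking$selection_frequency),
                 rfe$n_runs * cfg$stop_n)
    expect_equal(sort(rfe$ranking$rank), seq_len(nrow(rfe$ranking)))
    rfe2 <- run_msvm_rfe(zs$zscored, ts$classes, config = cfg)
    expect_identical(rfe$ranking, rfe2$ranking)
  }
})

test_that("noiseless class-coding genes are selected in every run and top-ranked", {
  ts <- planted_training_set(n_genes = 100, n_regions = 35, k_classes = 7,
                             n_informative = 15, signal = 2, noise_sd = 0,
                             seed = 13)
  cfg <- rfe_config(n_folds = 4, n_repeats = 2, stop_n = 15, seed = 5)
  rfe <- run_msvm_rfe(canprio:::matrix_to_expr(t(ts$x)), ts$classes,
                      gene_cluster_labels = setNames(ts$sim$truth$gene_cluster,
                                                     ts$sim$truth$gene_id),
                      config = cfg)
  planted <- ts$sim$truth$gene_id[ts$sim$truth$informative]
  rk <- rfe$ranking
  expect_equal(sort(rk$gene_id[rk$rank <= 15]), sort(planted))
  expect_true(all(rk$selection_frequency[rk$gene_id %in% planted] ==
                    rfe$n_runs))
  # a flat gene never enters any final set
  expect_true(all(rk$selection_frequency[!rk$gene_id %in% planted] == 0))

  hubs <- top_hub_genes(rfe, top_n = 15)
  expect_equal(sum(hubs$partition), 15)
  expect_equal(nrow(hubs$hub_genes), 15)
  expect_error(top_hub_genes(rfe, 0), "positive")
  all_part <- top_hub_genes(rfe, top_n = nrow(rk))$partition
  expect_equal(sum(all_part), nrow(rk))
})

test_that("cloned features earn identical records and adjacent ranks", {
  ts <- planted_training_set(n_genes = 40, n_regions = 18, k_classes = 3,
                             n_informative = 5, signal = 3, noise_sd = 0,
                             seed = 17)
  expr <- canprio:::matrix_to_expr(t(ts$x))
  clone <- expr[expr$gene_id == "gene0001", ]
  clone$gene_id <- "gene0001b"
  expr2 <- dplyr::bind_rows(expr, clone)
  cfg <- rfe_config(n_folds = 3, n_repeats = 2, stop_n = 10, seed = 4)
  rfe <- run_msvm_rfe(expr2, ts$classes, config = cfg)
  rk <- rfe$ranking
  r1 <- rk[rk$gene_id == "gene0001", ]
  r2 <- rk[rk$gene_id == "gene0001b", ]
  expect_equal(r1$selection_frequency, r2$selection_frequency)
  expect_equal(abs(r1$rank - r2$rank), 1)
  expect_lt(r1$rank, r2$rank)  # id tie-break favours the smaller id
})
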