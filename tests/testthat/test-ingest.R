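make_expr_file <- function(expr, path = tempfile(fileext = ".tsv")) {
  write_expression_matrix(expr, path)
  path
}

test_that("expression TSV round-trips values and orders exactly", {
  sim <- simulate_expression(synthetic_config(n_genes = 12, n_regions = 8,
                                              k_region_clusters = 2, seed = 2))
  path <- make_expr_file(sim$expression)
  back <- read_expression_matrix(path)
  expect_equal(back$expression, sim$expression)
  expect_equal(back$report$retained_genes, 12)
  expect_length(back$report$missing_genes, 0)
})

test_that("whitelist genes absent from the file are reported, not fabricated", {
  sim <- simulate_expression(synthetic_config(n_genes = 418, n_regions = 10,
                                              k_region_clusters = 2, seed = 6))
  path <- make_expr_file(sim$expression)
  # emulate requesting the full ECG gene set when only 418 have expression
  whitelist <- c(sim$truth$gene_id, sprintf("absent%02d", 1:44))
  res <- read_expression_matrix(path, gene_whitelist = whitelist)
  expect_equal(res$report$requested_genes, 462)
  expect_equal(res$report$retained_genes, 418)
  expect_length(res$report$missing_genes, 44)
  expect_equal(res$report$retained_genes + length(res$report$missing_genes),
               res$report$requested_genes)
  # retained order follows the whitelist
  expect_equal(res$expression$gene_id, sim$truth$gene_id)
})

test_that("malformed cells fail with row/column context", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tR1\tR2", "g1\t1.5\t2", "g2\t-1\t3"), tmp)
  expect_error(read_expression_matrix(tmp), "row 2, column R1")
  writeLines(c("gene_id\tR1", "g1\tabc"), tmp)
  expect_error(read_expression_matrix(tmp), "non-numeric")
  writeLines(c("gene_id\tR1", "g1\t1", "g1\t2"), tmp)
  expect_error(read_expression_matrix(tmp), "duplicate gene")
})

test_that("replicate collapsing keeps the max-total experiment with id tie-break", {
  rows <- tibble::tibble(gene_id = c("g1", "g2", "g2", "g3", "g3"),
                         experiment_id = c("e1", "B", "A", "x2", "x1"),
                         R1 = c(1, 5, 25, 2, 2), R2 = c(2, 5, 5, 3, 3))
  out <- collapse_replicates(rows)
  expect_equal(out$expression$gene_id, c("g1", "g2", "g3"))
  # g1 single experiment unchanged
  expect_equal(unlist(out$expression[1, c("R1", "R2")], use.names = FALSE),
               c(1, 2))
  # g2: totals 10 vs 30 -> the total-30 row (A) kept
  expect_equal(out$expression$R1[2], 25)
  # g3: equal totals -> lexicographically smallest experiment id kept
  expect_equal(out$experiments_per_gene[["g3"]], 2L)
  # idempotence: collapsing an already-collapsed table is the identity
  again <- collapse_replicates(dplyr::mutate(out$expression,
                                             experiment_id = "only"))
  expect_equal(again$expression[c("gene_id", "R1", "R2")],
               out$expression[c("gene_id", "R1", "R2")])
})

test_that("region subsetting restricts, reorders, and enforces strictness", {
  sim <- simulate_expression(synthetic_config(n_genes = 5, n_regions = 6,
                                              k_region_clusters = 2, seed = 3))
  regions <- sim$regions[rev(seq_len(6)), ]
  out <- subset_regions(sim$expression, regions)
  expect_equal(names(out)[-1], rev(sim$regions$region_id))
  expect_equal(subset_regions(out, regions), out)  # idempotent

  bad <- dplyr::bind_rows(regions,
                          tibble::tibble(region_id = "XYZ", acronym = "XYZ",
                                         can_role = "feedback",
                                         region_cluster = 1L))
  expect_error(subset_regions(sim$expression, bad, strict = TRUE),
               "region XYZ not in matrix")
  expect_warning(sub2 <- subset_regions(sim$expression, bad, strict = FALSE),
                 "XYZ")
  expect_equal(ncol(sub2), 7)
  expect_error(subset_regions(sim$expression, regions[0, ]), "empty")
})

test_that("a whole-brain-scale matrix reduces to the CAN region panel", {
  n_regions <- 2426
  m <- matrix(rexp(10 * n_regions), nrow = 10,
              dimnames = list(sprintf("g%02d", 1:10),
                              sprintf("R%04d", seq_len(n_regions))))
  expr <- canprio:::matrix_to_expr(m)
  panel <- tibble::tibble(region_id = sprintf("R%04d", round(seq(1, 2426, length.out = 47))),
                          acronym = sprintf("A%02d", 1:47),
                          can_role = rep(c("feedforward", "feedback"),
                                         length.out = 47))
  out <- subset_regions(expr, panel, strict = TRUE)
  expect_equal(ncol(out) - 1, 47)
})
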