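test_that("MTX triplet round-trips through write_tenx and read_count_matrix", {
  cfg <- default_simulation_config(seed = 2,
                                   n_cells = c(unwounded = 150, wounded = 150),
                                   n_background_genes = 30)
  sim <- generate_dataset(cfg)
  d <- withr::local_tempdir()
  write_tenx(sim$unwounded, d)
  back <- read_count_matrix(d, "unwounded")
  expect_equal(length(back$cell_ids), 150)
  expect_identical(back$cell_ids, sim$unwounded$cell_ids)
  expect_identical(back$gene_symbols, sim$unwounded$gene_symbols)
  expect_equal(as.matrix(back$counts), as.matrix(sim$unwounded$counts))
})

test_that("hand-written one-cell triplet parses; degenerate inputs error", {
  d <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 1 1", "1 1 5"), file.path(d, "matrix.mtx"))
  writeLines(c("geneA", "geneB"), file.path(d, "features.tsv"))
  writeLines("cell1", file.path(d, "barcodes.tsv"))
  m <- read_count_matrix(d, "unwounded")
  expect_equal(sum(m$counts), 5)
  expect_equal(dim(m$counts), c(1L, 2L))

  # zero cells
  d2 <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general", "2 0 0"),
             file.path(d2, "matrix.mtx"))
  writeLines(c("geneA", "geneB"), file.path(d2, "features.tsv"))
  writeLines(character(), file.path(d2, "barcodes.tsv"))
  expect_error(read_count_matrix(d2, "unwounded"), "no cells")

  # header/annotation mismatch
  d3 <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 1 1", "1 1 5"), file.path(d3, "matrix.mtx"))
  writeLines("geneA", file.path(d3, "features.tsv"))
  writeLines("cell1", file.path(d3, "barcodes.tsv"))
  expect_error(read_count_matrix(d3, "unwounded"), "features")

  expect_error(read_count_matrix(withr::local_tempdir(), "unwounded"),
               "missing input file")
})

test_that("qc_filter applies the three criteria and is idempotent", {
  counts <- rbind(
    good = c(600, 400, 5, 0),
    low_total = c(60, 39, 1, 0),
    apoptotic = c(100, 100, 0, 400),
    few_genes = c(700, 0, 0, 0))
  cm <- count_matrix(counts, rownames(counts),
                     c("g1", "g2", "g3", "Apop01"), "unwounded")
  res <- qc_filter(cm, min_counts = 500, min_genes = 0,
                   apoptotic_panel = "Apop01", max_apoptotic = 0.10)
  expect_identical(res$matrix$cell_ids, c("good", "few_genes"))
  expect_equal(res$report$pass, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(res$report$apoptotic_fraction[3], 400 / 600)

  # permissive thresholds are the identity
  res0 <- qc_filter(cm, 0, 0, "Apop01", 1.0)
  expect_identical(res0$matrix$cell_ids, cm$cell_ids)

  # min_genes criterion
  res_g <- qc_filter(cm, 0, 2, character(), 1)
  expect_equal(res_g$report$pass, c(TRUE, TRUE, TRUE, FALSE))

  # idempotence
  twice <- qc_filter(res$matrix, 500, 0, "Apop01", 0.10)
  expect_identical(twice$matrix$cell_ids, res$matrix$cell_ids)
  expect_identical(as.matrix(twice$matrix$counts), as.matrix(res$matrix$counts))

  expect_error(qc_filter(cm, 1e6, 0, character(), 1), "empty after QC")
})

test_that("planted QC failures are recovered with precision and recall >= 0.95", {
  cfg <- small_default_config(seed = 17)
  sim <- generate_dataset(cfg)
  gt <- sim$ground_truth
  for (cond in c("unwounded", "wounded")) {
    cm <- sim[[cond]]
    res <- qc_filter(cm, apoptotic_panel = gt$apoptotic_panel)
    flagged <- res$report$cell_id[!res$report$pass]
    truly_bad <- names(gt$qc_fail_mode)[gt$qc_fail_mode != "none"]
    truly_bad <- intersect(truly_bad, cm$cell_ids)
    precision <- mean(flagged %in% truly_bad)
    recall <- mean(truly_bad %in% flagged)
    expect_gte(precision, 0.95)
    expect_gte(recall, 0.95)
  }
})

test_that("normalization matches its closed form and per-entry oracle", {
  cm <- count_matrix(matrix(c(0, 10), 1, 2), "c1", c("g1", "g2"), "unwounded")
  nm <- normalize_counts(cm, scale = 1e4, pseudocount = 1)
  expect_equal(as.numeric(nm$expr), c(0, log(1 + 1e4)))

  set.seed(4)
  X <- matrix(rpois(20, 4) + 1, 5, 4)
  cm <- count_matrix(X, paste0("c", 1:5), paste0("g", 1:4), "wounded")
  nm <- normalize_counts(cm, scale = 100, pseudocount = 0.5)
  oracle <- matrix(0, 5, 4)
  for (i in 1:5) {
    for (j in 1:4) {
      oracle[i, j] <- log((100 * X[i, j] / sum(X[i, ]) + 0.5) / 0.5)
    }
  }
  expect_equal(unname(as.matrix(nm$expr)), oracle)
  expect_identical(nm$meta$scale, 100)
})

test_that("normalization is invariant to per-cell count scaling", {
  set.seed(8)
  X <- matrix(rpois(40, 3), 8, 5)
  X[rowSums(X) == 0, 1] <- 1
  X2 <- X
  X2[3, ] <- X2[3, ] * 2  # sequencing a cell twice as deep changes nothing
  n1 <- normalize_counts(count_matrix(X, paste0("c", 1:8), paste0("g", 1:5),
                                      "unwounded"))
  n2 <- normalize_counts(count_matrix(X2, paste0("c", 1:8), paste0("g", 1:5),
                                      "unwounded"))
  expect_equal(as.matrix(n1$expr), as.matrix(n2$expr))
  # zeros map to zeros, order within a cell is preserved
  expect_identical(unname(as.matrix(n1$expr)) == 0, unname(X == 0))
  expect_identical(order(as.matrix(n1$expr)[1, ]), order(X[1, ]))
})

test_that("zero-total cells and gene filtering behave as documented", {
  X <- rbind(c1 = c(0, 0, 0, 0), c2 = c(0, 5, 2, 0))
  cm <- count_matrix(X, rownames(X), paste0("g", 1:4), "unwounded")
  expect_error(normalize_counts(cm), "zero total")
  fg <- filter_genes(cm, min_cells = 1)
  expect_identical(fg$gene_symbols, c("g2", "g3"))
  expect_error(filter_genes(cm, min_cells = 3), "no gene")
})
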