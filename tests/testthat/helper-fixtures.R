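# shared fixture builders; everything is generated in code at test time

# a cluster_profiles object assembled by hand
manual_profiles <- function(ids, condition, n_cells, mean_linear,
                            mean_expr = NULL) {
  genes <- colnames(mean_linear)
  if (is.null(mean_expr)) mean_expr <- log1p(mean_linear)
  key <- paste(ids, condition, sep = "|")
  rownames(mean_linear) <- key
  rownames(mean_expr) <- key
  structure(list(cluster_id = ids, condition = condition,
                 n_cells = stats::setNames(n_cells, key),
                 mean_expr = mean_expr, mean_linear = mean_linear,
                 gene_symbols = genes),
            class = "cluster_profiles")
}

# a normalized_matrix wrapped around a dense expression matrix
manual_normalized <- function(X, condition = "unwounded") {
  if (is.null(rownames(X))) rownames(X) <- sprintf("cell%04d", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- sprintf("g%04d", seq_len(ncol(X)))
  expr <- methods::as(methods::as(Matrix::Matrix(X, sparse = TRUE),
                                  "generalMatrix"), "CsparseMatrix")
  structure(list(expr = expr, cell_ids = rownames(X),
                 gene_symbols = colnames(X), condition = condition,
                 meta = list(scale = 1e4, log_base = exp(1), pseudocount = 1)),
            class = "normalized_matrix")
}

manual_labeling <- function(labels, condition = "unwounded") {
  structure(list(labels = labels, condition = condition, params = list()),
            class = "cluster_labeling")
}

# small default-structure config for end-to-end tests
small_default_config <- function(seed, n_unwounded = 800, n_wounded = 1200) {
  default_simulation_config(
    seed = seed,
    n_cells = c(unwounded = n_unwounded, wounded = n_wounded))
}

fixture_tree_path <- function() {
  system.file("extdata", "epithelial_celltype_fixture.nwk",
              package = "limbtraj")
}

# two well-separated cell populations in normalized-expression space
two_population_matrix <- function(n_per = 100, n_genes = 30, seed = 1) {
  set.seed(seed)
  X <- matrix(abs(rnorm(2 * n_per * n_genes, 1, 0.3)), 2 * n_per, n_genes)
  X[seq_len(n_per), 1:10] <- X[seq_len(n_per), 1:10] + 3
  X[n_per + seq_len(n_per), 11:20] <- X[n_per + seq_len(n_per), 11:20] + 3
  X
}
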