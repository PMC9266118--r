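#' Construct a validated UMI count matrix
#'
#' The cells x genes raw UMI container used throughout the pipeline. Counts
#' are stored sparse; cell ids and gene symbols must be unique and match the
#' matrix dimensions; entries must be non-negative integers.
#'
#' @param counts A cells x genes matrix or sparse Matrix of non-negative
#'   integer counts.
#' @param cell_ids Character vector of unique cell barcodes (rows).
#' @param gene_symbols Character vector of unique gene symbols (columns).
#' @param condition `"unwounded"` or `"wounded"`.
#' @return A list with class `count_matrix`.
#' @export
count_matrix <- function(counts, cell_ids, gene_symbols, condition) {
  stop_if_not_condition(condition)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != length(cell_ids)) {
    stop("counts has ", nrow(counts), " rows but ", length(cell_ids),
         " cell ids")
  }
  if (ncol(counts) != length(gene_symbols)) {
    stop("counts has ", ncol(counts), " columns but ", length(gene_symbols),
         " gene symbols")
  }
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (anyDuplicated(gene_symbols)) stop("duplicate gene symbols")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x)))) {
    stop("counts must be non-negative integers")
  }
  dimnames(counts) <- list(cell_ids, gene_symbols)
  structure(list(counts = counts, cell_ids = cell_ids,
                 gene_symbols = gene_symbols, condition = condition),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d cells x %d genes, condition '%s'\n",
              length(x$cell_ids), length(x$gene_symbols), x$condition))
  invisible(x)
}

#' Read a 10x-style MTX triplet
#'
#' Reads `matrix.mtx` (genes x cells, MatrixMarket coordinate), with gene
#' symbols in `features.tsv` (first column) and barcodes in `barcodes.tsv`,
#' and returns the transposed cells x genes [count_matrix()]. Duplicate gene
#' symbols are made unique by suffixing unless `strict` is set, in which
#' case they are an error.
#'
#' @param path Directory holding the triplet.
#' @param condition `"unwounded"` or `"wounded"`.
#' @param strict Error on duplicated gene symbols instead of de-duplicating.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, condition, strict = FALSE) {
  stop_if_not_condition(condition)
  files <- file.path(path, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(basename(missing), collapse = ", "))
  }
  m <- Matrix::readMM(files[1])
  feats <- read.delim(files[2], header = FALSE,
                      stringsAsFactors = FALSE)[, 1]
  bcs <- readLines(files[3])
  if (nrow(m) != length(feats)) {
    stop("matrix has ", nrow(m), " genes but features.tsv lists ",
         length(feats))
  }
  if (ncol(m) != length(bcs)) {
    stop("matrix has ", ncol(m), " cells but barcodes.tsv lists ",
         length(bcs))
  }
  if (length(bcs) == 0) stop("no cells in ", path)
  if (anyDuplicated(feats)) {
    if (strict) stop("duplicate gene symbols in features.tsv")
    feats <- make.unique(feats, sep = ".")
  }
  count_matrix(Matrix::t(m), bcs, feats, condition)
}

#' Three-criterion cell quality control
#'
#' Excludes cells with low total UMI counts, low detected genes, or a high
#' fraction of counts on the apoptotic gene panel. Genes from the panel
#' that are absent from the matrix contribute zero. Cells are kept in their
#' original order; applying the filter twice with the same thresholds is a
#' no-op.
#'
#' @param m A [count_matrix()].
#' @param min_counts Minimum UMI total per cell.
#' @param min_genes Minimum number of genes with non-zero counts.
#' @param apoptotic_panel Character vector of apoptotic gene symbols.
#' @param max_apoptotic Maximum tolerated apoptotic-panel count fraction.
#' @return A list with `matrix` (the filtered [count_matrix()]) and
#'   `report`, a data.frame over all input cells with columns `cell_id`,
#'   `total_counts`, `detected_genes`, `apoptotic_fraction`, `pass`, plus
#'   the thresholds as attributes.
#' @export
qc_filter <- function(m, min_counts = 500, min_genes = 200,
                      apoptotic_panel = character(), max_apoptotic = 0.10) {
  stopifnot(inherits(m, "count_matrix"),
            min_counts >= 0, min_genes >= 0, max_apoptotic >= 0)
  total <- Matrix::rowSums(m$counts)
  detected <- Matrix::rowSums(m$counts > 0)
  in_panel <- m$gene_symbols %in% apoptotic_panel
  apo <- if (any(in_panel)) {
    Matrix::rowSums(m$counts[, in_panel, drop = FALSE])
  } else rep(0, length(total))
  apo_frac <- ifelse(total > 0, apo / total, 0)
  pass <- total >= min_counts & detected >= min_genes &
    apo_frac <= max_apoptotic
  report <- data.frame(cell_id = m$cell_ids, total_counts = total,
                       detected_genes = detected,
                       apoptotic_fraction = apo_frac, pass = pass,
                       row.names = NULL)
  attr(report, "thresholds") <- list(min_counts = min_counts,
                                     min_genes = min_genes,
                                     max_apoptotic = max_apoptotic)
  if (!any(pass)) stop("empty after QC: no cell passes the thresholds")
  filtered <- count_matrix(m$counts[pass, , drop = FALSE],
                           m$cell_ids[pass], m$gene_symbols, m$condition)
  list(matrix = filtered, report = report)
}

#' Drop genes detected in too few cells
#'
#' Noise-reduction step before clustering: genes with non-zero counts in
#' fewer than `min_cells` cells are removed. Set `min_cells = 0` to keep
#' everything.
#'
#' @param m A [count_matrix()].
#' @param min_cells Minimum number of cells a gene must be detected in.
#' @return A [count_matrix()] with the retained genes.
#' @export
filter_genes <- function(m, min_cells = 3) {
  stopifnot(inherits(m, "count_matrix"))
  keep <- Matrix::colSums(m$counts > 0) >= min_cells
  if (!any(keep)) stop("no gene detected in at least ", min_cells, " cells")
  count_matrix(m$counts[, keep, drop = FALSE], m$cell_ids,
               m$gene_symbols[keep], m$condition)
}

#' Library-size normalization with log transform
#'
#' Computes `expr[c, g] = log((scale * counts[c, g] / total[c] + pseudocount)
#' / pseudocount)` in natural log, which for the default `pseudocount = 1`
#' is the familiar log1p of counts-per-`scale`. Zero counts map exactly to
#' zero and the transform is strictly monotone within each cell, so
#' doubling every count of a cell leaves its normalized row unchanged.
#'
#' @param m A [count_matrix()] whose cells all have positive totals.
#' @param scale Library-size scale factor (default 10^4).
#' @param pseudocount Positive pseudocount (default 1).
#' @return A list with class `normalized_matrix`: `expr` (sparse cells x
#'   genes), `cell_ids`, `gene_symbols`, `condition`, and `meta` recording
#'   scale, log base and pseudocount.
#' @export
normalize_counts <- function(m, scale = 1e4, pseudocount = 1) {
  stopifnot(inherits(m, "count_matrix"), scale > 0, pseudocount > 0)
  total <- Matrix::rowSums(m$counts)
  if (any(total == 0)) {
    stop(sum(total == 0), " cell(s) with zero total counts; run qc_filter first")
  }
  expr <- m$counts
  row_of_x <- expr@i + 1L  # dgCMatrix @i: 0-based row index per nonzero
  expr@x <- log((scale * expr@x / total[row_of_x] + pseudocount) / pseudocount)
  structure(list(expr = expr, cell_ids = m$cell_ids,
                 gene_symbols = m$gene_symbols, condition = m$condition,
                 meta = list(scale = scale, log_base = exp(1),
                             pseudocount = pseudocount)),
            class = "normalized_matrix")
}
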