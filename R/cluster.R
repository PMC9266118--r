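#' Select highly variable genes by dispersion of log expression
#'
#' Genes are scored by the dispersion of their normalized log expression
#' (variance over mean, computed on the log scale). On log-transformed
#' data this statistic is flat in expression level for pure sampling
#' noise but large for genes that are bimodal across cell populations,
#' so the top `n` genes capture the cluster structure rather than highly
#' expressed housekeeping noise.
#'
#' @param nm A `normalized_matrix`.
#' @param n Number of genes to keep.
#' @return Character vector of gene symbols.
#' @export
variable_genes <- function(nm, n = 500) {
  stopifnot(inherits(nm, "normalized_matrix"))
  mu <- Matrix::colMeans(nm$expr)
  ex2 <- Matrix::colMeans(nm$expr^2)
  v <- pmax(ex2 - mu^2, 0) * nrow(nm$expr) / max(1, nrow(nm$expr) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  keep <- which(mu > 0)
  if (length(keep) <= n) return(nm$gene_symbols[keep])
  nm$gene_symbols[keep][order(disp[keep], decreasing = TRUE)[seq_len(n)]]
}

# PCA embedding on scaled variable genes
pca_embedding <- function(nm, genes, n_pcs) {
  X <- as.matrix(nm$expr[, genes, drop = FALSE])
  X <- scale(X)
  X[is.na(X)] <- 0
  X[X > 10] <- 10
  if (all(abs(X) < 1e-12)) stop("degenerate constant matrix, cannot cluster")
  n_pcs <- min(n_pcs, ncol(X), nrow(X) - 1)
  pr <- prcomp(X, center = FALSE, scale. = FALSE, rank. = n_pcs)
  pr$x[, seq_len(n_pcs), drop = FALSE]
}

# k nearest neighbours (excluding self) by blocked Euclidean search
knn_indices <- function(emb, k) {
  n <- nrow(emb)
  k <- min(k, n - 1)
  sq <- rowSums(emb^2)
  out <- matrix(0L, n, k)
  block <- 1024L
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(emb[idx, , drop = FALSE], emb)
    d2[cbind(seq_along(idx), idx)] <- Inf
    out[idx, ] <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  }
  out
}

# shared-nearest-neighbour graph with Jaccard weights, pruned
snn_graph <- function(nn, prune = 1 / 15) {
  n <- nrow(nn)
  k <- ncol(nn)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k + 1),
                            j = c(as.vector(nn), seq_len(n)),
                            x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  jac <- shared
  jac@x <- jac@x / (2 * (k + 1) - jac@x)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  igraph::graph_from_adjacency_matrix(Matrix::drop0(jac),
                                      mode = "undirected", weighted = TRUE)
}

#' Cluster cells on a PCA embedding
#'
#' Default method: shared-nearest-neighbour graph (k = 20, Jaccard weights
#' pruned below 1/15) on the top-`n_pcs` principal components of the scaled
#' variable genes, partitioned by Louvain community detection at the given
#' resolution. The number of clusters is emergent, never supplied. A
#' k-means alternative with Calinski-Harabasz model selection over k is
#' available via `method = "kmeans"`. Deterministic for a fixed seed.
#'
#' @param nm A `normalized_matrix`.
#' @param n_pcs Number of principal components (default 10).
#' @param k_neighbors Neighbourhood size of the SNN graph.
#' @param resolution Louvain resolution parameter.
#' @param n_variable_genes Number of variable genes entering PCA.
#' @param method `"graph"` (default) or `"kmeans"`.
#' @param k_range Candidate k values for the k-means fallback.
#' @param seed Integer seed.
#' @return A list with class `cluster_labeling`: `labels` (named character,
#'   cell id to cluster id), `condition`, `params`.
#' @export
cluster_cells <- function(nm, n_pcs = 10, k_neighbors = 20, resolution = 1,
                          n_variable_genes = 500,
                          method = c("graph", "kmeans"),
                          k_range = 2:20, seed = 42L) {
  stopifnot(inherits(nm, "normalized_matrix"))
  method <- match.arg(method)
  n <- nrow(nm$expr)
  if (n < 2) stop("need at least 2 cells to cluster")
  if (n_pcs > min(n, ncol(nm$expr)) - 1) {
    stop("n_pcs = ", n_pcs, " too large for a ", n, " x ",
         ncol(nm$expr), " matrix")
  }
  vg <- variable_genes(nm, n_variable_genes)
  emb <- pca_embedding(nm, vg, n_pcs)
  if (all(abs(emb) < 1e-12)) stop("degenerate constant matrix, cannot cluster")
  set.seed(seed)
  if (method == "graph") {
    g <- snn_graph(knn_indices(emb, k_neighbors))
    member <- igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
  } else {
    best <- NULL
    best_ch <- -Inf
    tot <- sum(scale(emb, scale = FALSE)^2)
    for (k in k_range[k_range < n]) {
      km <- kmeans(emb, centers = k, nstart = 10, iter.max = 50)
      ch <- ((tot - km$tot.withinss) / (k - 1)) /
        (km$tot.withinss / (n - k))
      if (ch > best_ch) {
        best_ch <- ch
        best <- km$cluster
      }
    }
    member <- best
  }
  sizes <- sort(table(member), decreasing = TRUE)
  prefix <- if (nm$condition == "unwounded") "U" else "W"
  new_names <- setNames(paste0(prefix, seq_along(sizes)), names(sizes))
  labels <- setNames(new_names[as.character(member)], nm$cell_ids)
  structure(list(labels = labels, condition = nm$condition,
                 params = list(n_pcs = n_pcs, k_neighbors = k_neighbors,
                               resolution = resolution,
                               n_variable_genes = n_variable_genes,
                               method = method, seed = seed)),
            class = "cluster_labeling")
}

#' Summarize clusters as expression profiles
#'
#' For each cluster: the cell count, the arithmetic mean of normalized
#' (log) expression per gene, and the mean of the de-logged normalized
#' expression (counts per scale factor) used for differentiation scoring,
#' which is the scale average-expression convention matches.
#'
#' @param nm A `normalized_matrix`.
#' @param labeling A `cluster_labeling` covering the cells of `nm`.
#' @return A list with class `cluster_profiles`: `cluster_id`, `condition`
#'   (per cluster), `n_cells` (named), `mean_expr` and `mean_linear`
#'   (clusters x genes matrices, rows named `<cluster>|<condition>`), and
#'   `gene_symbols`.
#' @export
profile_clusters <- function(nm, labeling) {
  stopifnot(inherits(nm, "normalized_matrix"),
            inherits(labeling, "cluster_labeling"))
  lab <- labeling$labels[nm$cell_ids]
  if (any(is.na(lab))) stop("labeling does not cover all cells")
  ids <- sort(unique(lab))
  mean_expr <- matrix(0, length(ids), ncol(nm$expr),
                      dimnames = list(NULL, nm$gene_symbols))
  mean_linear <- mean_expr
  n_cells <- integer(length(ids))
  for (i in seq_along(ids)) {
    rows <- which(lab == ids[i])
    n_cells[i] <- length(rows)
    sub <- nm$expr[rows, , drop = FALSE]
    mean_expr[i, ] <- Matrix::colMeans(sub)
    sub@x <- expm1(sub@x) * nm$meta$pseudocount
    mean_linear[i, ] <- Matrix::colMeans(sub)
  }
  key <- paste(ids, labeling$condition, sep = "|")
  rownames(mean_expr) <- key
  rownames(mean_linear) <- key
  structure(list(cluster_id = ids,
                 condition = rep(labeling$condition, length(ids)),
                 n_cells = setNames(n_cells, key),
                 mean_expr = mean_expr, mean_linear = mean_linear,
                 gene_symbols = nm$gene_symbols),
            class = "cluster_profiles")
}

#' Combine cluster profiles from several conditions
#'
#' @param ... `cluster_profiles` objects over the same gene universe.
#' @return A single `cluster_profiles` object.
#' @export
combine_profiles <- function(...) {
  ps <- list(...)
  stopifnot(all(vapply(ps, inherits, NA, "cluster_profiles")))
  g <- ps[[1]]$gene_symbols
  for (p in ps) {
    if (!identical(p$gene_symbols, g)) stop("gene universes differ")
  }
  structure(list(cluster_id = unlist(lapply(ps, `[[`, "cluster_id")),
                 condition = unlist(lapply(ps, `[[`, "condition")),
                 n_cells = do.call(c, lapply(ps, `[[`, "n_cells")),
                 mean_expr = do.call(rbind, lapply(ps, `[[`, "mean_expr")),
                 mean_linear = do.call(rbind, lapply(ps, `[[`, "mean_linear")),
                 gene_symbols = g),
            class = "cluster_profiles")
}

# exact rank-sum tie term per gene: sum(t^3 - t) over tied groups
tie_terms <- function(X) {
  apply(X, 2, function(x) {
    t <- table(x)
    t <- t[t > 1]
    sum(t^3 - t)
  })
}

#' One-vs-rest characteristic markers per cluster
#'
#' For every cluster, each gene is tested cluster-vs-rest with a Wilcoxon
#' rank-sum test (normal approximation with tie and continuity correction),
#' Benjamini-Hochberg adjusted across genes within the cluster. Genes with
#' adjusted p <= `alpha` and natural-log fold change >= `min_lfc` are
#' reported, ranked by fold change descending with ties broken by adjusted
#' p-value and then gene symbol.
#'
#' @param nm A `normalized_matrix`.
#' @param labeling A `cluster_labeling` with at least two clusters.
#' @param min_lfc Minimum natural-log fold change (difference of mean log
#'   expression).
#' @param alpha Benjamini-Hochberg adjusted p-value cut-off.
#' @return A data.frame with columns `cluster_id`, `gene`,
#'   `log_fold_change`, `statistic` (z), `p_value`, `adj_p_value`, `rank`.
#' @export
find_markers <- function(nm, labeling, min_lfc = 0.25, alpha = 0.05) {
  stopifnot(inherits(nm, "normalized_matrix"),
            inherits(labeling, "cluster_labeling"))
  lab <- labeling$labels[nm$cell_ids]
  ids <- sort(unique(lab))
  if (length(ids) < 2) stop("markers undefined for a single cluster")
  X <- as.matrix(nm$expr)
  n <- nrow(X)
  R <- apply(X, 2, rank)
  ties <- tie_terms(X)
  out <- vector("list", length(ids))
  for (ci in seq_along(ids)) {
    in_cl <- lab == ids[ci]
    n1 <- sum(in_cl)
    n2 <- n - n1
    rank_sum <- colSums(R[in_cl, , drop = FALSE])
    W <- rank_sum - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - ties / (n * (n - 1))))
    z <- (W - mu - sign(W - mu) * 0.5) / pmax(sigma, .Machine$double.eps)
    p <- 2 * pnorm(-abs(z))
    p <- pmin(p, 1)
    adj <- p.adjust(p, method = "BH")
    lfc <- colMeans(X[in_cl, , drop = FALSE]) -
      colMeans(X[!in_cl, , drop = FALSE])
    keep <- which(adj <= alpha & lfc >= min_lfc)
    if (!length(keep)) next
    df <- data.frame(cluster_id = ids[ci], gene = nm$gene_symbols[keep],
                     log_fold_change = lfc[keep], statistic = z[keep],
                     p_value = p[keep], adj_p_value = adj[keep],
                     row.names = NULL)
    ord <- order(-df$log_fold_change, df$adj_p_value, df$gene)
    df <- df[ord, ]
    df$rank <- seq_len(nrow(df))
    out[[ci]] <- df
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(cluster_id = character(), gene = character(),
                      log_fold_change = numeric(), statistic = numeric(),
                      p_value = numeric(), adj_p_value = numeric(),
                      rank = integer())
  }
  rownames(res) <- NULL
  res
}
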