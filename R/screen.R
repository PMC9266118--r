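#' Define the maturation-stage grouping
#'
#' Orders unwounded epithelial clusters along the stem-to-progenitor axis:
#' putative LSC clusters (low), putative LPC clusters (medium) and the
#' putative differentiating-LPC clusters (high). Only unwounded clusters
#' are eligible: expression during wound healing may be transient and
#' stage-specific, so it cannot serve as a homeostatic maturation marker.
#'
#' @param lsc,lpc,differentiating_lpc Character vectors of unwounded
#'   cluster ids, pairwise disjoint and non-empty.
#' @return A named list with class `stage_grouping`.
#' @export
stage_grouping <- function(lsc, lpc, differentiating_lpc) {
  stages <- list(lsc = lsc, lpc = lpc,
                 differentiating_lpc = differentiating_lpc)
  if (any(lengths(stages) == 0)) stop("every stage needs at least one cluster")
  all_ids <- unlist(stages)
  if (anyDuplicated(all_ids)) stop("stages must be disjoint")
  structure(stages, class = "stage_grouping")
}

#' Screen for monotone maturation markers
#'
#' A gene is a maturation-marker candidate when its expression is low in
#' the putative LSCs, medium in the putative LPCs and high in the
#' differentiating LPCs: each stage mean (cell-count-weighted across the
#' stage's clusters, pseudocount added) must exceed the previous stage's
#' by at least `min_ratio`. Passing genes are ranked by fold difference
#' between the trajectory endpoints, `(mean_high + pc) / (mean_low + pc)`,
#' descending with ties broken by gene symbol, and the top `top_n` are
#' selected.
#'
#' @param profiles A `cluster_profiles` object containing the unwounded
#'   stage clusters.
#' @param grouping A [stage_grouping()].
#' @param top_n Number of markers to select (default 10).
#' @param min_ratio Minimum per-step fold increase (default 2).
#' @param pseudocount Pseudocount added to every stage mean (default 0.01).
#' @param weighted Weight clusters by cell count within a stage (default);
#'   `FALSE` averages clusters equally.
#' @return A data.frame of the passing genes: `gene`, `mean_lsc`,
#'   `mean_lpc`, `mean_diff_lpc`, `fold_difference`, `rank`, `selected`.
#' @export
screen_maturation_markers <- function(profiles, grouping, top_n = 10,
                                      min_ratio = 2, pseudocount = 0.01,
                                      weighted = TRUE) {
  stopifnot(inherits(profiles, "cluster_profiles"),
            inherits(grouping, "stage_grouping"), top_n >= 1)
  stage_means <- lapply(grouping, function(ids) {
    keys <- paste(ids, "unwounded", sep = "|")
    missing <- keys[!keys %in% rownames(profiles$mean_linear)]
    if (length(missing)) {
      stop("stage cluster(s) not in profiles: ",
           paste(missing, collapse = ", "))
    }
    w <- if (weighted) profiles$n_cells[keys] else rep(1, length(keys))
    colSums(profiles$mean_linear[keys, , drop = FALSE] * w) / sum(w)
  })
  m1 <- stage_means$lsc + pseudocount
  m2 <- stage_means$lpc + pseudocount
  m3 <- stage_means$differentiating_lpc + pseudocount
  pass <- m2 >= min_ratio * m1 & m3 >= min_ratio * m2
  genes <- profiles$gene_symbols[pass]
  if (!length(genes)) {
    return(data.frame(gene = character(), mean_lsc = numeric(),
                      mean_lpc = numeric(), mean_diff_lpc = numeric(),
                      fold_difference = numeric(), rank = integer(),
                      selected = logical()))
  }
  fold <- (m3[pass]) / (m1[pass])
  ord <- order(-fold, genes)
  res <- data.frame(gene = genes[ord],
                    mean_lsc = unname(stage_means$lsc[pass][ord]),
                    mean_lpc = unname(stage_means$lpc[pass][ord]),
                    mean_diff_lpc = unname(stage_means$differentiating_lpc[pass][ord]),
                    fold_difference = unname(fold[ord]),
                    rank = seq_along(genes), row.names = NULL)
  if (top_n > nrow(res)) {
    warning("top_n = ", top_n, " exceeds the ", nrow(res),
            " passing genes; selecting all")
  }
  res$selected <- res$rank <= top_n
  res
}
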