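leaf_condition <- function(labels) sub("^.*\\|", "", labels)
leaf_cluster <- function(labels) sub("\\|.*$", "", labels)

#' Build the joint dendrogram over cluster profiles from both conditions
#'
#' Agglomerative hierarchical clustering of cluster mean-expression
#' profiles, by default with 1 - Pearson correlation distance over the
#' given gene subset and average (UPGMA) linkage, the convention of
#' centroid cluster trees in single-cell work. Profiles are ordered
#' canonically (sorted leaf labels) before clustering, so the result is
#' invariant to input order and bit-for-bit reproducible, including
#' zero-distance ties between identical profiles.
#'
#' @param profiles A `cluster_profiles` object (typically both conditions,
#'   see [combine_profiles()]).
#' @param genes Gene subset used for the distance; default all genes.
#'   Typically the union of each condition's variable genes.
#' @param distance `"correlation"` (1 - Pearson) or `"euclidean"`.
#' @param linkage `"average"` or `"complete"`.
#' @return A list with class `joint_dendrogram`: `phylo` (ape tree with
#'   leaf labels `<cluster>|<condition>` and ultrametric branch lengths),
#'   `hclust`, and `params`.
#' @export
build_joint_dendrogram <- function(profiles, genes = NULL,
                                   distance = c("correlation", "euclidean"),
                                   linkage = c("average", "complete")) {
  stopifnot(inherits(profiles, "cluster_profiles"))
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  M <- profiles$mean_expr
  if (nrow(M) < 2) stop("need at least 2 profiles")
  if (!is.null(genes)) {
    genes <- intersect(genes, colnames(M))
    if (!length(genes)) stop("gene subset is empty on the profiles")
    M <- M[, genes, drop = FALSE]
  }
  M <- M[order(rownames(M)), , drop = FALSE]
  d <- if (distance == "correlation") {
    as.dist(1 - cor(t(M)))
  } else {
    dist(M)
  }
  hc <- hclust(d, method = if (linkage == "average") "average" else "complete")
  phy <- ape::as.phylo(hc)
  structure(list(phylo = phy, hclust = hc,
                 params = list(distance = distance, linkage = linkage,
                               genes = colnames(M))),
            class = "joint_dendrogram")
}

#' Read / write a dendrogram in Newick format
#'
#' Leaf labels follow the `<cluster>|<condition>` convention; branch
#' lengths carry the ultrametric merge-height deltas.
#'
#' @param d A `joint_dendrogram` (or any object with a `$phylo`).
#' @param path File path.
#' @return `read_dendrogram` returns a `joint_dendrogram`;
#'   `write_dendrogram` returns `path` invisibly.
#' @export
write_dendrogram <- function(d, path) {
  phy <- if (inherits(d, "phylo")) d else d$phylo
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' @rdname write_dendrogram
#' @export
read_dendrogram <- function(path) {
  phy <- ape::read.tree(path)
  structure(list(phylo = phy, hclust = NULL, params = list()),
            class = "joint_dendrogram")
}

#' Extract the cherries of a dendrogram
#'
#' A cherry is an internal node whose two children are both leaves - the
#' "smallest unit" of branches. Cherries are the basis of the
#' cross-condition pairing rule in [assign_cell_types()].
#'
#' @param d A `joint_dendrogram` or `phylo`.
#' @return A list of character vectors of length 2 (sorted leaf labels),
#'   one per cherry.
#' @export
extract_cherries <- function(d) {
  phy <- if (inherits(d, "phylo")) d else d$phylo
  ntip <- length(phy$tip.label)
  if (ntip == 2) return(list(sort(phy$tip.label)))
  cherries <- list()
  internal <- unique(phy$edge[, 1])
  for (node in internal) {
    children <- phy$edge[phy$edge[, 1] == node, 2]
    if (length(children) == 2 && all(children <= ntip)) {
      cherries[[length(cherries) + 1]] <- sort(phy$tip.label[children])
    }
  }
  cherries[order(vapply(cherries, `[`, "", 1))]
}

#' Pair clusters across conditions into cell types
#'
#' Applies the cherry-pairing rule: two clusters joined directly by a
#' bracket without further branches, one from each condition, are the same
#' cell type observed under homeostasis and under wounding; it is recorded
#' once with presence class `shared`. Every other epithelial leaf -
#' including both members of a same-condition cherry, since the rule
#' requires opposite conditions - becomes its own condition-specific cell
#' type. The count identity `#types = #epithelial leaves -
#' #cross-condition cherries` always holds.
#'
#' @param d A `joint_dendrogram` or `phylo`.
#' @param epithelial_leaves Character vector of epithelial leaf labels
#'   (`<cluster>|<condition>`); must be a subset of the tree's leaves.
#' @param branches Optional named character (leaf label -> branch id) from
#'   [extract_branches()], attached to the output.
#' @return A data.frame with class `cell_types`: columns `name`,
#'   `presence` (`shared`, `unwounded_only`, `wounded_only`),
#'   `member_unwounded`, `member_wounded` (cluster ids, NA when absent),
#'   `branch`.
#' @export
assign_cell_types <- function(d, epithelial_leaves, branches = NULL) {
  phy <- if (inherits(d, "phylo")) d else d$phylo
  if (!all(epithelial_leaves %in% phy$tip.label)) {
    stop("epithelial_leaves must be leaves of the dendrogram")
  }
  cherries <- extract_cherries(d)
  used <- character()
  rows <- list()
  for (ch in cherries) {
    if (!all(ch %in% epithelial_leaves)) next
    conds <- leaf_condition(ch)
    if (length(unique(conds)) != 2) next  # the rule requires opposite conditions
    u <- ch[conds == "unwounded"]
    w <- ch[conds == "wounded"]
    rows[[length(rows) + 1]] <- data.frame(
      name = paste(leaf_cluster(u), leaf_cluster(w), sep = "+"),
      presence = "shared", member_unwounded = leaf_cluster(u),
      member_wounded = leaf_cluster(w),
      branch = if (!is.null(branches)) branches[[u]] else NA_character_)
    used <- c(used, ch)
  }
  singles <- setdiff(epithelial_leaves, used)
  for (lf in sort(singles)) {
    cond <- leaf_condition(lf)
    rows[[length(rows) + 1]] <- data.frame(
      name = leaf_cluster(lf),
      presence = if (cond == "unwounded") "unwounded_only" else "wounded_only",
      member_unwounded = if (cond == "unwounded") leaf_cluster(lf) else NA,
      member_wounded = if (cond == "wounded") leaf_cluster(lf) else NA,
      branch = if (!is.null(branches)) branches[[lf]] else NA_character_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cell_types", class(out))
  out
}

#' Cut the epithelial subtree into trajectory branches
#'
#' Restricts the dendrogram to the subtree spanned by the epithelial
#' leaves and cuts it at its k-1 highest internal merge heights, yielding
#' k connected leaf groups. k is an explicit parameter (the study
#' identifies branches visually), never inferred.
#'
#' @param d A `joint_dendrogram` or `phylo` with ultrametric branch
#'   lengths.
#' @param epithelial_leaves Leaf labels to retain.
#' @param k Number of branches (default 3).
#' @return Named character vector, leaf label -> branch id (`"B1"`..`"Bk"`,
#'   numbered in order of each branch's alphabetically first leaf).
#' @export
extract_branches <- function(d, epithelial_leaves, k = 3) {
  phy <- if (inherits(d, "phylo")) d else d$phylo
  if (!all(epithelial_leaves %in% phy$tip.label)) {
    stop("epithelial_leaves must be leaves of the dendrogram")
  }
  if (k < 1 || k > length(epithelial_leaves)) {
    stop("k must be between 1 and the number of epithelial leaves")
  }
  if (length(epithelial_leaves) == 1) {
    return(setNames("B1", epithelial_leaves))
  }
  sub <- ape::keep.tip(phy, epithelial_leaves)
  # an ultrametric tree is reproduced exactly by UPGMA on its cophenetic
  # distances, whose merge heights are the restricted tree's node heights
  dmat <- ape::cophenetic.phylo(sub)
  ord <- order(rownames(dmat))
  dmat <- dmat[ord, ord]
  hc <- hclust(as.dist(dmat), method = "average")
  grp <- cutree(hc, k = k)
  first_leaf <- vapply(split(names(grp), grp),
                       function(x) sort(x)[1], "")
  relabel <- setNames(paste0("B", order(order(first_leaf))),
                      names(first_leaf))
  setNames(unname(relabel[as.character(grp)]), names(grp))
}
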