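#' Segregate epithelial from non-epithelial clusters
#'
#' A cluster is epithelial when any cytokeratin-panel gene reaches the
#' threshold in mean normalized expression (linear scale): a single
#' strongly expressed cytokeratin suffices, matching how epithelial
#' identity is read in practice.
#'
#' @param profiles A `cluster_profiles` object.
#' @param panels A [marker_panels()] list.
#' @param threshold Mean-expression threshold (default 1 normalized unit).
#' @return Named logical vector over profile keys (`<cluster>|<condition>`).
#' @export
segregate_epithelial <- function(profiles, panels = marker_panels(),
                                 threshold = 1) {
  stopifnot(inherits(profiles, "cluster_profiles"))
  genes <- intersect(panels$epithelial, colnames(profiles$mean_linear))
  if (!length(genes)) {
    return(setNames(rep(FALSE, nrow(profiles$mean_linear)),
                    rownames(profiles$mean_linear)))
  }
  vals <- profiles$mean_linear[, genes, drop = FALSE]
  setNames(apply(vals, 1, max) >= threshold, rownames(profiles$mean_linear))
}

# per-gene z-scores of mean log expression across all profiles
profile_zscores <- function(profiles) {
  M <- profiles$mean_expr
  mu <- colMeans(M)
  s <- apply(M, 2, sd)
  Z <- sweep(M, 2, mu)
  Z <- sweep(Z, 2, ifelse(s > 0, s, 1), "/")
  Z[, s == 0] <- 0  # zero-variance genes carry no evidence
  Z
}

#' Type the non-epithelial clusters
#'
#' Assigns each non-epithelial cluster the lineage whose marker panel has
#' the highest mean z-score (genes z-scored across all profiles);
#' `unresolved` when the best panel does not beat the runner-up by the
#' margin.
#'
#' @param profiles A `cluster_profiles` object (all profiles, used for the
#'   z-scoring).
#' @param keys Profile keys to type (default all).
#' @param panels A [marker_panels()] list.
#' @param margin Minimum z-score lead of the winning panel.
#' @return Named character vector (`stromal`, `t_cell`, `macrophage`,
#'   `unresolved`) over `keys`.
#' @export
type_non_epithelial <- function(profiles, keys = NULL,
                                panels = marker_panels(), margin = 0.25) {
  stopifnot(inherits(profiles, "cluster_profiles"))
  Z <- profile_zscores(profiles)
  if (is.null(keys)) keys <- rownames(Z)
  cats <- c("stromal", "t_cell", "macrophage")
  scores <- vapply(cats, function(cat) {
    genes <- intersect(panels[[cat]], colnames(Z))
    if (!length(genes)) return(setNames(rep(0, length(keys)), keys))
    rowMeans(Z[keys, genes, drop = FALSE])
  }, numeric(length(keys)))
  if (length(keys) == 1) scores <- matrix(scores, nrow = 1,
                                          dimnames = list(keys, cats))
  apply(scores, 1, function(s) {
    ord <- order(s, decreasing = TRUE)
    if (s[ord[1]] - s[ord[2]] < margin) "unresolved" else cats[ord[1]]
  })
}

#' Corneal differentiation score from mean Krt12 expression
#'
#' The printed segregation ranges are <0.9 (score 1, least differentiated),
#' 5.5-20 (score 2) and >180 (score 3). Values in the empty gaps between
#' ranges are assigned to the nearest range on the multiplicative scale
#' (geometric-midpoint cut points at sqrt(0.9*5.5) ~ 2.22 and
#' sqrt(20*180) = 60); `gap_mode = "strict"` errors on gap values instead.
#'
#' @param krt12_mean Non-negative finite numeric vector of mean normalized
#'   Krt12 expression.
#' @param gap_mode `"midpoint"` (default) or `"strict"`.
#' @return Integer scores in 1:3.
#' @examples
#' corneal_diff_score(c(0, 10, 200))
#' @export
corneal_diff_score <- function(krt12_mean, gap_mode = c("midpoint", "strict")) {
  gap_mode <- match.arg(gap_mode)
  if (any(!is.finite(krt12_mean)) || any(krt12_mean < 0)) {
    stop("krt12_mean must be finite and non-negative")
  }
  if (gap_mode == "strict") {
    in_gap <- (krt12_mean >= 0.9 & krt12_mean < 5.5) |
      (krt12_mean > 20 & krt12_mean <= 180)
    if (any(in_gap)) {
      stop("value(s) in the empty gap between printed ranges: ",
           paste(krt12_mean[in_gap], collapse = ", "))
    }
  }
  findInterval(krt12_mean, c(sqrt(0.9 * 5.5), sqrt(20 * 180))) + 1L
}

#' Conjunctival differentiation score from mean Krt13 expression
#'
#' Printed ranges: <0.8 (score 1, undifferentiated) and >9 (score 2); the
#' gap cut point is the geometric midpoint sqrt(0.8*9) ~ 2.68.
#'
#' @param krt13_mean Non-negative finite numeric vector.
#' @param gap_mode `"midpoint"` (default) or `"strict"`.
#' @return Integer scores in 1:2.
#' @examples
#' conjunctival_diff_score(c(0.1, 15))
#' @export
conjunctival_diff_score <- function(krt13_mean,
                                    gap_mode = c("midpoint", "strict")) {
  gap_mode <- match.arg(gap_mode)
  if (any(!is.finite(krt13_mean)) || any(krt13_mean < 0)) {
    stop("krt13_mean must be finite and non-negative")
  }
  if (gap_mode == "strict") {
    in_gap <- krt13_mean >= 0.8 & krt13_mean <= 9
    if (any(in_gap)) {
      stop("value(s) in the empty gap between printed ranges: ",
           paste(krt13_mean[in_gap], collapse = ", "))
    }
  }
  findInterval(krt13_mean, sqrt(0.8 * 9)) + 1L
}

#' Cell-type shares of the epithelial label-retaining cells
#'
#' For each cell type and condition, its member cluster's cell count over
#' the total cells of all epithelial clusters in that condition
#' (non-epithelial cells are excluded from the denominator). Fractions sum
#' to 1 per condition.
#'
#' @param profiles A `cluster_profiles` object.
#' @param epithelial Named logical over profile keys from
#'   [segregate_epithelial()].
#' @param cell_types A `cell_types` data.frame from [assign_cell_types()].
#' @return A data.frame `name`, `condition`, `fraction`.
#' @export
epithelial_percentages <- function(profiles, epithelial, cell_types) {
  stopifnot(inherits(profiles, "cluster_profiles"))
  epi_keys <- names(epithelial)[epithelial]
  out <- list()
  for (cond in unique(profiles$condition)) {
    keys_c <- epi_keys[leaf_condition(epi_keys) == cond]
    denom <- sum(profiles$n_cells[keys_c])
    if (denom == 0) stop("no epithelial cells in condition '", cond, "'")
    member_col <- paste0("member_", cond)
    for (i in seq_len(nrow(cell_types))) {
      cl <- cell_types[[member_col]][i]
      if (is.na(cl)) next
      key <- paste(cl, cond, sep = "|")
      out[[length(out) + 1]] <- data.frame(
        name = cell_types$name[i], condition = cond,
        fraction = unname(profiles$n_cells[key]) / denom)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag proliferative clusters
#'
#' A cluster is proliferative when the mean z-score of the proliferation
#' panel (Mki67 plus the MCM family, z-scored per gene across profiles)
#' reaches the threshold. Zero-variance genes contribute z = 0.
#'
#' @param profiles A `cluster_profiles` object with at least 3 profiles.
#' @param panels A [marker_panels()] list.
#' @param z_threshold Mean panel z-score threshold (default 2).
#' @return Named logical over profile keys.
#' @export
flag_proliferative <- function(profiles, panels = marker_panels(),
                               z_threshold = 2) {
  stopifnot(inherits(profiles, "cluster_profiles"))
  if (nrow(profiles$mean_expr) < 3) {
    stop("need at least 3 profiles to z-score the proliferation panel")
  }
  Z <- profile_zscores(profiles)
  genes <- intersect(panels$proliferation, colnames(Z))
  if (!length(genes)) {
    return(setNames(rep(FALSE, nrow(Z)), rownames(Z)))
  }
  setNames(rowMeans(Z[, genes, drop = FALSE]) >= z_threshold, rownames(Z))
}

# cell-count-weighted mean of mean_linear over a type's member clusters
type_linear_mean <- function(profiles, cell_types, gene_set) {
  genes <- intersect(gene_set, colnames(profiles$mean_linear))
  vapply(seq_len(nrow(cell_types)), function(i) {
    keys <- c(if (!is.na(cell_types$member_unwounded[i]))
                paste(cell_types$member_unwounded[i], "unwounded", sep = "|"),
              if (!is.na(cell_types$member_wounded[i]))
                paste(cell_types$member_wounded[i], "wounded", sep = "|"))
    if (!length(genes)) return(0)
    w <- profiles$n_cells[keys]
    vals <- rowMeans(profiles$mean_linear[keys, genes, drop = FALSE])
    sum(vals * w) / sum(w)
  }, 0)
}

#' Designate epithelial cell types
#'
#' Applies the designation logic of the atlas: a branch of the dendrogram
#' shows a differentiation trajectory when it holds at least one shared,
#' least-differentiated cell type (corneal score 1) and at least one
#' partially differentiated one (corneal score >= 2). Within trajectory
#' branches, shared undifferentiated types (corneal and conjunctival score
#' 1) with a progenitor-panel mean at or above the median of the
#' undifferentiated cohort are putative limbal stem cells; an LSC whose share of epithelial
#' label-retaining cells drops by at least `delta` (relative) upon wounding
#' is a putative active LSC, otherwise a putative quiescent LSC. Partially
#' differentiated types in trajectory branches are putative LPCs. Outside
#' trajectory branches, conjunctival-score-2 types are putative
#' conjunctival progenitors (CjPC), remaining corneal-score-2/3 types are
#' putative differentiating LPCs, and undifferentiated types with
#' intermediate progenitor expression are stem/progenitor cells of unknown
#' origin. The proliferative flag is attached independently.
#'
#' @param cell_types A `cell_types` data.frame with branch assignments.
#' @param profiles A `cluster_profiles` object over both conditions.
#' @param epithelial Named logical from [segregate_epithelial()].
#' @param panels A [marker_panels()] list.
#' @param delta Relative decrease in epithelial share that separates
#'   active from quiescent LSCs (default 0.25).
#' @param gap_mode Gap handling for the differentiation scores.
#' @param z_threshold Proliferation-panel z threshold.
#' @return A data.frame with class `designations`: `cell_type`, `label`,
#'   `presence`, `branch`, `corneal_score`, `conjunctival_score`,
#'   `krt12_mean`, `krt13_mean`, `progenitor_mean`, `pct_unwounded`,
#'   `pct_wounded`, `abundance_change`, `proliferative`.
#' @export
designate <- function(cell_types, profiles, epithelial,
                      panels = marker_panels(), delta = 0.25,
                      gap_mode = "midpoint", z_threshold = 2) {
  stopifnot(inherits(profiles, "cluster_profiles"))
  if (any(is.na(cell_types$branch))) {
    stop("cell_types must carry branch assignments (see extract_branches)")
  }
  n <- nrow(cell_types)
  krt12 <- type_linear_mean(profiles, cell_types, "Krt12")
  krt13 <- type_linear_mean(profiles, cell_types, "Krt13")
  prog <- type_linear_mean(profiles, cell_types, panels$progenitor)
  corneal <- corneal_diff_score(krt12, gap_mode)
  conj <- conjunctival_diff_score(krt13, gap_mode)

  pct <- epithelial_percentages(profiles, epithelial, cell_types)
  pct_u <- setNames(rep(NA_real_, n), cell_types$name)
  pct_w <- pct_u
  for (i in seq_len(nrow(pct))) {
    if (pct$condition[i] == "unwounded") pct_u[pct$name[i]] <- pct$fraction[i]
    else pct_w[pct$name[i]] <- pct$fraction[i]
  }
  change <- ifelse(!is.na(pct_u) & !is.na(pct_w) & pct_u > 0,
                   (pct_w - pct_u) / pct_u, NA_real_)

  prolif_cluster <- flag_proliferative(profiles, panels, z_threshold)
  prolif <- vapply(seq_len(n), function(i) {
    keys <- c(if (!is.na(cell_types$member_unwounded[i]))
                paste(cell_types$member_unwounded[i], "unwounded", sep = "|"),
              if (!is.na(cell_types$member_wounded[i]))
                paste(cell_types$member_wounded[i], "wounded", sep = "|"))
    any(prolif_cluster[keys])
  }, NA)

  # which branches show a differentiation trajectory
  has_traj <- vapply(unique(cell_types$branch), function(b) {
    in_b <- cell_types$branch == b
    any(in_b & cell_types$presence == "shared" & corneal == 1) &&
      any(in_b & corneal >= 2)
  }, NA)
  names(has_traj) <- unique(cell_types$branch)
  if (!any(has_traj)) {
    warning("no trajectory branch found; LSC labels withheld")
  }

  in_traj <- has_traj[cell_types$branch]
  undiff <- corneal == 1
  cohort_median <- if (any(undiff)) median(prog[undiff]) else Inf
  lsc <- in_traj & cell_types$presence == "shared" & undiff & conj == 1 &
    prog >= cohort_median

  label <- rep(NA_character_, n)
  label[lsc & !is.na(change) & change <= -delta] <- "putative_active_LSC"
  label[lsc & is.na(label)] <- "putative_quiescent_LSC"
  label[is.na(label) & in_traj & corneal == 2] <- "putative_LPC"
  label[is.na(label) & in_traj & corneal == 3] <- "putative_differentiating_LPC"
  label[is.na(label) & conj == 2] <- "putative_CjPC"
  label[is.na(label) & corneal >= 2] <- "putative_differentiating_LPC"
  label[is.na(label)] <- "unknown_origin_SPC"

  out <- data.frame(cell_type = cell_types$name, label = label,
                    presence = cell_types$presence,
                    branch = cell_types$branch,
                    corneal_score = corneal, conjunctival_score = conj,
                    krt12_mean = krt12, krt13_mean = krt13,
                    progenitor_mean = prog,
                    pct_unwounded = unname(pct_u),
                    pct_wounded = unname(pct_w),
                    abundance_change = unname(change),
                    proliferative = prolif, row.names = NULL)
  class(out) <- c("designations", class(out))
  out
}
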