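#' Describe one simulated cell cluster
#'
#' A cluster spec fixes everything the simulator needs to draw cells for one
#' cluster: its share of each condition's cells, its lineage, its position on
#' the corneal (Krt12) and conjunctival (Krt13) maturation ladders, its
#' progenitor-marker level (the Krt14/Krt15 mean), whether it expresses the
#' proliferation program, its ground-truth dendrogram branch, and which
#' cluster in the opposite condition (if any) represents the same cell type.
#'
#' @param name Cluster name, unique within the config (e.g. `"EC7"`).
#' @param proportions Named numeric, fraction of cells in each condition
#'   (`unwounded`, `wounded`); 0 or absent means the cluster does not occur
#'   in that condition.
#' @param lineage One of `"epithelial"`, `"stromal"`, `"t_cell"`,
#'   `"macrophage"`.
#' @param corneal_stage Corneal maturation stage 1, 2 or 3 (epithelial
#'   clusters only; `NA` otherwise).
#' @param conjunctival_stage Conjunctival stage 1 or 2 (epithelial only).
#' @param progenitor_level Mean normalized expression planted on the
#'   progenitor panel genes (Krt14, Krt15).
#' @param proliferative Logical; plant the Mki67/MCM proliferation program.
#' @param branch Ground-truth branch label (epithelial clusters).
#' @param paired_with Name of the same-cell-type cluster in the opposite
#'   condition, or `NA` for condition-specific clusters.
#' @param extra_means Optional named numeric of additional per-gene planted
#'   means (e.g. `c(Edn2 = 29)`).
#' @param identity_genes Plant a private synthetic identity-gene program
#'   for this cell type (default); set `FALSE` for types whose identity is
#'   fully carried by named characteristic markers in `extra_means`.
#' @param cohorts Optional named numeric: shared-program cohorts this
#'   cluster belongs to (name -> relative strength). Clusters in the same
#'   cohort share a planted gene program, emulating condition-linked
#'   programs (e.g. a wound-response module) that tie related clusters of
#'   one condition together in the dendrogram.
#' @return A list with class `cluster_spec`.
#' @export
cluster_spec <- function(name, proportions, lineage = "epithelial",
                         corneal_stage = NA, conjunctival_stage = NA,
                         progenitor_level = 0, proliferative = FALSE,
                         branch = NA_character_, paired_with = NA_character_,
                         extra_means = NULL, identity_genes = TRUE,
                         cohorts = NULL) {
  lineage <- match.arg(lineage, c("epithelial", "stromal", "t_cell", "macrophage"))
  if (lineage == "epithelial") {
    if (is.na(corneal_stage) || !corneal_stage %in% 1:3) {
      stop("epithelial cluster '", name, "' needs corneal_stage in 1:3")
    }
    if (is.na(conjunctival_stage) || !conjunctival_stage %in% 1:2) {
      stop("epithelial cluster '", name, "' needs conjunctival_stage in 1:2")
    }
  } else if (!is.na(corneal_stage) || !is.na(conjunctival_stage)) {
    stop("non-epithelial cluster '", name, "' must not carry maturation stages")
  }
  prop <- c(unwounded = 0, wounded = 0)
  prop[names(proportions)] <- proportions
  structure(list(name = name, proportions = prop, lineage = lineage,
                 corneal_stage = corneal_stage,
                 conjunctival_stage = conjunctival_stage,
                 progenitor_level = progenitor_level,
                 proliferative = isTRUE(proliferative), branch = branch,
                 paired_with = paired_with,
                 extra_means = extra_means,
                 identity_genes = isTRUE(identity_genes),
                 cohorts = cohorts),
            class = "cluster_spec")
}

#' Assemble a simulation configuration
#'
#' Bundles the cluster specs with the global generative parameters of the
#' negative-binomial count model. Counts for gene g in cell c are drawn
#' NB(mean = L_c * m_g / S, size = 1/dispersion) where m_g is the cluster's
#' planted mean on the per-10^4 scale, S = `library_size_mean`, and L_c is a
#' log-normal library size with expectation S, so planted means are directly
#' recoverable as normalized (counts-per-10^4) cluster averages.
#'
#' @param clusters List of [cluster_spec()] objects.
#' @param seed Integer seed; together with the config it fully determines
#'   the output.
#' @param n_cells Named integer, cells emitted per condition (including the
#'   planted QC-failing cells).
#' @param n_background_genes Number of uninformative background genes.
#' @param nb_dispersion NB dispersion (1/size); 0.1 is typical of 10x UMI
#'   data at cluster level.
#' @param library_size_mean Expected UMI total per cell; also the
#'   normalization scale, so planted means live on the counts-per-10^4 scale.
#' @param library_size_sdlog Log-sd of the library-size log-normal.
#' @param apoptotic_gene_count Size of the synthetic apoptotic panel
#'   (`Apop01..`); a stand-in, the study names no gene list.
#' @param maturation_gene_count Number of synthetic planted monotone
#'   maturation genes (`Mat01..`); Krt12's stage ladder makes it an
#'   additional planted monotone gene, so the ground-truth planted set has
#'   `maturation_gene_count + 1` members when corneal stages are present.
#' @param maturation_base_mean Stage-1 mean of the synthetic planted genes.
#' @param maturation_fold_step Fold increase per corneal stage (> 1).
#' @param qc_fail_fraction Fraction of emitted cells planted as QC failures,
#'   split evenly between low-count, low-gene and high-apoptotic modes.
#' @param identity_genes_per_type,identity_mean Number and planted mean of
#'   private identity genes per cell type (paired clusters share them).
#' @param branch_gene_count,branch_mean Number and planted mean of shared
#'   branch-program genes per ground-truth branch; `branch_mean` may be a
#'   named vector (branch label -> mean) to make one branch more distinct
#'   than the others.
#' @param cohort_gene_count,cohort_mean Number and planted mean (at
#'   strength 1) of shared cohort-program genes per declared cohort.
#' @param krt12_stage_means Planted Krt12 mean per corneal stage; defaults
#'   sit inside the printed segregation ranges (<0.9, 5.5-20, >180).
#' @param krt13_stage_means Planted Krt13 mean per conjunctival stage
#'   (ranges <0.8, >9).
#' @param background_meanlog,background_sdlog Log-normal hyper-parameters of
#'   the shared background gene means.
#' @return A list with class `sim_config`.
#' @export
simulation_config <- function(clusters, seed = 42L,
                              n_cells = c(unwounded = 3136, wounded = 4967),
                              n_background_genes = 1833L,
                              nb_dispersion = 0.1,
                              library_size_mean = 1e4,
                              library_size_sdlog = 0.3,
                              apoptotic_gene_count = 10L,
                              maturation_gene_count = 9L,
                              maturation_base_mean = 1,
                              maturation_fold_step = 10,
                              qc_fail_fraction = 0.05,
                              identity_genes_per_type = 8L,
                              identity_mean = 8,
                              branch_gene_count = 40L,
                              branch_mean = 6,
                              cohort_gene_count = 10L,
                              cohort_mean = 8,
                              krt12_stage_means = c(0.3, 12, 250),
                              krt13_stage_means = c(0.2, 15),
                              background_meanlog = log(0.4),
                              background_sdlog = 0.5) {
  if (maturation_fold_step <= 1) stop("maturation_fold_step must be > 1")
  if (nb_dispersion <= 0 || library_size_mean <= 0) {
    stop("nb_dispersion and library_size_mean must be positive")
  }
  if (qc_fail_fraction < 0 || qc_fail_fraction >= 1) {
    stop("qc_fail_fraction must be in [0, 1)")
  }
  nms <- vapply(clusters, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate cluster names")
  names(clusters) <- nms
  for (cond in names(n_cells)) {
    tot <- sum(vapply(clusters, function(s) s$proportions[[cond]], 0))
    if (tot > 0 && abs(tot - 1) > 1e-9) {
      stop("cluster proportions for condition '", cond,
           "' sum to ", tot, ", not 1")
    }
  }
  for (s in clusters) {
    if (!is.na(s$paired_with)) {
      p <- clusters[[s$paired_with]]
      if (is.null(p)) stop("cluster '", s$name, "' paired with unknown '",
                           s$paired_with, "'")
      if (!identical(p$paired_with, s$name)) {
        stop("pairing not symmetric for '", s$name, "'")
      }
      if (which.max(s$proportions) == which.max(p$proportions)) {
        stop("pairing of '", s$name, "' does not cross conditions")
      }
    }
  }
  structure(list(clusters = clusters, seed = as.integer(seed),
                 n_cells = n_cells,
                 n_background_genes = as.integer(n_background_genes),
                 nb_dispersion = nb_dispersion,
                 library_size_mean = library_size_mean,
                 library_size_sdlog = library_size_sdlog,
                 apoptotic_gene_count = as.integer(apoptotic_gene_count),
                 maturation_gene_count = as.integer(maturation_gene_count),
                 maturation_base_mean = maturation_base_mean,
                 maturation_fold_step = maturation_fold_step,
                 qc_fail_fraction = qc_fail_fraction,
                 identity_genes_per_type = as.integer(identity_genes_per_type),
                 identity_mean = identity_mean,
                 branch_gene_count = as.integer(branch_gene_count),
                 branch_mean = branch_mean,
                 cohort_gene_count = as.integer(cohort_gene_count),
                 cohort_mean = cohort_mean,
                 krt12_stage_means = krt12_stage_means,
                 krt13_stage_means = krt13_stage_means,
                 background_meanlog = background_meanlog,
                 background_sdlog = background_sdlog),
            class = "sim_config")
}

# canonical type id: unwounded member of a pair, else own name
type_id_of <- function(spec) {
  if (is.na(spec$paired_with)) return(spec$name)
  min(spec$name, spec$paired_with)
}

#' Default study-design configuration
#'
#' The default composition mirrors the study design the pipeline targets:
#' 3136 unwounded cells in 11 clusters (8 epithelial EC1-EC8 plus stromal,
#' T-cell and macrophage clusters) and 4967 wounded cells in 12 clusters
#' (8 epithelial EC9-EC16 plus 4 non-epithelial). Cross-condition pairs
#' EC2-EC9, EC3-EC10, EC4-EC11, EC7-EC15 and EC8-EC16 are the same cell
#' type in both conditions. The two putative limbal stem cell types carry
#' the reported abundance shifts of label-retaining epithelial cells:
#' LSC1 (EC7/EC15) 18\% to 22\% of epithelial cells and LSC2 (EC8/EC16)
#' 20\% to 11\%. EC5 and EC13 are proliferative. Epithelial cells are 80\%
#' of each condition.
#'
#' @param seed Integer seed.
#' @param n_cells Named integer vector of cells per condition.
#' @param n_background_genes Background gene count; the default yields a
#'   2000-gene universe.
#' @param ... Further arguments passed to [simulation_config()].
#' @return A `sim_config`.
#' @examples
#' cfg <- default_simulation_config(seed = 1, n_cells = c(unwounded = 200, wounded = 300))
#' @export
default_simulation_config <- function(seed = 42L,
                                      n_cells = c(unwounded = 3136, wounded = 4967),
                                      n_background_genes = 1691L, ...) {
  epi <- function(name, pu, pw, cs, js, prog, prolif, branch, pair,
                  extra = NULL, id = TRUE, cohorts = NULL) {
    cluster_spec(name, c(unwounded = pu, wounded = pw), "epithelial",
                 corneal_stage = cs, conjunctival_stage = js,
                 progenitor_level = prog, proliferative = prolif,
                 branch = branch, paired_with = pair, extra_means = extra,
                 identity_genes = id, cohorts = cohorts)
  }
  clusters <- list(
    # unwounded epithelial (fractions of all unwounded cells; epithelium = 0.8)
    epi("EC1", 0.048, 0, 1, 1, 8, FALSE, "Branch1", NA),
    epi("EC2", 0.080, 0, 1, 1, 8, FALSE, "Branch1", "EC9"),
    epi("EC3", 0.096, 0, 3, 1, 2, FALSE, "Branch2", "EC10"),
    epi("EC4", 0.080, 0, 2, 2, 2, FALSE, "Branch2", "EC11"),
    epi("EC5", 0.096, 0, 2, 1, 15, TRUE,  "Branch3", NA,
        cohorts = c(homeoLPC = 1)),
    epi("EC6", 0.096, 0, 2, 1, 15, FALSE, "Branch3", NA,
        cohorts = c(homeoLPC = 1)),
    # LSC1's identity is carried by its named characteristic markers
    epi("EC7", 0.144, 0, 1, 1, 30, FALSE, "Branch3", "EC15",
        c(Edn2 = 29, Adm = 3.9), id = FALSE),
    epi("EC8", 0.160, 0, 1, 1, 30, FALSE, "Branch3", "EC16", c(Fmo2 = 8.9),
        cohorts = c(LSC2 = 1)),
    # wounded epithelial
    epi("EC9",  0, 0.080, 1, 1, 8, FALSE, "Branch1", "EC2"),
    epi("EC10", 0, 0.096, 3, 1, 2, FALSE, "Branch2", "EC3"),
    epi("EC11", 0, 0.080, 2, 2, 2, FALSE, "Branch2", "EC4"),
    # wounded-only LPCs share a wound-response program, partial in EC14
    epi("EC12", 0, 0.080, 2, 1, 15, FALSE, "Branch3", NA,
        cohorts = c(woundLPC = 1)),
    epi("EC13", 0, 0.104, 2, 1, 15, TRUE,  "Branch3", NA,
        cohorts = c(woundLPC = 1)),
    epi("EC14", 0, 0.096, 2, 1, 15, FALSE, "Branch3", NA,
        cohorts = c(woundLPC = 0.5)),
    epi("EC15", 0, 0.176, 1, 1, 30, FALSE, "Branch3", "EC7",
        c(Edn2 = 13, Adm = 1.0), id = FALSE),
    epi("EC16", 0, 0.088, 1, 1, 30, FALSE, "Branch3", "EC8", c(Fmo2 = 6.8),
        cohorts = c(LSC2 = 1)),
    # non-epithelial
    cluster_spec("SC1", c(unwounded = 0.10), "stromal", paired_with = "SC2"),
    cluster_spec("TC1", c(unwounded = 0.05), "t_cell", paired_with = "TC2"),
    cluster_spec("MC1", c(unwounded = 0.05), "macrophage", paired_with = "MC2"),
    cluster_spec("SC2", c(wounded = 0.06), "stromal", paired_with = "SC1"),
    # wound-activated stromal state: decorin/Cd34 high, fibrillar
    # collagens reduced, inflammatory chemokines expressed
    cluster_spec("SC3", c(wounded = 0.05), "stromal",
                 extra_means = c(Cd34 = 15, Dcn = 40, Col1a1 = 12,
                                 Col1a2 = 10, Cxcl2 = 12, Ccl4 = 8)),
    cluster_spec("TC2", c(wounded = 0.04), "t_cell", paired_with = "TC1"),
    cluster_spec("MC2", c(wounded = 0.05), "macrophage", paired_with = "MC1")
  )
  defaults <- list(clusters = clusters, seed = seed, n_cells = n_cells,
                   n_background_genes = n_background_genes,
                   # Branch1 sits distal from the other epithelial branches
                   branch_mean = c(Branch1 = 12, Branch2 = 6, Branch3 = 6))
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# expected designation per cluster, derived from the spec attributes;
# recorded as ground truth so end-to-end recovery can be scored
expected_designation_of <- function(spec, shared) {
  if (spec$lineage != "epithelial") return(spec$lineage)
  if (!is.na(spec$branch) && spec$branch == "Branch3" &&
      spec$corneal_stage == 1 && shared) {
    # an LSC type; active vs quiescent needs both members, caller resolves
    return(NA_character_)
  }
  if (spec$corneal_stage == 2 && spec$conjunctival_stage == 2) {
    return("putative_CjPC")
  }
  if (!is.na(spec$branch) && spec$branch == "Branch3" &&
      spec$corneal_stage >= 2) {
    return("putative_LPC")
  }
  if (spec$corneal_stage >= 2) return("putative_differentiating_LPC")
  "unknown_origin_SPC"
}

build_gene_universe <- function(config) {
  panel <- c("Krt12", "Krt13", "Krt14", "Krt15", "Krt17", "Krt19",
             "Col1a1", "Col1a2", "Dcn", "Cd34", "Trdc", "Cd3g", "Trbc1",
             "Cxcl2", "Ccl4", "Cd14", "Cd44", "Cd19",
             "Mki67", paste0("Mcm", 2:7), "Edn2", "Adm", "Fmo2")
  apop <- if (config$apoptotic_gene_count > 0) {
    sprintf("Apop%02d", seq_len(config$apoptotic_gene_count))
  } else character()
  mat <- if (config$maturation_gene_count > 0) {
    sprintf("Mat%02d", seq_len(config$maturation_gene_count))
  } else character()
  branches <- sort(unique(stats::na.omit(
    vapply(config$clusters, `[[`, "", "branch"))))
  branch_genes <- lapply(branches, function(b) {
    sprintf("%s.pg%02d", b, seq_len(config$branch_gene_count))
  })
  names(branch_genes) <- branches
  with_id <- vapply(config$clusters, function(s) s$identity_genes %||% TRUE, NA)
  types <- unique(vapply(config$clusters[with_id], type_id_of, ""))
  id_genes <- lapply(types, function(ty) {
    if (config$identity_genes_per_type == 0) return(character())
    sprintf("%s.id%d", ty, seq_len(config$identity_genes_per_type))
  })
  names(id_genes) <- types
  cohort_names <- sort(unique(unlist(lapply(config$clusters, function(s) {
    names(s$cohorts)
  }))))
  cohort_genes <- lapply(cohort_names, function(co) {
    if (config$cohort_gene_count == 0) return(character())
    sprintf("%s.cg%02d", co, seq_len(config$cohort_gene_count))
  })
  names(cohort_genes) <- cohort_names
  bg <- if (config$n_background_genes > 0) {
    sprintf("Bg%04d", seq_len(config$n_background_genes))
  } else character()
  symbols <- c(panel, apop, mat, unlist(branch_genes, use.names = FALSE),
               unlist(id_genes, use.names = FALSE),
               unlist(cohort_genes, use.names = FALSE), bg)
  list(symbols = symbols, panel = panel, apop = apop, mat = mat,
       branch_genes = branch_genes, id_genes = id_genes,
       cohort_genes = cohort_genes, background = bg)
}

# planted mean vector (counts-per-10^4 scale) for one cluster
cluster_mean_vector <- function(spec, genes, config, bg_means) {
  # off-genes keep a low leaky baseline rather than true zero: real
  # transcriptomes are rarely silent, and a stable baseline keeps ratio
  # statistics (e.g. the maturation screen) well behaved
  m <- setNames(rep(0.3, length(genes$symbols)), genes$symbols)
  m[genes$background] <- bg_means
  m[genes$apop] <- 1
  m[c("Edn2", "Adm", "Fmo2")] <- 0.02
  if (spec$lineage == "epithelial") {
    m["Krt17"] <- 10
    m["Krt19"] <- 10
    m["Krt12"] <- config$krt12_stage_means[spec$corneal_stage]
    m["Krt13"] <- config$krt13_stage_means[spec$conjunctival_stage]
    m["Krt14"] <- spec$progenitor_level
    m["Krt15"] <- spec$progenitor_level
    if (length(genes$mat)) {
      m[genes$mat] <- config$maturation_base_mean *
        config$maturation_fold_step^(spec$corneal_stage - 1)
    }
  } else if (spec$lineage == "stromal") {
    m[c("Col1a1", "Col1a2", "Dcn", "Cd34", "Cd44")] <- c(40, 30, 20, 5, 5)
  } else if (spec$lineage == "t_cell") {
    m[c("Trdc", "Cd3g", "Trbc1", "Cd44")] <- c(20, 15, 15, 8)
  } else if (spec$lineage == "macrophage") {
    m[c("Cxcl2", "Ccl4", "Cd14", "Cd44")] <- c(25, 20, 15, 5)
  }
  prolif <- c("Mki67", paste0("Mcm", 2:7))
  m[prolif] <- if (spec$proliferative) c(15, rep(10, 6)) else 0.3
  if (!is.na(spec$branch) && spec$branch %in% names(genes$branch_genes)) {
    bm <- config$branch_mean
    bm <- if (!is.null(names(bm)) && spec$branch %in% names(bm)) {
      bm[[spec$branch]]
    } else bm[[1]]
    m[genes$branch_genes[[spec$branch]]] <- bm
  }
  own_id <- genes$id_genes[[type_id_of(spec)]]
  if (length(own_id)) m[own_id] <- config$identity_mean
  for (co in names(spec$cohorts)) {
    m[genes$cohort_genes[[co]]] <- config$cohort_mean * spec$cohorts[[co]]
  }
  if (!is.null(spec$extra_means)) m[names(spec$extra_means)] <- spec$extra_means
  # background genes absorb the remaining transcriptome mass so that the
  # vector sums to the library size and planted means are directly on the
  # counts-per-scale normalized scale; without enough background mass the
  # whole vector is rescaled instead (planted means then become relative)
  S <- config$library_size_mean
  signal <- sum(m) - sum(m[genes$background])
  if (length(genes$background) && signal < S && sum(bg_means) > 0) {
    m[genes$background] <- bg_means * (S - signal) / sum(bg_means)
  } else if (sum(m) > 0) {
    m <- m * S / sum(m)
  }
  m
}

#' Generate a two-condition synthetic dataset with ground truth
#'
#' Draws UMI count matrices for the unwounded and wounded conditions from
#' the negative-binomial model described in [simulation_config()], together
#' with a ground-truth record of every planted structure: the cell-cluster
#' assignment, QC-failure modes, cross-condition pairing, branch labels,
#' planted monotone maturation genes, and the expected stem/progenitor
#' designation of every cluster. The seed in the config fully determines
#' the output.
#'
#' @param config A `sim_config` from [simulation_config()] or
#'   [default_simulation_config()].
#' @return A list with elements `unwounded` and `wounded` (each a
#'   [count_matrix()]) and `ground_truth`, a list with `cell_to_cluster`
#'   (named character over all emitted cells), `qc_fail_mode` (named
#'   character: `none`, `low_counts`, `low_genes`, `high_apoptotic`),
#'   `pairing` (named character), `branch`, `expected_designation`,
#'   `planted_maturation_genes`, `apoptotic_panel` and `planted_means`
#'   (clusters x genes matrix of configured means).
#' @examples
#' cfg <- default_simulation_config(seed = 1,
#'   n_cells = c(unwounded = 150, wounded = 200), n_background_genes = 50)
#' sim <- generate_dataset(cfg)
#' dim(sim$unwounded$counts)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- build_gene_universe(config)
  bg_means <- if (length(genes$background)) {
    rlnorm(length(genes$background), config$background_meanlog,
           config$background_sdlog)
  } else numeric()
  specs <- config$clusters
  planted <- t(vapply(specs, cluster_mean_vector, genes = genes,
                      config = config, bg_means = bg_means,
                      FUN.VALUE = numeric(length(genes$symbols))))
  rownames(planted) <- names(specs)

  out <- list()
  cell_to_cluster <- character()
  qc_mode <- character()
  size <- 1 / config$nb_dispersion
  S <- config$library_size_mean
  for (cond in names(config$n_cells)) {
    present <- names(specs)[vapply(specs, function(s) s$proportions[[cond]] > 0,
                                   NA)]
    if (length(present) == 0) next
    props <- vapply(specs[present], function(s) s$proportions[[cond]], 0)
    n_cond <- config$n_cells[[cond]]
    n_per <- apportion(n_cond, props)
    if (any(n_per == 0)) {
      stop("cluster '", present[which(n_per == 0)[1]],
           "' has zero cells in condition '", cond, "' after rounding")
    }
    blocks <- vector("list", length(present))
    cl_lab <- rep(present, n_per)
    modes <- sample(c("none", "low_counts", "low_genes", "high_apoptotic"),
                    n_cond, replace = TRUE,
                    prob = c(1 - config$qc_fail_fraction,
                             rep(config$qc_fail_fraction / 3, 3)))
    offset <- 0L
    for (i in seq_along(present)) {
      nk <- n_per[i]
      mk <- planted[present[i], ]
      p <- mk / sum(mk)
      mode_k <- modes[offset + seq_len(nk)]
      offset <- offset + nk
      L <- rlnorm(nk, log(S) - config$library_size_sdlog^2 / 2,
                  config$library_size_sdlog)
      L[mode_k == "low_counts"] <- rlnorm(sum(mode_k == "low_counts"),
                                          log(150), 0.3)
      P <- matrix(p, nrow = nk, ncol = length(p), byrow = TRUE)
      lg <- which(mode_k == "low_genes")
      if (length(lg)) {
        keep <- order(p, decreasing = TRUE)[seq_len(min(100L, length(p)))]
        prow <- numeric(length(p))
        prow[keep] <- p[keep] / sum(p[keep])
        P[lg, ] <- matrix(prow, nrow = length(lg), ncol = length(p),
                          byrow = TRUE)
      }
      ha <- which(mode_k == "high_apoptotic")
      if (length(ha) && length(genes$apop)) {
        papop <- numeric(length(p))
        papop[match(genes$apop, genes$symbols)] <- 1 / length(genes$apop)
        for (j in ha) P[j, ] <- 0.7 * P[j, ] + 0.3 * papop
      }
      mu <- P * L
      cnt <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = size),
                    nrow = nk)
      blocks[[i]] <- methods::as(methods::as(Matrix::Matrix(cnt, sparse = TRUE),
                                             "generalMatrix"), "CsparseMatrix")
    }
    counts <- do.call(rbind, blocks)
    ids <- sprintf("%s_c%05d", cond, seq_len(nrow(counts)))
    out[[cond]] <- count_matrix(counts, ids, genes$symbols, cond)
    cell_to_cluster[ids] <- cl_lab
    # modes were consumed cluster-block-wise in the same order as cl_lab
    qc_mode[ids] <- modes
  }

  pairing <- character()
  for (s in specs) if (!is.na(s$paired_with)) pairing[s$name] <- s$paired_with
  shared <- function(s) !is.na(s$paired_with)
  desig <- vapply(names(specs), function(nm) {
    s <- specs[[nm]]
    d <- expected_designation_of(s, shared(s))
    if (!is.na(d)) return(d)
    # LSC types: active iff the planted epithelial share drops upon wounding
    pair <- specs[[s$paired_with]]
    pu <- max(s$proportions[["unwounded"]], pair$proportions[["unwounded"]])
    pw <- max(s$proportions[["wounded"]], pair$proportions[["wounded"]])
    if (pw < pu) "putative_active_LSC" else "putative_quiescent_LSC"
  }, "")

  planted_mat <- c(genes$mat,
                   if (any(vapply(specs, function(s)
                     s$lineage == "epithelial", NA))) "Krt12")
  list(unwounded = out[["unwounded"]], wounded = out[["wounded"]],
       ground_truth = list(
         cell_to_cluster = cell_to_cluster,
         qc_fail_mode = qc_mode,
         pairing = pairing,
         branch = setNames(vapply(specs, `[[`, "", "branch"), names(specs)),
         lineage = setNames(vapply(specs, `[[`, "", "lineage"), names(specs)),
         expected_designation = desig,
         planted_maturation_genes = planted_mat,
         apoptotic_panel = genes$apop,
         planted_means = planted))
}

#' Write a simulated condition as a 10x-style MTX triplet
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate integer, genes x cells),
#' `features.tsv` and `barcodes.tsv` into `dir`, plus `ground_truth.json`
#' when ground truth is supplied.
#'
#' @param cm A [count_matrix()].
#' @param dir Output directory (created if missing).
#' @param ground_truth Optional ground-truth list from [generate_dataset()];
#'   serialized as JSON alongside the triplet.
#' @return `dir`, invisibly.
#' @export
write_tenx <- function(cm, dir, ground_truth = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::t(cm$counts)  # genes x cells on disk, the 10x convention
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(cm$gene_symbols, file.path(dir, "features.tsv"))
  writeLines(cm$cell_ids, file.path(dir, "barcodes.tsv"))
  if (!is.null(ground_truth)) {
    gt <- ground_truth
    gt$planted_means <- NULL # large; regenerate from the config instead
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
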