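#' Assemble a pipeline configuration
#'
#' One configuration object drives the whole chain from raw counts (or the
#' simulator) to the designation atlas. Exactly one of `sim` or
#' `input_dirs` must be supplied.
#'
#' @param sim A `sim_config`: the pipeline starts by simulating.
#' @param input_dirs Named list/character (`unwounded`, `wounded`) of
#'   directories holding MTX triplets.
#' @param apoptotic_panel Apoptotic gene symbols for QC; defaults to the
#'   simulator's synthetic panel (`Apop*`) when simulating, otherwise to
#'   any `Apop*`-prefixed genes found in the matrix.
#' @param min_counts,min_genes,max_apoptotic Cell QC thresholds.
#' @param gene_min_cells Drop genes detected in fewer cells (in both
#'   conditions) before analysis; 0 keeps all genes.
#' @param scale,pseudocount Normalization parameters.
#' @param n_pcs,k_neighbors,resolution,n_variable_genes,cluster_method
#'   Clustering parameters, see [cluster_cells()].
#' @param distance,linkage Dendrogram parameters.
#' @param k_branches Number of epithelial trajectory branches to cut.
#' @param epithelial_threshold Cytokeratin threshold for
#'   [segregate_epithelial()].
#' @param delta Active-LSC relative decrease threshold.
#' @param gap_mode Differentiation-score gap handling.
#' @param z_threshold Proliferation z threshold.
#' @param screen_top_n,screen_min_ratio,screen_pseudocount Maturation
#'   screen parameters.
#' @param compute_markers Run the one-vs-rest marker stage (the slowest
#'   stage; designation does not depend on it).
#' @param seed Integer seed governing every stochastic stage.
#' @param out_dir Optional output directory; when given, every stage
#'   artifact is written (CSV/Newick/JSON).
#' @return A list with class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, input_dirs = NULL,
                            apoptotic_panel = NULL,
                            min_counts = 500, min_genes = 200,
                            max_apoptotic = 0.10, gene_min_cells = 3,
                            scale = 1e4, pseudocount = 1,
                            n_pcs = 10, k_neighbors = 20, resolution = 1,
                            n_variable_genes = 500, cluster_method = "graph",
                            distance = "correlation", linkage = "average",
                            k_branches = 3, epithelial_threshold = 1,
                            delta = 0.25, gap_mode = "midpoint",
                            z_threshold = 2, screen_top_n = 10,
                            screen_min_ratio = 2, screen_pseudocount = 0.01,
                            compute_markers = TRUE, seed = 42L,
                            out_dir = NULL) {
  if (is.null(sim) == is.null(input_dirs)) {
    stop("supply exactly one of 'sim' or 'input_dirs'")
  }
  if (!is.null(input_dirs)) {
    for (cond in c("unwounded", "wounded")) {
      if (is.null(input_dirs[[cond]]) || !dir.exists(input_dirs[[cond]])) {
        stop("input_dirs$", cond, " is not an existing directory")
      }
      if (!file.exists(file.path(input_dirs[[cond]], "matrix.mtx"))) {
        stop("no matrix.mtx in ", input_dirs[[cond]])
      }
    }
  }
  structure(as.list(environment()), class = "pipeline_config")
}

write_stage_csv <- function(df, out_dir, name) {
  if (!is.null(out_dir)) {
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
}

#' Run the full pipeline
#'
#' Executes simulate/read, QC, normalization, per-condition clustering,
#' profiling, the joint dendrogram, cherry pairing into cell types, branch
#' extraction, designation, and the maturation screen, collecting a
#' machine-readable run report. Re-running with an identical configuration
#' reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A list with `report` (stage counts and parameter echo) and
#'   `data` (every intermediate object: matrices, labelings, profiles,
#'   dendrogram, cell types, branches, designations, screen table, and the
#'   simulator ground truth when simulating).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  warnings_log <- character()
  note <- function(...) {
    warnings_log <<- c(warnings_log, paste0(...))
  }

  # -- input stage ----------------------------------------------------
  ground_truth <- NULL
  if (!is.null(config$sim)) {
    sim <- generate_dataset(config$sim)
    raw <- list(unwounded = sim$unwounded, wounded = sim$wounded)
    ground_truth <- sim$ground_truth
    apop <- config$apoptotic_panel %||% ground_truth$apoptotic_panel
  } else {
    raw <- list(
      unwounded = read_count_matrix(config$input_dirs[["unwounded"]],
                                    "unwounded"),
      wounded = read_count_matrix(config$input_dirs[["wounded"]], "wounded"))
    apop <- config$apoptotic_panel %||%
      grep("^Apop", raw$unwounded$gene_symbols, value = TRUE)
  }

  # -- QC + shared gene filter ---------------------------------------
  qc <- lapply(raw, qc_filter, min_counts = config$min_counts,
               min_genes = config$min_genes, apoptotic_panel = apop,
               max_apoptotic = config$max_apoptotic)
  if (config$gene_min_cells > 0) {
    keep <- Matrix::colSums(qc$unwounded$matrix$counts > 0) >=
      config$gene_min_cells |
      Matrix::colSums(qc$wounded$matrix$counts > 0) >= config$gene_min_cells
    filtered <- lapply(qc, function(q) {
      count_matrix(q$matrix$counts[, keep, drop = FALSE],
                   q$matrix$cell_ids, q$matrix$gene_symbols[keep],
                   q$matrix$condition)
    })
  } else {
    filtered <- lapply(qc, `[[`, "matrix")
  }

  # -- normalize + cluster + profile ---------------------------------
  nms <- lapply(filtered, normalize_counts, scale = config$scale,
                pseudocount = config$pseudocount)
  labelings <- list(
    unwounded = cluster_cells(nms$unwounded, n_pcs = config$n_pcs,
                              k_neighbors = config$k_neighbors,
                              resolution = config$resolution,
                              n_variable_genes = config$n_variable_genes,
                              method = config$cluster_method,
                              seed = config$seed),
    wounded = cluster_cells(nms$wounded, n_pcs = config$n_pcs,
                            k_neighbors = config$k_neighbors,
                            resolution = config$resolution,
                            n_variable_genes = config$n_variable_genes,
                            method = config$cluster_method,
                            seed = config$seed + 1L))
  profiles <- combine_profiles(
    profile_clusters(nms$unwounded, labelings$unwounded),
    profile_clusters(nms$wounded, labelings$wounded))

  markers <- NULL
  if (isTRUE(config$compute_markers)) {
    markers <- rbind(find_markers(nms$unwounded, labelings$unwounded),
                     find_markers(nms$wounded, labelings$wounded))
  }

  # -- dendrogram, cell types, branches ------------------------------
  vg <- union(variable_genes(nms$unwounded, config$n_variable_genes),
              variable_genes(nms$wounded, config$n_variable_genes))
  dend <- build_joint_dendrogram(profiles, genes = vg,
                                 distance = config$distance,
                                 linkage = config$linkage)
  epithelial <- segregate_epithelial(profiles,
                                     threshold = config$epithelial_threshold)
  epi_leaves <- names(epithelial)[epithelial]
  branches <- extract_branches(dend, epi_leaves, k = config$k_branches)
  cell_types <- assign_cell_types(dend, epi_leaves, branches = branches)

  # -- classification -------------------------------------------------
  designations <- withCallingHandlers(
    designate(cell_types, profiles, epithelial, delta = config$delta,
              gap_mode = config$gap_mode, z_threshold = config$z_threshold),
    warning = function(w) {
      note(conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  non_epi_keys <- names(epithelial)[!epithelial]
  non_epi_types <- if (length(non_epi_keys)) {
    type_non_epithelial(profiles, keys = non_epi_keys)
  } else character()

  # -- maturation screen ---------------------------------------------
  grouping <- NULL
  screen <- NULL
  lsc_cl <- designations$cell_type[grepl("LSC$", designations$label)]
  stage_members <- function(labels) {
    i <- designations$label %in% labels
    m <- cell_types$member_unwounded[match(designations$cell_type[i],
                                           cell_types$name)]
    m[!is.na(m)]
  }
  st <- list(lsc = stage_members(c("putative_quiescent_LSC",
                                   "putative_active_LSC")),
             lpc = stage_members("putative_LPC"),
             differentiating_lpc = stage_members("putative_differentiating_LPC"))
  if (all(lengths(st) > 0)) {
    grouping <- stage_grouping(st$lsc, st$lpc, st$differentiating_lpc)
    screen <- withCallingHandlers(
      screen_maturation_markers(profiles, grouping,
                                top_n = config$screen_top_n,
                                min_ratio = config$screen_min_ratio,
                                pseudocount = config$screen_pseudocount),
      warning = function(w) {
        note(conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  } else {
    note("maturation screen skipped: a stage has no unwounded cluster")
  }

  # -- report ---------------------------------------------------------
  report <- list(
    parameters = config[setdiff(names(config), c("sim", "out_dir"))],
    seed = config$seed,
    cells_in = vapply(raw, function(m) length(m$cell_ids), 0L),
    cells_pass_qc = vapply(qc, function(q) sum(q$report$pass), 0L),
    genes_kept = length(filtered$unwounded$gene_symbols),
    clusters = vapply(labelings, function(l) length(unique(l$labels)), 0L),
    epithelial_clusters = vapply(c("unwounded", "wounded"), function(cond) {
      sum(epithelial[leaf_condition(names(epithelial)) == cond])
    }, 0L),
    cell_types = nrow(cell_types),
    presence = table(cell_types$presence),
    designations = table(designations$label),
    non_epithelial = table(unname(non_epi_types)),
    screened_markers = if (is.null(screen)) 0L else sum(screen$selected),
    warnings = warnings_log)

  # -- artifacts -------------------------------------------------------
  if (!is.null(config$out_dir)) {
    od <- config$out_dir
    for (cond in names(labelings)) {
      write_stage_csv(data.frame(cell_id = names(labelings[[cond]]$labels),
                                 cluster_id = unname(labelings[[cond]]$labels)),
                      od, paste0("labels_", cond, ".csv"))
      write_stage_csv(qc[[cond]]$report, od, paste0("qc_", cond, ".csv"))
    }
    long <- data.frame(
      key = rep(rownames(profiles$mean_expr), ncol(profiles$mean_expr)),
      gene = rep(colnames(profiles$mean_expr),
                 each = nrow(profiles$mean_expr)),
      mean_log = as.vector(profiles$mean_expr),
      mean_linear = as.vector(profiles$mean_linear))
    write_stage_csv(long, od, "profiles.csv")
    if (!is.null(markers)) write_stage_csv(markers, od, "markers.csv")
    write_dendrogram(dend, file.path(od, "dendrogram.nwk"))
    write_stage_csv(cell_types, od, "cell_types.csv")
    write_stage_csv(data.frame(leaf = names(branches),
                               branch = unname(branches)),
                    od, "branches.csv")
    write_stage_csv(designations, od, "designations.csv")
    if (!is.null(screen)) write_stage_csv(screen, od, "maturation_screen.csv")
    jsonlite::write_json(report, file.path(od, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }

  list(report = report,
       data = list(raw = raw, qc = qc, normalized = nms,
                   labelings = labelings, profiles = profiles,
                   markers = markers, dendrogram = dend,
                   epithelial = epithelial, branches = branches,
                   cell_types = cell_types, designations = designations,
                   non_epithelial_types = non_epi_types,
                   stage_grouping = grouping, screen = screen,
                   ground_truth = ground_truth))
}

#' Map recovered clusters to ground-truth clusters by majority vote
#'
#' @param labels Named character, cell id -> recovered cluster.
#' @param truth Named character, cell id -> true cluster.
#' @return Named character, recovered cluster -> majority true cluster.
#' @export
majority_map <- function(labels, truth) {
  truth <- truth[names(labels)]
  vapply(split(truth, labels), function(x) {
    names(sort(table(x), decreasing = TRUE))[1]
  }, "")
}
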