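#' Default marker gene panels
#'
#' The gene panels used throughout the pipeline to segregate epithelial from
#' non-epithelial clusters and to type the non-epithelial ones. Epithelial
#' identity is read from the cytokeratin family; stromal cells from collagen
#' and decorin; T cells from TCR subunits; macrophages from chemokines and
#' Cd14. The progenitor panel (Krt14/Krt15) quantifies the undifferentiated
#' epithelial state, the proliferation panel (Mki67 plus the MCM helicase
#' family) marks cycling clusters, and the hematopoietic panel is reported
#' descriptively for cell types of unresolved origin. Genes absent from a
#' matrix contribute zero expression rather than an error.
#'
#' @param epithelial,stromal,t_cell,macrophage,progenitor,proliferation,hematopoietic
#'   Character vectors of gene symbols overriding the defaults.
#' @return A named list of character vectors with class `marker_panels`.
#' @examples
#' p <- marker_panels()
#' p$progenitor
#' @export
marker_panels <- function(epithelial = c("Krt12", "Krt13", "Krt14", "Krt15",
                                         "Krt17", "Krt19"),
                          stromal = c("Col1a1", "Col1a2", "Dcn", "Cd34"),
                          t_cell = c("Trdc", "Cd3g", "Trbc1"),
                          macrophage = c("Cxcl2", "Ccl4", "Cd14"),
                          progenitor = c("Krt14", "Krt15"),
                          proliferation = c("Mki67", paste0("Mcm", 2:7)),
                          hematopoietic = c("Cd34", "Cd44", "Cd14", "Cd19")) {
  panels <- list(epithelial = epithelial, stromal = stromal, t_cell = t_cell,
                 macrophage = macrophage, progenitor = progenitor,
                 proliferation = proliferation, hematopoietic = hematopoietic)
  for (nm in names(panels)) {
    if (!is.character(panels[[nm]]) || length(panels[[nm]]) == 0) {
      stop("panel '", nm, "' must be a non-empty character vector")
    }
  }
  structure(panels, class = "marker_panels")
}
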