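#' Default cell-type vocabulary
#'
#' The cell types the pipeline reasons about, with the flags downstream stages
#' rely on: endocrine types are merged into a single "Endocrine" label when
#' composition windows are built, the (unique) acinar type normalises
#' abundances, and acinar/epithelial types are excluded from neighbourhood
#' names.
#'
#' @return A tibble with columns `type`, `is_endocrine`, `is_acinar`,
#'   `is_epithelial`, `is_immune`.
#' @export
default_vocabulary <- function() {
  tibble::tribble(
    ~type,            ~is_endocrine, ~is_acinar, ~is_epithelial, ~is_immune,
    "acinar",         FALSE,         TRUE,       FALSE,          FALSE,
    "ductal",         FALSE,         FALSE,      TRUE,           FALSE,
    "alpha",          TRUE,          FALSE,      FALSE,          FALSE,
    "beta",           TRUE,          FALSE,      FALSE,          FALSE,
    "delta",          TRUE,          FALSE,      FALSE,          FALSE,
    "CD8T",           FALSE,         FALSE,      FALSE,          TRUE,
    "CD4T",           FALSE,         FALSE,      FALSE,          TRUE,
    "Bcell",          FALSE,         FALSE,      FALSE,          TRUE,
    "macrophage_DC",  FALSE,         FALSE,      FALSE,          TRUE,
    "neutrophil",     FALSE,         FALSE,      FALSE,          TRUE,
    "vasculature",    FALSE,         FALSE,      FALSE,          FALSE,
    "nerve",          FALSE,         FALSE,      FALSE,          FALSE,
    "GzmB_CD3neg",    FALSE,         FALSE,      FALSE,          TRUE,
    "stroma",         FALSE,         FALSE,      FALSE,          FALSE
  )
}

#' Merge fine endocrine types into a single label
#'
#' Alpha, beta, and delta cells are combined into one "Endocrine" type for
#' window composition; the merged label is "Islet" in neighbourhood names.
#'
#' @param types Character vector of cell-type labels.
#' @param vocabulary Vocabulary tibble (see [default_vocabulary()]).
#' @param label Merged label to use.
#' @return Character vector with endocrine types replaced by `label`.
#' @export
merge_endocrine <- function(types, vocabulary = default_vocabulary(),
                            label = "Endocrine") {
  endo <- vocabulary$type[vocabulary$is_endocrine]
  ifelse(types %in% endo, label, types)
}

#' Merged window vocabulary
#'
#' @param vocabulary Vocabulary tibble.
#' @param label Merged endocrine label.
#' @return Character vector of window composition types (merged).
#' @export
window_vocabulary <- function(vocabulary = default_vocabulary(),
                              label = "Endocrine") {
  unique(merge_endocrine(vocabulary$type, vocabulary, label))
}

#' Default lineage signature matrix
#'
#' Expected marker expression per cell type used to auto-annotate clusters:
#' +1 expected high, -1 expected low, 0 uninformative. Replaces interactive
#' annotation of marker heatmaps with a reproducible scoring rule.
#'
#' @return A tibble with a `type` column and one column per lineage marker.
#' @export
default_signatures <- function() {
  markers <- c("Amylase", "Cytokeratin", "Glucagon", "Proinsulin",
               "Somatostatin", "CD3", "CD8", "CD4", "CD20", "CD68", "MPO",
               "CD31", "GFAP", "GranzymeB", "Podoplanin")
  vocab <- default_vocabulary()$type
  sig <- matrix(0L, nrow = length(vocab), ncol = length(markers),
                dimnames = list(vocab, markers))
  sig["acinar", "Amylase"] <- 1L
  sig["ductal", "Cytokeratin"] <- 1L
  sig["alpha", "Glucagon"] <- 1L
  sig["beta", "Proinsulin"] <- 1L
  sig["delta", "Somatostatin"] <- 1L
  sig["CD8T", c("CD3", "CD8")] <- 1L
  sig["CD4T", c("CD3", "CD4")] <- 1L
  sig["Bcell", "CD20"] <- 1L
  sig["macrophage_DC", "CD68"] <- 1L
  sig["neutrophil", "MPO"] <- 1L
  sig["vasculature", "CD31"] <- 1L
  sig["nerve", "GFAP"] <- 1L
  sig["GzmB_CD3neg", "GranzymeB"] <- 1L
  sig["GzmB_CD3neg", "CD3"] <- -1L
  sig["stroma", "Podoplanin"] <- 1L
  dplyr::bind_cols(tibble::tibble(type = vocab), tibble::as_tibble(sig))
}

#' Default functional markers gated on CD8 T cells
#'
#' @return Character vector of the ten gated activation/differentiation markers.
#' @export
default_functional_markers <- function() {
  c("CD45RA", "CD45RO", "PD1", "LAG3", "ICOS", "GranzymeB", "CD57",
    "CD69", "TOX", "CD44")
}
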