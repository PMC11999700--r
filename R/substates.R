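#' Per-islet CD8 marker-positivity frequencies
#'
#' For each inflamed islet, CD8 T cells inside the islet and within `band_um`
#' of its boundary are combined, and the fraction positive for each functional
#' marker is computed. Islets with fewer than `min_cd8` CD8 T cells are
#' excluded and listed in the `excluded` attribute.
#'
#' @param islets Islet tibble (from [extract_islets()]).
#' @param table Cell table with `pos_<marker>` columns.
#' @param stages Tibble with `islet_id`, `stage` (from [label_stages()]).
#' @param band_um Band beyond the islet boundary.
#' @param min_cd8 Minimum CD8 count for inclusion.
#' @param markers Functional markers.
#' @param stage_filter Stages to include (default Inflamed).
#' @param cd8_type Cell-type label of CD8 T cells.
#' @return Tibble `islet_id`, `donor_id`, `n_cd8`, one `freq_<marker>` column
#'   per marker; attribute `excluded`.
#' @export
cd8_marker_frequencies <- function(islets, table, stages, band_um = 20,
                                   min_cd8 = 1,
                                   markers = default_functional_markers(),
                                   stage_filter = "Inflamed",
                                   cd8_type = "CD8T") {
  keep_ids <- stages$islet_id[stages$stage %in% stage_filter]
  if (length(keep_ids) == 0) stop("no islets in the requested stage(s)",
                                  call. = FALSE)
  sel <- islets[islets$islet_id %in% keep_ids, ]
  attr_tbl <- .attribute_cells_to_islets(sel, table)
  in_scope <- attr_tbl$inside | attr_tbl$dist_um <= band_um
  cd8 <- table$cell_type == cd8_type
  rows <- which(in_scope & cd8 & !is.na(attr_tbl$islet_id))
  df <- tibble::tibble(islet_id = attr_tbl$islet_id[rows])
  for (m in markers) df[[m]] <- table[[paste0("pos_", m)]][rows]
  agg <- df |>
    dplyr::group_by(.data$islet_id) |>
    dplyr::summarise(n_cd8 = dplyr::n(),
                     dplyr::across(dplyr::all_of(markers), mean))
  names(agg)[match(markers, names(agg))] <- paste0("freq_", markers)
  out <- dplyr::left_join(
    tibble::tibble(islet_id = sel$islet_id, donor_id = sel$donor_id), agg,
    by = "islet_id")
  out$n_cd8[is.na(out$n_cd8)] <- 0L
  excluded <- out$islet_id[out$n_cd8 < min_cd8]
  out <- out[out$n_cd8 >= min_cd8, ]
  attr(out, "excluded") <- excluded
  out
}

#' Cluster inflamed islets into CD8 sub-states
#'
#' Marker-frequency columns are z-normalised and the islets clustered with
#' Leiden on a kNN graph (Euclidean distance on z-scores), replacing
#' interactive embedding gating. The mean marker-frequency profile of each
#' sub-state is attached.
#'
#' @param freq Tibble from [cd8_marker_frequencies()].
#' @param n_neighbors Neighbours in the kNN graph.
#' @param resolution Leiden resolution.
#' @param seed Integer seed.
#' @return Tibble `islet_id`, `substate` (integer); attribute `profiles`
#'   (mean raw frequencies per sub-state).
#' @export
cluster_substates <- function(freq, n_neighbors = 15, resolution = 1,
                              seed = 1L) {
  cols <- grep("^freq_", names(freq), value = TRUE)
  n <- nrow(freq)
  if (n < n_neighbors + 1) stop("need at least n_neighbors + 1 islets",
                                call. = FALSE)
  X <- as.matrix(freq[, cols])
  Z <- apply(X, 2, function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  nn <- knn_feature_cpp(Z, n_neighbors, cosine = FALSE)
  g <- .knn_graph(nn)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5)
  substate <- as.integer(igraph::membership(cl))
  out <- tibble::tibble(islet_id = freq$islet_id, substate = substate)
  prof <- rowsum(X, substate) / as.vector(table(substate))
  attr(out, "profiles") <- prof
  out
}

#' Donor-pooled CD8 marker frequencies in islets
#'
#' CD8 T cells from all islets of the requested stages are pooled within each
#' donor before the frequency is computed.
#'
#' @inheritParams cd8_marker_frequencies
#' @return Tibble `donor_id`, `marker`, `freq`, `n_cd8`.
#' @export
cd8_islet_pooled_freq <- function(islets, table, stages, band_um = 20,
                                  markers = default_functional_markers(),
                                  stage_filter = "Inflamed",
                                  cd8_type = "CD8T") {
  keep_ids <- stages$islet_id[stages$stage %in% stage_filter]
  sel <- islets[islets$islet_id %in% keep_ids, ]
  attr_tbl <- .attribute_cells_to_islets(sel, table)
  in_scope <- attr_tbl$inside | attr_tbl$dist_um <= band_um
  rows <- which(in_scope & table$cell_type == cd8_type &
                  !is.na(attr_tbl$islet_id))
  .pooled_freq(table, rows, markers)
}

#' Donor-pooled CD8 marker frequencies in distance swaths
#'
#' @param islets Islet tibble.
#' @param table Cell table with `pos_<marker>` columns.
#' @param bands List of `c(lo, hi)` distance bands (micrometres from the islet
#'   boundary).
#' @param markers Functional markers.
#' @param cd8_type Cell-type label of CD8 T cells.
#' @return Tibble `donor_id`, `band`, `marker`, `freq`, `n_cd8`.
#' @export
cd8_swath_pooled_freq <- function(islets, table,
                                  bands = list(c(0, 25), c(25, 50), c(50, 100)),
                                  markers = default_functional_markers(),
                                  cd8_type = "CD8T") {
  attr_tbl <- .attribute_cells_to_islets(islets, table)
  out <- list()
  for (b in bands) {
    rows <- which(!attr_tbl$inside & attr_tbl$dist_um >= b[1] &
                    attr_tbl$dist_um < b[2] & table$cell_type == cd8_type)
    f <- .pooled_freq(table, rows, markers)
    f$band <- sprintf("%g-%g", b[1], b[2])
    out[[length(out) + 1]] <- f
  }
  dplyr::bind_rows(out)
}

.pooled_freq <- function(table, rows, markers) {
  df <- tibble::tibble(donor_id = table$donor_id[rows])
  for (m in markers) df[[m]] <- table[[paste0("pos_", m)]][rows]
  df |>
    dplyr::group_by(.data$donor_id) |>
    dplyr::summarise(n_cd8 = dplyr::n(),
                     dplyr::across(dplyr::all_of(markers), mean)) |>
    tidyr::pivot_longer(dplyr::all_of(markers), names_to = "marker",
                        values_to = "freq")
}

#' Islet-versus-swath marker enrichment with paired tests
#'
#' For each marker (and each swath band), the per-donor pooled islet frequency
#' is compared with the per-donor pooled swath frequency by a two-sided
#' Wilcoxon signed-rank test across donors (zero differences dropped, standard
#' signed-rank convention). P-values are raw; pass `p_adjust = "BH"` for a
#' Benjamini-Hochberg option.
#'
#' @param islet_freq Tibble `donor_id`, `marker`, `freq` (from
#'   [cd8_islet_pooled_freq()]).
#' @param swath_freq Tibble `donor_id`, `band`, `marker`, `freq` (from
#'   [cd8_swath_pooled_freq()]).
#' @param p_adjust Multiplicity correction (default `"none"`, mirroring the
#'   raw-p convention for these comparisons).
#' @return Tibble `marker`, `band`, `n_pairs`, `mean_diff`, `statistic`,
#'   `p_value`, `method`.
#' @export
enrichment_vs_swaths <- function(islet_freq, swath_freq,
                                 p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  joined <- dplyr::inner_join(
    islet_freq[, c("donor_id", "marker", "freq")],
    swath_freq[, c("donor_id", "band", "marker", "freq")],
    by = c("donor_id", "marker"), suffix = c("_islet", "_swath"))
  out <- joined |>
    dplyr::group_by(.data$marker, .data$band) |>
    dplyr::group_modify(function(g, key) {
      d <- g$freq_islet - g$freq_swath
      wt <- wilcoxon_signed_rank(d)
      tibble::tibble(n_pairs = length(d), mean_diff = mean(d),
                     statistic = wt$statistic, p_value = wt$p_value,
                     method = wt$method)
    }) |>
    dplyr::ungroup()
  if (p_adjust == "BH") out$p_adj <- stats::p.adjust(out$p_value, "BH")
  out
}

#' Two-sided Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped; the exact null distribution is used for small
#' untied samples (via [stats::wilcox.test()]), otherwise the normal
#' approximation, and the method used is reported. Fewer than 3 non-zero
#' pairs, or all-zero differences, give an NA p-value with a warning.
#'
#' @param d Numeric vector of paired differences.
#' @return List `statistic`, `p_value`, `n`, `method`.
#' @export
wilcoxon_signed_rank <- function(d) {
  d <- d[d != 0]
  if (length(d) < 3) {
    warning("fewer than 3 non-zero paired differences; test skipped")
    return(list(statistic = NA_real_, p_value = NA_real_, n = length(d),
                method = "undefined"))
  }
  wt <- suppressWarnings(stats::wilcox.test(d, exact = NULL))
  method <- if (grepl("continuity", wt$method) ||
                length(unique(abs(d))) < length(d)) "approximate" else "exact"
  # wilcox.test silently switches to the approximation when ties exist
  exact_used <- length(d) < 50 && length(unique(abs(d))) == length(d)
  list(statistic = unname(wt$statistic), p_value = wt$p.value, n = length(d),
       method = if (exact_used) "exact" else "approximate")
}
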