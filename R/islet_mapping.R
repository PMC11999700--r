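#' Spatial composition windows
#'
#' For every cell, its window is the set of its `k` nearest spatial neighbours
#' (Euclidean distance in micrometres, the index cell excluded, ties broken by
#' cell order), summarised as counts per cell type. Alpha, beta, and delta
#' cells are merged into one "Endocrine" type by default. Windows never cross
#' donors.
#'
#' @param table Cell table with `x_um`, `y_um`, `cell_type`, `donor_id`.
#' @param k Window size (number of neighbours).
#' @param merge_endocrine Merge fine endocrine types before counting.
#' @param vocabulary Cell-type vocabulary.
#' @return A `cell_windows` object: list with `cell_id`, `donor_id`,
#'   `cell_type` (merged), `comp` (n x types count matrix, rows sum to `k`),
#'   `types`, `k`.
#' @export
compute_windows <- function(table, k = 20, merge_endocrine = TRUE,
                            vocabulary = default_vocabulary()) {
  types <- if (merge_endocrine) window_vocabulary(vocabulary) else
    vocabulary$type
  tlab <- if (merge_endocrine) {
    merge_endocrine(table$cell_type, vocabulary)
  } else table$cell_type
  extra <- setdiff(unique(tlab), types)
  types <- c(types, extra)
  code <- match(tlab, types)
  n <- nrow(table)
  comp <- matrix(0L, n, length(types), dimnames = list(NULL, types))
  for (d in unique(table$donor_id)) {
    rows <- which(table$donor_id == d)
    if (length(rows) <= k) {
      stop("donor ", d, " has <= k cells; cannot build windows", call. = FALSE)
    }
    nn <- knn2d_cpp(table$x_um[rows], table$y_um[rows], k)
    ncode <- matrix(code[rows][nn], nrow(nn), k)
    for (t in seq_along(types)) {
      comp[rows, t] <- rowSums(ncode == t)
    }
  }
  structure(list(cell_id = table$cell_id, donor_id = table$donor_id,
                 cell_type = tlab, comp = comp, types = types, k = k),
            class = "cell_windows")
}

#' Detect the islet region from window composition
#'
#' Window composition vectors are over-clustered with mini-batch k-means; the
#' islet region is the union of cells whose cluster's mean endocrine window
#' fraction exceeds the threshold. Several clusters may jointly form the
#' region.
#'
#' @param windows A `cell_windows` object (endocrine merged).
#' @param n_clusters Number of k-means clusters.
#' @param endocrine_fraction_threshold Mean endocrine window fraction a cluster
#'   must exceed.
#' @param seed Integer seed.
#' @param endocrine_label Merged endocrine label.
#' @return Character vector of islet-region cell ids.
#' @export
detect_islet_region <- function(windows, n_clusters = 200,
                                endocrine_fraction_threshold = 0.5,
                                seed = 1L, endocrine_label = "Endocrine") {
  stopifnot(inherits(windows, "cell_windows"))
  if (!endocrine_label %in% windows$types) {
    return(character(0))
  }
  frac <- windows$comp / windows$k
  km <- minibatch_kmeans(frac, k = min(n_clusters, nrow(frac)), seed = seed)
  endo_frac <- tapply(frac[, endocrine_label], km$cluster, mean)
  keep <- as.integer(names(endo_frac))[endo_frac > endocrine_fraction_threshold]
  if (length(keep) == 0) {
    if (any(frac[, endocrine_label] > 0)) {
      warning("no cluster exceeds the endocrine fraction threshold; ",
              "returning an empty islet region")
    }
    return(character(0))
  }
  windows$cell_id[km$cluster %in% keep]
}

#' Extract islet instances as spatial connected components
#'
#' Islet-region cells are linked in a symmetric kNN graph (an edge joins two
#' cells if either is among the other's `adjacency_k` nearest region cells,
#' per donor); connected components with at least `min_cells` cells and at
#' least one endocrine cell become islet instances.
#'
#' @param table Cell table.
#' @param region_ids Islet-region cell ids (from [detect_islet_region()]).
#' @param adjacency_k Neighbours in the component graph.
#' @param min_cells Minimum component size (components below are discarded).
#' @param vocabulary Cell-type vocabulary.
#' @return Tibble of islet instances: `islet_id`, `donor_id`, `group`,
#'   `n_cells`, centroid `x_um`/`y_um`, `n_endocrine`, `n_beta`, one
#'   `n_<type>` inside-count column per type, and a `members` list-column of
#'   cell ids.
#' @export
extract_islets <- function(table, region_ids, adjacency_k = 5, min_cells = 10,
                           vocabulary = default_vocabulary()) {
  region <- table[table$cell_id %in% region_ids, ]
  out <- list()
  endo_types <- vocabulary$type[vocabulary$is_endocrine]
  for (d in unique(region$donor_id)) {
    sub <- region[region$donor_id == d, ]
    n <- nrow(sub)
    if (n == 0) next
    comp <- if (n == 1) {
      1L
    } else {
      nn <- knn2d_cpp(sub$x_um, sub$y_um, min(adjacency_k, n - 1))
      g <- .knn_graph(nn)
      as.integer(igraph::components(g)$membership)
    }
    for (cmp in unique(comp)) {
      members <- sub[comp == cmp, ]
      if (nrow(members) < min_cells) next
      counts <- table(factor(members$cell_type, levels = vocabulary$type))
      n_endo <- sum(counts[endo_types])
      if (n_endo < 1) next
      row <- tibble::tibble(
        donor_id = d,
        group = if ("group" %in% names(members)) members$group[1] else NA,
        n_cells = nrow(members),
        x_um = mean(members$x_um), y_um = mean(members$y_um),
        n_endocrine = as.integer(n_endo),
        n_beta = as.integer(counts[["beta"]]))
      for (t in vocabulary$type) row[[paste0("n_", t)]] <- as.integer(counts[[t]])
      row$members <- list(members$cell_id)
      out[[length(out) + 1]] <- row
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(islet_id = character(0), donor_id = character(0)))
  }
  res <- dplyr::bind_rows(out)
  res <- res[order(res$donor_id, -res$n_cells), ]
  res <- tibble::add_column(
    res, islet_id = sprintf("%s_i%03d", res$donor_id,
                            stats::ave(seq_len(nrow(res)), res$donor_id,
                                       FUN = seq_along)),
    .before = 1)
  res
}

#' Attach detected islet membership to the cell table
#' @param table Cell table.
#' @param islets Islet tibble from [extract_islets()].
#' @return `table` with an `islet_id` column (NA for extra-islet cells).
#' @export
add_islet_ids <- function(table, islets) {
  map <- tibble::tibble(
    cell_id = unlist(islets$members),
    islet_id = rep(islets$islet_id, lengths(islets$members)))
  table$islet_id <- map$islet_id[match(table$cell_id, map$cell_id)]
  table
}

# distance from every cell to its nearest islet-member cell (per donor).
# Members have dist 0 and their own islet; non-members get the islet of the
# nearest member (nearest-islet assignment).
.attribute_cells_to_islets <- function(islets, table) {
  member_map <- tibble::tibble(
    cell_id = unlist(islets$members),
    islet_id = rep(islets$islet_id, lengths(islets$members)))
  out <- tibble::tibble(cell_id = table$cell_id,
                        islet_id = NA_character_,
                        dist_um = Inf, inside = FALSE)
  m <- match(table$cell_id, member_map$cell_id)
  out$islet_id[!is.na(m)] <- member_map$islet_id[m[!is.na(m)]]
  out$dist_um[!is.na(m)] <- 0
  out$inside[!is.na(m)] <- TRUE
  for (d in unique(table$donor_id)) {
    rows <- table$donor_id == d
    ref <- rows & !is.na(m)
    qry <- rows & is.na(m)
    if (!any(ref) || !any(qry)) next
    nn <- nn1_cpp(table$x_um[ref], table$y_um[ref],
                  table$x_um[qry], table$y_um[qry])
    ref_islet <- out$islet_id[ref]
    out$islet_id[qry] <- ref_islet[nn$index]
    out$dist_um[qry] <- nn$dist
  }
  out
}

#' Islet composition counts and features
#'
#' For each islet, each cell type is counted inside the islet and in the band
#' within `band_um` of the islet boundary (distance to the nearest member
#' cell); band cells belonging to any islet are excluded, and band cells are
#' attributed to their nearest islet. The feature for each non-endocrine type
#' is `log1p(count / n_endocrine)` with `n_endocrine` the endocrine count
#' inside the islet.
#'
#' @param islets Islet tibble from [extract_islets()].
#' @param table Cell table.
#' @param band_um Band width beyond the islet boundary (micrometres).
#' @param vocabulary Cell-type vocabulary.
#' @return Tibble with islet metadata, combined `count_<type>` columns
#'   (inside + band) and `feat_<type>` feature columns for non-endocrine
#'   types.
#' @export
islet_composition_features <- function(islets, table, band_um = 20,
                                       vocabulary = default_vocabulary()) {
  if (any(islets$n_endocrine < 1)) {
    stop("islet with zero endocrine cells", call. = FALSE)
  }
  attr_tbl <- .attribute_cells_to_islets(islets, table)
  band <- attr_tbl[!attr_tbl$inside & attr_tbl$dist_um <= band_um, ]
  band_cells <- table[match(band$cell_id, table$cell_id), ]
  band_cells$islet_id <- band$islet_id
  feat_types <- vocabulary$type[!vocabulary$is_endocrine]
  res <- islets[, c("islet_id", "donor_id", "group", "n_cells", "n_endocrine",
                    "n_beta")]
  for (t in feat_types) {
    inside_ct <- islets[[paste0("n_", t)]]
    band_ct <- tapply(band_cells$cell_type == t, band_cells$islet_id, sum)
    bc <- unname(ifelse(is.na(band_ct[res$islet_id]), 0L,
                        as.integer(band_ct[res$islet_id])))
    res[[paste0("count_", t)]] <- as.integer(inside_ct + bc)
    res[[paste0("feat_", t)]] <- log1p((inside_ct + bc) / res$n_endocrine)
  }
  res
}

#' Feature matrix of an islet feature tibble
#' @param features Output of [islet_composition_features()].
#' @return Numeric matrix (islets x types) of the `feat_` columns, rownames
#'   islet ids.
#' @export
feature_matrix <- function(features) {
  cols <- grep("^feat_", names(features), value = TRUE)
  m <- as.matrix(features[, cols])
  rownames(m) <- features$islet_id
  colnames(m) <- sub("^feat_", "", cols)
  m
}

#' Cell-type composition of distance swaths around islets
#'
#' Extra-islet cells are attributed to their nearest islet and binned into
#' half-open distance bands `[lo, hi)` measured from the islet boundary
#' (nearest member cell). Fractions within each non-empty band sum to 1 over
#' the vocabulary.
#'
#' @param islets Islet tibble.
#' @param table Cell table.
#' @param bands List of `c(lo, hi)` pairs in micrometres; must not overlap.
#' @param vocabulary Cell-type vocabulary.
#' @return Tibble: `islet_id`, `band`, `lo_um`, `hi_um`, `n_cells`, `empty`,
#'   and one `frac_<type>` column per type.
#' @export
swath_composition <- function(islets, table,
                              bands = list(c(0, 25), c(25, 50), c(50, 100)),
                              vocabulary = default_vocabulary()) {
  lo <- vapply(bands, `[`, numeric(1), 1)
  hi <- vapply(bands, `[`, numeric(1), 2)
  ord <- order(lo)
  if (any(hi[ord][-length(ord)] > lo[ord][-1]) || any(hi <= lo)) {
    stop("bands must be non-overlapping half-open intervals", call. = FALSE)
  }
  attr_tbl <- .attribute_cells_to_islets(islets, table)
  extra <- attr_tbl[!attr_tbl$inside, ]
  cells <- table[match(extra$cell_id, table$cell_id), ]
  out <- list()
  for (b in seq_along(bands)) {
    in_band <- extra$dist_um >= lo[b] & extra$dist_um < hi[b]
    band_name <- sprintf("%g-%g", lo[b], hi[b])
    for (isl in islets$islet_id) {
      sel <- in_band & extra$islet_id == isl
      n <- sum(sel)
      counts <- table(factor(cells$cell_type[sel], levels = vocabulary$type))
      row <- tibble::tibble(islet_id = isl, band = band_name,
                            lo_um = lo[b], hi_um = hi[b],
                            n_cells = n, empty = n == 0)
      fr <- if (n > 0) as.numeric(counts) / n else rep(NA_real_,
                                                       length(counts))
      for (t in seq_along(vocabulary$type)) {
        row[[paste0("frac_", vocabulary$type[t])]] <- fr[t]
      }
      out[[length(out) + 1]] <- row
    }
  }
  dplyr::bind_rows(out)
}
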