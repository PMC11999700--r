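#' Marker columns of a cell table
#'
#' Every column that is not a reserved metadata/derived column and not a
#' positivity flag is treated as a marker intensity.
#'
#' @param table Cell table.
#' @return Character vector of marker column names.
#' @export
marker_columns <- function(table) {
  reserved <- c("cell_id", "donor_id", "group", "x_um", "y_um", "cell_type",
                "islet_id", "lobule_id", "niche_id", "cn_label", "cluster")
  cand <- setdiff(names(table), reserved)
  cand[!startsWith(cand, "pos_") &
         vapply(table[cand], is.numeric, logical(1))]
}

#' Z-normalise marker intensities within each donor
#'
#' Technical variation across donors (staining, acquisition) is removed by
#' z-scoring each marker within each donor: mean 0 and sample standard
#' deviation 1 (denominator n-1) per donor and marker.
#'
#' @param table Cell table.
#' @param markers Marker columns (default: all of [marker_columns()]).
#' @return The table with the marker columns replaced by z-scores.
#' @export
znormalize_markers <- function(table, markers = marker_columns(table)) {
  for (d in unique(table$donor_id)) {
    rows <- table$donor_id == d
    if (sum(rows) < 2) stop("donor ", d, " has fewer than 2 cells",
                            call. = FALSE)
    for (m in markers) {
      x <- table[[m]][rows]
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) {
        stop("marker ", m, " has zero variance within donor ", d,
             call. = FALSE)
      }
      table[[m]][rows] <- (x - mean(x)) / s
    }
  }
  table
}

#' Cluster cells by marker expression (kNN + Leiden)
#'
#' Leiden community detection on the k-nearest-neighbour graph of per-donor
#' z-normalised marker vectors (Euclidean distance on z-scores).
#' Deterministic given `seed`.
#'
#' @param table Cell table.
#' @param markers Marker columns to use.
#' @param n_neighbors Neighbours in the kNN graph.
#' @param resolution Leiden resolution parameter.
#' @param seed Integer seed.
#' @param znormalize Z-normalise within donor first (set `FALSE` if `table`
#'   already holds z-scores).
#' @param log_transform Apply `log1p` to intensities before z-normalising
#'   (recommended for right-skewed fluorescence; ignored when
#'   `znormalize = FALSE`).
#' @return Integer vector of cluster labels, one per row of `table`.
#' @export
cluster_cell_types <- function(table, markers = marker_columns(table),
                               n_neighbors = 15, resolution = 1, seed = 1L,
                               znormalize = TRUE, log_transform = TRUE) {
  if (nrow(table) < n_neighbors + 1) {
    stop("need at least n_neighbors + 1 cells", call. = FALSE)
  }
  if (znormalize) {
    if (log_transform) for (m in markers) table[[m]] <- log1p(table[[m]])
    table <- znormalize_markers(table, markers)
  }
  X <- as.matrix(table[, markers])
  nn <- knn_feature_cpp(X, n_neighbors, cosine = FALSE)
  g <- .knn_graph(nn)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5)
  as.integer(igraph::membership(cl))
}

# undirected simple graph from a kNN index matrix
.knn_graph <- function(nn) {
  n <- nrow(nn)
  from <- rep(seq_len(n), ncol(nn))
  to <- as.vector(nn)
  el <- cbind(pmin(from, to), pmax(from, to))
  el <- unique(el)
  igraph::graph_from_edgelist(el, directed = FALSE) |>
    igraph::simplify()
}

#' Annotate clusters against a signature matrix
#'
#' Each cluster is assigned the cell type whose signature row maximises the
#' mean over its non-zero entries of signature entry times the cluster's mean
#' z-score (averaging makes rows with many markers comparable to rows with
#' one); clusters scoring identically for several types take the first type in
#' vocabulary order and are flagged as ties. Identically annotated clusters are
#' thereby merged, replacing interactive cluster merging.
#'
#' With `rescale = TRUE` (the default) the cluster-mean matrix is standardised
#' across clusters per marker before scoring. This removes the dilution that
#' abundant cell types suffer on their own markers (their positives dominate
#' the per-cell z-normalisation, compressing their z-scores) and makes the
#' rule robust when a large type is split over several clusters.
#'
#' @param labels Integer cluster labels (from [cluster_cell_types()]).
#' @param table Cell table holding z-normalised marker columns.
#' @param signatures Signature tibble (see [default_signatures()]).
#' @param rescale Standardise cluster means across clusters before scoring.
#' @return Character vector of cell types per cell, with a `clusters`
#'   attribute tibble (cluster, assigned type, score, tie flag).
#' @export
annotate_clusters <- function(labels, table, signatures = default_signatures(),
                              rescale = TRUE) {
  if (ncol(signatures) < 2 || nrow(signatures) == 0) {
    stop("empty signature matrix", call. = FALSE)
  }
  markers <- intersect(setdiff(names(signatures), "type"), names(table))
  if (length(markers) == 0) stop("no signature markers found in table",
                                 call. = FALSE)
  sig <- as.matrix(signatures[, markers])
  rownames(sig) <- signatures$type
  means <- rowsum(as.matrix(table[, markers]), labels) /
    as.vector(table(labels)[as.character(sort(unique(labels)))])
  if (rescale && nrow(means) > 1) {
    means <- apply(means, 2, function(x) {
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) x - mean(x) else (x - mean(x)) / s
    })
  }
  scores <- means %*% t(sig) # clusters x types
  scores <- sweep(scores, 2, pmax(rowSums(sig != 0), 1), "/")
  best <- apply(scores, 1, function(s) which(s == max(s))[1])
  tie <- apply(scores, 1, function(s) sum(s == max(s)) > 1)
  info <- tibble::tibble(cluster = sort(unique(labels)),
                         cell_type = signatures$type[best],
                         score = scores[cbind(seq_along(best), best)],
                         tie = tie)
  out <- info$cell_type[match(labels, info$cluster)]
  attr(out, "clusters") <- info
  out
}

#' Gate marker positivity at the 99th percentile of a background distribution
#'
#' Cell types known not to express a marker provide its background intensity
#' distribution; a cell is called positive when its intensity is strictly
#' greater than the 99th percentile (type-7 linear interpolation) of that
#' background. Thresholds are computed per donor by default, consistent with
#' per-donor normalisation, or pooled across donors.
#'
#' @param table Cell table with intensity columns.
#' @param marker Marker to gate.
#' @param background_types Cell types forming the background.
#' @param per_donor Compute one threshold per donor (default) or pooled.
#' @param percentile Background percentile (default 0.99).
#' @param floor Minimum background size below which a warning is raised.
#' @return A `gate_result`: list with `marker`, `background_types`,
#'   `thresholds` (tibble donor/threshold/n_background), and `calls`
#'   (tibble cell_id, positive).
#' @export
gate_marker_positivity <- function(table, marker, background_types,
                                   per_donor = TRUE, percentile = 0.99,
                                   floor = 100) {
  if (!marker %in% names(table)) stop("marker not in table", call. = FALSE)
  bg_rows <- table$cell_type %in% background_types
  if (!any(bg_rows)) stop("no background cells for marker ", marker,
                          call. = FALSE)
  scope <- if (per_donor) table$donor_id else rep("pooled", nrow(table))
  thr <- vapply(split(table[[marker]][bg_rows], scope[bg_rows]), function(x) {
    stats::quantile(x, percentile, type = 7, names = FALSE)
  }, numeric(1))
  nbg <- vapply(split(seq_len(sum(bg_rows)), scope[bg_rows]), length, 1L)
  if (any(nbg < floor)) {
    warning("background smaller than ", floor, " cells for marker ", marker)
  }
  missing_scope <- setdiff(unique(scope), names(thr))
  if (length(missing_scope)) {
    stop("no background cells for: ", paste(missing_scope, collapse = ", "),
         call. = FALSE)
  }
  positive <- table[[marker]] > thr[scope]
  structure(list(
    marker = marker, background_types = background_types,
    percentile = percentile,
    thresholds = tibble::tibble(scope = names(thr), threshold = unname(thr),
                                n_background = unname(nbg[names(thr)])),
    calls = tibble::tibble(cell_id = table$cell_id, positive = positive)),
    class = "gate_result")
}

#' Gate a set of markers and attach positivity columns
#'
#' @param table Cell table.
#' @param markers Markers to gate.
#' @param background_types Background cell types (shared across markers).
#' @param ... Passed to [gate_marker_positivity()].
#' @return `table` with one logical `pos_<marker>` column per marker.
#' @export
gate_all_markers <- function(table, markers, background_types, ...) {
  for (m in markers) {
    g <- gate_marker_positivity(table, m, background_types, ...)
    table[[paste0("pos_", m)]] <- g$calls$positive
  }
  table
}
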