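#' Identify cellular neighbourhoods by over-cluster-and-merge naming
#'
#' Window composition vectors are over-clustered with mini-batch k-means
#' (large `n_clusters`); each raw cluster is named by the set of cell types
#' present (at least one cell in the window) in strictly more than
#' `presence_threshold` of its windows, with acinar and epithelial types used
#' in clustering but excluded from names; clusters with the same name are
#' merged. Clusters with an empty name form a single "(background)"
#' neighbourhood, so every cell carries a CN label. The merged endocrine type
#' appears in names as `islet_label`.
#'
#' @param windows A `cell_windows` object (endocrine merged).
#' @param n_clusters Raw k-means clusters.
#' @param presence_threshold Strict presence fraction for naming.
#' @param seed Integer seed.
#' @param vocabulary Cell-type vocabulary (supplies the acinar/epithelial
#'   exclusion).
#' @param islet_label Label replacing the merged endocrine type in names.
#' @return A `cn_model`: list with `assignment` (tibble `cell_id`,
#'   `cn_label`), `cluster_names` (raw cluster to CN name map), `presence`
#'   (raw cluster x type presence fractions), `cn_names`, and parameters.
#' @export
identify_cns <- function(windows, n_clusters = 200, presence_threshold = 0.8,
                         seed = 1L, vocabulary = default_vocabulary(),
                         islet_label = "Islet") {
  stopifnot(inherits(windows, "cell_windows"))
  n <- nrow(windows$comp)
  if (n_clusters > n) stop("n_clusters exceeds the number of cells",
                           call. = FALSE)
  km <- minibatch_kmeans(windows$comp, k = n_clusters, seed = seed)
  present <- windows$comp > 0
  counts <- as.vector(table(factor(km$cluster, levels = seq_len(n_clusters))))
  presence <- rowsum(present + 0, km$cluster)
  presence <- presence / counts[as.integer(rownames(presence))]
  excluded <- vocabulary$type[vocabulary$is_acinar | vocabulary$is_epithelial]
  nameable <- setdiff(colnames(presence), excluded)
  cluster_names <- apply(presence[, nameable, drop = FALSE], 1, function(p) {
    hit <- nameable[p > presence_threshold]
    hit <- sub("^Endocrine$", islet_label, hit)
    if (length(hit) == 0) "(background)" else paste(sort(hit), collapse = "|")
  })
  full_names <- rep("(background)", n_clusters)
  full_names[as.integer(rownames(presence))] <- cluster_names
  structure(list(
    assignment = tibble::tibble(cell_id = windows$cell_id,
                                cn_label = full_names[km$cluster]),
    cluster_names = full_names,
    presence = presence,
    cn_names = sort(unique(full_names)),
    k = windows$k, n_clusters = n_clusters,
    presence_threshold = presence_threshold), class = "cn_model")
}

#' Attach CN labels to the cell table
#' @param table Cell table.
#' @param model A `cn_model`.
#' @return `table` with a `cn_label` column.
#' @export
add_cn_labels <- function(table, model) {
  table$cn_label <- model$assignment$cn_label[
    match(table$cell_id, model$assignment$cell_id)]
  table
}

#' Symmetric spatial kNN graph over all cells of each donor
#'
#' An edge joins two cells when either is among the other's `k` nearest
#' neighbours. Distances in tissue are physical, so the graph is built over
#' all cells before any restriction to a neighbourhood's cells.
#'
#' @param table Cell table.
#' @param k Neighbours.
#' @return Tibble of undirected edges: `donor_id`, `from`, `to` (cell ids).
#' @export
build_spatial_graph <- function(table, k = 5) {
  out <- list()
  for (d in unique(table$donor_id)) {
    rows <- which(table$donor_id == d)
    if (length(rows) < 2) next
    nn <- knn2d_cpp(table$x_um[rows], table$y_um[rows],
                    min(k, length(rows) - 1))
    from <- rep(seq_len(nrow(nn)), ncol(nn))
    to <- as.vector(nn)
    a <- pmin(from, to); b <- pmax(from, to)
    keep <- !duplicated(cbind(a, b))
    out[[d]] <- tibble::tibble(donor_id = d,
                               from = table$cell_id[rows][a[keep]],
                               to = table$cell_id[rows][b[keep]])
  }
  dplyr::bind_rows(out)
}

#' Extract CN instances as spatial connected components
#'
#' For each neighbourhood, its instances are the connected components of the
#' spatial kNN graph restricted to that neighbourhood's cells.
#'
#' @param table Cell table with a `cn_label` column.
#' @param graph Edge tibble from [build_spatial_graph()] (computed with
#'   `adjacency_k` if NULL).
#' @param adjacency_k Neighbours if the graph must be built.
#' @return Tibble of instances: `instance_id`, `cn_label`, `donor_id`,
#'   `n_cells`, centroid `x_um`/`y_um`, `members` list-column.
#' @export
extract_cn_instances <- function(table, graph = NULL, adjacency_k = 5) {
  stopifnot("cn_label" %in% names(table))
  if (is.null(graph)) graph <- build_spatial_graph(table, adjacency_k)
  cn_of <- stats::setNames(table$cn_label, table$cell_id)
  same <- graph[cn_of[graph$from] == cn_of[graph$to], ]
  g <- igraph::graph_from_data_frame(
    same[, c("from", "to")], directed = FALSE,
    vertices = tibble::tibble(name = table$cell_id))
  memb <- igraph::components(g)$membership[table$cell_id]
  inst_key <- paste(table$donor_id, table$cn_label, memb, sep = "\r")
  idx <- match(inst_key, unique(inst_key))
  df <- tibble::tibble(cell_id = table$cell_id, donor_id = table$donor_id,
                       cn_label = table$cn_label,
                       x_um = table$x_um, y_um = table$y_um, inst = idx)
  inst <- df |>
    dplyr::group_by(.data$inst) |>
    dplyr::summarise(cn_label = .data$cn_label[1],
                     donor_id = .data$donor_id[1],
                     n_cells = dplyr::n(),
                     x_um = mean(.data$x_um), y_um = mean(.data$y_um),
                     members = list(.data$cell_id)) |>
    dplyr::ungroup()
  inst$instance_id <- sprintf("%s_inst%05d", inst$donor_id, inst$inst)
  inst[, c("instance_id", "cn_label", "donor_id", "n_cells", "x_um", "y_um",
           "members")]
}

# tibble of adjacent instance pairs (cell-contact through the kNN graph)
.instance_adjacency_pairs <- function(instances, graph) {
  inst_of <- stats::setNames(rep(instances$instance_id,
                                 lengths(instances$members)),
                             unlist(instances$members))
  a <- inst_of[graph$from]; b <- inst_of[graph$to]
  keep <- !is.na(a) & !is.na(b) & a != b
  lo <- pmin(a[keep], b[keep])
  hi <- pmax(a[keep], b[keep])
  unique(tibble::tibble(a = lo, b = hi))
}

#' Adjacency frequency between two neighbourhoods
#'
#' Two instances are adjacent when some cell of one is a spatial kNN neighbour
#' of some cell of the other. The adjacency frequency from `source` to `dest`
#' is the number of source-CN instances adjacent to at least one dest-CN
#' instance divided by the number of source-CN instances. `source == dest` is
#' allowed; an instance is never adjacent to itself.
#'
#' @param instances Instance tibble from [extract_cn_instances()].
#' @param graph Edge tibble from [build_spatial_graph()].
#' @param source,dest CN names.
#' @return Fraction in \[0, 1\].
#' @export
adjacency_frequency <- function(instances, graph, source, dest) {
  src <- instances$instance_id[instances$cn_label == source]
  if (length(src) == 0) stop("undefined frequency: source CN has no instances",
                             call. = FALSE)
  dst <- instances$instance_id[instances$cn_label == dest]
  if (length(dst) == 0) return(0)
  pairs <- .instance_adjacency_pairs(instances, graph)
  hit <- (pairs$a %in% src & pairs$b %in% dst) |
    (pairs$b %in% src & pairs$a %in% dst)
  adj_src <- unique(c(pairs$a[hit & pairs$a %in% src],
                      pairs$b[hit & pairs$b %in% src]))
  length(adj_src) / length(src)
}

#' Full source-by-destination adjacency frequency table
#'
#' @param instances Instance tibble.
#' @param graph Edge tibble.
#' @return Tibble `source`, `dest`, `frequency`, `n_source_instances`.
#' @export
adjacency_matrix <- function(instances, graph) {
  pairs <- .instance_adjacency_pairs(instances, graph)
  cn_of_inst <- stats::setNames(instances$cn_label, instances$instance_id)
  long <- tibble::tibble(
    src_inst = c(pairs$a, pairs$b),
    dst_cn = cn_of_inst[c(pairs$b, pairs$a)])
  cns <- sort(unique(instances$cn_label))
  counts <- as.vector(table(factor(instances$cn_label, levels = cns)))
  grid <- tidyr::expand_grid(source = cns, dest = cns)
  long$src_cn <- cn_of_inst[long$src_inst]
  adj <- long |>
    dplyr::distinct(.data$src_inst, .data$dst_cn, .keep_all = TRUE) |>
    dplyr::count(.data$src_cn, .data$dst_cn, name = "n_adjacent")
  out <- dplyr::left_join(grid, adj,
                          by = c(source = "src_cn", dest = "dst_cn"))
  out$n_adjacent[is.na(out$n_adjacent)] <- 0L
  out$n_source_instances <- counts[match(out$source, cns)]
  out$frequency <- out$n_adjacent / out$n_source_instances
  out[, c("source", "dest", "frequency", "n_source_instances")]
}

#' Neighbourhood abundance and group contrast
#'
#' Per donor, a neighbourhood's abundance is its cell count divided by the
#' donor's acinar cell count (normalising for tissue area). Neighbourhoods are
#' ranked by the fold increase of mean abundance in `group_a` over `group_b`,
#' with a two-sided Mann-Whitney U test per CN across donor groups (raw
#' p-values).
#'
#' @param table Cell table with `cn_label`.
#' @param acinar_type Cell-type label of acinar cells.
#' @param group_a,group_b Donor groups contrasted (fold = mean a / mean b).
#' @return List with `abundance` (tibble `donor_id`, `group`, `cn_label`,
#'   `abundance`) and `contrast` (tibble `cn_label`, `mean_a`, `mean_b`,
#'   `fold_change`, `p_value`, ranked by fold change).
#' @export
cn_abundance_and_contrast <- function(table, acinar_type = "acinar",
                                      group_a = "T1D", group_b = "nonT1D") {
  stopifnot("cn_label" %in% names(table))
  donors <- unique(table[, c("donor_id", "group")])
  acinar <- table |>
    dplyr::filter(.data$cell_type == acinar_type) |>
    dplyr::count(.data$donor_id, name = "n_acinar")
  if (any(!donors$donor_id %in% acinar$donor_id)) {
    stop("donor with zero acinar cells", call. = FALSE)
  }
  ab <- table |>
    dplyr::count(.data$donor_id, .data$group, .data$cn_label) |>
    tidyr::complete(tidyr::nesting(donor_id, group),
                    cn_label = unique(table$cn_label),
                    fill = list(n = 0L)) |>
    dplyr::left_join(acinar, by = "donor_id") |>
    dplyr::mutate(abundance = .data$n / .data$n_acinar)
  contrast <- ab |>
    dplyr::group_by(.data$cn_label) |>
    dplyr::group_modify(function(g, key) {
      xa <- g$abundance[g$group == group_a]
      xb <- g$abundance[g$group == group_b]
      p <- if (length(xa) > 0 && length(xb) > 0 &&
               (length(unique(c(xa, xb))) > 1)) {
        suppressWarnings(stats::wilcox.test(xa, xb)$p.value)
      } else if (length(xa) > 0 && length(xb) > 0) 1 else NA_real_
      tibble::tibble(mean_a = mean(xa), mean_b = mean(xb),
                     fold_change = mean(xa) / mean(xb), p_value = p)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$fold_change))
  list(abundance = ab[, c("donor_id", "group", "cn_label", "abundance")],
       contrast = contrast)
}
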