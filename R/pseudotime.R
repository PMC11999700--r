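#' Build the islet trajectory graph
#'
#' A kNN graph over islet feature vectors under cosine distance, Leiden
#' clustering at the given resolution, and a cluster-connectivity matrix in
#' the style of partition-based graph abstraction: observed inter-cluster edge
#' counts divided by their expectation under random edge assignment.
#'
#' @param features Islet feature tibble (from
#'   [islet_composition_features()]) or a numeric matrix with islet rownames.
#' @param n_neighbors Neighbours in the kNN graph.
#' @param resolution Leiden resolution.
#' @param seed Integer seed.
#' @return An `islet_trajectory`: list with `islet_id`, `X` (feature matrix),
#'   `graph` (igraph), `cluster` (integer labels), `connectivity` (cluster x
#'   cluster matrix).
#' @export
build_trajectory <- function(features, n_neighbors = 15, resolution = 1,
                             seed = 1L) {
  X <- if (is.matrix(features)) features else feature_matrix(features)
  n <- nrow(X)
  if (n < n_neighbors + 1) stop("need at least n_neighbors + 1 islets",
                                call. = FALSE)
  nn <- knn_feature_cpp(X, n_neighbors, cosine = TRUE)
  g <- .knn_graph(nn)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5)
  cluster <- as.integer(igraph::membership(cl))
  structure(list(islet_id = rownames(X), X = X, graph = g, cluster = cluster,
                 connectivity = .paga_connectivity(g, cluster)),
            class = "islet_trajectory")
}

# observed inter-cluster edges / expectation under random edge placement
.paga_connectivity <- function(g, cluster) {
  ncl <- max(cluster)
  n <- igraph::vcount(g)
  E <- igraph::ecount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  sizes <- tabulate(cluster, ncl)
  conn <- matrix(0, ncl, ncl)
  for (i in seq_len(nrow(el))) {
    a <- cluster[el[i, 1]]; b <- cluster[el[i, 2]]
    if (a != b) {
      conn[a, b] <- conn[a, b] + 1
      conn[b, a] <- conn[b, a] + 1
    }
  }
  expected <- 2 * E * outer(sizes, sizes) / (n * (n - 1))
  out <- ifelse(expected > 0, conn / expected, 0)
  diag(out) <- 0
  out
}

# diffusion pseudotime from a root vertex on an undirected graph component.
# Transition matrix T = D^-1 A; dpt(x, root)^2 =
#   sum_m (lam_m / (1 - lam_m))^2 (psi_m(x) - psi_m(root))^2
# over non-stationary eigenpairs of T.
.dpt_from_root <- function(A, root) {
  d <- pmax(rowSums(A), .Machine$double.eps)
  S <- A / sqrt(d) / rep(sqrt(d), each = nrow(A))
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  keep <- eig$values < 1 - 1e-8
  lam <- eig$values[keep]
  psi <- (eig$vectors / sqrt(d))[, keep, drop = FALSE]
  w <- lam / (1 - lam)
  diff2 <- (psi - rep(psi[root, ], each = nrow(psi)))^2
  sqrt(drop(diff2 %*% w^2))
}

#' Diffusion pseudotime from the non-T1D centroid
#'
#' The root islet is the one whose feature vector is nearest (cosine) to the
#' mean feature vector of non-T1D islets; pseudotime is the diffusion distance
#' from the root on the trajectory graph, min-max normalised to \[0, 1\].
#' Islets listed in `omit_ids` are removed before the computation (isolating a
#' path, as when bridging islets blur a trajectory) and afterwards inherit the
#' pseudotime of their nearest retained neighbour in feature space; this never
#' changes retained islets' values. A disconnected graph is handled per
#' component (local root nearest the non-T1D centroid) with a warning.
#'
#' @param trajectory An `islet_trajectory`.
#' @param nonT1D_ids Islet ids of the non-T1D islets (defines the root).
#' @param omit_ids Optional islet ids to omit during computation.
#' @return Tibble `islet_id`, `pseudotime`, `cluster`, `omitted`; attributes
#'   `root_id` and `connectivity`.
#' @export
compute_pseudotime <- function(trajectory, nonT1D_ids, omit_ids = NULL) {
  stopifnot(inherits(trajectory, "islet_trajectory"))
  X <- trajectory$X
  ids <- trajectory$islet_id
  nonT1D_ids <- intersect(nonT1D_ids, ids)
  if (length(nonT1D_ids) == 0) stop("no non-T1D islets given", call. = FALSE)
  centroid <- colMeans(X[nonT1D_ids, , drop = FALSE])
  cosd <- .cosine_dist_to(X, centroid)
  retained <- !(ids %in% omit_ids)
  if (!any(retained)) stop("all islets omitted", call. = FALSE)
  root_global <- ids[retained][which.min(cosd[retained])]

  sub <- igraph::induced_subgraph(trajectory$graph, which(retained))
  A <- as.matrix(igraph::as_adjacency_matrix(sub, attr =
    if ("weight" %in% igraph::edge_attr_names(sub)) "weight" else NULL))
  comp <- igraph::components(sub)$membership
  if (max(comp) > 1) warning("trajectory graph is disconnected; ",
                             "pseudotime computed per component")
  rid <- ids[retained]
  pt <- numeric(length(rid))
  for (cc in seq_len(max(comp))) {
    inc <- comp == cc
    local_root <- which.min(replace(cosd[retained], !inc, Inf))
    Ai <- A[inc, inc, drop = FALSE]
    if (sum(inc) == 1) {
      pt[inc] <- 0
    } else {
      pt[inc] <- .dpt_from_root(Ai, match(local_root, which(inc)))
    }
  }
  full <- numeric(length(ids))
  full[retained] <- pt
  if (any(!retained)) {
    # nearest retained neighbour in feature space donates its pseudotime
    for (i in which(!retained)) {
      dists <- .cosine_dist_to(X[retained, , drop = FALSE], X[i, ])
      full[i] <- pt[which.min(dists)]
    }
  }
  rng <- range(full)
  if (diff(rng) > 0) full <- (full - rng[1]) / diff(rng)
  out <- tibble::tibble(islet_id = ids, pseudotime = full,
                        cluster = trajectory$cluster,
                        omitted = !retained)
  attr(out, "root_id") <- root_global
  attr(out, "connectivity") <- trajectory$connectivity
  out
}

.cosine_dist_to <- function(X, v) {
  nv <- sqrt(sum(v^2))
  nx <- sqrt(rowSums(X^2))
  sim <- drop(X %*% v) / pmax(nx * nv, .Machine$double.eps)
  1 - sim
}

#' Assign insulitis stage labels
#'
#' Trajectory clusters are mapped to stages: clusters with beta-cells and
#' immune enrichment below the cutoff are Normal; with beta-cells and
#' enrichment above the cutoff Inflamed; beta-free islets are Insulin-Depleted
#' regardless of cluster. Within the Insulin-Depleted group, islets with
#' strictly more than `cd8_thresh` CD8 T cells and strictly more than
#' `mac_thresh` macrophage/DCs form the Insulin-Depleted + Immune sub-state;
#' by default the thresholds are the 95th percentiles of those counts over
#' Normal islets.
#'
#' @param pseudotime Tibble from [compute_pseudotime()].
#' @param features Islet feature tibble with `count_CD8T`,
#'   `count_macrophage_DC`, `n_beta`, `n_endocrine`, `group`.
#' @param cd8_thresh,mac_thresh Explicit count thresholds (NULL = calibrate
#'   from Normal islets).
#' @param beta_frac_thresh Beta fraction above which a cluster counts as
#'   beta-present.
#' @param enrich_quantile Quantile of non-T1D immune enrichment defining the
#'   Inflamed cutoff.
#' @return `pseudotime` with a `stage` column; attribute `thresholds`.
#' @export
label_stages <- function(pseudotime, features, cd8_thresh = NULL,
                         mac_thresh = NULL, beta_frac_thresh = 0.05,
                         enrich_quantile = 0.90) {
  drop <- setdiff(intersect(names(features), names(pseudotime)), "islet_id")
  df <- dplyr::left_join(pseudotime, features[, setdiff(names(features), drop)],
                         by = "islet_id")
  df$beta_frac <- df$n_beta / df$n_endocrine
  df$enrich <- (df$count_CD8T + df$count_macrophage_DC) / df$n_endocrine
  ref <- df$enrich[df$group == "nonT1D"]
  if (length(ref) == 0) ref <- df$enrich
  cutoff <- stats::quantile(ref, enrich_quantile, type = 7, names = FALSE)
  cl_stage <- df |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      beta_present = stats::median(.data$beta_frac) > beta_frac_thresh,
      inflamed = stats::median(.data$enrich) > cutoff) |>
    dplyr::mutate(stage = dplyr::case_when(
      !.data$beta_present ~ "InsulinDepleted",
      .data$inflamed ~ "Inflamed",
      TRUE ~ "Normal"))
  df$stage <- cl_stage$stage[match(df$cluster, cl_stage$cluster)]
  df$stage[df$n_beta == 0] <- "InsulinDepleted"

  if (is.null(cd8_thresh) || is.null(mac_thresh)) {
    normal <- df$stage == "Normal"
    if (!any(normal)) {
      stop("no Normal islets to calibrate thresholds; supply cd8_thresh and ",
           "mac_thresh explicitly", call. = FALSE)
    }
    if (is.null(cd8_thresh)) {
      cd8_thresh <- stats::quantile(df$count_CD8T[normal], 0.95, type = 7,
                                    names = FALSE)
    }
    if (is.null(mac_thresh)) {
      mac_thresh <- stats::quantile(df$count_macrophage_DC[normal], 0.95,
                                    type = 7, names = FALSE)
    }
  }
  idi <- df$stage == "InsulinDepleted" & df$count_CD8T > cd8_thresh &
    df$count_macrophage_DC > mac_thresh
  df$stage[idi] <- "InsulinDepletedImmune"
  out <- pseudotime
  out$stage <- df$stage
  attr(out, "thresholds") <- c(cd8 = cd8_thresh, mac = mac_thresh)
  attr(out, "root_id") <- attr(pseudotime, "root_id")
  attr(out, "connectivity") <- attr(pseudotime, "connectivity")
  out
}
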