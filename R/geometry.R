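#' Build a lobule partition as a clipped Voronoi tessellation
#'
#' Pancreatic lobules are emulated by the Voronoi tessellation of uniformly
#' placed seed points, clipped to the tissue rectangle: a space-filling,
#' irregular planar partition. The reserved label `"edge"` denotes
#' interlobular space; a Voronoi partition covers the tissue, so `"edge"` only
#' receives cells when a partition with gaps (e.g. from GeoJSON) is used.
#'
#' @param n_lobules Number of lobules (>= 1).
#' @param tissue_size Numeric length-2, tissue width and height in micrometres.
#' @param seed Integer seed for the seed-point layout.
#' @return A `lobule_partition`: list with `polygons` (named list of two-column
#'   x/y matrices, one ring per lobule), `lobule_id`, and `tissue_size`.
#' @export
make_lobule_partition <- function(n_lobules, tissue_size, seed = 1L) {
  if (length(tissue_size) != 2 || any(!is.finite(tissue_size)) ||
      any(tissue_size <= 0)) {
    stop("tissue_size must be two positive dimensions (um)", call. = FALSE)
  }
  if (!is.numeric(n_lobules) || n_lobules < 1) {
    stop("n_lobules must be >= 1", call. = FALSE)
  }
  n_lobules <- as.integer(n_lobules)
  w <- tissue_size[1]
  h <- tissue_size[2]
  ids <- paste0("lobule_", seq_len(n_lobules))
  if (n_lobules == 1L) {
    polys <- list(cbind(x = c(0, w, w, 0), y = c(0, 0, h, h)))
    names(polys) <- ids
    return(structure(list(polygons = polys, lobule_id = ids,
                          tissue_size = c(w, h)),
                     class = "lobule_partition"))
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  # margin keeps seed points off the clipping boundary
  sx <- stats::runif(n_lobules, 0.02 * w, 0.98 * w)
  sy <- stats::runif(n_lobules, 0.02 * h, 0.98 * h)
  dd <- deldir::deldir(sx, sy, rw = c(0, w, 0, h), suppressMsge = TRUE)
  tiles <- deldir::tile.list(dd)
  polys <- lapply(tiles, function(t) cbind(x = t$x, y = t$y))
  names(polys) <- ids[vapply(tiles, function(t) t$ptNum, 1L)]
  polys <- polys[ids]
  structure(list(polygons = polys, lobule_id = ids, tissue_size = c(w, h)),
            class = "lobule_partition")
}

#' Polygon area by the shoelace formula
#' @param poly Two-column x/y matrix (one ring, not closed).
#' @return Absolute area.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Even-odd point-in-polygon test
#'
#' Vectorised ray casting (even-odd rule) for one polygon ring. Points on an
#' edge follow the half-open crossing convention, so a planar partition assigns
#' boundary points to exactly one tile in almost all configurations.
#'
#' @param px,py Point coordinates.
#' @param poly Two-column x/y matrix.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (y[j] > py)) &
      (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Assign cells to lobules
#'
#' Point-in-polygon assignment of each cell to a lobule of the partition; cells
#' falling outside every polygon are assigned to the reserved `"edge"` label
#' (interlobular space). If `table` already carries `lobule_id` and
#' `partition` is `NULL`, the column is kept as-is.
#'
#' @param table Cell table with `x_um`, `y_um`.
#' @param partition A `lobule_partition`, or `NULL` to pass through an existing
#'   `lobule_id` column.
#' @return `table` with a `lobule_id` column.
#' @export
assign_lobules <- function(table, partition) {
  if (is.null(partition)) {
    if (!"lobule_id" %in% names(table)) {
      stop("no partition given and no lobule_id column present", call. = FALSE)
    }
    return(table)
  }
  stopifnot(inherits(partition, "lobule_partition"))
  for (p in partition$polygons) {
    if (nrow(p) < 3 || any(!is.finite(p))) {
      stop("malformed polygon in partition", call. = FALSE)
    }
  }
  lab <- rep("edge", nrow(table))
  unassigned <- rep(TRUE, nrow(table))
  for (id in names(partition$polygons)) {
    if (!any(unassigned)) break
    hit <- point_in_polygon(table$x_um[unassigned], table$y_um[unassigned],
                            partition$polygons[[id]])
    lab[which(unassigned)[hit]] <- id
    unassigned[which(unassigned)[hit]] <- FALSE
  }
  table$lobule_id <- lab
  table
}

#' Write a lobule partition as GeoJSON
#' @param partition A `lobule_partition`.
#' @param path Output file.
#' @export
write_partition_geojson <- function(partition, path) {
  feats <- lapply(names(partition$polygons), function(id) {
    p <- partition$polygons[[id]]
    ring <- rbind(p, p[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(lobule_id = id),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) as.numeric(ring[i, ])))))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a lobule partition from GeoJSON
#' @param path GeoJSON file with Polygon features carrying a `lobule_id`
#'   property.
#' @param tissue_size Optional tissue dimensions to record.
#' @return A `lobule_partition`.
#' @export
read_partition_geojson <- function(path, tissue_size = NULL) {
  gj <- jsonlite::read_json(path)
  polys <- list()
  for (f in gj$features) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    if (all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    colnames(m) <- c("x", "y")
    polys[[f$properties$lobule_id]] <- m
  }
  structure(list(polygons = polys, lobule_id = names(polys),
                 tissue_size = tissue_size),
            class = "lobule_partition")
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}
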