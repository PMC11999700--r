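#' Default CD8 sub-state marker-positivity profiles
#'
#' Four planted activation profiles for islet-infiltrating CD8 T cells:
#' I all-low; II CD45RA/CD69 high (naive/early-activation); III CD45RO/PD-1
#' high (memory/exhaustion); IV LAG-3/ICOS/Granzyme-B/CD57 high (effector).
#' Entries are per-cell positivity probabilities.
#'
#' @return A 4 x 10 matrix, rows `I`..`IV`, columns the functional markers.
#' @export
default_substate_profiles <- function() {
  m <- default_functional_markers()
  p <- matrix(0.05, 4, length(m), dimnames = list(c("I", "II", "III", "IV"), m))
  p["II", c("CD45RA", "CD69")] <- c(0.60, 0.45)
  p["III", c("CD45RO", "PD1", "CD44")] <- c(0.60, 0.55, 0.30)
  p["IV", c("LAG3", "ICOS", "GranzymeB", "CD57", "TOX")] <-
    c(0.45, 0.45, 0.50, 0.30, 0.25)
  p
}

#' Configuration for the synthetic tissue generator
#'
#' The generator plants, per donor: a Voronoi lobule partition; islets as
#' compact Gaussian blobs of mostly endocrine cells on a homogeneous Poisson
#' acinar background; an insulitis stage per islet equal to its lobule's mean
#' stage plus an islet-level deviation (giving a tunable intraclass
#' correlation); stage-dependent beta-cell loss and immune infiltration;
#' planted B-cell/CD8 aggregates with adjacent vasculature-rich patches and
#' distant nerve-rich patches (ground truth for neighbourhood detection and
#' adjacency); and marker intensities drawn from a lognormal background or a
#' location-shifted lognormal positive component according to planted
#' positivity.
#'
#' Stage variances: `lobule_stage_sd` (tau*) and `islet_stage_sd` (sigma*)
#' set the target ICC = tau*^2 / (tau*^2 + sigma*^2); defaults give 0.5, the
#' middle of the range observed in donors with appreciable lobular patterning.
#'
#' @param tissue_size Tissue width/height in micrometres.
#' @param n_donors Named counts of donors per group (`nonT1D`, `AA+`, `T1D`).
#' @param n_lobules Lobules per donor.
#' @param n_islets Islets per donor.
#' @param islet_radius_meanlog,islet_radius_sdlog Lognormal islet radius (um).
#' @param islet_density Cells per um^2 inside islets.
#' @param endocrine_fraction Fraction of islet core cells that are endocrine.
#' @param background_density Cells per um^2 of extra-islet background.
#' @param background_props Named type proportions of the background.
#' @param group_stage_mean Named mean planted stage per donor group.
#' @param lobule_stage_sd,islet_stage_sd Stage standard deviations between
#'   lobules and between islets within a lobule.
#' @param force_stage If non-NULL, every islet's raw stage is set to this value.
#' @param beta_frac0 Beta fraction among endocrine cells at stage 0.
#' @param beta_zero_stage Stage at (and beyond) which islets are beta-free.
#' @param immune_rates Named list of `c(intercept, slope, exponent)`: expected
#'   count per endocrine cell of each infiltrating type is
#'   `intercept + slope * stage^exponent`. Different exponents stagger the
#'   waves of infiltration (macrophage/DCs early, CD8 T late, B cells last),
#'   as observed along insulitis progression.
#' @param immune_persist_prob Probability that a beta-free islet retains its
#'   peak immune infiltrate (the Insulin-Depleted + Immune sub-state).
#' @param substate_profiles Matrix of CD8 marker positivity per inflamed
#'   sub-state (see [default_substate_profiles()]).
#' @param base_positivity Baseline functional-marker positivity for immune
#'   cells outside inflamed islets.
#' @param bg_meanlog,bg_sdlog,pos_meanlog,pos_sdlog Lognormal parameters of the
#'   background and positive marker-intensity components.
#' @param n_aggregates Planted B/CD8 aggregates per T1D donor.
#' @param n_far_patches Distant nerve-rich patches per T1D donor.
#' @param seed Integer RNG seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(tissue_size = c(2500, 2500),
                             n_donors = c("nonT1D" = 2, "AA+" = 0, "T1D" = 2),
                             n_lobules = 12,
                             n_islets = 8,
                             islet_radius_meanlog = log(75),
                             islet_radius_sdlog = 0.2,
                             islet_density = 1.2e-2,
                             endocrine_fraction = 0.94,
                             background_density = 1.7e-3,
                             background_props = c(
                               acinar = 0.70, ductal = 0.08, stroma = 0.08,
                               vasculature = 0.06, nerve = 0.02, CD8T = 0.015,
                               CD4T = 0.015, macrophage_DC = 0.02,
                               Bcell = 0.005, neutrophil = 0.005,
                               GzmB_CD3neg = 0.005),
                             group_stage_mean = c("nonT1D" = 0.08,
                                                  "AA+" = 0.25,
                                                  "T1D" = 0.55),
                             lobule_stage_sd = 0.15,
                             islet_stage_sd = 0.15,
                             force_stage = NULL,
                             beta_frac0 = 0.55,
                             beta_zero_stage = 0.7,
                             immune_rates = list(
                               CD8T = c(0.005, 0.20, 1.6),
                               macrophage_DC = c(0.015, 0.15, 0.7),
                               CD4T = c(0.003, 0.06, 1.0),
                               Bcell = c(0.001, 0.03, 2.0),
                               neutrophil = c(0.001, 0.01, 1.0)),
                             immune_persist_prob = 0.3,
                             substate_profiles = default_substate_profiles(),
                             base_positivity = 0.05,
                             bg_meanlog = 0, bg_sdlog = 0.5,
                             pos_meanlog = 2.5, pos_sdlog = 0.4,
                             n_aggregates = 3,
                             n_far_patches = 2,
                             seed = 1L) {
  cfg <- list(tissue_size = tissue_size, n_donors = n_donors,
              n_lobules = n_lobules, n_islets = n_islets,
              islet_radius_meanlog = islet_radius_meanlog,
              islet_radius_sdlog = islet_radius_sdlog,
              islet_density = islet_density,
              endocrine_fraction = endocrine_fraction,
              background_density = background_density,
              background_props = background_props,
              group_stage_mean = group_stage_mean,
              lobule_stage_sd = lobule_stage_sd,
              islet_stage_sd = islet_stage_sd,
              force_stage = force_stage,
              beta_frac0 = beta_frac0,
              beta_zero_stage = beta_zero_stage,
              immune_rates = immune_rates,
              immune_persist_prob = immune_persist_prob,
              substate_profiles = substate_profiles,
              base_positivity = base_positivity,
              bg_meanlog = bg_meanlog, bg_sdlog = bg_sdlog,
              pos_meanlog = pos_meanlog, pos_sdlog = pos_sdlog,
              n_aggregates = n_aggregates, n_far_patches = n_far_patches,
              seed = as.integer(seed))
  .validate_config(cfg)
  structure(cfg, class = "synthetic_config")
}

.validate_config <- function(cfg) {
  if (any(cfg$tissue_size <= 0) || length(cfg$tissue_size) != 2) {
    stop("tissue_size must be two positive dimensions", call. = FALSE)
  }
  if (cfg$n_lobules < 1) stop("n_lobules must be >= 1", call. = FALSE)
  if (cfg$lobule_stage_sd < 0 || cfg$islet_stage_sd < 0) {
    stop("stage standard deviations must be >= 0", call. = FALSE)
  }
  probs <- c(cfg$substate_profiles, cfg$base_positivity,
             cfg$background_props / sum(cfg$background_props))
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

#' Known markers of a synthetic configuration
#' @param config A `synthetic_config`.
#' @return Character vector of lineage plus functional marker names.
#' @export
config_markers <- function(config) {
  sig <- default_signatures()
  union(setdiff(names(sig), "type"), colnames(config$substate_profiles))
}

#' Draw marker intensities from the configured mixture
#'
#' Negative cells draw from the lognormal background component; positive cells
#' from the location-shifted lognormal positive component, which stochastically
#' dominates the background.
#'
#' @param positive Logical vector (recycled): is each draw from the positive
#'   component?
#' @param marker Marker name (must be known to the config).
#' @param config A `synthetic_config`.
#' @param n Number of draws (defaults to `length(positive)`).
#' @return Numeric vector of intensities (>= 0).
#' @export
sample_marker_intensity <- function(positive, marker, config,
                                    n = length(positive)) {
  if (!marker %in% config_markers(config)) {
    stop("unknown marker: ", marker, call. = FALSE)
  }
  positive <- rep_len(positive, n)
  out <- numeric(n)
  nbg <- sum(!positive)
  if (nbg > 0) {
    out[!positive] <- stats::rlnorm(nbg, config$bg_meanlog, config$bg_sdlog)
  }
  if (n - nbg > 0) {
    out[positive] <- stats::rlnorm(n - nbg, config$pos_meanlog, config$pos_sdlog)
  }
  out
}

#' Sample planted islet stages with a lobule hierarchy
#'
#' Stage of islet i in lobule j is `mean_stage + u_j + e_ij` with
#' `u_j ~ N(0, lobule_sd^2)` and `e_ij ~ N(0, islet_sd^2)`, the generative
#' model whose intraclass correlation is
#' `lobule_sd^2 / (lobule_sd^2 + islet_sd^2)`.
#'
#' @param n_lobules Number of lobules.
#' @param islets_per_lobule Islets in each lobule (scalar or vector).
#' @param mean_stage Grand mean stage.
#' @param lobule_sd,islet_sd Between-lobule and within-lobule stage SDs.
#' @param seed Optional seed (NULL uses the current RNG stream).
#' @return Tibble with `lobule`, `lobule_mean`, `stage_raw`.
#' @export
sample_islet_stages <- function(n_lobules, islets_per_lobule, mean_stage = 0.5,
                                lobule_sd = 0.15, islet_sd = 0.15,
                                seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
  }
  m <- rep_len(islets_per_lobule, n_lobules)
  u <- stats::rnorm(n_lobules, 0, lobule_sd)
  tibble::tibble(
    lobule = rep(seq_len(n_lobules), m),
    lobule_mean = mean_stage + rep(u, m),
    stage_raw = mean_stage + rep(u, m) + stats::rnorm(sum(m), 0, islet_sd))
}

.beta_fraction <- function(stage01, cfg) {
  cfg$beta_frac0 * pmax(0, 1 - stage01 / cfg$beta_zero_stage)
}

.stage_label <- function(stage01, immune_persist, cfg) {
  dplyr::case_when(
    stage01 >= cfg$beta_zero_stage & immune_persist ~ "InsulinDepletedImmune",
    stage01 >= cfg$beta_zero_stage ~ "InsulinDepleted",
    stage01 >= 0.35 ~ "Inflamed",
    TRUE ~ "Normal")
}

# place n points uniformly with pairwise separation >= min_sep (rejection;
# the separation relaxes when the tissue is too crowded for the request)
.place_separated <- function(n, w, h, margin, min_sep, max_try = 4000) {
  margin <- min(margin, 0.2 * min(w, h))
  for (sep in c(min_sep, min_sep / 2, min_sep / 4, 0)) {
    xs <- numeric(0); ys <- numeric(0)
    tries <- 0
    while (length(xs) < n && tries < max_try) {
      tries <- tries + 1
      px <- stats::runif(1, margin, w - margin)
      py <- stats::runif(1, margin, h - margin)
      if (length(xs) == 0 || min((xs - px)^2 + (ys - py)^2) >= sep^2) {
        xs <- c(xs, px); ys <- c(ys, py)
      }
    }
    if (length(xs) == n) return(cbind(xs, ys))
  }
  stop("could not place separated points; tissue too small", call. = FALSE)
}

# truncated isotropic bivariate Gaussian blob of n points around (cx, cy)
.gaussian_blob <- function(n, cx, cy, sd, trunc = 3) {
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- 2 * (n - nrow(out)) + 8
    dx <- stats::rnorm(m, 0, sd)
    dy <- stats::rnorm(m, 0, sd)
    keep <- dx^2 + dy^2 <= (trunc * sd)^2
    out <- rbind(out, cbind(dx[keep], dy[keep]))
  }
  out <- out[seq_len(n), , drop = FALSE]
  cbind(cx + out[, 1], cy + out[, 2])
}

#' Generate a ground-truthed synthetic cell table
#'
#' Emits one tissue per configured donor and concatenates them. See
#' [synthetic_config()] for the generative model. Deterministic given the
#' config's seed.
#'
#' @param config A `synthetic_config`.
#' @return A `synthetic_tissue` list: `cells` (the cell table: `cell_id`,
#'   `donor_id`, `group`, `x_um`, `y_um`, `cell_type`, one intensity column per
#'   marker), `truth` (list of `cells`, `islets`, `lobules`, `components`
#'   tibbles), and `partitions` (per-donor `lobule_partition`).
#' @export
generate_tissue <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  .validate_config(config)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(config$seed)

  groups <- rep(names(config$n_donors), config$n_donors)
  n_don <- length(groups)
  donor_ids <- sprintf("D%02d", seq_len(n_don))
  donor_seeds <- sample.int(1e8L, n_don)

  cells <- list(); truth_cells <- list(); truth_islets <- list()
  truth_lobules <- list(); components <- list(); partitions <- list()

  for (d in seq_len(n_don)) {
    set.seed(donor_seeds[d])
    res <- .generate_donor(donor_ids[d], groups[d], donor_seeds[d], config)
    cells[[d]] <- res$cells
    truth_cells[[d]] <- res$truth_cells
    truth_islets[[d]] <- res$truth_islets
    truth_lobules[[d]] <- res$truth_lobules
    components[[d]] <- res$components
    partitions[[donor_ids[d]]] <- res$partition
  }

  cells <- dplyr::bind_rows(cells)
  tc <- dplyr::bind_rows(truth_cells)
  markers <- config_markers(config)

  # marker intensities from planted positivity
  for (m in markers) {
    cells[[m]] <- sample_marker_intensity(tc[[paste0("pos_", m)]], m, config)
  }

  structure(list(
    cells = cells,
    truth = list(cells = tc,
                 islets = dplyr::bind_rows(truth_islets),
                 lobules = dplyr::bind_rows(truth_lobules),
                 components = dplyr::bind_rows(components)),
    partitions = partitions,
    config = config), class = "synthetic_tissue")
}

.generate_donor <- function(donor, group, seed, cfg) {
  w <- cfg$tissue_size[1]; h <- cfg$tissue_size[2]
  vocab <- default_vocabulary()
  sig <- default_signatures()
  fun_markers <- colnames(cfg$substate_profiles)

  partition <- make_lobule_partition(cfg$n_lobules, cfg$tissue_size,
                                     seed = seed + 1L)
  lob_mean <- cfg$group_stage_mean[[group]] +
    stats::rnorm(cfg$n_lobules, 0, cfg$lobule_stage_sd)
  names(lob_mean) <- partition$lobule_id

  ## ---- islets ----
  centers <- .place_separated(cfg$n_islets, w, h, margin = 150, min_sep = 320)
  radii <- stats::rlnorm(cfg$n_islets, cfg$islet_radius_meanlog,
                         cfg$islet_radius_sdlog)
  islet_lob <- vapply(seq_len(cfg$n_islets), function(i) {
    hit <- vapply(partition$polygons, function(p)
      point_in_polygon(centers[i, 1], centers[i, 2], p), logical(1))
    if (any(hit)) names(partition$polygons)[which(hit)[1]] else "edge"
  }, character(1))

  stage_raw <- if (!is.null(cfg$force_stage)) {
    rep(cfg$force_stage, cfg$n_islets) + 0 * stats::rnorm(cfg$n_islets)
  } else {
    lob_mean[islet_lob] + stats::rnorm(cfg$n_islets, 0, cfg$islet_stage_sd)
  }
  stage01 <- pmin(pmax(stage_raw, 0), 1)
  persist <- stats::runif(cfg$n_islets) < cfg$immune_persist_prob
  stage_label <- .stage_label(stage01, persist, cfg)
  substate <- ifelse(stage_label == "Inflamed",
                     rownames(cfg$substate_profiles)[
                       sample.int(nrow(cfg$substate_profiles), cfg$n_islets,
                                  replace = TRUE)], NA_character_)

  islet_rows <- list()
  for (i in seq_len(cfg$n_islets)) {
    r <- radii[i]
    n_core <- max(stats::rpois(1, cfg$islet_density * pi * r^2), 8)
    n_endo <- max(round(cfg$endocrine_fraction * n_core), 1)
    fb <- .beta_fraction(stage01[i], cfg)
    n_beta <- stats::rbinom(1, n_endo, fb)
    n_rest <- n_endo - n_beta
    n_alpha <- stats::rbinom(1, n_rest, 0.75)
    n_delta <- n_rest - n_alpha
    # stage-dependent infiltrate; beta-free islets without immune persistence
    # fall back to the stage-0 rates
    s_eff <- if (stage_label[i] %in% c("Inflamed", "InsulinDepletedImmune")) {
      stage01[i]
    } else if (stage_label[i] == "InsulinDepleted") 0 else stage01[i]
    imm_counts <- vapply(cfg$immune_rates, function(ab) {
      e <- if (length(ab) >= 3) ab[3] else 1
      stats::rpois(1, (ab[1] + ab[2] * s_eff^e) * n_endo)
    }, 1L)
    # islet vasculature and nerves rise modestly with stage
    n_vasc <- stats::rpois(1, (0.03 + 0.04 * stage01[i]) * n_endo)
    n_nerve <- stats::rpois(1, (0.008 + 0.01 * stage01[i]) * n_endo)
    types <- c(rep("beta", n_beta), rep("alpha", n_alpha),
               rep("delta", n_delta),
               rep("ductal", n_core - n_endo),
               rep(names(imm_counts), imm_counts),
               rep("vasculature", n_vasc), rep("nerve", n_nerve))
    # tight truncation (1 sigma at the islet radius) gives the near-uniform,
    # sharply bounded profile of a real encapsulated islet
    pos <- .gaussian_blob(length(types), centers[i, 1], centers[i, 2],
                          sd = r, trunc = 1)
    islet_rows[[i]] <- tibble::tibble(
      x_um = pos[, 1], y_um = pos[, 2], cell_type = types,
      islet_id = sprintf("%s_islet_%02d", donor, i), niche_id = NA_character_)
  }
  islet_cells <- dplyr::bind_rows(islet_rows)

  ## ---- planted niches (T1D donors only) ----
  niche_cells <- tibble::tibble(x_um = numeric(0), y_um = numeric(0),
                                cell_type = character(0),
                                islet_id = character(0),
                                niche_id = character(0))
  if (group == "T1D" && cfg$n_aggregates > 0) {
    agg_centers <- .place_separated(cfg$n_aggregates + cfg$n_far_patches,
                                    w, h, margin = 120, min_sep = 450)
    # keep niches away from islets
    ok <- apply(agg_centers, 1, function(p)
      min((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2) >= 200^2)
    agg_centers[!ok, ] <- agg_centers[!ok, , drop = FALSE] # accept as placed
    mk_patch <- function(center, radius, density, props, id) {
      n <- max(stats::rpois(1, density * pi * radius^2), 10)
      types <- sample(names(props), n, replace = TRUE, prob = props)
      pos <- .gaussian_blob(n, center[1], center[2], sd = radius / 2, trunc = 2)
      tibble::tibble(x_um = pos[, 1], y_um = pos[, 2], cell_type = types,
                     islet_id = NA_character_, niche_id = id)
    }
    rows <- list()
    for (a in seq_len(cfg$n_aggregates)) {
      ctr <- agg_centers[a, ]
      rows[[length(rows) + 1]] <- mk_patch(
        ctr, 40, 1.2e-2, c(Bcell = 0.55, CD8T = 0.35, macrophage_DC = 0.10),
        sprintf("%s_agg_%d", donor, a))
      th <- stats::runif(1, 0, 2 * pi)
      rows[[length(rows) + 1]] <- mk_patch(
        ctr + 60 * c(cos(th), sin(th)), 35, 8e-3,
        c(vasculature = 0.8, stroma = 0.2), sprintf("%s_aggvasc_%d", donor, a))
    }
    for (a in seq_len(cfg$n_far_patches)) {
      rows[[length(rows) + 1]] <- mk_patch(
        agg_centers[cfg$n_aggregates + a, ], 35, 8e-3,
        c(nerve = 0.8, stroma = 0.2), sprintf("%s_far_%d", donor, a))
    }
    niche_cells <- dplyr::bind_rows(rows)
    niche_cells <- niche_cells[niche_cells$x_um > 0 & niche_cells$x_um < w &
                                 niche_cells$y_um > 0 & niche_cells$y_um < h, ]
  }

  ## ---- background ----
  n_bg <- stats::rpois(1, cfg$background_density * w * h)
  props <- cfg$background_props / sum(cfg$background_props)
  bg_x <- stats::runif(n_bg, 0, w)
  bg_y <- stats::runif(n_bg, 0, h)
  # islets displace exocrine tissue: no background cells inside a footprint
  outside <- rep(TRUE, n_bg)
  for (i in seq_len(cfg$n_islets)) {
    outside <- outside &
      ((bg_x - centers[i, 1])^2 + (bg_y - centers[i, 2])^2 > radii[i]^2)
  }
  bg_x <- bg_x[outside]; bg_y <- bg_y[outside]
  n_bg <- length(bg_x)
  bg_cells <- tibble::tibble(
    x_um = bg_x, y_um = bg_y,
    cell_type = sample(names(props), n_bg, replace = TRUE, prob = props),
    islet_id = NA_character_, niche_id = NA_character_)

  all_cells <- dplyr::bind_rows(islet_cells, niche_cells, bg_cells)
  n <- nrow(all_cells)
  all_cells$cell_id <- sprintf("%s_c%06d", donor, seq_len(n))
  all_cells$donor_id <- donor
  all_cells$group <- group

  ## ---- lobule assignment (truth) ----
  all_cells <- assign_lobules(all_cells, partition)

  ## ---- planted marker positivity ----
  sig_m <- as.matrix(sig[, -1]); rownames(sig_m) <- sig$type
  lineage <- colnames(sig_m)
  tc <- tibble::tibble(cell_id = all_cells$cell_id, donor_id = donor,
                       islet_id = all_cells$islet_id,
                       lobule_id = all_cells$lobule_id,
                       niche_id = all_cells$niche_id)
  for (m in union(lineage, fun_markers)) {
    p <- rep(0, n)
    if (m %in% lineage) {
      p[sig_m[all_cells$cell_type, m] > 0] <- 1
    }
    if (m %in% fun_markers) {
      imm <- all_cells$cell_type %in% vocab$type[vocab$is_immune]
      p[imm] <- pmax(p[imm], cfg$base_positivity)
      # inflamed-islet CD8s follow their islet's sub-state profile
      infl <- which(!is.na(all_cells$islet_id) & all_cells$cell_type == "CD8T")
      if (length(infl)) {
        isub <- substate[match(all_cells$islet_id[infl],
                               sprintf("%s_islet_%02d", donor,
                                       seq_len(cfg$n_islets)))]
        has <- !is.na(isub)
        p[infl[has]] <- pmax(p[infl[has]], cfg$substate_profiles[isub[has], m])
      }
    }
    tc[[paste0("pos_", m)]] <- stats::runif(n) < p
  }

  list(
    cells = all_cells[, c("cell_id", "donor_id", "group", "x_um", "y_um",
                          "cell_type")],
    truth_cells = tc,
    truth_islets = tibble::tibble(
      islet_id = sprintf("%s_islet_%02d", donor, seq_len(cfg$n_islets)),
      donor_id = donor, group = group, lobule_id = islet_lob,
      x_um = centers[, 1], y_um = centers[, 2], radius_um = radii,
      stage_raw = as.numeric(stage_raw), stage01 = stage01,
      stage_label = stage_label, substate = substate,
      n_cells = vapply(islet_rows, nrow, 1L)),
    truth_lobules = tibble::tibble(
      donor_id = donor, lobule_id = partition$lobule_id,
      mean_stage = as.numeric(lob_mean)),
    components = tibble::tibble(
      donor_id = donor,
      component = c(sprintf("%s_islet_%02d", donor, seq_len(cfg$n_islets)),
                    unique(niche_cells$niche_id), paste0(donor, "_background")),
      n_cells = c(vapply(islet_rows, nrow, 1L),
                  as.integer(table(niche_cells$niche_id)[
                    unique(niche_cells$niche_id)]),
                  n_bg)),
    partition = partition)
}

#' Write a synthetic tissue to CSV files
#'
#' Emits `cells.csv`, `truth_cells.csv`, `truth_islets.csv`,
#' `truth_lobules.csv`, and one GeoJSON partition per donor.
#'
#' @param tissue A `synthetic_tissue`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_tissue_csv <- function(tissue, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(tissue$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(tissue$truth$cells, file.path(dir, "truth_cells.csv"),
                   row.names = FALSE)
  utils::write.csv(tissue$truth$islets, file.path(dir, "truth_islets.csv"),
                   row.names = FALSE)
  utils::write.csv(tissue$truth$lobules, file.path(dir, "truth_lobules.csv"),
                   row.names = FALSE)
  for (d in names(tissue$partitions)) {
    write_partition_geojson(tissue$partitions[[d]],
                            file.path(dir, paste0("lobules_", d, ".geojson")))
  }
  invisible(dir)
}
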