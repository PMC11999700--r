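# lobule assignment, extra-islet abundances, the ICC model, and the two- and
# three-level hierarchical models with Satterthwaite inference

fake_abundance <- function(lobules, islets) {
  structure(list(lobules = lobules, islets = islets,
                 excluded = tibble::tibble()),
            class = "lobular_abundance")
}

sim_two_level <- function(g1, J = 40, m = 10, tau = 1, sigma = 1,
                          donor = "D") {
  x <- rnorm(J)
  u <- rnorm(J, 0, tau)
  y <- g1 * rep(x, each = m) + rep(u, each = m) + rnorm(J * m, 0, sigma)
  fake_abundance(
    tibble::tibble(donor_id = donor, lobule_id = paste0("L", 1:J),
                   z_CD8T = x),
    tibble::tibble(islet_id = paste0(donor, "_i", 1:(J * m)),
                   donor_id = donor,
                   lobule_id = rep(paste0("L", 1:J), each = m),
                   pseudotime = y, pt_z = y))
}

sim_three_level <- function(g1 = 0.5, K = 5, J = 20, m = 8, tau = 1,
                            sigma = 1, slope_sd = 0) {
  ab <- lapply(1:K, function(k) {
    s <- sim_two_level(g1 + rnorm(1, 0, slope_sd), J, m, tau, sigma,
                       donor = paste0("D", k))
    s$islets$pt_z <- s$islets$pt_z + rnorm(1, 0, 0.3)
    s
  })
  fake_abundance(dplyr::bind_rows(lapply(ab, `[[`, "lobules")),
                 dplyr::bind_rows(lapply(ab, `[[`, "islets")))
}

test_that("cells map to lobules by point-in-polygon with an edge fallback", {
  p <- make_lobule_partition(6, c(500, 500), seed = 2)
  set.seed(71)
  cells <- make_cells(runif(400, 0, 500), runif(400, 0, 500),
                      rep("acinar", 400))
  out <- assign_lobules(cells, p)
  # oracle: winding-number test per polygon; first hit wins
  oracle <- rep("edge", nrow(cells))
  for (id in names(p$polygons)) {
    hit <- winding_pip(cells$x_um, cells$y_um, p$polygons[[id]]) &
      oracle == "edge"
    oracle[hit] <- id
  }
  expect_identical(out$lobule_id, oracle)
  # a point far outside every polygon is "edge"
  far <- assign_lobules(make_cells(1e4, 1e4, "acinar"), p)
  expect_equal(far$lobule_id, "edge")
  # GeoJSON round trip preserves assignment
  path <- tempfile(fileext = ".geojson")
  write_partition_geojson(p, path)
  p2 <- read_partition_geojson(path)
  expect_identical(assign_lobules(cells, p2)$lobule_id, out$lobule_id)
})

test_that("lobular abundance uses extra-islet cells over extra-islet acinar", {
  cells <- dplyr::bind_rows(
    make_cells(1:10 / 10, rep(1, 10), rep("CD8T", 10)),
    make_cells(1:100 / 10, rep(2, 100), rep("acinar", 100)),
    make_cells(1:5 / 10, rep(3, 5), rep("CD8T", 5)), # these sit in an islet
    make_cells(1:30 / 10 + 50, rep(1, 30), rep("acinar", 30)),
    make_cells(1:6 / 10 + 50, rep(2, 6), rep("CD8T", 6)))
  cells$cell_id <- sprintf("c%04d", seq_len(nrow(cells)))
  cells$lobule_id <- c(rep("L1", 115), rep("L2", 36))
  islets <- tibble::tibble(
    islet_id = "I1", donor_id = "D1",
    members = list(cells$cell_id[111:115]))
  pt <- tibble::tibble(islet_id = "I1", pseudotime = 0.4)
  cells$islet_id <- ifelse(cells$cell_id %in% cells$cell_id[111:115], "I1",
                           NA_character_)
  ab <- lobular_abundance(cells, islets, pt)
  l1 <- ab$lobules[ab$lobules$lobule_id == "L1", ]
  expect_equal(l1$raw_CD8T, 10 / 100) # islet CD8s omitted
  # within-donor z-scores have mean 0, sd 1 across lobules
  expect_equal(mean(ab$lobules$z_CD8T), 0, tolerance = 1e-12)
  expect_equal(sd(ab$lobules$z_CD8T), 1, tolerance = 1e-12)
  # islet linked to its lobule with its pseudotime
  expect_equal(ab$islets$lobule_id, "L1")

  # a lobule with no extra-islet acinar cells is excluded with a warning
  cells2 <- cells
  cells2$cell_type[cells2$lobule_id == "L2" &
                     cells2$cell_type == "acinar"] <- "stroma"
  expect_warning(ab2 <- lobular_abundance(cells2, islets, pt), "zero")
  expect_false("L2" %in% ab2$lobules$lobule_id)
})

test_that("ICC model recovers degenerate and simulated variance ratios", {
  # no within-lobule variance: ICC near 1
  df <- tibble::tibble(pseudotime = rep(1:10 / 10, each = 5) +
                         rnorm(50, 0, 1e-4),
                       lobule_id = rep(paste0("L", 1:10), each = 5),
                       donor_id = "D")
  expect_gte(fit_icc(df)$icc, 0.99)
  # equal lobule means: ICC near 0
  df2 <- tibble::tibble(pseudotime = rnorm(50),
                        lobule_id = rep(paste0("L", 1:10), each = 5),
                        donor_id = "D")
  df2$pseudotime <- df2$pseudotime - ave(df2$pseudotime, df2$lobule_id)
  expect_lte(fit_icc(df2)$icc, 0.01)

  # REML agrees with the one-way ANOVA moment estimator on a balanced design
  d <- sample_islet_stages(100, 20, 0.5, 1, 1, seed = 72)
  df3 <- tibble::tibble(pseudotime = d$stage_raw,
                        lobule_id = paste0("L", d$lobule), donor_id = "D")
  f <- fit_icc(df3)
  expect_lt(abs(f$icc - icc_anova(df3$pseudotime, df3$lobule_id)), 0.02)
  expect_gte(f$tau2, 0)
  expect_true(f$icc >= 0 && f$icc <= 1)

  expect_error(fit_icc(df3[df3$lobule_id == "L1", ]), "at least 2 lobules")
})

test_that("two-level slope equals OLS when tau^2 = 0 on a balanced design", {
  set.seed(73)
  ab <- sim_two_level(0.5, J = 30, m = 8, tau = 0)
  f <- fit_two_level_hlm(ab, "CD8T", donor = "D")
  df <- dplyr::inner_join(ab$islets, ab$lobules, by = c("donor_id",
                                                        "lobule_id"))
  ols <- coef(lm(pt_z ~ z_CD8T, df))[["z_CD8T"]]
  est <- tidy(f)$estimate[tidy(f)$term == "x"]
  expect_lt(abs(est - ols), 1e-6)
})

test_that("Satterthwaite df matches the balanced-design closed form", {
  set.seed(74)
  J <- 40
  ab <- sim_two_level(0.5, J = J, m = 10, tau = 1, sigma = 1)
  f <- fit_two_level_hlm(ab, "CD8T", donor = "D")
  t <- tidy(f)
  # lobule-level covariate in a balanced design: slope df = J - 2
  expect_lt(abs(t$df[t$term == "x"] - (J - 2)), 0.5)
  expect_equal(t$inference[t$term == "x"], "satterthwaite")

  one <- sim_two_level(0.5, J = 1, m = 10)
  expect_error(fit_two_level_hlm(one, "CD8T", donor = "D"), "inestimable|fewer")
  few <- sim_two_level(0.5, J = 3, m = 10)
  expect_error(fit_two_level_hlm(few, "CD8T", donor = "D"), "fewer than")
})

test_that("three-level model pools a shared slope and rejects bad designs", {
  set.seed(75)
  ab <- sim_three_level(0.5)
  f <- fit_three_level_hlm(ab, "CD8T")
  t <- tidy(f)
  expect_lt(abs(t$estimate[t$term == "x"] - 0.5), 0.2)
  expect_lt(t$p_value[t$term == "x"], 0.01)

  ab2 <- sim_three_level(0.5, K = 2)
  expect_error(fit_three_level_hlm(ab2, "CD8T"), "at least 3 donors")
  ab3 <- sim_three_level(0.5)
  ab3$lobules$z_CD8T <- 0
  expect_error(fit_three_level_hlm(ab3, "CD8T"), "constant")
})

test_that("tidy and glance expose the fit in broom style", {
  set.seed(76)
  f <- fit_two_level_hlm(sim_two_level(0.3), "CD8T", donor = "D")
  t <- tidy(f)
  expect_true(all(c("term", "estimate", "se", "df", "p_value") %in% names(t)))
  g <- glance(f)
  expect_equal(nrow(g), 1)
  expect_gte(g$tau2, 0)
  expect_gte(g$sigma2, 0)
})
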