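# CD8 marker frequencies of inflamed islets, sub-state clustering, and the
# islet-versus-swath enrichment tests

islet_with_cd8 <- function(n_cd8, pd1_pos, offset = 0, donor = "D1",
                           islet_tag = "A") {
  beta <- make_cells(seq(0, 45, 5) + offset, rep(0, 10), rep("beta", 10),
                     donor = donor)
  beta$cell_id <- paste0(beta$cell_id, "_", islet_tag)
  cd8 <- if (n_cd8 > 0) {
    cc <- make_cells(seq_len(n_cd8) * 4 + offset, rep(2, n_cd8),
                     rep("CD8T", n_cd8), donor = donor)
    cc$cell_id <- paste0("cd8_", islet_tag, "_", seq_len(n_cd8))
    cc
  } else NULL
  cells <- dplyr::bind_rows(beta, cd8)
  cells$pos_PD1 <- c(rep(FALSE, 10), if (n_cd8 > 0) pd1_pos else logical(0))
  cells
}

test_that("CD8 marker frequencies combine islet and 20 um band", {
  cells <- islet_with_cd8(4, c(TRUE, TRUE, FALSE, FALSE))
  isl <- extract_islets(cells, cells$cell_id[cells$cell_type == "beta"])
  stages <- tibble::tibble(islet_id = isl$islet_id, stage = "Inflamed")
  f <- cd8_marker_frequencies(isl, cells, stages, markers = "PD1")
  expect_equal(f$n_cd8, 4L)
  expect_equal(f$freq_PD1, 0.5)

  # CD8 at 15 um outside counted; at 30 um not
  far <- cells
  far$y_um[far$cell_id == "cd8_A_1"] <- 15
  far$y_um[far$cell_id == "cd8_A_2"] <- 30
  # cd8_A_2 (positive) drops out; remaining are one positive, two negative
  f2 <- cd8_marker_frequencies(isl, far, stages, markers = "PD1")
  expect_equal(f2$n_cd8, 3L)
  expect_equal(f2$freq_PD1, 1 / 3)

  # islet without CD8s is excluded and reported
  none <- islet_with_cd8(0, logical(0), offset = 500, islet_tag = "B")
  both <- dplyr::bind_rows(cells, none)
  isl2 <- extract_islets(both, both$cell_id[both$cell_type == "beta"])
  stages2 <- tibble::tibble(islet_id = isl2$islet_id, stage = "Inflamed")
  f3 <- cd8_marker_frequencies(isl2, both, stages2, markers = "PD1")
  expect_equal(nrow(f3), 1)
  expect_length(attr(f3, "excluded"), 1)

  expect_error(cd8_marker_frequencies(isl, cells,
                                      tibble::tibble(islet_id = isl$islet_id,
                                                     stage = "Normal"),
                                      markers = "PD1"),
               "no islets")
})

test_that("donor-pooled frequency equals the count-weighted islet mean", {
  a <- islet_with_cd8(4, c(TRUE, TRUE, TRUE, FALSE), islet_tag = "A")
  b <- islet_with_cd8(8, rep(c(TRUE, FALSE), 4), offset = 600,
                      islet_tag = "B")
  cells <- dplyr::bind_rows(a, b)
  isl <- extract_islets(cells, cells$cell_id[cells$cell_type == "beta"])
  stages <- tibble::tibble(islet_id = isl$islet_id, stage = "Inflamed")
  per <- cd8_marker_frequencies(isl, cells, stages, markers = "PD1")
  pooled <- cd8_islet_pooled_freq(isl, cells, stages, markers = "PD1")
  expect_equal(pooled$freq,
               sum(per$freq_PD1 * per$n_cd8) / sum(per$n_cd8))
})

test_that("sub-state clustering is deterministic and collapses identical rows", {
  ft <- tibble::tibble(islet_id = paste0("i", 1:40),
                       freq_PD1 = 0.3, freq_LAG3 = 0.1)
  cl <- cluster_substates(ft, n_neighbors = 10, seed = 1)
  expect_equal(length(unique(cl$substate)), 1)

  set.seed(51)
  ft2 <- tibble::tibble(islet_id = paste0("i", 1:60),
                        freq_PD1 = c(rbeta(30, 2, 20), rbeta(30, 20, 2)),
                        freq_LAG3 = runif(60, 0, 0.1))
  c1 <- cluster_substates(ft2, n_neighbors = 10, resolution = 0.05, seed = 2)
  c2 <- cluster_substates(ft2, n_neighbors = 10, resolution = 0.05, seed = 2)
  expect_identical(c1$substate, c2$substate)
  expect_equal(ari(c1$substate, rep(1:2, each = 30)), 1)
  expect_error(cluster_substates(ft2[1:5, ], n_neighbors = 10), "n_neighbors")
})

test_that("enrichment versus swaths: nulls, antisymmetry, planted signal", {
  donors <- paste0("D", 1:6)
  isletf <- tidyr::expand_grid(donor_id = donors, marker = "PD1")
  swathf <- tidyr::expand_grid(donor_id = donors, band = "0-25",
                               marker = "PD1")
  # identical frequencies: zero differences, test undefined
  isletf$freq <- 0.3; swathf$freq <- 0.3
  expect_warning(e0 <- enrichment_vs_swaths(isletf, swathf), "skipped")
  expect_true(is.na(e0$p_value))
  expect_equal(e0$mean_diff, 0)

  # planted islet-only marker: positive difference in every donor and the
  # smallest attainable exact signed-rank p for n = 6 (2 / 2^6)
  set.seed(52)
  isletf$freq <- 0.5 + runif(6, 0, 0.05); swathf$freq <- 0
  e1 <- enrichment_vs_swaths(isletf, swathf)
  expect_equal(e1$p_value, 2 / 2^6)
  expect_equal(e1$method, "exact")

  # swapping islet and band negates the differences
  swathf2 <- swathf; swathf2$freq <- isletf$freq
  isletf2 <- isletf; isletf2$freq <- 0
  e2 <- enrichment_vs_swaths(isletf2, dplyr::select(swathf2, donor_id, band,
                                                    marker, freq))
  expect_equal(e2$mean_diff, -e1$mean_diff)
  expect_equal(e2$p_value, e1$p_value)
})

test_that("signed-rank p-values match exact enumeration for small n", {
  set.seed(53)
  for (n in c(5, 8, 10)) {
    for (rep in 1:5) {
      d <- round(rnorm(n), 3)
      d <- d[d != 0]
      w <- wilcoxon_signed_rank(d)
      expect_equal(w$p_value, wilcox_exact_enum(d), tolerance = 1e-12)
    }
  }
})
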