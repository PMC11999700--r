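# composition windows, islet-region detection, islet extraction, composition
# features, and distance swaths

test_that("windows contain exactly the k nearest neighbours per donor", {
  # donor with exactly 21 cells: every window holds all other 20 cells
  set.seed(31)
  cells <- make_cells(runif(21, 0, 100), runif(21, 0, 100),
                      sample(c("alpha", "acinar"), 21, replace = TRUE))
  w <- compute_windows(cells, k = 20)
  expect_true(all(rowSums(w$comp) == 20))
  expect_equal(unname(w$comp[1, "Endocrine"] + w$comp[1, "acinar"]), 20)

  # 50 cells on a line: interior window = 10 on each side (brute oracle)
  line <- make_cells(1:50, rep(0, 50), rep("acinar", 50))
  wl <- compute_windows(line, k = 20)
  oracle <- brute_knn(line$x_um, line$y_um, 20)
  expect_equal(sort(oracle[25, ]), c(15:24, 26:35))
  expect_true(all(wl$comp[, "acinar"] == 20))

  expect_error(compute_windows(line[1:10, ], k = 20), "<= k")
})

test_that("windows merge endocrine types and never cross donors", {
  cells <- dplyr::bind_rows(
    make_cells(1:30, rep(0, 30), rep(c("alpha", "beta", "delta"), 10),
               donor = "A"),
    make_cells(1:30, rep(0, 30), rep("acinar", 30), donor = "B"))
  w <- compute_windows(cells, k = 5)
  expect_true(all(w$comp[w$donor_id == "A", "Endocrine"] == 5))
  expect_true(all(w$comp[w$donor_id == "B", "acinar"] == 5))
})

test_that("islet region detection handles the degenerate compositions", {
  set.seed(32)
  none <- make_cells(runif(300, 0, 500), runif(300, 0, 500),
                     rep("acinar", 300))
  w <- compute_windows(none, k = 10)
  expect_identical(detect_islet_region(w, n_clusters = 20), character(0))

  all_endo <- make_cells(runif(300, 0, 500), runif(300, 0, 500),
                         rep("beta", 300))
  w2 <- compute_windows(all_endo, k = 10)
  expect_setequal(detect_islet_region(w2, n_clusters = 20), all_endo$cell_id)
})

test_that("islet extraction is component-exact and enforces the 10-cell filter", {
  set.seed(33)
  # blob A: 10 cells, blob B: 9 cells, far apart
  xa <- rnorm(10, 0, 5); ya <- rnorm(10, 0, 5)
  xb <- rnorm(9, 500, 5); yb <- rnorm(9, 500, 5)
  cells <- make_cells(c(xa, xb), c(ya, yb), rep("beta", 19))
  isl <- extract_islets(cells, cells$cell_id)
  expect_equal(nrow(isl), 1)
  expect_equal(isl$n_cells, 10)

  # two 40-cell blobs -> exactly two islets matching the brute-force oracle
  x <- c(rnorm(40, 0, 10), rnorm(40, 800, 10))
  y <- c(rnorm(40, 0, 10), rnorm(40, 800, 10))
  cells2 <- make_cells(x, y, rep("alpha", 80))
  isl2 <- extract_islets(cells2, cells2$cell_id)
  expect_equal(nrow(isl2), 2)
  comp <- brute_components(x, y, 5)
  for (i in 1:2) {
    members <- match(isl2$members[[i]], cells2$cell_id)
    expect_equal(length(unique(comp[members])), 1)
  }
  # components are disjoint
  expect_equal(anyDuplicated(unlist(isl2$members)), 0)

  expect_equal(nrow(extract_islets(cells2, character(0))), 0)
})

test_that("composition features implement log1p(count / n_endocrine)", {
  # 10 endocrine members with 5 CD8 inside and an empty band
  cells <- make_cells(c(seq(0, 45, 5), 1:5 + 0.5), rep(0, 15),
                      c(rep("beta", 10), rep("CD8T", 5)))
  isl <- extract_islets(cells, cells$cell_id)
  expect_equal(isl$n_endocrine, 10)
  f <- islet_composition_features(isl, cells)
  expect_equal(f$feat_CD8T, log1p(5 / 10))
  expect_equal(f$feat_Bcell, 0) # zero count -> log1p(0) = 0

  # a CD8 cell 15 um outside the boundary is counted; at 30 um it is not
  near <- make_cells(c(seq(0, 45, 5), 20), c(rep(0, 10), 15),
                     c(rep("beta", 10), "CD8T"))
  isl_n <- extract_islets(near, near$cell_id[near$cell_type == "beta"])
  f_n <- islet_composition_features(isl_n, near)
  expect_equal(f_n$count_CD8T, 1L)
  far <- near; far$y_um[11] <- 30
  isl_f <- extract_islets(far, far$cell_id[far$cell_type == "beta"])
  f_f <- islet_composition_features(isl_f, far)
  expect_equal(f_f$count_CD8T, 0L)

  # adding one cell of a type strictly increases that type's feature
  plus <- dplyr::bind_rows(near, make_cells(25, 10, "CD8T") |>
                             dplyr::mutate(cell_id = "D1_extra"))
  isl_p <- extract_islets(plus, plus$cell_id[plus$cell_type == "beta"])
  f_p <- islet_composition_features(isl_p, plus)
  expect_gt(f_p$feat_CD8T, f_n$feat_CD8T)
})

test_that("band cells belonging to another islet are excluded from counts", {
  # two islets 100 um apart; a CD8 cell 15 um from islet A belongs to no islet
  # and is attributed to its nearest islet only
  cells <- dplyr::bind_rows(
    make_cells(seq(0, 45, 5), rep(0, 10), rep("beta", 10)),
    make_cells(seq(200, 245, 5), rep(0, 10), rep("alpha", 10)),
    make_cells(50, 15, "CD8T") |> dplyr::mutate(cell_id = "D1_q"))
  isl <- extract_islets(cells, cells$cell_id[cells$cell_type != "CD8T"])
  f <- islet_composition_features(isl, cells)
  expect_equal(sum(f$count_CD8T), 1L) # counted once, by the nearest islet
})

test_that("swath composition uses half-open bands and normalised fractions", {
  cells <- dplyr::bind_rows(
    make_cells(seq(0, 45, 5), rep(0, 10), rep("beta", 10)),
    make_cells(c(45 + 25, 45 + 30, 45 + 60), rep(0, 3),
               c("CD8T", "CD8T", "acinar")))
  isl <- extract_islets(cells, cells$cell_id[cells$cell_type == "beta"])
  sw <- swath_composition(isl, cells)
  # cell at exactly 25 um falls in the second band [25, 50)
  b2 <- sw[sw$band == "25-50", ]
  expect_equal(b2$n_cells, 2L)
  expect_equal(b2$frac_CD8T, 1)
  b1 <- sw[sw$band == "0-25", ]
  expect_true(b1$empty)
  b3 <- sw[sw$band == "50-100", ]
  frac_cols <- grep("^frac_", names(sw), value = TRUE)
  expect_equal(sum(b3[, frac_cols]), 1, tolerance = 1e-12)

  expect_error(swath_composition(isl, cells, bands = list(c(0, 30), c(25, 50))),
               "non-overlapping")
})
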