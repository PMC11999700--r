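# CN identification by over-cluster-and-merge naming, instance extraction,
# adjacency, and abundance contrasts

fake_windows <- function(comp, donor = "D1") {
  structure(list(cell_id = sprintf("c%04d", seq_len(nrow(comp))),
                 donor_id = rep(donor, nrow(comp)),
                 cell_type = rep("acinar", nrow(comp)),
                 comp = comp, types = colnames(comp), k = max(rowSums(comp))),
            class = "cell_windows")
}

test_that("cluster naming uses strict 80% presence and excludes acinar/ductal", {
  # one k-means cluster (n_clusters = 1): presence A 90%, B 81%, C 50%
  comp <- cbind(CD8T = as.integer(seq_len(100) <= 90),
                Bcell = as.integer(seq_len(100) <= 81),
                vasculature = as.integer(seq_len(100) <= 50))
  comp <- comp + 0L
  w <- fake_windows(comp)
  m <- identify_cns(w, n_clusters = 1, seed = 1)
  expect_equal(m$cluster_names, "Bcell|CD8T")

  # presence of exactly 80% is excluded (strictly greater than)
  comp2 <- cbind(CD8T = as.integer(seq_len(100) <= 90),
                 Bcell = as.integer(seq_len(100) <= 80))
  m2 <- identify_cns(fake_windows(comp2), n_clusters = 1, seed = 1)
  expect_equal(m2$cluster_names, "CD8T")

  # acinar and ductal never appear in names; empty names become background
  comp3 <- cbind(acinar = rep(1L, 100), ductal = rep(1L, 100))
  m3 <- identify_cns(fake_windows(comp3), n_clusters = 1, seed = 1)
  expect_equal(m3$cluster_names, "(background)")

  # the merged endocrine label is renamed Islet in CN names
  comp4 <- cbind(Endocrine = rep(1L, 100), acinar = rep(1L, 100))
  m4 <- identify_cns(fake_windows(comp4), n_clusters = 1, seed = 1)
  expect_equal(m4$cluster_names, "Islet")

  expect_error(identify_cns(fake_windows(comp), n_clusters = 1000), "exceeds")
})

test_that("same-name clusters merge and every cell gets exactly one CN", {
  set.seed(61)
  # two spatial groups with identical composition must merge into one CN
  comp <- cbind(CD8T = rep(1L, 200), Bcell = rep(c(1L, 0L), each = 100))
  w <- fake_windows(comp)
  m <- identify_cns(w, n_clusters = 4, seed = 2)
  expect_lte(length(m$cn_names), 4)
  expect_equal(nrow(m$assignment), 200)
  expect_false(anyNA(m$assignment$cn_label))
  cells <- make_cells(runif(200), runif(200), rep("acinar", 200))
  cells <- add_cn_labels(dplyr::mutate(cells, cell_id = w$cell_id), m)
  expect_false(anyNA(cells$cn_label))
})

test_that("CN instances are spatial connected components (oracle check)", {
  set.seed(62)
  x <- c(rnorm(30, 0, 5), rnorm(30, 300, 5), rnorm(40, 600, 5))
  y <- c(rnorm(30, 0, 5), rnorm(30, 300, 5), rnorm(40, 600, 5))
  cells <- make_cells(x, y, rep("CD8T", 100))
  cells$cn_label <- c(rep("A", 60), rep("B", 40))
  g <- build_spatial_graph(cells, k = 5)
  inst <- extract_cn_instances(cells, g)
  expect_equal(sum(inst$cn_label == "A"), 2) # two far-apart groups
  expect_equal(sum(inst$cn_label == "B"), 1)
  # instances partition the CN's cells
  expect_setequal(unlist(inst$members), cells$cell_id)
  expect_equal(anyDuplicated(unlist(inst$members)), 0)

  # a lone labelled cell is a singleton instance
  cells2 <- cells
  cells2$cn_label[1] <- "C"
  inst2 <- extract_cn_instances(cells2, build_spatial_graph(cells2, k = 5))
  expect_equal(inst2$n_cells[inst2$cn_label == "C"], 1L)
})

test_that("adjacency frequency matches a brute-force all-pairs oracle", {
  set.seed(63)
  # 3 source blobs; 2 have a dest blob in contact, 1 is isolated
  mk <- function(cx, cy, lab, n = 12) {
    cells <- make_cells(rnorm(n, cx, 4), rnorm(n, cy, 4), rep("CD8T", n))
    cells$cn_label <- lab
    cells
  }
  cells <- dplyr::bind_rows(
    mk(0, 0, "S"), mk(15, 0, "T"),
    mk(400, 0, "S"), mk(415, 0, "T"),
    mk(800, 0, "S"),
    mk(1200, 0, "T"))
  cells$cell_id <- sprintf("c%04d", seq_len(nrow(cells)))
  g <- build_spatial_graph(cells, k = 5)
  inst <- extract_cn_instances(cells, g)
  f <- adjacency_frequency(inst, g, "S", "T")
  expect_equal(f, 2 / 3)
  expect_equal(adjacency_frequency(inst, g, "S", "missing"), 0)
  expect_error(adjacency_frequency(inst, g, "missing", "T"), "undefined")

  # brute-force oracle: instances adjacent iff any cross-instance cell pair
  # is a k = 5 neighbour pair
  nn <- brute_knn(cells$x_um, cells$y_um, 5)
  edges <- unique(t(apply(cbind(rep(1:nrow(cells), 5), as.vector(nn)), 1,
                          sort)))
  inst_of <- setNames(rep(inst$instance_id, lengths(inst$members)),
                      unlist(inst$members))
  ia <- inst_of[cells$cell_id[edges[, 1]]]
  ib <- inst_of[cells$cell_id[edges[, 2]]]
  cn_of <- setNames(inst$cn_label, inst$instance_id)
  cross <- ia != ib
  adj_pairs <- unique(cbind(pmin(ia[cross], ib[cross]),
                            pmax(ia[cross], ib[cross])))
  src <- inst$instance_id[inst$cn_label == "S"]
  hit <- vapply(src, function(s) {
    any((adj_pairs[, 1] == s & cn_of[adj_pairs[, 2]] == "T") |
          (adj_pairs[, 2] == s & cn_of[adj_pairs[, 1]] == "T"))
  }, logical(1))
  expect_equal(f, mean(hit))

  # pair-level symmetry: S adjacent to T implies T adjacent to S
  am <- adjacency_matrix(inst, g)
  n_st <- am$frequency[am$source == "S" & am$dest == "T"] *
    sum(inst$cn_label == "S")
  n_ts <- am$frequency[am$source == "T" & am$dest == "S"] *
    sum(inst$cn_label == "T")
  expect_equal(n_st, 2) # both S instances touch one T each
  expect_equal(n_ts, 2)
  expect_true(all(am$frequency >= 0 & am$frequency <= 1))
})

test_that("CN abundance normalises by acinar count and ranks fold changes", {
  mk_donor <- function(d, grp, n_cn, n_acinar) {
    cells <- make_cells(runif(n_cn + n_acinar), runif(n_cn + n_acinar),
                        c(rep("CD8T", n_cn), rep("acinar", n_acinar)),
                        donor = d, group = grp)
    cells$cn_label <- c(rep("X", n_cn), rep("(background)", n_acinar))
    cells
  }
  cells <- dplyr::bind_rows(
    mk_donor("T1", "T1D", 50, 100), mk_donor("T2", "T1D", 60, 100),
    mk_donor("N1", "nonT1D", 10, 100), mk_donor("N2", "nonT1D", 15, 100))
  res <- cn_abundance_and_contrast(cells)
  ab <- res$abundance
  expect_equal(ab$abundance[ab$donor_id == "T1" & ab$cn_label == "X"], 0.5)
  x_row <- res$contrast[res$contrast$cn_label == "X", ]
  expect_equal(x_row$fold_change, mean(c(0.5, 0.6)) / mean(c(0.1, 0.15)))
  expect_equal(res$contrast$cn_label[1], "X") # enriched CN ranks first

  # identical abundances in both groups: fold 1, p = 1
  cells_eq <- dplyr::bind_rows(
    mk_donor("T1", "T1D", 50, 100), mk_donor("T2", "T1D", 50, 100),
    mk_donor("N1", "nonT1D", 50, 100), mk_donor("N2", "nonT1D", 50, 100))
  res_eq <- cn_abundance_and_contrast(cells_eq)
  x_eq <- res_eq$contrast[res_eq$contrast$cn_label == "X", ]
  expect_equal(x_eq$fold_change, 1)
  expect_equal(x_eq$p_value, 1)

  no_acinar <- mk_donor("T1", "T1D", 50, 100)
  no_acinar$cell_type <- "CD8T"
  expect_error(cn_abundance_and_contrast(no_acinar), "acinar")
})
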