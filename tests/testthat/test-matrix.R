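# Window matrices: tiling, construction, two-pass filter, clustering,
# merging.

test_that("window tiling is exact, half-open, last window short", {
  sizes <- data.table::data.table(chrom = c("c1", "c2"),
                                  size = c(1000000L, 1000001L))
  w <- make_windows(sizes, 250000L, "CH")
  expect_equal(sum(w$chrom == "c1"), 4L)
  expect_equal(sum(w$chrom == "c2"), 5L)
  last <- w[chrom == "c2"][5]
  expect_equal(last$end - last$start, 1L)
  for (cn in sizes$chrom) {
    sub <- w[chrom == cn]
    expect_equal(sub$start[1], 0L)
    expect_equal(sub$end[nrow(sub)], sizes[chrom == cn]$size)
    expect_true(all(sub$start[-1] == sub$end[-nrow(sub)]))  # no gaps
  }
})

test_that("matrix construction aggregates calls per cell-window", {
  calls <- data.table::data.table(
    barcode = c("c1", "c1", "c2"), chrom = "chr1",
    pos = c(10L, 20L, 1500L), strand = "+", context = "CH",
    state = c("methylated", "unmethylated", "methylated"))
  win <- make_windows(data.table::data.table(chrom = "chr1",
                                             size = 2000L), 1000L, "CH")
  m <- build_matrix(calls, win)
  expect_equal(m$meth_fraction["c1", 1], 0.5)
  expect_equal(m$site_count["c1", 1], 2L)
  expect_true(is.na(m$meth_fraction["c1", 2]))       # no calls
  expect_equal(m$site_count["c2", 2], 1L)
  expect_equal(sum(m$site_count), 3L)
  expect_error(build_matrix(calls,
                            make_windows(data.table::data.table(
                              chrom = "chr1", size = 2000L), 1000L, "CG")),
               "context")
})

test_that("matrix row means recover type-level global mCH", {
  cells <- data.table::data.table(
    cell_id = sprintf("c%03d", 1:60), species = "speciesA",
    type = rep(c("neuron_ex", "glia"), each = 30L))
  sc <- simulate_calls(tiny_genomes(), cells, default_cell_types(),
                       sites_per_cell = 3000L, context = "CH", seed = 4L)
  win <- make_windows(chrom_sizes(tiny_genomes()[1]), 2000L, "CH")
  m <- build_matrix(sc$calls, win)
  profs <- default_cell_types()
  for (ty in c("neuron_ex", "glia")) {
    rows <- cells[type == ty]$cell_id
    got <- mean(m$meth_fraction[rows, ], na.rm = TRUE)
    expect_lt(abs(got - profs[[ty]]$global_mch), 0.01, label = ty)
  }
})

test_that("the two-pass filter matches an exhaustive oracle", {
  # 4 x 4 toy with hand-set counts
  cnt <- matrix(c(25L, 25L, 25L, 25L,
                  25L, 25L, 25L,  0L,
                  25L, 25L,  0L,  0L,
                  0L,   0L,  0L,  0L), 4L, byrow = TRUE)
  m <- mk_mat(cnt)
  f <- filter_matrix(m, 20L, 0.75, 0.75)
  o <- oracle_filter(cnt, 20L, 0.75, 0.75)
  expect_equal(f$barcodes, pc("c", o$cells))
  expect_equal(f$windows$window_id, pc("w", o$windows))
  # random matrices, both CH and CG parameterizations
  set.seed(77)
  for (i in 1:8) {
    cnt <- matrix(stats::rpois(50 * 200, 12), 50L, 200L)
    m <- mk_mat(cnt)
    for (p in list(c(20, 0.75, 0.75), c(5, 0.25, 0.50))) {
      f <- filter_matrix(m, p[1], p[2], p[3])
      o <- oracle_filter(cnt, p[1], p[2], p[3])
      expect_equal(f$barcodes, pc("c", o$cells))
      expect_equal(f$windows$window_id, pc("w", o$windows))
    }
  }
})

test_that("filtering is an identity when coverage is saturated", {
  cnt <- matrix(50L, 6L, 5L)
  f <- filter_matrix(mk_mat(cnt), 20L, 0.75, 0.75)
  expect_equal(length(f$barcodes), 6L)
  expect_equal(nrow(f$windows), 5L)
})

test_that("raising min_sites never enlarges the retained sets", {
  set.seed(13)
  cnt <- matrix(stats::rpois(40 * 60, 15), 40L, 60L)
  m <- mk_mat(cnt)
  prev <- NULL
  for (ms in c(5L, 10L, 15L, 20L, 25L)) {
    f <- filter_matrix(m, ms, 0.5, 0.5)
    if (!is.null(prev)) {
      expect_lte(length(f$barcodes), length(prev$barcodes))
      expect_lte(nrow(f$windows), nrow(prev$windows))
      expect_true(all(f$barcodes %in% prev$barcodes))
    }
    prev <- f
  }
})

test_that("cells are judged on all windows, windows on retained cells", {
  # window 2 fails against all cells but passes against retained cells:
  # the pass-two denominator must be the retained set
  cnt <- matrix(c(25L, 25L,
                  25L, 25L,
                  25L, 25L,
                  0L,  0L,
                  0L,  0L), 5L, byrow = TRUE)
  f <- filter_matrix(mk_mat(cnt), 20L, 1.0, 0.8)
  expect_equal(f$barcodes, c("c1", "c2", "c3"))
  expect_equal(nrow(f$windows), 2L)       # 3/3 retained cells pass w2
  # judged against ALL cells w2 would fail (3/5 = 0.6 < 0.8); the
  # distinct outcome pins the pass ordering
  o_all <- mean(cnt[, 2] >= 20L)
  expect_lt(o_all, 0.8)
})

test_that("empty filter results are valid empty matrices", {
  cnt <- matrix(0L, 3L, 3L)
  f <- filter_matrix(mk_mat(cnt), 20L, 0.75, 0.75)
  expect_equal(length(f$barcodes), 0L)
  expect_equal(nrow(f$windows), 0L)
})

test_that("clustering recovers well-separated simulated types", {
  set.seed(3)
  cells <- data.table::data.table(
    cell_id = sprintf("c%03d", 1:90), species = "speciesA",
    type = rep(c("neuron_ex", "neuron_in", "glia"), each = 30L))
  sc <- simulate_calls(tiny_genomes(), cells, default_cell_types(),
                       sites_per_cell = 4000L, context = "CH", seed = 6L)
  win <- make_windows(chrom_sizes(tiny_genomes()[1]), 1000L, "CH")
  m <- filter_matrix(build_matrix(sc$calls, win), 20L, 0.75, 0.75)
  cr <- reduce_and_cluster(m, n_components = 50L, knn_k = 15L, seed = 2L)
  truth <- cells$type[match(names(cr$labels), cells$cell_id)]
  expect_gte(ari(cr$labels, truth), 0.9)
  # determinism
  cr2 <- reduce_and_cluster(m, n_components = 50L, knn_k = 15L, seed = 2L)
  expect_identical(cr$labels, cr2$labels)
  # labels are contiguous positive integers
  expect_setequal(unique(cr$labels), seq_len(max(cr$labels)))
})

test_that("identical rows collapse to a single cluster", {
  cnt <- matrix(30L, 12L, 6L)
  frac <- matrix(0.25, 12L, 6L)
  m <- mk_mat(cnt, frac)
  cr <- reduce_and_cluster(m, n_components = 5L, knn_k = 4L, seed = 1L)
  expect_equal(length(unique(cr$labels)), 1L)
})

test_that("SVD reconstruction error is non-increasing in components", {
  set.seed(10)
  x <- matrix(stats::runif(400), 20L)
  sv <- La.svd(sweep(x, 2, colMeans(x)))
  errs <- vapply(1:10, function(k) {
    approx <- sv$u[, 1:k, drop = FALSE] %*%
      diag(sv$d[1:k], k) %*% sv$vt[1:k, , drop = FALSE]
    sum((sweep(x, 2, colMeans(x)) - approx)^2)
  }, 0)
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("matrix merging concatenates without normalization", {
  set.seed(11)
  cnt1 <- matrix(stats::rpois(20, 30), 4L, 5L)
  cnt2 <- matrix(stats::rpois(15, 30), 3L, 5L)
  m1 <- mk_mat(cnt1)
  m2 <- mk_mat(cnt2)
  mm <- merge_matrices(list(a = m1, b = m2))
  expect_equal(length(mm$barcodes), 7L)
  expect_equal(mm$barcodes[1:4], paste0("a_c", 1:4))
  expect_equal(unname(mm$meth_fraction[5, ]),
               unname(m2$meth_fraction[1, ]))
  # mismatched window sets are fatal
  m3 <- mk_mat(matrix(1L, 2L, 4L))
  expect_error(merge_matrices(list(m1, m3)), "window sets differ")
})

test_that("merge then filter equals filter of pooled calls", {
  cells <- data.table::data.table(
    cell_id = sprintf("c%03d", 1:40), species = "speciesA",
    type = rep(c("neuron_ex", "glia"), 20L))
  sc <- simulate_calls(tiny_genomes(), cells, default_cell_types(),
                       sites_per_cell = 2000L, context = "CH", seed = 9L)
  win <- make_windows(chrom_sizes(tiny_genomes()[1]), 2000L, "CH")
  half <- cells$cell_id[1:20]
  m1 <- build_matrix(sc$calls[barcode %in% half], win)
  m2 <- build_matrix(sc$calls[!barcode %in% half], win)
  mm <- merge_matrices(list(x = m1, y = m2))
  fm <- filter_matrix(mm, 10L, 0.5, 0.5)
  pooled <- data.table::copy(sc$calls)
  pooled[, barcode := paste0(ifelse(barcode %in% half, "x_", "y_"),
                             barcode)]
  fp <- filter_matrix(build_matrix(pooled, win), 10L, 0.5, 0.5)
  expect_setequal(fm$barcodes, fp$barcodes)
  expect_equal(fm$windows$window_id, fp$windows$window_id)
  expect_equal(fm$meth_fraction[fp$barcodes, ],
               fp$meth_fraction[fp$barcodes, ])
})

test_that("batch-free batches mix within clusters", {
  cells <- data.table::data.table(
    cell_id = sprintf("c%03d", 1:80), species = "speciesA",
    type = rep(c("neuron_ex", "glia"), 40L))
  sc <- simulate_calls(tiny_genomes(), cells, default_cell_types(),
                       sites_per_cell = 3000L, context = "CH", seed = 14L)
  win <- make_windows(chrom_sizes(tiny_genomes()[1]), 2000L, "CH")
  half <- cells$cell_id[1:40]
  m1 <- build_matrix(sc$calls[barcode %in% half], win)
  m2 <- build_matrix(sc$calls[!barcode %in% half], win)
  mm <- filter_matrix(merge_matrices(list(b1 = m1, b2 = m2)),
                      10L, 0.5, 0.5)
  cr <- reduce_and_cluster(mm, n_components = 20L, knn_k = 10L, seed = 3L)
  batch <- sub("_.*$", "", names(cr$labels))
  for (cl in unique(cr$labels)) {
    tab <- table(batch[cr$labels == cl])
    p <- tab / sum(tab)
    ent <- -sum(p * log2(p))
    expect_gt(ent, 0.8)        # near-maximal (1 bit) batch mixing
  }
})

test_that("CG and CH pipelines recover the same major partition", {
  cells <- data.table::data.table(
    cell_id = sprintf("c%03d", 1:90), species = "speciesA",
    type = rep(c("neuron_ex", "neuron_in", "glia"), each = 30L))
  profs <- list(
    neuron_ex = cell_type_profile("neuron_ex", 0.06, 0.85),
    neuron_in = cell_type_profile("neuron_in", 0.04, 0.70),
    glia = cell_type_profile("glia", 0.005, 0.55))
  ch <- simulate_calls(tiny_genomes(), cells, profs,
                       sites_per_cell = 4000L, context = "CH", seed = 21L)
  cg <- simulate_calls(tiny_genomes(), cells, profs,
                       sites_per_cell = 3000L, context = "CG", seed = 22L)
  win_ch <- make_windows(chrom_sizes(tiny_genomes()[1]), 1000L, "CH")
  win_cg <- make_windows(chrom_sizes(tiny_genomes()[1]), 1000L, "CG")
  m_ch <- filter_matrix(build_matrix(ch$calls, win_ch), 20L, 0.75, 0.75)
  m_cg <- filter_matrix(build_matrix(cg$calls, win_cg), 5L, 0.25, 0.50)
  cr_ch <- reduce_and_cluster(m_ch, 50L, 15L, seed = 4L)
  cr_cg <- reduce_and_cluster(m_cg, 50L, 15L, seed = 4L)
  common <- intersect(names(cr_ch$labels), names(cr_cg$labels))
  expect_gte(partition_agreement(cr_cg$labels[common],
                                 cr_ch$labels[common]), 0.8)
})
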