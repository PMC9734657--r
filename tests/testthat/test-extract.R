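# Duplicate removal, methylation calling, call files, QC, TSS enrichment.

toy_aln <- function(...) {
  data.table::data.table(...)
}

test_that("dedup keeps one record per (barcode, chrom, start, strand)", {
  aln <- toy_aln(
    barcode = c("b1", "b1", "b1", "b2"),
    qname = c("r3", "r1", "r2", "r4"),
    chrom = "chr1", start = 100L, strand = "+",
    xg = "CT", seq = "ACGT")
  dd <- dedup(aln)
  expect_equal(nrow(dd$unique), 2L)                 # b1 once, b2 once
  expect_equal(sort(dd$unique$barcode), c("b1", "b2"))
  # deterministic tie-break: smallest read name wins
  expect_equal(dd$unique[barcode == "b1"]$qname, "r1")
  expect_equal(dd$cell_stats[barcode == "b1"]$unique_fraction, 1 / 3)
})

test_that("dedup is idempotent and order-invariant", {
  run <- small_run()
  al <- read_alignments(run$sim$files$truth_sam)$alignments
  dd1 <- dedup(al)
  set.seed(8)
  dd2 <- dedup(al[sample.int(nrow(al))])
  data.table::setkey(dd1$unique, qname)
  data.table::setkey(dd2$unique, qname)
  expect_equal(dd1$unique, dd2$unique)
  dd3 <- dedup(dd1$unique)
  expect_equal(nrow(dd3$unique), nrow(dd1$unique))
})

test_that("dedup matches the brute-force unique-key set and truth", {
  run <- small_run()
  al <- read_alignments(run$sim$files$truth_sam)$alignments
  al <- al[endsWith(qname, "_2")]                  # one end per molecule
  dd <- dedup(al)
  brute <- unique(al[, .(barcode, chrom, start, strand)])
  expect_equal(nrow(dd$unique), nrow(brute))
  got <- dd$unique[, .(barcode, chrom, start, strand)]
  data.table::setkey(got, barcode, chrom, start, strand)
  data.table::setkey(brute, barcode, chrom, start, strand)
  expect_equal(got, brute)
  # read-2 of an OT molecule starts at the fragment start; OB at the far
  # end -- reconstruct the truth keys and compare
  mol <- run$sim$molecules
  mol[, r2start := ifelse(xg == "CT", start, start + frag_len -
                            (run$design$read_length - 8L -
                               nchar(scmethpipe:::MOSAIC_END)))]
  truth_keys <- unique(mol[, .(barcode, chrom, r2start,
                               strand = ifelse(xg == "CT", "+", "-"))])
  expect_equal(nrow(dd$unique), nrow(truth_keys))
})

test_that("methylation calls follow conversion-strand logic", {
  g <- new_species_genome("toy", c(chr = "ACGT"))
  aln <- toy_aln(barcode = "b", qname = "r", chrom = "chr", start = 0L,
                 strand = "+", xg = "CT", seq = "ACGT")
  cl <- call_methylation(aln, g)
  expect_equal(cl[, .(pos, strand, context, state)],
               data.table::data.table(pos = 1L, strand = "+",
                                      context = "CG",
                                      state = "methylated"))
  aln$seq <- "ATGT"
  expect_equal(call_methylation(aln, g)$state, "unmethylated")
  g2 <- new_species_genome("toy2", c(chr = "ACAT"))
  aln2 <- toy_aln(barcode = "b", qname = "r", chrom = "chr", start = 0L,
                  strand = "+", xg = "CT", seq = "ACAT")
  cl2 <- call_methylation(aln2, g2)
  expect_equal(cl2[, .(pos, context, state)],
               data.table::data.table(pos = 1L, context = "CH",
                                      state = "methylated"))
  # bottom-strand logic: reference G positions, G = methylated
  aln3 <- toy_aln(barcode = "b", qname = "r", chrom = "chr", start = 0L,
                  strand = "-", xg = "GA", seq = "ACGT")
  cl3 <- call_methylation(aln3, g)
  expect_equal(cl3[, .(pos, strand, context, state)],
               data.table::data.table(pos = 2L, strand = "-",
                                      context = "CG",
                                      state = "methylated"))
  aln3$seq <- "ACAT"
  expect_equal(call_methylation(aln3, g)$state, "unmethylated")
  # sequencing error at a cytosine yields no call
  aln$seq <- "AGGT"
  expect_equal(nrow(call_methylation(aln, g)), 0L)
})

test_that("zero-noise calls equal truth states at every covered site", {
  run <- clean_run()
  al <- read_alignments(run$sim$files$truth_sam)$alignments
  al[, barcode := cell]            # compare per nucleus, not per barcode
  dd <- dedup(al)
  calls <- call_methylation(dd$unique, tiny_genomes())
  st <- run$sim$site_table
  j <- st[calls, on = c(cell_id = "barcode", "chrom", "pos", "strand"),
          nomatch = NA]
  expect_false(anyNA(j$state))            # every call is a truth site
  expect_true(all(j$state == j$i.state))
  expect_true(all(j$context == j$i.context))
  # both conversion strands are exercised
  expect_setequal(unique(calls$strand), c("+", "-"))
})

test_that("call contexts match the reference dinucleotide (oracle)", {
  run <- clean_run()
  al <- read_alignments(run$sim$files$truth_sam)$alignments
  calls <- call_methylation(al[1:200], tiny_genomes())
  set.seed(12)
  samp <- calls[sample.int(nrow(calls), 200L)]
  seqs <- c(tiny_genomes()[[1]]$chromosomes, tiny_genomes()[[2]]$chromosomes)
  ora <- vapply(seq_len(nrow(samp)), function(i) {
    ch <- strsplit(seqs[[samp$chrom[i]]], "")[[1]]
    p <- samp$pos[i] + 1L
    if (samp$strand[i] == "+") {
      if (p < length(ch) && ch[p + 1L] == "G") "CG" else "CH"
    } else {
      if (p > 1L && ch[p - 1L] == "C") "CG" else "CH"
    }
  }, character(1))
  expect_equal(samp$context, ora)
})

test_that("per-cell call files conserve counts in a fixed layout", {
  run <- clean_run()
  al <- read_alignments(run$sim$files$truth_sam)$alignments
  calls <- call_methylation(dedup(al)$unique, tiny_genomes())
  out <- file.path(tempdir(), "calldir")
  res <- extract_cells(calls, out)
  expect_equal(res$n_total, nrow(calls))
  expect_true(all(file.exists(res$files$path)))
  expect_setequal(unique(res$files$context), c("CG", "CH"))
  back <- read_call_dir(out)
  expect_equal(nrow(back), nrow(calls))
  # empty input still produces a valid layout
  res0 <- extract_cells(calls[0], file.path(tempdir(), "calldir0"))
  expect_equal(res0$n_total, 0L)
  expect_true(dir.exists(file.path(tempdir(), "calldir0", "CG")))
})

test_that("cell QC applies the read and global-mCH thresholds", {
  mk_calls <- function(bc, n_meth, n_tot) {
    data.table::data.table(
      barcode = bc, chrom = "chr1", pos = seq_len(n_tot), strand = "+",
      context = "CH",
      state = rep(c("methylated", "unmethylated"),
                  c(n_meth, n_tot - n_meth)))
  }
  calls <- rbind(mk_calls("pass", 5000L, 100000L),
                 mk_calls("fail_mch", 15000L, 100000L))
  calls <- rbind(calls, data.table::data.table(
    barcode = "fail_noch", chrom = "chr1", pos = 1:10, strand = "+",
    context = "CG", state = "methylated"))
  stats <- data.table::data.table(
    barcode = c("pass", "fail_mch", "fail_noch"),
    total_reads = 2000L, unique_reads = 1000L)
  qc <- cell_qc(calls, stats, min_unique_reads = 100L)
  expect_true(qc[barcode == "pass"]$pass_qc)
  expect_false(qc[barcode == "fail_mch"]$pass_qc)    # 15% >= 10%
  expect_false(qc[barcode == "fail_noch"]$pass_qc)   # undefined mCH
  expect_equal(qc[barcode == "pass"]$global_mch, 0.05)
  # insufficient reads fails too
  qc2 <- cell_qc(calls, stats, min_unique_reads = 5000L)
  expect_false(any(qc2$pass_qc))
})

test_that("TSS enrichment is calibrated on constructed coverage", {
  L <- 30000L
  w <- 50L
  base <- data.table::data.table(
    barcode = "b", chrom = "chr1",
    start = seq.int(0L, L - w, by = 1L), width = w)
  tss <- data.table::data.table(chrom = "chr1", pos = 15000L,
                                strand = "+")
  expect_equal(tss_enrichment(base, tss)$score, 1.0, tolerance = 1e-6)
  boost <- data.table::data.table(
    barcode = "b", chrom = "chr1",
    start = rep(15000L - 100L, w), width = 200L)
  expect_equal(tss_enrichment(rbind(base, boost), tss)$score, 2.0,
               tolerance = 1e-6)
  # signal window emptied, background untouched -> 0
  away <- base[start + w <= 14900L | start >= 15100L]
  expect_equal(tss_enrichment(away, tss)$score, 0.0)
  # zero background -> undefined
  only_tss <- data.table::data.table(barcode = "b", chrom = "chr1",
                                     start = 14950L, width = 100L)
  expect_true(is.na(tss_enrichment(only_tss, tss)$score))
})

test_that("TSS-enriched versus uniform coverage mirrors nucleosome QC", {
  set.seed(5)
  ann <- simulate_annotations(tiny_genomes()[1], n_genes = 10L, seed = 3L)
  tss <- ann$tss[, .(chrom, pos, strand)]
  L <- 20000L
  unif <- data.table::data.table(
    barcode = "b", chrom = tss$chrom[1],
    start = sample.int(L - 60L, 20000L, replace = TRUE), width = 50L)
  s_unif <- tss_enrichment(unif, tss)$score
  expect_lt(abs(s_unif - 1), 0.15)
  enriched <- rbind(unif, data.table::data.table(
    barcode = "b", chrom = tss$chrom,
    start = pmax(0L, tss$pos - 100L), width = 200L)[
      rep(seq_len(nrow(tss)), 200L)])
  expect_gt(tss_enrichment(enriched, tss)$score, 1.2)
})
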