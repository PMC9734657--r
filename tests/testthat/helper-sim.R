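# Shared fixtures, built once per test run.

# Small two-species genome pair (1 chromosome x 20 kb each).
tiny_genomes <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_genomes(1L, 20000L, 0.4, seed = 7L)
    cache
  }
})

# A small full sequencing run with mild noise.
small_run <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    des <- experiment_design(
      n_cells_per_species = c(speciesA = 30L, speciesB = 10L),
      events_per_well = 4L, n_tag_barcodes = 24L, reads_per_cell = 20L,
      duplicate_rate = 1.5, seed = 3L)
    tr <- assign_cells(des, default_cell_types())
    sim <- simulate_reads(tiny_genomes(), tr, default_cell_types(), des,
                          outdir = file.path(tempdir(), "small_run"))
    cache <<- list(design = des, truth = tr, sim = sim)
    cache
  }
})

# A zero-noise run: perfect conversion, no sequencing or index errors,
# no duplication.
clean_run <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    des <- experiment_design(
      n_cells_per_species = c(speciesA = 16L, speciesB = 8L),
      events_per_well = 3L, n_tag_barcodes = 16L, reads_per_cell = 25L,
      duplicate_rate = 1, barcode_error_rate = 0, seq_error_rate = 0,
      conversion_failure_rate = 0, overconversion_rate = 0, seed = 11L)
    tr <- assign_cells(des, default_cell_types())
    sim <- simulate_reads(tiny_genomes(), tr, default_cell_types(), des,
                          outdir = file.path(tempdir(), "clean_run"))
    cache <<- list(design = des, truth = tr, sim = sim)
    cache
  }
})

# Three cell types with block-structured CG methylomes: each type is
# strongly methylated in its own third of the genome and hypomethylated
# elsewhere (type-specific differentially methylated regions). Needed
# wherever within-type site-level concordance must exceed between-type
# concordance: types with flat site probabilities have no shared
# pattern for cells to agree on.
dmr_profiles <- function(genome, p_hi = 0.9, p_lo = 0.1) {
  chroms <- names(genome$chromosomes)
  mk_regions <- function(k) {
    data.table::rbindlist(lapply(chroms, function(cn) {
      L <- nchar(genome$chromosomes[[cn]])
      b <- floor(L / 3)
      data.table::data.table(
        chrom = cn, start = (k - 1L) * b,
        end = if (k == 3L) L else k * b,
        context = "CG", prob = p_hi)
    }))
  }
  nm <- c("neuron_ex", "neuron_in", "glia")
  out <- lapply(1:3, function(k) {
    cell_type_profile(nm[k], global_mch = c(0.06, 0.04, 0.005)[k],
                      global_mcg = p_lo, marker_regions = mk_regions(k))
  })
  stats::setNames(out, nm)
}

# Independent brute-force nearest-whitelist oracle used by demux tests.
oracle_correct <- function(observed, whitelist, max_hamming) {
  if (nchar(observed) != nchar(whitelist[1])) return("malformed")
  d <- vapply(whitelist, function(w) {
    sum(strsplit(observed, "")[[1]] != strsplit(w, "")[[1]])
  }, 0L)
  dmin <- min(d)
  if (dmin > max_hamming) return("no_match")
  if (sum(d == dmin) > 1L) return("ambiguous")
  whitelist[which.min(d)]
}

# Inject exactly k substitutions at distinct positions of a sequence.
inject_errors <- function(seqs, k) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_along(seqs), function(i) {
    ch <- strsplit(seqs[i], "")[[1]]
    if (k[i] > 0L) {
      at <- sample.int(length(ch), k[i])
      for (p in at) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    }
    paste(ch, collapse = "")
  }, character(1))
}

# Orientation-normalized genomic segment from a truth-SAM alignment row.
aln_fastq_view <- function(aln) {
  ifelse(aln$strand == "-", scmethpipe:::revcomp(aln$seq), aln$seq)
}

# Best-match agreement between two partitions: map each cluster of `a`
# to its majority cluster in `b` and measure the matched fraction.
partition_agreement <- function(a, b) {
  tab <- table(a, b)
  mapped <- colnames(tab)[max.col(tab, ties.method = "first")]
  mean(mapped[match(as.character(a), rownames(tab))] == as.character(b))
}

# Cluster labels: adjusted Rand index against truth (mclust oracle).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# brute-force reimplementation of the two-pass filter on raw counts
oracle_filter <- function(cnt, min_sites, cell_frac, window_frac) {
  pass <- cnt >= min_sites
  cells <- which(vapply(seq_len(nrow(cnt)), function(i)
    mean(pass[i, ]) >= cell_frac, TRUE))
  wins <- which(vapply(seq_len(ncol(cnt)), function(j)
    mean(pass[cells, j]) >= window_frac, TRUE))
  list(cells = cells, windows = wins)
}

# paste that keeps zero-length index sets zero-length
pc <- function(prefix, idx) {
  if (length(idx)) paste0(prefix, idx) else character(0)
}

mk_mat <- function(cnt, frac = NULL) {
  if (is.null(frac)) {
    frac <- matrix(stats::runif(length(cnt)), nrow(cnt))
    frac[cnt == 0] <- NA
  }
  win <- data.table::data.table(
    window_id = paste0("w", seq_len(ncol(cnt))), chrom = "chr1",
    start = (seq_len(ncol(cnt)) - 1L) * 1000L,
    end = seq_len(ncol(cnt)) * 1000L)
  scmethpipe:::new_window_matrix(frac, cnt, win,
                                 paste0("c", seq_len(nrow(cnt))),
                                 "CH", 1000L)
}

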