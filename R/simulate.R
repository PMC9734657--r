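# Synthetic sequencing-run simulator: molecules, bisulfite conversion,
# PCR duplication, index errors, FASTQ/SAM emission with recorded truth.

# Methylation probability per site for one cell-type profile, honouring
# marker-region overrides.
site_meth_prob <- function(profile, sites) {
  p <- ifelse(sites$context == "CG", profile$global_mcg,
              profile$global_mch)
  mr <- profile$marker_regions
  if (!is.null(mr) && nrow(mr)) {
    for (i in seq_len(nrow(mr))) {
      hit <- sites$chrom == mr$chrom[i] & sites$context == mr$context[i] &
        sites$pos >= mr$start[i] & sites$pos < mr$end[i]
      p[hit] <- mr$prob[i]
    }
  }
  p
}

# Random substitutions at `rate` per base; substituted base is uniform
# over the three alternatives.
mutate_bases <- function(x, rate) {
  if (rate <= 0 || !length(x)) return(x)
  n <- nchar(x)
  k <- stats::rbinom(length(x), n, rate)
  hit <- which(k > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    ch <- seq_chars(x[i])
    posn <- sample.int(n[i], k[i])
    for (p in posn) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    x[i] <- paste(ch, collapse = "")
  }
  x
}

# 10-base random-priming segment of H bases (A, C, T each 1/3).
h_randomers <- function(n, width = 10L) {
  m <- matrix(sample(c("A", "C", "T"), n * width, replace = TRUE),
              nrow = n)
  apply(m, 1L, paste, collapse = "")
}

#' Simulate a full sequencing run from an assigned cell population
#'
#' Generates, per nucleus, `reads_per_cell` unique molecules: a genomic
#' fragment drawn uniformly from the nucleus' species genome, assigned
#' with equal probability to the original-top (`CT`) or original-bottom
#' (`GA`) bisulfite conversion strand. True methylation states are drawn
#' once per (cell, site) from the cell type's profile, so duplicates and
#' overlapping molecules of one cell agree. Conversion is applied with
#' the design's failure/over-conversion rates (per molecule, so PCR
#' copies share conversion outcomes), then each molecule is emitted
#' `1 + Poisson(duplicate_rate - 1)` times with fresh sequencing errors.
#'
#' Read 1 starts with a 10-base H-composition randomer followed by
#' genomic bases in PBAT (complementary) orientation from the far end of
#' the fragment; read 2 starts with the 8-base tagmentation index, the
#' fixed 21-base mosaic-end segment, then genomic bases in directional
#' orientation; i5/i7 are emitted as separate index reads. Index segments
#' receive substitutions at `barcode_error_rate`, and an optional
#' `crosstalk_rate` reassigns a read pair's index segments to a random
#' other observed barcode.
#'
#' @param genomes list of `species_genome` objects (from [make_genomes()]).
#' @param truth a `sim_truth` from [assign_cells()].
#' @param profiles list of [cell_type_profile()]s covering all assigned
#'   types.
#' @param design the [experiment_design()]; must match `truth$design`
#'   scales.
#' @param outdir directory for output files; created if missing.
#' @param seed integer seed (defaults to `design$seed`).
#' @return a `sim_experiment` list: `truth` (cells/barcodes), `molecules`
#'   (molecule table with locus, conversion strand and copy counts),
#'   `site_table` (true state per covered (cell, site)), `files` (paths of
#'   R1/R2/I1/I2 FASTQ, truth SAM, reference FASTA, chrom.sizes, truth
#'   TSVs), `design`, `scheme`.
#' @export
simulate_reads <- function(genomes, truth, profiles, design,
                           outdir = tempfile("simrun"), seed = NULL) {
  if (is.null(seed)) seed <- design$seed
  g1 <- design$read_length - 10L
  g2 <- design$read_length - 8L - nchar(MOSAIC_END)
  if (g1 < 10L || g2 < 10L)
    stop_param("read_length too short for structural prefixes")
  flen <- g1 + g2 + 20L
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(derive_seed(seed, 53L))

  cells <- data.table::copy(truth$cells)
  prof_by_label <- stats::setNames(profiles,
                                   vapply(profiles, `[[`, "", "type_label"))
  if (!all(cells$type %in% names(prof_by_label)))
    stop_param("profiles do not cover all assigned cell types")

  ## -- molecule table -------------------------------------------------
  n_mol_per_cell <- design$reads_per_cell
  mol <- cells[rep(seq_len(.N), each = n_mol_per_cell),
               .(cell_id, species, type, barcode)]
  mol[, molecule_id := sprintf("m%07d", seq_len(.N))]
  # chromosome weighted by length, start uniform
  for (sp in names(genomes)) {
    g <- genomes[[sp]]
    lens <- nchar(g$chromosomes)
    idx <- which(mol$species == sp)
    ch <- sample(names(lens), length(idx), replace = TRUE,
                 prob = lens / sum(lens))
    mol[idx, chrom := ch]
    mol[idx, start_ := floor(stats::runif(length(idx)) *
                               (lens[ch] - flen))]
  }
  mol[, start_ := as.integer(start_)]
  mol[, xg := sample(c("CT", "GA"), .N, replace = TRUE)]
  mol[, n_copies := 1L + stats::rpois(.N, design$duplicate_rate - 1)]

  ## -- true site states per (cell, covered site) ----------------------
  site_table <- data.table::rbindlist(lapply(names(genomes), function(sp) {
    sites <- genomes[[sp]]$sites
    m <- mol[species == sp,
             .(molecule_id, cell_id, type, chrom, start_, xg)]
    if (!nrow(m)) return(NULL)
    m[, end_ := start_ + flen]
    m[, strand := ifelse(xg == "CT", "+", "-")]
    j <- sites[m, on = .(chrom, strand, pos >= start_, pos < end_),
               .(molecule_id = i.molecule_id, cell_id = i.cell_id,
                 type = i.type, chrom, pos = x.pos, strand = x.strand,
                 context = x.context), nomatch = NULL]
    j
  }))
  mol_sites <- site_table
  site_table <- unique(site_table[, .(cell_id, type, chrom, pos, strand,
                                      context)])
  p <- numeric(nrow(site_table))
  for (ty in unique(site_table$type)) {
    idx <- which(site_table$type == ty)
    p[idx] <- site_meth_prob(prof_by_label[[ty]], site_table[idx])
  }
  site_table[, state := ifelse(stats::runif(.N) < p,
                               "methylated", "unmethylated")]

  ## -- conversion outcome per molecule-site (shared by PCR copies) ----
  ms <- site_table[mol_sites,
                   on = .(cell_id, chrom, pos, strand, context),
                   .(molecule_id, chrom, pos, strand, state)]
  ms <- mol[, .(molecule_id, start_, xg)][ms, on = "molecule_id"]
  u <- stats::runif(nrow(ms))
  meth <- ms$state == "methylated"
  keep_c <- (meth & u >= design$overconversion_rate) |
    (!meth & u < design$conversion_failure_rate)
  ms[, read_base := data.table::fifelse(
    xg == "CT", data.table::fifelse(keep_c, "C", "T"),
    data.table::fifelse(keep_c, "G", "A"))]
  ms[, relpos := pos - start_ + 1L]

  ## -- converted fragment sequences -----------------------------------
  frag <- character(nrow(mol))
  for (sp in names(genomes)) {
    chroms <- genomes[[sp]]$chromosomes
    for (cn in names(chroms)) {
      idx <- which(mol$chrom == cn)
      if (length(idx))
        frag[idx] <- substring(chroms[[cn]], mol$start_[idx] + 1L,
                               mol$start_[idx] + flen)
    }
  }
  conv <- split(ms[, .(relpos, read_base)],
                factor(ms$molecule_id, levels = mol$molecule_id))
  frag_chars <- strsplit(frag, "", fixed = TRUE)
  for (i in seq_along(frag_chars)) {
    cv <- conv[[i]]
    if (!is.null(cv) && nrow(cv))
      frag_chars[[i]][cv$relpos] <- cv$read_base
  }
  frag <- vapply(frag_chars, paste, character(1), collapse = "")

  ## -- expand copies, lay out read pairs -------------------------------
  reads <- mol[rep(seq_len(.N), n_copies)]
  reads[, copy := seq_len(.N), by = molecule_id]
  reads[, read_id := paste0("sim.", sub("^m", "", molecule_id), ".", copy)]
  fragr <- rep(frag, mol$n_copies)
  is_ot <- reads$xg == "CT"
  r1_seg <- ifelse(is_ot, substring(fragr, flen - g1 + 1L, flen),
                   substring(fragr, 1L, g1))
  r2_seg <- ifelse(is_ot, substring(fragr, 1L, g2),
                   substring(fragr, flen - g2 + 1L, flen))
  r1_pos <- ifelse(is_ot, reads$start_ + flen - g1, reads$start_)
  r2_pos <- ifelse(is_ot, reads$start_, reads$start_ + flen - g2)
  r1_strand <- ifelse(is_ot, "-", "+")
  r2_strand <- ifelse(is_ot, "+", "-")
  r1_seg <- mutate_bases(r1_seg, design$seq_error_rate)
  r2_seg <- mutate_bases(r2_seg, design$seq_error_rate)

  ## -- emitted barcodes (crosstalk + index errors) ----------------------
  bc <- truth$barcodes
  reads[, true_barcode := barcode]
  reads[, obs_barcode := barcode]
  if (design$crosstalk_rate > 0 && nrow(bc) > 1L) {
    swap <- which(stats::runif(nrow(reads)) < design$crosstalk_rate)
    if (length(swap)) {
      other <- sample(bc$barcode, length(swap), replace = TRUE)
      # avoid self-assignment so the swap is a genuine crosstalk event
      same <- other == reads$obs_barcode[swap]
      while (any(same)) {
        other[same] <- sample(bc$barcode, sum(same), replace = TRUE)
        same <- other == reads$obs_barcode[swap]
      }
      reads[swap, obs_barcode := other]
    }
  }
  reads[, `:=`(i5 = bc$i5[match(obs_barcode, bc$barcode)],
               i7 = bc$i7[match(obs_barcode, bc$barcode)],
               tag = bc$tag[match(obs_barcode, bc$barcode)])]
  i1 <- mutate_bases(reads$i5, design$barcode_error_rate)
  i2 <- mutate_bases(reads$i7, design$barcode_error_rate)
  tagobs <- mutate_bases(reads$tag, design$barcode_error_rate)

  ## -- FASTQ emission ---------------------------------------------------
  orient <- function(seg, strand) {
    out <- seg
    neg <- strand == "-"
    if (any(neg)) out[neg] <- revcomp(seg[neg])
    out
  }
  r1_fastq <- paste0(h_randomers(nrow(reads)), orient(r1_seg, r1_strand))
  r2_fastq <- paste0(tagobs, MOSAIC_END, orient(r2_seg, r2_strand))
  files <- list(
    r1 = file.path(outdir, "R1.fastq.gz"),
    r2 = file.path(outdir, "R2.fastq.gz"),
    i1 = file.path(outdir, "I1.fastq.gz"),
    i2 = file.path(outdir, "I2.fastq.gz"),
    truth_sam = file.path(outdir, "truth.sam"),
    reference = file.path(outdir, "reference.fa"),
    chrom_sizes = file.path(outdir, "reference.chrom.sizes"),
    cells = file.path(outdir, "truth_cells.tsv"),
    barcodes = file.path(outdir, "truth_barcodes.tsv"),
    molecules = file.path(outdir, "truth_molecules.tsv"),
    site_table = file.path(outdir, "truth_sites.tsv")
  )
  write_fastq(r1_fastq, reads$read_id, files$r1)
  write_fastq(r2_fastq, reads$read_id, files$r2)
  write_fastq(i1, reads$read_id, files$i1)
  write_fastq(i2, reads$read_id, files$i2)
  write_genomes(genomes, files$reference, files$chrom_sizes)

  ## -- truth SAM --------------------------------------------------------
  sam <- data.table::data.table(
    qname = c(paste0(reads$read_id, "_1"), paste0(reads$read_id, "_2")),
    flag = c(ifelse(r1_strand == "-", 16L, 0L),
             ifelse(r2_strand == "-", 16L, 0L)),
    chrom = rep(reads$chrom, 2L),
    pos = c(r1_pos, r2_pos) + 1L,
    seq_ = c(r1_seg, r2_seg),
    xg = rep(reads$xg, 2L),
    barcode = rep(reads$obs_barcode, 2L),
    cell = rep(reads$cell_id, 2L),
    mate = rep(c(1L, 2L), each = nrow(reads))
  )
  write_truth_sam(sam, chrom_sizes(genomes), files$truth_sam)

  molecules <- mol[, .(molecule_id, cell_id, barcode, chrom,
                       start = start_, frag_len = flen, xg, n_copies)]
  data.table::fwrite(truth$cells, files$cells, sep = "\t")
  data.table::fwrite(truth$barcodes, files$barcodes, sep = "\t")
  data.table::fwrite(molecules, files$molecules, sep = "\t")
  data.table::fwrite(site_table, files$site_table, sep = "\t")

  structure(list(truth = truth, molecules = molecules,
                 site_table = site_table, files = files,
                 design = design, scheme = truth$scheme,
                 read_geometry = list(g1 = g1, g2 = g2, frag_len = flen)),
            class = "sim_experiment")
}

#' Simulate methylation calls directly (no read-level noise)
#'
#' Fast generator for matrix/clustering/similarity analyses: per cell,
#' samples `sites_per_cell` cytosine sites without replacement from its
#' species genome (optionally restricted by context) and draws the true
#' methylation state from the cell type's profile. The emitted calls
#' equal the truth states, i.e. the generator models perfect conversion
#' and calling; read-level noise belongs to [simulate_reads()].
#'
#' @param genomes list of `species_genome`s.
#' @param cells `data.table` with `cell_id`, `species`, `type` (e.g.
#'   `truth$cells` from [assign_cells()], or any hand-built table).
#' @param profiles list of [cell_type_profile()]s.
#' @param sites_per_cell number of sites sampled per cell.
#' @param context "CG", "CH" or "both".
#' @param seed integer seed.
#' @return list with `calls` (barcode, chrom, pos, strand, context,
#'   state; barcode = cell_id) and `truth` (same table, the generator is
#'   noise-free).
#' @export
simulate_calls <- function(genomes, cells, profiles, sites_per_cell = 2000L,
                           context = c("both", "CG", "CH"), seed = 1L) {
  context <- match.arg(context)
  ctx_sel <- context
  set.seed(derive_seed(seed, 71L))
  prof_by_label <- stats::setNames(profiles,
                                   vapply(profiles, `[[`, "", "type_label"))
  calls <- data.table::rbindlist(lapply(seq_len(nrow(cells)), function(i) {
    g <- genomes[[cells$species[i]]]
    sites <- g$sites
    if (ctx_sel != "both") sites <- sites[sites[["context"]] == ctx_sel]
    n <- min(sites_per_cell, nrow(sites))
    s <- sites[sample.int(nrow(sites), n)]
    p <- site_meth_prob(prof_by_label[[cells$type[i]]], s)
    s[, state := ifelse(stats::runif(.N) < p, "methylated",
                        "unmethylated")]
    s[, barcode := cells$cell_id[i]]
    s
  }))
  data.table::setcolorder(calls, c("barcode", "chrom", "pos", "strand",
                                   "context", "state"))
  list(calls = calls, truth = calls)
}

#' Simulated gene/TSS/motif annotations for a genome set
#'
#' Places `n_genes` non-overlapping gene bodies per genome uniformly at
#' random with alternating strand, derives TSS positions, and scatters
#' `n_motifs` motif centers. Intended for exercising TSS enrichment,
#' region methylation and motif profiling on synthetic runs.
#'
#' @param genomes list of `species_genome`s.
#' @param n_genes genes per genome.
#' @param gene_length gene body length in bases.
#' @param n_motifs motif centers per genome.
#' @param seed integer seed.
#' @return list of `data.table`s: `genes` (chrom, start, end, name,
#'   strand), `tss` (chrom, pos, strand, name), `motifs` (chrom, center,
#'   strand, name). All coordinates 0-based.
#' @export
simulate_annotations <- function(genomes, n_genes = 50L,
                                 gene_length = 2000L, n_motifs = 100L,
                                 seed = 1L) {
  set.seed(derive_seed(seed, 89L))
  sizes <- chrom_sizes(genomes)
  genes <- data.table::rbindlist(lapply(seq_len(nrow(sizes)), function(i) {
    L <- sizes$size[i]
    n <- max(1L, round(n_genes * L / sum(sizes$size)))
    slots <- floor(L / (2L * gene_length))
    n <- min(n, slots)
    at <- sort(sample.int(slots, n)) - 1L
    data.table::data.table(
      chrom = sizes$chrom[i],
      start = at * 2L * gene_length,
      end = at * 2L * gene_length + gene_length,
      name = sprintf("%s_g%03d", sizes$chrom[i], seq_len(n)),
      strand = rep(c("+", "-"), length.out = n))
  }))
  tss <- genes[, .(chrom, pos = ifelse(strand == "+", start, end - 1L),
                   strand, name)]
  motifs <- data.table::rbindlist(lapply(seq_len(nrow(sizes)), function(i) {
    L <- sizes$size[i]
    n <- max(1L, round(n_motifs * L / sum(sizes$size)))
    data.table::data.table(
      chrom = sizes$chrom[i],
      center = sort(sample.int(L - 1200L, n)) + 600L,
      strand = sample(c("+", "-"), n, replace = TRUE),
      name = sprintf("%s_m%03d", sizes$chrom[i], seq_len(n)))
  }))
  list(genes = genes, tss = tss, motifs = motifs)
}
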