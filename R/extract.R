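# Barcode-aware duplicate removal, per-cytosine methylation calling,
# per-cell call files, QC and TSS enrichment.

#' Barcode-aware PCR duplicate removal
#'
#' Keeps exactly one alignment per (barcode, chrom, start, strand) key --
#' the duplicate key is the alignment start alone, appropriate for
#' randomly primed bisulfite libraries where fragment ends are
#' unreliable. The retained record is the one with the lexicographically
#' smallest read name, making the result invariant to input order.
#'
#' @param alignments alignment `data.table` (see [read_alignments()]).
#' @return list with `unique` (retained alignments), and `cell_stats`
#'   per barcode: `total_reads`, `unique_reads`, `unique_fraction`.
#' @export
dedup <- function(alignments) {
  dt <- data.table::as.data.table(alignments)
  data.table::setorder(dt, chrom, start, strand, barcode, qname)
  uni <- dt[!duplicated(dt, by = c("barcode", "chrom", "start", "strand"))]
  stats <- dt[, .(total_reads = .N), by = barcode][
    uni[, .(unique_reads = .N), by = barcode], on = "barcode"]
  stats[, unique_fraction := unique_reads / total_reads]
  list(unique = uni, cell_stats = stats[])
}

# Flatten one or more species genomes into a chromosome lookup.
chrom_lookup <- function(genome) {
  if (is(genome, "species_genome")) genome <- list(genome)
  seqs <- unlist(lapply(genome, `[[`, "chromosomes"))
  names(seqs) <- unlist(lapply(genome, function(g) names(g$chromosomes)))
  seqs
}

#' Call per-cytosine methylation from conversion-tagged alignments
#'
#' For `XG:Z:CT` (original-top) alignments, every reference cytosine
#' covered by the read yields a call: read base `C` is methylated, `T`
#' unmethylated, anything else (sequencing error) gives no call. For
#' `XG:Z:GA` (original-bottom) the mirrored logic applies at reference
#' `G` positions (`G` methylated, `A` unmethylated) and the site is
#' recorded on the minus strand. Context is always derived from the
#' reference dinucleotide: CG when the next base on the site's own
#' strand is `G`, otherwise CH (CHG and CHH merged).
#'
#' @param alignments alignment `data.table` with `barcode`, `chrom`,
#'   `start` (0-based), `xg`, `seq` (reference-forward orientation).
#' @param genome one `species_genome` or a list of them covering all
#'   chromosomes.
#' @return `data.table` of calls: `barcode`, `chrom`, `pos` (0-based,
#'   the cytosine on its own strand), `strand`, `context`, `state`.
#' @export
call_methylation <- function(alignments, genome) {
  seqs <- chrom_lookup(genome)
  aln <- data.table::as.data.table(alignments)
  bad <- !aln$chrom %in% names(seqs)
  if (any(bad)) stop_param("alignments on chromosomes absent from genome")
  out <- vector("list", length(unique(aln$chrom)))
  k <- 0L
  for (cn in unique(aln$chrom)) {
    refc <- seq_chars(seqs[[cn]])
    sub <- aln[chrom == cn]
    res <- vector("list", nrow(sub))
    for (i in seq_len(nrow(sub))) {
      s0 <- sub$start[i]                    # 0-based
      rd <- seq_chars(sub$seq[i])
      L <- length(rd)
      if (s0 + L > length(refc)) next
      win <- refc[(s0 + 1L):(s0 + L)]
      if (sub$xg[i] == "CT") {
        at <- which(win == "C")
        if (!length(at)) next
        base <- rd[at]
        state <- ifelse(base == "C", "methylated",
                        ifelse(base == "T", "unmethylated", NA))
        pos <- s0 + at - 1L
        nxt <- ifelse(pos + 2L <= length(refc), refc[pos + 2L], "")
        ctx <- ifelse(nxt == "G", "CG", "CH")
        strandv <- "+"
      } else {
        at <- which(win == "G")
        if (!length(at)) next
        base <- rd[at]
        state <- ifelse(base == "G", "methylated",
                        ifelse(base == "A", "unmethylated", NA))
        pos <- s0 + at - 1L
        prv <- ifelse(pos >= 1L, refc[pmax(pos, 1L)], "")
        ctx <- ifelse(prv == "C", "CG", "CH")
        strandv <- "-"
      }
      ok <- !is.na(state)
      if (!any(ok)) next
      res[[i]] <- data.table::data.table(
        barcode = sub$barcode[i], chrom = cn, pos = pos[ok],
        strand = strandv, context = ctx[ok], state = state[ok])
    }
    k <- k + 1L
    out[[k]] <- data.table::rbindlist(res)
  }
  calls <- data.table::rbindlist(out[seq_len(k)])
  if (!nrow(calls))
    calls <- data.table::data.table(barcode = character(),
                                    chrom = character(), pos = integer(),
                                    strand = character(),
                                    context = character(),
                                    state = character())
  calls[]
}

#' Split methylation calls into per-context, per-chromosome files
#'
#' Writes the deterministic layout `{context}/{chrom}.tsv`, each file
#' sorted by (barcode, pos); total written rows conserve the input call
#' count.
#'
#' @param calls call `data.table` from [call_methylation()].
#' @param outdir output directory.
#' @return list with `files` (data.table: context, chrom, path, n_calls)
#'   and `n_total`.
#' @export
extract_cells <- function(calls, outdir) {
  for (ctx in c("CG", "CH"))
    dir.create(file.path(outdir, ctx), showWarnings = FALSE,
               recursive = TRUE)
  calls <- data.table::as.data.table(calls)
  idx <- list()
  if (nrow(calls)) {
    grp <- calls[, .N, by = .(context, chrom)]
    for (i in seq_len(nrow(grp))) {
      sub <- calls[context == grp$context[i] & chrom == grp$chrom[i]]
      data.table::setorder(sub, barcode, pos)
      path <- file.path(outdir, grp$context[i],
                        paste0(grp$chrom[i], ".tsv"))
      data.table::fwrite(sub, path, sep = "\t")
      idx[[i]] <- data.table::data.table(
        context = grp$context[i], chrom = grp$chrom[i], path = path,
        n_calls = nrow(sub))
    }
  }
  files <- data.table::rbindlist(idx)
  list(files = files,
       n_total = if (nrow(files)) sum(files$n_calls) else 0L)
}

#' Read back a per-context call directory written by [extract_cells()]
#' @param outdir directory with `{context}/{chrom}.tsv` files.
#' @param context optional context filter.
#' @return call `data.table`.
#' @export
read_call_dir <- function(outdir, context = c("CG", "CH")) {
  paths <- unlist(lapply(intersect(context, dir(outdir)), function(ctx) {
    list.files(file.path(outdir, ctx), pattern = "\\.tsv$",
               full.names = TRUE)
  }))
  if (!length(paths)) return(data.table::data.table())
  data.table::rbindlist(lapply(paths, data.table::fread))
}

#' Per-cell QC profiles and pass/fail flags
#'
#' A cell passes QC iff it has at least `min_unique_reads` unique reads
#' and a global CH methylation fraction strictly below `max_global_mch`
#' (incomplete bisulfite conversion inflates apparent mCH, so high-mCH
#' cells are conversion failures rather than biology -- except in
#' neurons, whose true mCH still sits well below the 10% default). Cells
#' with zero CH calls have undefined global mCH and fail.
#'
#' @param calls call `data.table`.
#' @param cell_stats per-barcode read stats from [dedup()] (needs
#'   `barcode`, `unique_reads`, `total_reads`).
#' @param min_unique_reads minimal unique read count (the coverage
#'   threshold is experiment-dependent; no default is claimed).
#' @param max_global_mch maximal global mCH fraction (default 0.10).
#' @return `data.table`, one row per barcode: read counts, global
#'   mCG/mCH, covered site counts, `pass_qc`.
#' @export
cell_qc <- function(calls, cell_stats, min_unique_reads,
                    max_global_mch = 0.10) {
  calls <- data.table::as.data.table(calls)
  prof <- calls[, .(
    global_mch = sum(state == "methylated" & context == "CH") /
      max(1L, sum(context == "CH")),
    global_mcg = sum(state == "methylated" & context == "CG") /
      max(1L, sum(context == "CG")),
    n_ch_calls = sum(context == "CH"),
    n_cg_calls = sum(context == "CG"),
    covered_cg_sites = data.table::uniqueN(
      paste0(chrom, ":", pos)[context == "CG"]),
    covered_ch_sites = data.table::uniqueN(
      paste0(chrom, ":", pos)[context == "CH"])
  ), by = barcode]
  prof[cell_stats, on = "barcode",
       `:=`(unique_reads = i.unique_reads, total_reads = i.total_reads)]
  prof[is.na(unique_reads), `:=`(unique_reads = 0L, total_reads = 0L)]
  prof[, global_mch := ifelse(n_ch_calls > 0L, global_mch, NA_real_)]
  prof[, global_mcg := ifelse(n_cg_calls > 0L, global_mcg, NA_real_)]
  prof[, pass_qc := !is.na(global_mch) & global_mch < max_global_mch &
         unique_reads >= min_unique_reads]
  prof[]
}

#' TSS enrichment score of a library
#'
#' Signal is the mean per-base read coverage in the 200 bp window
#' centered on each TSS; background is the mean over two 200 bp windows
#' whose centers sit `background_offset` (default 1000) bp up- and
#' downstream of the TSS. The score is pooled signal / pooled
#' background. Shotgun-like uniform coverage scores ~1; intact-chromatin
#' tagmentation scores above 1, and effective nucleosome disruption
#' brings the score back to ~1 or below.
#'
#' @param alignments alignment `data.table` (`chrom`, `start`, `seq` or
#'   `width`).
#' @param tss `data.table` with `chrom`, `pos` (0-based TSS), `strand`.
#' @param half_width half of the signal window (default 100).
#' @param background_offset distance from TSS to background window
#'   centers (default 1000).
#' @return list with `score` (NA when background coverage is zero),
#'   `signal_mean`, `background_mean`, `n_tss`.
#' @export
tss_enrichment <- function(alignments, tss, half_width = 100L,
                           background_offset = 1000L) {
  if (!nrow(tss)) stop_param("at least one TSS required")
  aln <- data.table::as.data.table(alignments)
  if (!"width" %in% names(aln)) aln[, width := nchar(seq)]
  sig_sum <- 0; sig_n <- 0; bg_sum <- 0; bg_n <- 0
  for (cn in unique(tss$chrom)) {
    sub <- aln[chrom == cn]
    tsub <- tss[chrom == cn]
    cov <- IRanges::coverage(
      IRanges::IRanges(start = sub$start + 1L, width = sub$width))
    cov_len <- length(cov)
    win_mean <- function(centers, hw) {
      st <- pmax(1L, centers - hw + 1L)
      en <- pmin(cov_len, centers + hw)
      keep <- en >= st
      if (!any(keep)) return(c(0, 0))
      v <- IRanges::Views(cov, start = st[keep], end = en[keep])
      c(sum(IRanges::viewSums(v)), sum(en[keep] - st[keep] + 1L))
    }
    # windows are half-open [center - hw, center + hw) in 0-based
    # coordinates; the formulas below are 1-based inclusive
    centers0 <- tsub$pos
    s <- win_mean(centers0, half_width)
    b1 <- win_mean(centers0 - background_offset, half_width)
    b2 <- win_mean(centers0 + background_offset, half_width)
    sig_sum <- sig_sum + s[1]; sig_n <- sig_n + s[2]
    bg_sum <- bg_sum + b1[1] + b2[1]; bg_n <- bg_n + b1[2] + b2[2]
  }
  signal_mean <- if (sig_n > 0) sig_sum / sig_n else NA_real_
  background_mean <- if (bg_n > 0) bg_sum / bg_n else NA_real_
  score <- if (!is.na(background_mean) && background_mean > 0)
    signal_mean / background_mean else NA_real_
  list(score = score, signal_mean = signal_mean,
       background_mean = background_mean, n_tss = nrow(tss))
}
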