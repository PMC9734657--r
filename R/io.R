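# File formats: FASTQ (gz), truth/alignment SAM, BED, whitelists,
# matrix import/export.

#' Write sequences as (gzipped) FASTQ with constant quality
#' @param seqs character vector of sequences.
#' @param names read names.
#' @param path output path; `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, names, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names
  Biostrings::writeXStringSet(
    x, path, format = "fastq", compress = grepl("\\.gz$", path),
    qualities = Biostrings::BStringSet(strrep("I", nchar(seqs))))
  invisible(path)
}

#' Read a FASTQ file into a data.table
#' @param path FASTQ path (optionally gzipped).
#' @return `data.table` with `name` (full header) and `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = FALSE)
  data.table::data.table(name = names(x), seq = as.character(x))
}

# SAM emission for simulator truth alignments. One line per read;
# SEQ in reference-forward orientation, FLAG 16 for reverse-strand.
write_truth_sam <- function(sam, sizes, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", sizes$chrom, sizes$size))
  body <- sprintf(
    "%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tXG:Z:%s\tCB:Z:%s\tXI:Z:%s",
    sam$qname, sam$flag, sam$chrom, sam$pos, nchar(sam$seq_), sam$seq_,
    strrep("I", nchar(sam$seq_)), sam$xg, sam$barcode, sam$cell)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read aligned reads from a SAM file into an alignment table
#'
#' Parses the mandatory SAM columns plus the `XG` conversion-strand tag
#' (`CT`/`GA`, bismark convention) and the cell barcode, taken from a
#' `CB:Z:` tag when present, else from the read-name prefix before the
#' first `:`. Unmapped records (flag 0x4 or `*` reference) are dropped
#' and counted.
#'
#' @param path SAM path (plain text).
#' @return list with `alignments` (`data.table`: `barcode`, `qname`,
#'   `chrom`, `start` 0-based, `strand`, `xg`, `seq`) and `stats`
#'   (`n_records`, `n_unmapped`, `n_missing_xg`).
#' @export
read_alignments <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(list(alignments = data.table::data.table(
      barcode = character(), qname = character(), chrom = character(),
      start = integer(), strand = character(), xg = character(),
      seq = character()),
      stats = list(n_records = 0L, n_unmapped = 0L, n_missing_xg = 0L)))
  }
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE, keep = 1:10)
  dt <- data.table::data.table(
    qname = f[[1]], flag = as.integer(f[[2]]), chrom = f[[3]],
    pos = as.integer(f[[4]]), seq = f[[10]])
  xg <- sub(".*\tXG:Z:([A-Z]+).*", "\\1", lines)
  xg[!grepl("\tXG:Z:", lines, fixed = TRUE)] <- NA_character_
  cb <- sub(".*\tCB:Z:([^\t]+).*", "\\1", lines)
  cb[!grepl("\tCB:Z:", lines, fixed = TRUE)] <- NA_character_
  xi <- sub(".*\tXI:Z:([^\t]+).*", "\\1", lines)
  xi[!grepl("\tXI:Z:", lines, fixed = TRUE)] <- NA_character_
  dt[, xg := xg]
  dt[, cell := xi]
  dt[, barcode := data.table::fifelse(is.na(cb),
                                      sub(":.*$", "", qname), cb)]
  n_rec <- nrow(dt)
  unmapped <- bitwAnd(dt$flag, 4L) != 0L | dt$chrom == "*"
  dt <- dt[!unmapped]
  miss_xg <- is.na(dt$xg)
  dt <- dt[!miss_xg]
  aln <- dt[, .(barcode, cell, qname, chrom, start = pos - 1L,
                strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
                xg, seq)]
  list(alignments = aln,
       stats = list(n_records = n_rec, n_unmapped = sum(unmapped),
                    n_missing_xg = sum(miss_xg)))
}

#' Read/write one-sequence-per-line whitelists
#' @param path text file, one barcode per line.
#' @return character vector.
#' @export
read_whitelist <- function(path) {
  wl <- readLines(path)
  wl[nzchar(wl)]
}

#' @rdname read_whitelist
#' @param whitelist character vector of barcodes.
#' @export
write_whitelist <- function(whitelist, path) {
  writeLines(whitelist, path)
  invisible(path)
}

#' Read a BED-like annotation file
#'
#' Minimal BED reader: columns chrom, start, end, then optional name,
#' score, strand. Missing strand defaults to `+`.
#'
#' @param path BED path.
#' @return `data.table` with `chrom`, `start`, `end`, `name`, `strand`.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE)
  data.table::setnames(dt, seq_len(ncol(dt)),
                       c("chrom", "start", "end", "name", "score",
                         "strand")[seq_len(ncol(dt))])
  if (!"name" %in% names(dt)) dt[, name := paste0("r", .I)]
  if (!"strand" %in% names(dt)) dt[, strand := "+"]
  dt[, .(chrom, start = as.integer(start), end = as.integer(end),
         name = as.character(name), strand)]
}

#' @rdname read_bed
#' @param regions `data.frame` with chrom, start, end, optional name and
#'   strand.
#' @export
write_bed <- function(regions, path) {
  dt <- data.table::as.data.table(regions)
  if (!"name" %in% names(dt)) dt[, name := paste0("r", .I)]
  if (!"strand" %in% names(dt)) dt[, strand := "+"]
  data.table::fwrite(dt[, .(chrom, start, end, name, score = 0L, strand)],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Export / import a window matrix
#'
#' Writes the methylation-fraction and site-count matrices as MatrixMarket
#' sparse files with sidecar window BED and barcode list, the layout the
#' clustering step and cross-experiment merging consume.
#'
#' @param m a `window_matrix`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_window_matrix <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  frac <- m$meth_fraction
  frac[is.na(frac)] <- 0
  Matrix::writeMM(methods::as(Matrix::Matrix(frac, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "meth_fraction.mtx"))
  Matrix::writeMM(methods::as(Matrix::Matrix(m$site_count, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "site_count.mtx"))
  write_bed(m$windows[, .(chrom, start, end, name = window_id)],
            file.path(dir, "windows.bed"))
  writeLines(m$barcodes, file.path(dir, "barcodes.txt"))
  writeLines(c(paste0("context\t", m$context),
               paste0("window_size\t", m$window_size)),
             file.path(dir, "meta.tsv"))
  invisible(dir)
}

#' @rdname write_window_matrix
#' @export
read_window_matrix <- function(dir) {
  frac <- as.matrix(Matrix::readMM(file.path(dir, "meth_fraction.mtx")))
  cnt <- as.matrix(Matrix::readMM(file.path(dir, "site_count.mtx")))
  frac[cnt == 0] <- NA_real_
  windows <- read_bed(file.path(dir, "windows.bed"))
  data.table::setnames(windows, "name", "window_id")
  meta <- data.table::fread(file.path(dir, "meta.tsv"), header = FALSE)
  new_window_matrix(
    meth_fraction = frac, site_count = cnt,
    windows = windows[, .(window_id, chrom, start, end)],
    barcodes = readLines(file.path(dir, "barcodes.txt")),
    context = meta$V2[meta$V1 == "context"],
    window_size = as.integer(meta$V2[meta$V1 == "window_size"]))
}
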