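# Three-index demultiplexing with hamming-distance correction and
# structural trimming.

#' Correct observed index sequences against a whitelist
#'
#' Returns, per observed sequence, the unique whitelist entry within
#' `max_hamming` substitutions; `"ambiguous"` when two or more entries
#' tie at the minimal distance within the radius; `"no_match"` when none
#' is within the radius; `"malformed"` when the observed length differs
#' from the whitelist width. `N` (and any non-ACGT base) counts as a
#' mismatch against every base.
#'
#' @param observed character vector of observed index sequences.
#' @param whitelist character vector of equal-length barcodes.
#' @param max_hamming correction radius.
#' @return character vector: whitelist entry or rejection reason.
#' @export
correct_barcode <- function(observed, whitelist, max_hamming = 2L) {
  L <- unique(nchar(whitelist))
  stopifnot(length(L) == 1L)
  out <- rep("malformed", length(observed))
  ok <- !is.na(observed) & nchar(observed) == L
  if (!any(ok)) return(out)
  d <- hamming_distances(observed[ok], whitelist)
  dmin <- do.call(pmin, as.data.frame(d))
  nmin <- rowSums(d == dmin)
  res <- whitelist[max.col(-d, ties.method = "first")]
  res[nmin > 1L & dmin <= max_hamming] <- "ambiguous"
  res[dmin > max_hamming] <- "no_match"
  out[ok] <- res
  out
}

#' Demultiplex a synthetic or real run into barcode-tagged trimmed reads
#'
#' Corrects the three indexes independently (i5, i7 from index reads or
#' the read-header comment; tagmentation index from the first bases of
#' read 2) against their whitelists at the scheme's hamming radius. A
#' pair is assigned only if all three correct uniquely; failures are
#' rejected with reason `no_match`, `ambiguous` or `malformed`. The
#' composite barcode i5+i7+tag is prepended to the read name
#' (`<barcode>:<name>`), the first 10 bases of read 1 (random-priming
#' region) are trimmed, and read 2 loses its index plus mosaic-end prefix
#' (bases 1-29).
#'
#' Index dialects: pass `i1`/`i2` FASTQs when indexes were written as
#' separate reads; omit them to parse `<i5>+<i7>` from the trailing
#' field of each read-1 header (Illumina header dialect). Input that is
#' already barcode-tagged (names starting with the composite barcode and
#' `:`) is passed through unchanged.
#'
#' @param r1,r2 read FASTQs (paths) or `data.table`s from [read_fastq()].
#' @param scheme a [barcode_scheme()].
#' @param i1,i2 optional index-read FASTQs.
#' @param outdir optional directory; when given, trimmed tagged FASTQs
#'   and a demux summary TSV are written there.
#' @return a `demux_result` list: `r1`, `r2` (tagged, trimmed read
#'   tables), `assignments` (per pair: `name`, `composite` or `NA`,
#'   `reason`), `barcode_counts`, `summary` (assigned/rejected tallies),
#'   and output `files` when `outdir` was given.
#' @export
demultiplex <- function(r1, r2, scheme, i1 = NULL, i2 = NULL,
                        outdir = NULL) {
  if (is.character(r1)) r1 <- read_fastq(r1)
  if (is.character(r2)) r2 <- read_fastq(r2)
  if (is.character(i1)) i1 <- read_fastq(i1)
  if (is.character(i2)) i2 <- read_fastq(i2)
  stopifnot(nrow(r1) == nrow(r2))
  bc_width <- nchar(scheme$i5_whitelist[1]) + nchar(scheme$i7_whitelist[1]) +
    scheme$r2_index_len

  # pass-through for already-tagged input
  if (nrow(r1) &&
      all(grepl(paste0("^[ACGT]{", bc_width, "}:"), r1$name))) {
    composite <- substr(r1$name, 1L, bc_width)
    return(demux_result(r1, r2, data.table::data.table(
      name = r1$name, composite = composite, reason = NA_character_),
      outdir, passthrough = TRUE))
  }

  if (is.null(i1) != is.null(i2))
    stop_param("provide both index reads or neither")
  if (!is.null(i1)) {
    obs_i5 <- i1$seq
    obs_i7 <- i2$seq
  } else {
    idx <- sub("^.*[: ]([ACGTN]+)\\+([ACGTN]+)$", "\\1\t\\2", r1$name)
    halves <- data.table::tstrsplit(idx, "\t", fixed = TRUE)
    if (length(halves) != 2L)
      stop_param("no index reads given and no <i5>+<i7> header field found")
    obs_i5 <- halves[[1]]
    obs_i7 <- halves[[2]]
  }
  obs_tag <- substr(r2$seq, 1L, scheme$r2_index_len)
  short <- nchar(r2$seq) < scheme$r2_index_len + scheme$r2_me_len |
    nchar(r1$seq) < scheme$r1_prefix_trim
  obs_tag[nchar(obs_tag) < scheme$r2_index_len] <- NA_character_

  c_i5 <- correct_barcode(obs_i5, scheme$i5_whitelist, scheme$max_hamming)
  c_i7 <- correct_barcode(obs_i7, scheme$i7_whitelist, scheme$max_hamming)
  c_tag <- correct_barcode(obs_tag, scheme$tag_whitelist,
                           scheme$max_hamming)
  bad <- cbind(c_i5, c_i7, c_tag)
  fail_reason <- apply(bad, 1L, function(r) {
    r <- r[r %in% c("malformed", "ambiguous", "no_match")]
    if (length(r)) r[1] else NA_character_
  })
  fail_reason[short] <- "malformed"
  assigned <- is.na(fail_reason)
  composite <- ifelse(assigned, paste0(c_i5, c_i7, c_tag), NA_character_)

  keep <- which(assigned)
  r1_out <- data.table::data.table(
    name = paste0(composite[keep], ":", r1$name[keep]),
    seq = substr(r1$seq[keep], scheme$r1_prefix_trim + 1L,
                 nchar(r1$seq[keep])))
  r2_out <- data.table::data.table(
    name = paste0(composite[keep], ":", r2$name[keep]),
    seq = substr(r2$seq[keep],
                 scheme$r2_index_len + scheme$r2_me_len + 1L,
                 nchar(r2$seq[keep])))
  demux_result(r1_out, r2_out, data.table::data.table(
    name = r1$name, composite = composite, reason = fail_reason), outdir)
}

demux_result <- function(r1, r2, assignments, outdir,
                         passthrough = FALSE) {
  counts <- assignments[!is.na(composite), .N, by = composite]
  data.table::setnames(counts, "composite", "barcode")
  summary <- list(
    n_pairs = nrow(assignments),
    n_assigned = sum(!is.na(assignments$composite)),
    n_rejected = sum(is.na(assignments$composite)),
    reasons = table(assignments$reason[is.na(assignments$composite)]),
    passthrough = passthrough)
  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    files <- list(r1 = file.path(outdir, "demux.R1.fastq.gz"),
                  r2 = file.path(outdir, "demux.R2.fastq.gz"),
                  summary = file.path(outdir, "demux_summary.tsv"))
    write_fastq(r1$seq, r1$name, files$r1)
    write_fastq(r2$seq, r2$name, files$r2)
    data.table::fwrite(counts, files$summary, sep = "\t")
  }
  structure(list(r1 = r1, r2 = r2, assignments = assignments,
                 barcode_counts = counts, summary = summary,
                 files = files),
            class = "demux_result")
}

#' @exportS3Method base::print
print.demux_result <- function(x, ...) {
  s <- x$summary
  cat("demux_result:", s$n_pairs, "pairs,", s$n_assigned, "assigned,",
      s$n_rejected, "rejected\n")
  invisible(x)
}

# Standard sequencing adapter read-through into the 3' end.
DEFAULT_ADAPTER <- "AGATCGGAAGAGC"

#' Trim adapter read-through and the random-primer tail from read 2
#'
#' Removes a perfect 3'-suffix match of at least `min_overlap` bases of
#' the adapter (the read's tail matching the adapter's start), then
#' removes the last `tail` bases, which may derive from the random-primer
#' region of the mate. Reads shorter than the tail trim are emitted as
#' empty strings (dropped).
#'
#' @param read2 character vector of structurally trimmed read-2
#'   sequences.
#' @param adapter adapter sequence.
#' @param tail number of 3' bases to always remove (default 10).
#' @param min_overlap minimal adapter suffix match length (default 5).
#' @return character vector of trimmed sequences ("" = dropped).
#' @export
adapter_tail_trim <- function(read2, adapter = DEFAULT_ADAPTER,
                              tail = 10L, min_overlap = 5L) {
  out <- read2
  n <- nchar(out)
  kmax <- pmin(n, nchar(adapter))
  for (k in seq(nchar(adapter), min_overlap)) {
    idx <- which(kmax >= k & n >= k &
                   substr(out, n - k + 1L, n) ==
                   substr(adapter, 1L, k))
    if (length(idx)) {
      out[idx] <- substr(out[idx], 1L, n[idx] - k)
      n[idx] <- n[idx] - k
      kmax[idx] <- 0L       # only the longest match is removed
    }
  }
  ifelse(n > tail, substr(out, 1L, n - tail), "")
}
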