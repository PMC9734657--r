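# Internal helpers shared across modules.

#' @import data.table
#' @importFrom methods is
NULL

# Silence R CMD check notes for data.table NSE column names.
utils::globalVariables(c(
  ".", ".N", ".SD", "..keep", "barcode", "chrom", "pos", "strand", "context",
  "state", "meth", "n_meth", "n_total", "window_id", "cell", "copy", "locus",
  "molecule_id", "n_copies", "well", "tag", "i5", "i7", "species", "type",
  "is_collision_doublet", "reads_A", "reads_B", "purity", "assignment",
  "cluster", "region", "frac", "z", "bin", "offset", "qname", "key_", "V1",
  "N", "count", "site", "total", "start_", "end_", "flag", "seq_", "xg",
  "n_sites", "obs_barcode", "member_cells", "species_mix_label", "dist_",
  "read_id", "true_barcode", "assigned", "reason", "composite", "value"
))

#' Pairwise hamming distances between observed sequences and a whitelist
#'
#' All sequences must share one length. `N` (or any non-ACGT character)
#' mismatches every base, including another `N`.
#'
#' @param observed character vector of observed index sequences.
#' @param whitelist character vector of reference sequences.
#' @return integer matrix, `length(observed)` x `length(whitelist)`.
#' @keywords internal
hamming_distances <- function(observed, whitelist) {
  L <- unique(nchar(whitelist))
  stopifnot(length(L) == 1L, all(nchar(observed) == L))
  om <- matrix(utf8ToInt(paste(observed, collapse = "")),
               ncol = L, byrow = TRUE)
  wm <- matrix(utf8ToInt(paste(whitelist, collapse = "")),
               ncol = L, byrow = TRUE)
  acgt <- utf8ToInt("ACGT")
  # non-ACGT observed bases mismatch everything
  bad <- !(om %in% acgt)
  om[bad] <- -1L
  d <- matrix(0L, nrow = nrow(om), ncol = nrow(wm))
  for (j in seq_len(nrow(wm))) {
    d[, j] <- as.integer(rowSums(om != matrix(wm[j, ], nrow = nrow(om),
                                              ncol = L, byrow = TRUE)))
  }
  d
}

#' Reverse-complement character sequences
#' @param x character vector of DNA sequences.
#' @return character vector.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Derive a stream-specific seed from a user seed; keeps values < 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 2000L + as.integer(offset) %% 2000L
}

# substring over a char vector representation of a chromosome
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)
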