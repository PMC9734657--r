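#' Simulated species genomes
#'
#' Generates a pair of random genomes with independent i.i.d. base
#' composition, one per species of a two-species barnyard mixing
#' experiment. Because the two sequences are drawn independently their
#' expected per-base identity is \eqn{2(g/2)^2 + 2((1-g)/2)^2} for GC
#' fraction \eqn{g} (0.26 at the default 0.4), far below what is needed to
#' assign reads unambiguously to a species. Cytosine site indexes (CG and
#' merged CH context, both strands) are derived at construction.
#'
#' @param n_chroms number of chromosomes per genome.
#' @param chrom_length chromosome length in bases (>= 10000).
#' @param gc_fraction probability of a G/C base, in (0, 1). The degenerate
#'   values 0 and 1 are accepted for constructing edge-case fixtures.
#' @param seed integer seed; the same seed reproduces both genomes exactly.
#' @param species_labels two distinct labels.
#' @return list of two `species_genome` objects, named by label. Each holds
#'   `species_label`, `chromosomes` (named character vector) and `sites`,
#'   a `data.table` with columns `chrom`, `pos` (0-based, position of the
#'   cytosine on its own strand), `strand` (+/-) and `context` (CG/CH).
#' @export
make_genomes <- function(n_chroms = 2L, chrom_length = 100000L,
                         gc_fraction = 0.4, seed = 1L,
                         species_labels = c("speciesA", "speciesB")) {
  if (chrom_length < 10000) stop_param("chrom_length must be >= 10 kb")
  if (gc_fraction < 0 || gc_fraction > 1)
    stop_param("gc_fraction must be in [0, 1]")
  if (length(species_labels) != 2L ||
      species_labels[1] == species_labels[2])
    stop_param("two distinct species labels required")
  set.seed(derive_seed(seed, 11L))
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  out <- lapply(species_labels, function(lab) {
    chroms <- vapply(seq_len(n_chroms), function(i) {
      paste(sample(names(p), chrom_length, replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
    names(chroms) <- paste0(lab, "_chr", seq_len(n_chroms))
    new_species_genome(lab, chroms)
  })
  names(out) <- species_labels
  out
}

#' Construct a species genome from explicit sequences
#'
#' @param species_label species name.
#' @param chromosomes named character vector of chromosome sequences
#'   (alphabet ACGT).
#' @return a `species_genome` object (see [make_genomes()]).
#' @export
new_species_genome <- function(species_label, chromosomes) {
  stopifnot(is.character(chromosomes), !is.null(names(chromosomes)))
  sites <- data.table::rbindlist(lapply(names(chromosomes), function(cn) {
    cytosine_sites(chromosomes[[cn]], cn)
  }))
  structure(list(species_label = species_label,
                 chromosomes = chromosomes,
                 sites = sites),
            class = "species_genome")
}

# All cytosine positions of one chromosome, both strands, with CG/CH
# context taken from the reference dinucleotide. A cytosine at a
# chromosome edge with no next base is CH by convention.
cytosine_sites <- function(seq, chrom_name) {
  ch <- seq_chars(seq)
  n <- length(ch)
  fwd <- which(ch == "C")                       # 1-based
  fwd_ctx <- ifelse(fwd < n & ch[pmin(fwd + 1L, n)] == "G", "CG", "CH")
  rev <- which(ch == "G")                       # C on minus strand
  rev_ctx <- ifelse(rev > 1L & ch[pmax(rev - 1L, 1L)] == "C", "CG", "CH")
  data.table::data.table(
    chrom = chrom_name,
    pos = c(fwd, rev) - 1L,
    strand = rep(c("+", "-"), c(length(fwd), length(rev))),
    context = c(fwd_ctx, rev_ctx)
  )[order(pos, strand)]
}

#' @exportS3Method base::print
print.species_genome <- function(x, ...) {
  cat("species_genome:", x$species_label, "-", length(x$chromosomes),
      "chromosome(s),", sum(nchar(x$chromosomes)), "bp,",
      nrow(x$sites), "cytosine sites (",
      sum(x$sites$context == "CG"), "CG /",
      sum(x$sites$context == "CH"), "CH )\n")
  invisible(x)
}

#' CG / CH site positions of a genome
#' @param genome a `species_genome`.
#' @param context "CG" or "CH".
#' @return `data.table` subset of the site index.
#' @export
genome_sites <- function(genome, context = c("CG", "CH")) {
  context <- match.arg(context)
  genome$sites[genome$sites$context == context]
}

#' Write genomes as FASTA plus a chrom.sizes table
#' @param genomes list of `species_genome` objects.
#' @param fasta output FASTA path.
#' @param chrom_sizes optional chrom.sizes TSV path.
#' @return `fasta`, invisibly.
#' @export
write_genomes <- function(genomes, fasta, chrom_sizes = NULL) {
  seqs <- unlist(lapply(genomes, `[[`, "chromosomes"))
  names(seqs) <- unlist(lapply(genomes, function(g) names(g$chromosomes)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta)
  if (!is.null(chrom_sizes)) {
    data.table::fwrite(
      data.table::data.table(chrom = names(seqs), size = nchar(seqs)),
      chrom_sizes, sep = "\t", col.names = FALSE)
  }
  invisible(fasta)
}

#' Combined chrom.sizes table for a set of genomes
#' @param genomes list of `species_genome` objects.
#' @return `data.table` with `chrom` and `size`.
#' @export
chrom_sizes <- function(genomes) {
  if (is(genomes, "species_genome")) genomes <- list(genomes)
  data.table::rbindlist(lapply(genomes, function(g) {
    data.table::data.table(chrom = names(g$chromosomes),
                           size = nchar(g$chromosomes))
  }))
}
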