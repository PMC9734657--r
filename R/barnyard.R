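# Species assignment, doublet-rate estimation, expected collision model
# and cell-cell crosstalk from a two-species mixing experiment.

#' Per-barcode species counts from a joint-reference alignment table
#'
#' @param alignments alignment `data.table` with `barcode` and `chrom`.
#' @param species_of_chrom named character vector mapping chromosome to
#'   species label, or a list of `species_genome`s to derive it from.
#' @return `data.table` with `barcode`, `reads_A`, `reads_B` and the two
#'   species labels as attributes.
#' @export
species_counts <- function(alignments, species_of_chrom) {
  if (is.list(species_of_chrom) &&
      all(vapply(species_of_chrom, is, TRUE, "species_genome"))) {
    species_of_chrom <- do.call(c, unname(lapply(species_of_chrom,
                                                 function(g) {
      stats::setNames(rep(g$species_label, length(g$chromosomes)),
                      names(g$chromosomes))
    })))
  }
  labs <- sort(unique(species_of_chrom))
  stopifnot(length(labs) == 2L)
  aln <- data.table::as.data.table(alignments)
  aln[, species := species_of_chrom[chrom]]
  if (anyNA(aln$species))
    stop_param("alignments on chromosomes absent from the species map")
  cnt <- data.table::dcast(aln[, .N, by = .(barcode, species)],
                           barcode ~ species, value.var = "N", fill = 0L)
  for (l in labs) if (!l %in% names(cnt)) cnt[, (l) := 0L]
  out <- cnt[, .(barcode, reads_A = get(labs[1]), reads_B = get(labs[2]))]
  data.table::setattr(out, "species_labels", labs)
  out[]
}

#' Assign barcodes to species or flag them as mixed
#'
#' A barcode is assigned to the majority species when its purity
#' (majority reads / total reads) reaches `purity_threshold`; otherwise
#' it is `mixed` -- the barnyard signature of a cross-species collision
#' doublet. Barcodes below `min_reads` total reads are excluded.
#'
#' @param counts `data.table` with `barcode`, `reads_A`, `reads_B`.
#' @param purity_threshold minimal majority fraction (default 0.9).
#' @param min_reads minimal total reads per barcode (default 1).
#' @return `data.table`: `barcode`, `reads_A`, `reads_B`, `purity`,
#'   `assignment` in {A, B, mixed}.
#' @export
assign_species <- function(counts, purity_threshold = 0.9,
                           min_reads = 1L) {
  dt <- data.table::as.data.table(counts)
  dt <- dt[reads_A + reads_B >= max(1L, min_reads)]
  dt[, purity := pmax(reads_A, reads_B) / (reads_A + reads_B)]
  dt[, assignment := data.table::fifelse(
    purity < purity_threshold, "mixed",
    data.table::fifelse(reads_A >= reads_B, "A", "B"))]
  dt[]
}

#' Observed and mixing-corrected doublet rates
#'
#' The observed rate is the fraction of barcodes called `mixed`. Since
#' same-species collisions are invisible to a barnyard readout, the
#' total rate is estimated as `observed / (2 pA pB)` where `pA`, `pB`
#' are the singlet species proportions: `2 pA pB` is the probability
#' that a random two-cell collision spans both species. Binomial 95%
#' confidence intervals for the observed rate are scaled by the same
#' factor.
#'
#' @param table output of [assign_species()].
#' @param conf.level confidence level (default 0.95).
#' @return list: `n_total`, `n_mixed`, `observed`, `observed_ci`,
#'   `p_A`, `p_B`, `corrected`, `corrected_ci` (NA when one species is
#'   absent).
#' @export
doublet_estimate <- function(table, conf.level = 0.95) {
  n <- nrow(table)
  n_mixed <- sum(table$assignment == "mixed")
  obs <- n_mixed / n
  ci <- stats::binom.test(n_mixed, n, conf.level = conf.level)$conf.int
  n_a <- sum(table$assignment == "A")
  n_b <- sum(table$assignment == "B")
  if (n_a == 0L || n_b == 0L) {
    return(list(n_total = n, n_mixed = n_mixed, observed = obs,
                observed_ci = as.numeric(ci), p_A = NA_real_,
                p_B = NA_real_, corrected = NA_real_,
                corrected_ci = c(NA_real_, NA_real_)))
  }
  p_a <- n_a / (n_a + n_b)
  p_b <- n_b / (n_a + n_b)
  f <- 2 * p_a * p_b
  list(n_total = n, n_mixed = n_mixed, observed = obs,
       observed_ci = as.numeric(ci), p_A = p_a, p_B = p_b,
       corrected = obs / f, corrected_ci = as.numeric(ci) / f)
}

#' Expected collision fraction of the combinatorial-indexing layout
#'
#' Probability that a nucleus shares its tagmentation barcode with at
#' least one of the other `events_per_well - 1` nuclei in its well:
#' \eqn{1 - (1 - 1/B)^{n-1}}. This is the package's collision model; it
#' is monotone increasing in events per well and decreasing in the
#' number of tag barcodes.
#'
#' @param events_per_well nuclei deposited per well (>= 1).
#' @param n_tag_barcodes tagmentation whitelist size (>= 1).
#' @return expected collision fraction.
#' @export
expected_collision <- function(events_per_well, n_tag_barcodes) {
  if (events_per_well < 1 || n_tag_barcodes < 1)
    stop_param("events_per_well and n_tag_barcodes must be >= 1")
  1 - (1 - 1 / n_tag_barcodes)^(events_per_well - 1)
}

#' Cell-cell crosstalk: contamination of singlet cells by the other
#' species
#'
#' For every barcode assigned to species A, the fraction of its reads
#' aligning to species B is its contamination estimate (and vice versa);
#' mixed barcodes are excluded. Reported per cell and as per-species
#' means.
#'
#' @param table output of [assign_species()].
#' @return list: `per_cell` (`barcode`, `assignment`, `contamination`),
#'   `species_means` (named numeric, NA for a species with no singlet
#'   cells).
#' @export
crosstalk <- function(table) {
  dt <- data.table::as.data.table(table)[assignment %in% c("A", "B")]
  per_cell <- dt[, .(barcode, assignment,
                     contamination = data.table::fifelse(
                       assignment == "A",
                       reads_B / (reads_A + reads_B),
                       reads_A / (reads_A + reads_B)))]
  means <- c(
    A = if (any(per_cell$assignment == "A"))
      mean(per_cell$contamination[per_cell$assignment == "A"])
    else NA_real_,
    B = if (any(per_cell$assignment == "B"))
      mean(per_cell$contamination[per_cell$assignment == "B"])
    else NA_real_)
  list(per_cell = per_cell[], species_means = means)
}

#' Split demultiplexed reads by assigned species
#'
#' Reads of mixed barcodes are dropped; reads whose barcode is absent
#' from the table go to `unassigned`. Counts are conserved:
#' |A| + |B| + |dropped| + |unassigned| = input.
#'
#' @param reads `data.table` with `name` (barcode-tagged,
#'   `<barcode>:...`) and `seq`.
#' @param table output of [assign_species()].
#' @param outdir optional directory; per-species FASTQs are written
#'   there when given.
#' @return list of read tables `A`, `B`, `dropped`, `unassigned`, plus
#'   `counts` and `files` (when written).
#' @export
split_by_species <- function(reads, table, outdir = NULL) {
  reads <- data.table::as.data.table(reads)
  bc <- sub(":.*$", "", reads$name)
  asn <- table$assignment[match(bc, table$barcode)]
  grp <- data.table::fifelse(is.na(asn), "unassigned",
                             data.table::fifelse(asn == "mixed",
                                                 "dropped", asn))
  out <- list(A = reads[grp == "A"], B = reads[grp == "B"],
              dropped = reads[grp == "dropped"],
              unassigned = reads[grp == "unassigned"])
  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    files <- list()
    for (g in c("A", "B")) {
      files[[g]] <- file.path(outdir, paste0("species_", g, ".fastq.gz"))
      write_fastq(out[[g]]$seq, out[[g]]$name, files[[g]])
    }
  }
  c(out, list(counts = vapply(out, nrow, 0L), files = files))
}
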