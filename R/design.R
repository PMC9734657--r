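#' Cell-type methylation profile
#'
#' Defines the genome-wide methylation landscape of one simulated cell
#' type: a global CG methylation probability, a global CH methylation
#' probability, and optional per-region overrides (marker regions where a
#' type is specifically hypo- or hyper-methylated, used to emulate marker
#' promoters and gene bodies).
#'
#' Mammalian brain conventions motivate the presets returned by
#' [default_cell_types()]: neurons carry abundant non-CG methylation
#' (global mCH of a few percent) while glia are nearly devoid of it, and
#' CG methylation is globally high (~0.7-0.8) in all types.
#'
#' @param type_label name of the type.
#' @param global_mch probability a CH site is methylated.
#' @param global_mcg probability a CG site is methylated.
#' @param marker_regions optional `data.frame` with columns `chrom`,
#'   `start`, `end` (0-based half-open), `context` (CG/CH) and `prob`,
#'   overriding the global probability inside the region.
#' @return a `cell_type_profile` object.
#' @export
cell_type_profile <- function(type_label, global_mch, global_mcg,
                              marker_regions = NULL) {
  if (any(c(global_mch, global_mcg) < 0 | c(global_mch, global_mcg) > 1))
    stop_param("methylation probabilities must be in [0, 1]")
  if (!is.null(marker_regions)) {
    marker_regions <- data.table::as.data.table(marker_regions)
    stopifnot(all(c("chrom", "start", "end", "context", "prob") %in%
                    names(marker_regions)),
              all(marker_regions$prob >= 0 & marker_regions$prob <= 1))
  }
  structure(list(type_label = type_label, global_mch = global_mch,
                 global_mcg = global_mcg, marker_regions = marker_regions),
            class = "cell_type_profile")
}

#' Preset neuron-like and glia-like cell types
#'
#' Three types spanning the neuron/glia global-mCH split: two neuron-like
#' types with high CH methylation and one glia-like type with nearly none.
#'
#' @return named list of `cell_type_profile` objects.
#' @export
default_cell_types <- function() {
  list(
    neuron_ex = cell_type_profile("neuron_ex", global_mch = 0.06,
                                  global_mcg = 0.80),
    neuron_in = cell_type_profile("neuron_in", global_mch = 0.04,
                                  global_mcg = 0.75),
    glia      = cell_type_profile("glia",      global_mch = 0.005,
                                  global_mcg = 0.72)
  )
}

#' Experiment design for the synthetic sequencing run
#'
#' Bundles every tunable of the simulator: how many cells of each species,
#' the combinatorial-indexing layout (sort events per well, number of
#' tagmentation barcodes, number of PCR wells), and the noise model
#' (PCR duplication, index and genomic sequencing errors, bisulfite
#' conversion failure and over-conversion, optional barcode crosstalk).
#'
#' Defaults mirror the mixing-experiment conditions the pipeline targets:
#' 22 sort events deposited per well, 96 tagmentation barcodes, a skewed
#' ~90/10 two-species mix, mean 1.5 PCR copies per unique molecule, and
#' small error rates typical of a well-behaved run.
#'
#' @param n_cells_per_species named integer vector, cells per species.
#' @param species_mix sampling proportions per species (must sum to 1);
#'   defaults to proportions of `n_cells_per_species`.
#' @param events_per_well nuclei deposited per PCR well.
#' @param n_tag_barcodes size of the tagmentation-index whitelist.
#' @param n_pcr_wells number of PCR wells (i5 x i7 combinations)
#'   available; defaults to exactly as many as the cells require.
#' @param duplicate_rate mean PCR copies per unique molecule (>= 1).
#' @param barcode_error_rate per-base substitution probability on index
#'   segments.
#' @param seq_error_rate per-base substitution probability on genomic
#'   bases.
#' @param conversion_failure_rate probability an unmethylated C is read
#'   as C (incomplete conversion).
#' @param overconversion_rate probability a methylated C is read as T.
#' @param crosstalk_rate fraction of reads reassigned to a random other
#'   barcode (cell-cell crosstalk); default 0.
#' @param reads_per_cell read pairs generated per nucleus.
#' @param read_length bases per read.
#' @param seed integer master seed.
#' @return an `experiment_design` object.
#' @export
experiment_design <- function(n_cells_per_species = c(speciesA = 900L,
                                                      speciesB = 100L),
                              species_mix = NULL,
                              events_per_well = 22L,
                              n_tag_barcodes = 96L,
                              n_pcr_wells = NULL,
                              duplicate_rate = 1.5,
                              barcode_error_rate = 0.001,
                              seq_error_rate = 0.001,
                              conversion_failure_rate = 0.005,
                              overconversion_rate = 0.005,
                              crosstalk_rate = 0,
                              reads_per_cell = 50L,
                              read_length = 60L,
                              seed = 1L) {
  if (is.null(species_mix))
    species_mix <- n_cells_per_species / sum(n_cells_per_species)
  rates <- c(barcode_error_rate, seq_error_rate, conversion_failure_rate,
             overconversion_rate, crosstalk_rate)
  if (any(rates < 0 | rates > 1)) stop_param("rates must be in [0, 1]")
  if (abs(sum(species_mix) - 1) > 1e-9)
    stop_param("species_mix must sum to 1")
  if (any(species_mix < 0)) stop_param("species_mix must be nonnegative")
  counts <- c(events_per_well, n_tag_barcodes, reads_per_cell, read_length,
              n_cells_per_species)
  if (any(counts <= 0)) stop_param("counts must be positive")
  if (duplicate_rate < 1)
    stop_param("duplicate_rate is a mean copy number, must be >= 1")
  n_total <- sum(n_cells_per_species)
  wells_needed <- ceiling(n_total / events_per_well)
  if (is.null(n_pcr_wells)) n_pcr_wells <- wells_needed
  if (n_pcr_wells < wells_needed)
    stop_param("n_pcr_wells too small for ", n_total, " cells at ",
               events_per_well, " events per well")
  structure(list(
    n_cells_per_species = n_cells_per_species,
    species_mix = species_mix,
    events_per_well = as.integer(events_per_well),
    n_tag_barcodes = as.integer(n_tag_barcodes),
    n_pcr_wells = as.integer(n_pcr_wells),
    duplicate_rate = duplicate_rate,
    barcode_error_rate = barcode_error_rate,
    seq_error_rate = seq_error_rate,
    conversion_failure_rate = conversion_failure_rate,
    overconversion_rate = overconversion_rate,
    crosstalk_rate = crosstalk_rate,
    reads_per_cell = as.integer(reads_per_cell),
    read_length = as.integer(read_length),
    seed = as.integer(seed)
  ), class = "experiment_design")
}
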