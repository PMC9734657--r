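# Barcode whitelists and the combinatorial-indexing layout.

#' Generate a random barcode whitelist with a guaranteed minimum distance
#'
#' Rejection-samples random sequences, keeping a candidate only if its
#' hamming distance to every accepted barcode is at least `min_dist`.
#' A minimum pairwise distance of 5 makes distance-2 correction
#' collision-free: an observed sequence with <= 2 substitutions is within
#' distance 2 of exactly one entry. Note the combinatorial limit: at width
#' 8 only a few dozen distance-5 codewords fit, so large whitelists
#' (e.g. 96 tagmentation barcodes in an 8-base index) must use a smaller
#' `min_dist` (3 gives exact single-error correction).
#'
#' @param n number of barcodes.
#' @param width barcode length in bases.
#' @param min_dist minimum pairwise hamming distance.
#' @param seed integer seed.
#' @param max_tries sampling attempts before giving up.
#' @return character vector of `n` barcodes.
#' @export
generate_whitelist <- function(n, width = 8L, min_dist = 5L, seed = 1L,
                               max_tries = 200000L) {
  if (n < 1 || width < 1 || min_dist < 0) stop_param("invalid parameters")
  set.seed(derive_seed(seed, 23L))
  bases <- c("A", "C", "G", "T")
  acc <- matrix(integer(0), ncol = width)
  tries <- 0L
  while (nrow(acc) < n && tries < max_tries) {
    tries <- tries + 1L
    cand <- sample.int(4L, width, replace = TRUE)
    ok <- nrow(acc) == 0L ||
      all(rowSums(acc != matrix(cand, nrow(acc), width, byrow = TRUE)) >=
            min_dist)
    if (ok) acc <- rbind(acc, cand)
  }
  if (nrow(acc) < n)
    stop_param("could not place ", n, " barcodes of width ", width,
               " at min distance ", min_dist, " (reached ", nrow(acc), ")")
  apply(acc, 1L, function(r) paste(bases[r], collapse = ""))
}

# Canonical 19-base Tn5 mosaic end, padded to 21 bases so that read 2
# positions 9-29 are structural (8-base index + this constant).
MOSAIC_END <- "AGATGTGTATAAGAGACAGCA"

#' Barcode scheme: whitelists plus structural read offsets
#'
#' Describes the three-index layout of a run: tagmentation index (first 8
#' bases of read 2), i5/i7 PCR indexes (separate index reads), the
#' hamming-correction radius, and the structural trim coordinates --
#' the first 10 bases of read 1 (random-priming region) and bases 1-29 of
#' read 2 (8-base index plus 21-base mosaic end), with a further 10-base
#' 3' tail trim of read 2 applied at the adapter-trimming step.
#'
#' @param tag_whitelist,i5_whitelist,i7_whitelist character vectors of
#'   equal-width barcodes (per list).
#' @param max_hamming correction radius (default 2).
#' @return a `barcode_scheme` object.
#' @export
barcode_scheme <- function(tag_whitelist, i5_whitelist, i7_whitelist,
                           max_hamming = 2L) {
  for (wl in list(tag_whitelist, i5_whitelist, i7_whitelist)) {
    stopifnot(length(unique(nchar(wl))) == 1L,
              all(grepl("^[ACGT]+$", wl)), !anyDuplicated(wl))
  }
  if (max_hamming < 0) stop_param("max_hamming must be >= 0")
  structure(list(
    tag_whitelist = tag_whitelist,
    i5_whitelist = i5_whitelist,
    i7_whitelist = i7_whitelist,
    max_hamming = as.integer(max_hamming),
    r1_prefix_trim = 10L,
    r2_index_len = nchar(tag_whitelist[1]),
    r2_me_len = nchar(MOSAIC_END),
    r2_tail_trim = 10L
  ), class = "barcode_scheme")
}

#' Default scheme for an experiment design
#'
#' Tag whitelist of `design$n_tag_barcodes` 8-mers and i5/i7 whitelists of
#' 8-mers sized to cover `design$n_pcr_wells` wells. Whitelists up to 30
#' entries use minimum pairwise distance 5 (collision-free distance-2
#' correction); larger ones fall back to distance 3, which an 8-base index
#' can accommodate (see [generate_whitelist()]).
#'
#' @param design an [experiment_design()].
#' @return a `barcode_scheme`.
#' @export
scheme_for_design <- function(design) {
  mind <- function(n) if (n <= 30L) 5L else 3L
  n_side <- ceiling(sqrt(design$n_pcr_wells))
  barcode_scheme(
    tag_whitelist = generate_whitelist(design$n_tag_barcodes, 8L,
                                       mind(design$n_tag_barcodes),
                                       seed = design$seed),
    i5_whitelist = generate_whitelist(n_side, 8L, mind(n_side),
                                      seed = design$seed + 1L),
    i7_whitelist = generate_whitelist(n_side, 8L, mind(n_side),
                                      seed = design$seed + 2L),
    max_hamming = 2L
  )
}

#' Assign simulated nuclei to wells, barcodes and cell types
#'
#' Emulates the combinatorial-indexing sort: nuclei are deposited
#' `events_per_well` at a time into PCR wells (each well is one i5/i7
#' combination) and each nucleus independently receives one of the
#' tagmentation barcodes. Two nuclei in the same well drawing the same
#' tagmentation barcode are physically indistinguishable downstream: they
#' are merged into a single observed barcode and flagged as a collision
#' doublet. The per-nucleus collision probability is
#' \eqn{1 - (1 - 1/B)^{n-1}} for B tag barcodes and n events per well.
#'
#' @param design an [experiment_design()].
#' @param profiles list of [cell_type_profile()] objects; each nucleus is
#'   assigned a type uniformly at random.
#' @param scheme optional [barcode_scheme()]; defaults to
#'   [scheme_for_design()].
#' @param seed integer seed (defaults to `design$seed`).
#' @return a `sim_truth` object with `cells` (one row per nucleus:
#'   `cell_id`, `species`, `type`, `well`, `tag`, `barcode`,
#'   `is_collision_doublet`), `barcodes` (one row per observed barcode
#'   with member cells, species composition and doublet flag) and the
#'   `scheme` and `design` used.
#' @export
assign_cells <- function(design, profiles, scheme = NULL, seed = NULL) {
  if (is.null(scheme)) scheme <- scheme_for_design(design)
  if (is.null(seed)) seed <- design$seed
  n_total <- sum(design$n_cells_per_species)
  if (length(profiles) > n_total)
    stop_param("more cell-type profiles than cells")
  set.seed(derive_seed(seed, 37L))

  species <- rep(names(design$n_cells_per_species),
                 design$n_cells_per_species)
  type <- sample(vapply(profiles, `[[`, "", "type_label"), n_total,
                 replace = TRUE)
  ord <- sample.int(n_total)           # random deposition order
  well <- integer(n_total)
  well[ord] <- ceiling(seq_len(n_total) / design$events_per_well)
  n_wells <- max(well)
  if (n_wells > length(scheme$i5_whitelist) * length(scheme$i7_whitelist))
    stop_param("scheme i5/i7 whitelists cover too few wells")
  grid <- data.table::CJ(i5 = scheme$i5_whitelist,
                         i7 = scheme$i7_whitelist, sorted = FALSE)
  tag <- sample(scheme$tag_whitelist, n_total, replace = TRUE)

  cells <- data.table::data.table(
    cell_id = sprintf("cell%05d", seq_len(n_total)),
    species = species, type = type, well = well, tag = tag,
    i5 = grid$i5[well], i7 = grid$i7[well]
  )
  cells[, barcode := paste0(i5, i7, tag)]
  cells[, is_collision_doublet := .N > 1L, by = .(well, tag)]

  barcodes <- cells[, .(
    i5 = i5[1], i7 = i7[1], tag = tag[1],
    n_cells = .N,
    member_cells = paste(cell_id, collapse = ","),
    types = paste(sort(unique(type)), collapse = ","),
    species_mix_label = paste(sort(unique(species)), collapse = ","),
    is_collision_doublet = .N > 1L
  ), by = barcode]

  structure(list(cells = cells, barcodes = barcodes, scheme = scheme,
                 design = design),
            class = "sim_truth")
}

#' @exportS3Method base::print
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", nrow(x$cells), "nuclei,", nrow(x$barcodes),
      "observed barcodes,",
      sum(x$barcodes$is_collision_doublet), "collision doublets\n")
  invisible(x)
}
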