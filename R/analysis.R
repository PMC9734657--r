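# Post-clustering methylome statistics: coverage saturation, region
# methylation with z-scoring, cell-cell concordance, motif profiles.

#' Region presets around TSSs and gene bodies
#'
#' Builds strand-aware region sets from gene annotations: the promoter
#' used for methylation calling spans 1500 bp upstream to 1000 bp
#' downstream of the TSS; the wide promoter 5000 upstream / 2500
#' downstream; the flanked gene body extends the gene by 2000 bp on each
#' side. Intervals are clipped to chromosome bounds.
#'
#' @param genes `data.table` with `chrom`, `start`, `end`, `name`,
#'   `strand` (0-based half-open; TSS = `start` on `+`, `end - 1` on
#'   `-`).
#' @param sizes chrom sizes `data.table` for clipping.
#' @param preset one of "promoter_call", "promoter_wide",
#'   "gene_body_flank".
#' @param upstream,downstream overrides of the preset distances.
#' @return `data.table` with `chrom`, `start`, `end`, `name`, `strand`.
#' @export
region_preset <- function(genes, sizes,
                          preset = c("promoter_call", "promoter_wide",
                                     "gene_body_flank"),
                          upstream = NULL, downstream = NULL) {
  preset <- match.arg(preset)
  p <- switch(preset,
              promoter_call = c(1500L, 1000L),
              promoter_wide = c(5000L, 2500L),
              gene_body_flank = c(2000L, 2000L))
  up <- upstream %||% p[1]
  dn <- downstream %||% p[2]
  g <- data.table::as.data.table(genes)
  if (preset == "gene_body_flank") {
    st <- g$start - up
    en <- g$end + dn
  } else {
    tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
    st <- ifelse(g$strand == "+", tss - up, tss - dn + 1L)
    en <- ifelse(g$strand == "+", tss + dn, tss + up + 1L)
  }
  lim <- stats::setNames(sizes$size, sizes$chrom)
  out <- data.table::data.table(
    chrom = g$chrom,
    start = pmax(0L, as.integer(st)),
    end = pmin(as.integer(lim[g$chrom]), as.integer(en)),
    name = g$name, strand = g$strand)
  out[end > start]
}

#' Methylome coverage saturation by cumulative cell sampling
#'
#' Repeats `n_iter` times: sample `n_cells` cells without replacement in
#' a random order and accumulate the union of their covered sites,
#' recording the covered fraction of the site universe after each added
#' cell. Reports the per-iteration and mean number of cells needed to
#' reach `threshold` of the universe (Inf when never reached).
#'
#' @param cell_sites named list: per cell, an integer vector of covered
#'   site ids (any stable encoding of sites).
#' @param universe_size total number of sites in scope (> 0).
#' @param n_iter iterations (default 100).
#' @param n_cells cells sampled per iteration (default 250, capped at
#'   the number available).
#' @param threshold coverage fraction defining saturation (default 0.8).
#' @param seed integer seed.
#' @return a `saturation_curve` list: `curves` (n_iter x n_cells matrix
#'   of covered fractions), `mean_curve`, `cells_to_threshold`
#'   (per-iteration), `mean_cells_to_threshold`, `threshold`.
#' @export
coverage_saturation <- function(cell_sites, universe_size, n_iter = 100L,
                                n_cells = 250L, threshold = 0.8,
                                seed = 1L) {
  if (universe_size <= 0) stop_param("universe_size must be positive")
  n_avail <- length(cell_sites)
  if (n_cells > n_avail) stop_param("n_cells exceeds available cells")
  set.seed(derive_seed(seed, 131L))
  curves <- matrix(NA_real_, n_iter, n_cells)
  hit <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    sel <- sample.int(n_avail, n_cells)
    seen <- logical(universe_size)
    acc <- 0L
    for (j in seq_len(n_cells)) {
      s <- cell_sites[[sel[j]]]
      new <- s[!seen[s]]
      seen[new] <- TRUE
      acc <- acc + length(unique(new))
      curves[it, j] <- acc / universe_size
    }
    reached <- which(curves[it, ] >= threshold)
    hit[it] <- if (length(reached)) reached[1] else NA_integer_
  }
  cells_to <- ifelse(is.na(hit), Inf, hit)
  structure(list(curves = curves, mean_curve = colMeans(curves),
                 cells_to_threshold = cells_to,
                 mean_cells_to_threshold = mean(cells_to),
                 threshold = threshold),
            class = "saturation_curve")
}

#' @exportS3Method base::print
print.saturation_curve <- function(x, ...) {
  cat(sprintf(
    "saturation_curve: %d iterations x %d cells; mean %.1f cells to %.0f%% coverage\n",
    nrow(x$curves), ncol(x$curves), x$mean_cells_to_threshold,
    100 * x$threshold))
  invisible(x)
}

#' Cluster-level region methylation with cross-cluster z-scores
#'
#' Pools calls of all member cells per (cluster, region): methylated /
#' total calls in the region (cluster pooling is the stable estimator
#' under sparse per-cell coverage). Each region is then z-scored across
#' clusters with the sample standard deviation; regions with zero calls
#' in a cluster are missing there and excluded from that region's
#' z-scoring; a zero standard deviation yields z = 0.
#'
#' @param calls call `data.table` of one context.
#' @param regions region `data.table` (`chrom`, `start`, `end`, `name`,
#'   `strand`).
#' @param labels named cluster vector (names = barcodes).
#' @param context "CG" or "CH"; calls are filtered to it.
#' @return list with `fraction` and `z` (clusters x regions matrices)
#'   and the long table `long`.
#' @export
region_methylation <- function(calls, regions, labels,
                               context = c("CG", "CH")) {
  context <- match.arg(context)
  ctx_sel <- context
  if (!nrow(regions)) stop_param("regions must be non-empty")
  calls <- data.table::as.data.table(calls)
  calls <- calls[calls[["context"]] == ctx_sel &
                   calls[["barcode"]] %in% names(labels)]
  if (!nrow(calls)) stop_param("no calls for labeled cells in context ",
                               context)
  calls[, cluster := labels[barcode]]
  gr_r <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start + 1L,
                                                  regions$end))
  gr_c <- GenomicRanges::GRanges(calls$chrom,
                                 IRanges::IRanges(calls$pos + 1L,
                                                  width = 1L))
  hit <- GenomicRanges::findOverlaps(gr_c, gr_r)
  long <- calls[S4Vectors::queryHits(hit)]
  long[, region := regions$name[S4Vectors::subjectHits(hit)]]
  agg <- long[, .(frac = mean(state == "methylated"), n_total = .N),
              by = .(cluster, region)]
  clusters <- sort(unique(labels))
  frac <- matrix(NA_real_, length(clusters), nrow(regions),
                 dimnames = list(as.character(clusters), regions$name))
  frac[cbind(match(agg$cluster, clusters),
             match(agg$region, regions$name))] <- agg$frac
  z <- apply(frac, 2L, function(v) {
    ok <- !is.na(v)
    if (sum(ok) < 2L) return(rep(NA_real_, length(v)))
    s <- stats::sd(v[ok])
    out <- rep(NA_real_, length(v))
    out[ok] <- if (s > 0) (v[ok] - mean(v[ok])) / s else 0
    out
  })
  dimnames(z) <- dimnames(frac)
  list(fraction = frac, z = z, long = agg[])
}

#' Cell-cell methylation concordance within regions
#'
#' Restricts CG calls to the given regions, binarizes each (cell, site)
#' to methylated iff its methylated-call fraction is >= 0.5 (most sites
#' carry a single read; ties go to methylated), and computes, for every
#' cell pair, shared-state sites / shared sites. Pairs with fewer than
#' `min_shared_sites` shared sites are missing.
#'
#' @param calls call `data.table` (CG context used).
#' @param regions region `data.table`; NULL uses all calls.
#' @param labels optional named cluster vector for the within/between
#'   summaries.
#' @param min_shared_sites minimal shared sites per pair (default 1).
#' @return list: `concordance` (symmetric cells x cells matrix, unit
#'   diagonal, NA where too few shared sites), `shared` (shared-site
#'   counts), and when labels are given `within_cluster` (per-cluster
#'   mean of within pairs) and `cluster_means` (cluster x cluster mean
#'   matrix, hierarchically ordered).
#' @export
pairwise_similarity <- function(calls, regions = NULL, labels = NULL,
                                min_shared_sites = 1L) {
  calls <- data.table::as.data.table(calls)
  calls <- calls[calls[["context"]] == "CG"]
  if (!is.null(regions) && nrow(regions)) {
    gr_r <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start + 1L,
                                                    regions$end))
    gr_c <- GenomicRanges::GRanges(calls$chrom,
                                   IRanges::IRanges(calls$pos + 1L,
                                                    width = 1L))
    calls <- calls[unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(gr_c, gr_r)))]
  }
  if (!nrow(calls)) stop_param("no CG calls in scope")
  site_state <- calls[, .(meth = mean(state == "methylated") >= 0.5),
                      by = .(barcode, chrom, pos, strand)]
  site_state[, site := paste0(chrom, ":", pos, ":", strand)]
  cells <- sort(unique(site_state$barcode))
  sites <- unique(site_state$site)
  i <- match(site_state$barcode, cells)
  j <- match(site_state$site, sites)
  Cov <- Matrix::sparseMatrix(i, j, x = 1,
                              dims = c(length(cells), length(sites)))
  M <- Matrix::sparseMatrix(i, j, x = as.numeric(site_state$meth),
                            dims = c(length(cells), length(sites)))
  shared <- as.matrix(Matrix::tcrossprod(Cov))
  same <- as.matrix(Matrix::tcrossprod(M) +
                      Matrix::tcrossprod(Cov - M))
  conc <- same / shared
  conc[shared < min_shared_sites] <- NA_real_
  diag(conc) <- 1
  dimnames(conc) <- list(cells, cells)
  dimnames(shared) <- dimnames(conc)
  out <- list(concordance = conc, shared = shared)
  if (!is.null(labels)) {
    lab <- labels[cells]
    cl <- sort(unique(lab))
    cm <- matrix(NA_real_, length(cl), length(cl),
                 dimnames = list(as.character(cl), as.character(cl)))
    for (a in seq_along(cl)) for (b in seq_along(cl)) {
      block <- conc[lab == cl[a], lab == cl[b], drop = FALSE]
      if (a == b) diag(block) <- NA
      cm[a, b] <- mean(block, na.rm = TRUE)
    }
    out$within_cluster <- diag(cm)
    ord <- if (nrow(cm) > 2L)
      stats::hclust(stats::dist(cm))$order else seq_len(nrow(cm))
    out$cluster_means <- cm[ord, ord, drop = FALSE]
  }
  out
}

#' Motif-centered methylation profile by cluster
#'
#' Bins calls around motif centers into 100 half-open 10 bp bins
#' covering [-500, +500) (center at the bin boundary), flipping offsets
#' for minus-strand motifs, and pools the methylation fraction per
#' (cluster, bin) over all motif instances. Out-of-bounds bins at
#' chromosome edges contribute nothing.
#'
#' @param calls call `data.table` of one context.
#' @param motifs `data.table` with `chrom`, `center` (0-based),
#'   `strand`.
#' @param labels named cluster vector.
#' @param context "CG" or "CH".
#' @param span half-width in bp (default 500).
#' @param step bin width in bp (default 10).
#' @return list: `profile` (clusters x bins matrix of fractions, NA
#'   where no calls), `counts` (call totals), `bin_offsets` (bin left
#'   edges relative to center).
#' @export
motif_profile <- function(calls, motifs, labels,
                          context = c("CG", "CH"), span = 500L,
                          step = 10L) {
  context <- match.arg(context)
  ctx_sel <- context
  calls <- data.table::as.data.table(calls)
  calls <- calls[calls[["context"]] == ctx_sel &
                   calls[["barcode"]] %in% names(labels)]
  calls[, cluster := labels[barcode]]
  gr_m <- GenomicRanges::GRanges(
    motifs$chrom, IRanges::IRanges(pmax(1L, motifs$center + 1L - span),
                                   motifs$center + span))
  gr_c <- GenomicRanges::GRanges(calls$chrom,
                                 IRanges::IRanges(calls$pos + 1L,
                                                  width = 1L))
  hit <- GenomicRanges::findOverlaps(gr_c, gr_m)
  long <- calls[S4Vectors::queryHits(hit)]
  mi <- S4Vectors::subjectHits(hit)
  off <- long$pos - motifs$center[mi]
  off[motifs$strand[mi] == "-"] <- -off[motifs$strand[mi] == "-"]
  keep <- off >= -span & off < span
  long <- long[keep]
  off <- off[keep]
  long[, bin := (off + span) %/% step + 1L]     # 1 .. 2*span/step
  n_bins <- 2L * span %/% step
  agg <- long[, .(frac = mean(state == "methylated"), n_total = .N),
              by = .(cluster, bin)]
  clusters <- sort(unique(labels))
  prof <- matrix(NA_real_, length(clusters), n_bins,
                 dimnames = list(as.character(clusters), NULL))
  cnts <- matrix(0L, length(clusters), n_bins,
                 dimnames = dimnames(prof))
  ri <- match(agg$cluster, clusters)
  prof[cbind(ri, agg$bin)] <- agg$frac
  cnts[cbind(ri, agg$bin)] <- agg$n_total
  list(profile = prof, counts = cnts,
       bin_offsets = seq(-span, span - step, by = step))
}
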