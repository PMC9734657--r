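# Cells x genomic-window methylation matrices: construction, the
# two-pass coverage filter, SVD + Louvain clustering, merging.

#' Tile chromosomes into non-overlapping windows
#'
#' Half-open windows of `window_size` bases tiling each chromosome
#' exactly; the last window of a chromosome may be short. Conventional
#' sizes: 250 kbp for CH-context matrices (features at gene-body scale),
#' 50 kbp for CG-only analyses (CG-island-scale features).
#'
#' @param sizes `data.table` with `chrom` and `size` (see
#'   [chrom_sizes()]), or a path to a chrom.sizes TSV.
#' @param window_size window width in bases.
#' @param context "CH" or "CG" (recorded, used to match call tables).
#' @return a `window_set`: `data.table` with `window_id`, `chrom`,
#'   `start`, `end` plus `window_size`/`context` attributes.
#' @export
make_windows <- function(sizes, window_size, context = c("CH", "CG")) {
  context <- match.arg(context)
  if (is.character(sizes)) {
    sizes <- data.table::fread(sizes, header = FALSE,
                               col.names = c("chrom", "size"))
  }
  if (window_size <= 0 || any(sizes$size <= 0))
    stop_param("sizes and window_size must be positive")
  win <- data.table::rbindlist(lapply(seq_len(nrow(sizes)), function(i) {
    L <- sizes$size[i]
    st <- seq.int(0L, L - 1L, by = window_size)
    data.table::data.table(chrom = sizes$chrom[i], start = st,
                           end = pmin(st + window_size, L))
  }))
  win[, window_id := sprintf("%s:%d-%d", chrom, start, end)]
  data.table::setcolorder(win, c("window_id", "chrom", "start", "end"))
  data.table::setattr(win, "window_size", as.integer(window_size))
  data.table::setattr(win, "context", context)
  win[]
}

new_window_matrix <- function(meth_fraction, site_count, windows,
                              barcodes, context, window_size) {
  stopifnot(identical(dim(meth_fraction), dim(site_count)),
            nrow(meth_fraction) == length(barcodes),
            ncol(meth_fraction) == nrow(windows))
  dimnames(meth_fraction) <- list(barcodes, windows$window_id)
  dimnames(site_count) <- dimnames(meth_fraction)
  structure(list(meth_fraction = meth_fraction, site_count = site_count,
                 windows = data.table::as.data.table(windows),
                 barcodes = barcodes, context = context,
                 window_size = as.integer(window_size)),
            class = "window_matrix")
}

#' @exportS3Method base::print
print.window_matrix <- function(x, ...) {
  cat("window_matrix:", length(x$barcodes), "cells x", nrow(x$windows),
      sprintf("windows (%s, %d bp); %.1f%% entries covered\n",
              x$context, x$window_size,
              100 * mean(x$site_count > 0)))
  invisible(x)
}

#' Build a cells x windows methylation matrix from calls
#'
#' Per (cell, window): `site_count` is the number of distinct called
#' sites and `meth_fraction` the methylated / total call ratio; entries
#' with no calls are missing (NA). Calls whose context does not match
#' the window set are rejected.
#'
#' @param calls call `data.table` (from [call_methylation()] or
#'   [simulate_calls()]).
#' @param windows a `window_set` from [make_windows()].
#' @return a `window_matrix`.
#' @export
build_matrix <- function(calls, windows) {
  ctx <- attr(windows, "context")
  calls <- data.table::as.data.table(calls)
  if (nrow(calls) && !all(calls$context == ctx))
    stop_param("calls contain contexts other than the window set's ", ctx)
  gw <- GenomicRanges::GRanges(windows$chrom,
                               IRanges::IRanges(windows$start + 1L,
                                                windows$end))
  gc <- GenomicRanges::GRanges(calls$chrom,
                               IRanges::IRanges(calls$pos + 1L, width = 1L))
  hit <- GenomicRanges::findOverlaps(gc, gw)
  stopifnot(length(hit) == nrow(calls))     # tiling covers every call
  calls[, window_id := windows$window_id[S4Vectors::subjectHits(hit)]]
  agg <- calls[, .(n_total = .N,
                   n_meth = sum(state == "methylated"),
                   n_sites = data.table::uniqueN(paste0(pos, strand))),
               by = .(barcode, window_id)]
  barcodes <- sort(unique(calls$barcode))
  frac <- matrix(NA_real_, length(barcodes), nrow(windows))
  cnt <- matrix(0L, length(barcodes), nrow(windows))
  ri <- match(agg$barcode, barcodes)
  ci <- match(agg$window_id, windows$window_id)
  frac[cbind(ri, ci)] <- agg$n_meth / agg$n_total
  cnt[cbind(ri, ci)] <- agg$n_sites
  new_window_matrix(frac, cnt, windows, barcodes, ctx,
                    attr(windows, "window_size"))
}

#' Two-pass coverage filter on a window matrix
#'
#' Pass 1 (cells): keep cells for which at least `cell_frac` of ALL
#' windows have `site_count >= min_sites`. Pass 2 (windows): keep
#' windows for which at least `window_frac` of the RETAINED cells have
#' `site_count >= min_sites`. The order matters and is fixed. CH
#' defaults: 20 sites / 75% / 75%; CG analyses conventionally use
#' 5 sites / 25% / 50%.
#'
#' @param m a `window_matrix`.
#' @param min_sites minimal called sites per cell-window.
#' @param cell_frac minimal fraction of windows a cell must cover.
#' @param window_frac minimal fraction of retained cells a window must
#'   be covered in.
#' @return a filtered `window_matrix`; zero retained cells or windows
#'   yields a valid empty matrix.
#' @export
filter_matrix <- function(m, min_sites = 20L, cell_frac = 0.75,
                          window_frac = 0.75) {
  stopifnot(inherits(m, "window_matrix"),
            cell_frac >= 0, cell_frac <= 1,
            window_frac >= 0, window_frac <= 1, min_sites >= 0)
  ok <- m$site_count >= min_sites
  keep_cells <- rowMeans(ok) >= cell_frac
  ok2 <- ok[keep_cells, , drop = FALSE]
  keep_wins <- if (nrow(ok2)) colMeans(ok2) >= window_frac
  else rep(FALSE, ncol(ok))
  new_window_matrix(
    m$meth_fraction[keep_cells, keep_wins, drop = FALSE],
    m$site_count[keep_cells, keep_wins, drop = FALSE],
    m$windows[keep_wins], m$barcodes[keep_cells], m$context,
    m$window_size)
}

#' Merge window matrices from multiple experiments
#'
#' Row-wise concatenation on an identical window set (same genome
#' build, window size and context); barcodes are prefixed with their
#' experiment id to guarantee uniqueness. No batch normalization is
#' applied.
#'
#' @param mats named list of `window_matrix` objects (names become
#'   experiment prefixes; unnamed lists get `exp1`, `exp2`, ...).
#' @return merged `window_matrix`.
#' @export
merge_matrices <- function(mats) {
  stopifnot(length(mats) >= 1L)
  if (is.null(names(mats)) || any(!nzchar(names(mats))))
    names(mats) <- paste0("exp", seq_along(mats))
  ref <- mats[[1]]
  for (m in mats[-1]) {
    if (!identical(m$windows$window_id, ref$windows$window_id) ||
        m$context != ref$context || m$window_size != ref$window_size) {
      d <- c(setdiff(ref$windows$window_id, m$windows$window_id),
             setdiff(m$windows$window_id, ref$windows$window_id))
      stop_param("window sets differ; e.g.: ",
                 paste(utils::head(d, 3L), collapse = ", "))
    }
  }
  frac <- do.call(rbind, lapply(mats, `[[`, "meth_fraction"))
  cnt <- do.call(rbind, lapply(mats, `[[`, "site_count"))
  bcs <- unlist(lapply(names(mats), function(nm) {
    paste0(nm, "_", mats[[nm]]$barcodes)
  }))
  new_window_matrix(frac, cnt, ref$windows, bcs, ref$context,
                    ref$window_size)
}

# Impute missing fractions: window mean across covered cells, or the
# cell's own global methylation level.
impute_matrix <- function(frac, method = c("window_mean", "cell_global")) {
  method <- match.arg(method)
  out <- frac
  if (method == "window_mean") {
    fill <- colMeans(frac, na.rm = TRUE)
    fill[is.nan(fill)] <- 0
    idx <- which(is.na(out), arr.ind = TRUE)
    out[idx] <- fill[idx[, 2]]
  } else {
    fill <- rowMeans(frac, na.rm = TRUE)
    fill[is.nan(fill)] <- 0
    idx <- which(is.na(out), arr.ind = TRUE)
    out[idx] <- fill[idx[, 1]]
  }
  out
}

#' Dimensionality reduction and graph clustering of a window matrix
#'
#' Missing entries are imputed (window mean by default), windows are
#' mean-centered (configurable off), and the matrix is reduced by
#' truncated SVD to `min(n_components, rank)` component scores. Cells
#' are then connected to their `knn_k` Euclidean nearest neighbours in
#' component space and the graph is partitioned by Louvain community
#' detection under a fixed seed; labels are contiguous integers ordered
#' by decreasing cluster size. A 2-D embedding is computed from the same
#' scores by a pluggable embedder (default: the first two components).
#'
#' @param m a filtered `window_matrix`.
#' @param n_components SVD components (default 50).
#' @param knn_k neighbours per cell (default 30; reduced with a warning
#'   when fewer cells are available).
#' @param seed integer seed for Louvain.
#' @param center center windows before SVD (default TRUE).
#' @param impute "window_mean" or "cell_global".
#' @param embed_fun function(scores) -> n x 2 matrix, or NULL for the
#'   default.
#' @return a `cluster_result`: `labels` (named integer per cell),
#'   `scores` (cells x components), `embedding` (cells x 2), `d`
#'   (singular values), `params`.
#' @export
reduce_and_cluster <- function(m, n_components = 50L, knn_k = 30L,
                               seed = 1L, center = TRUE,
                               impute = "window_mean",
                               embed_fun = NULL) {
  stopifnot(inherits(m, "window_matrix"))
  if (length(m$barcodes) == 0L || nrow(m$windows) == 0L)
    stop_param("cannot cluster an empty window matrix ",
               "(all cells or windows removed by filtering?)")
  x <- impute_matrix(m$meth_fraction, impute)
  if (center) x <- sweep(x, 2L, colMeans(x))
  k_svd <- min(n_components, dim(x) - 1L, min(dim(x)))
  sv <- La.svd(x, nu = k_svd, nv = 0L)
  scores <- sv$u %*% diag(sv$d[seq_len(k_svd)], k_svd)
  rownames(scores) <- m$barcodes

  n <- nrow(scores)
  if (knn_k >= n) {
    warning("knn_k reduced to ", n - 1L, " (only ", n, " cells)")
    knn_k <- n - 1L
  }
  dm <- as.matrix(stats::dist(scores))
  edges <- lapply(seq_len(n), function(i) {
    ord <- order(dm[i, ], seq_len(n))     # index tie-break: determinism
    nb <- setdiff(ord, i)[seq_len(knn_k)]
    cbind(i, nb)
  })
  e <- do.call(rbind, edges)
  e <- unique(t(apply(e, 1L, sort)))      # undirected union kNN graph
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  set.seed(derive_seed(seed, 101L))
  comm <- igraph::cluster_louvain(g)
  lab <- igraph::membership(comm)
  # relabel contiguously by decreasing size
  sizes <- sort(table(lab), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  labels <- as.integer(relab[as.character(lab)])
  names(labels) <- m$barcodes

  embedding <- if (is.null(embed_fun)) {
    scores[, seq_len(min(2L, ncol(scores))), drop = FALSE]
  } else {
    embed_fun(scores)
  }
  structure(list(labels = labels, scores = scores, embedding = embedding,
                 d = sv$d,
                 params = list(n_components = n_components, knn_k = knn_k,
                               seed = seed, center = center,
                               impute = impute)),
            class = "cluster_result")
}

#' @exportS3Method base::print
print.cluster_result <- function(x, ...) {
  cat("cluster_result:", length(x$labels), "cells,",
      length(unique(x$labels)), "clusters\n")
  print(table(cluster = x$labels))
  invisible(x)
}
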