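## Copy-number inference from expression (moving-average profile) and from
## binned bisulfite read counts (GC/mappability-corrected ratios with
## median-run thresholds).

#' Expression-based CNV profile
#'
#' Genes are ordered along the genome; each gene's `log2(TPM + 1)` is
#' replaced by the moving average over the 50 genes upstream and 50
#' downstream (plus itself; truncated at chromosome boundaries), then
#' centered per cell by subtracting the cell's genome-wide mean of adjusted
#' values.
#'
#' @param expr expression matrix (genes x cells, TPM).
#' @param gene_models gene model data.frame (positions used for ordering).
#' @param k half-window in genes (default 50).
#' @param min_genes_per_chrom chromosomes with fewer genes are skipped with
#'   a warning (default 5).
#' @return list of class `CNVProfile`: `genes` (ordered metadata),
#'   `values` (genes x cells centered moving-average signal),
#'   `source = "rna"`.
#' @export
rna_cnv_profile <- function(expr, gene_models, k = 50L,
                            min_genes_per_chrom = 5L) {
  gm <- gene_models[gene_models$gene_id %in% rownames(expr), , drop = FALSE]
  gm$pos <- pmin(gm$tss, gm$tes)
  gm <- gm[order(gm$chrom, gm$pos), , drop = FALSE]
  counts <- table(gm$chrom)
  drop <- names(counts)[counts < min_genes_per_chrom]
  if (length(drop)) {
    warning("chromosome(s) with < ", min_genes_per_chrom, " genes skipped: ",
            paste(drop, collapse = ", "))
    gm <- gm[!gm$chrom %in% drop, , drop = FALSE]
  }
  x <- log2(expr[gm$gene_id, , drop = FALSE] + 1)
  adj <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(x))
  for (ch in unique(gm$chrom)) {
    rows <- which(gm$chrom == ch)
    n <- length(rows)
    cs <- rbind(0, apply(x[rows, , drop = FALSE], 2, cumsum))
    lo <- pmax(seq_len(n) - k, 1L)
    hi <- pmin(seq_len(n) + k, n)
    adj[rows, ] <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
      (hi - lo + 1L)
  }
  adj <- sweep(adj, 2, colMeans(adj))
  structure(list(genes = gm[, c("gene_id", "chrom", "pos")], values = adj,
                 source = "rna"), class = "CNVProfile")
}

#' GC/mappability-corrected bin copy ratios
#'
#' Per cell: bins with mappability below `min_map` are masked; counts are
#' divided by the mappable fraction, normalized by the median count of bins
#' in the same GC decile (deciles over all unmasked bins), and finally
#' divided by the genome-wide median corrected count, giving a copy ratio
#' centered at 1 for neutral bins.
#'
#' @param counts integer matrix bins x cells of raw read counts.
#' @param gc optional per-bin GC content in \[0,1\]; NULL skips the decile
#'   normalization.
#' @param mappability optional per-bin mappable fraction; NULL = all 1.
#' @param n_gc_bins number of GC strata (default 10 = deciles).
#' @param min_map mask threshold (default 0.75).
#' @return numeric matrix bins x cells of copy ratios (NA where masked).
#' @export
correct_bin_counts <- function(counts, gc = NULL, mappability = NULL,
                               n_gc_bins = 10L, min_map = 0.75) {
  counts <- as.matrix(counts)
  n_bins <- nrow(counts)
  mapp <- mappability %||% rep(1, n_bins)
  mask <- mapp < min_map
  gc_stratum <- NULL
  if (!is.null(gc)) {
    br <- unique(quantile(gc[!mask], probs = seq(0, 1, length.out = n_gc_bins + 1)))
    # constant GC collapses to a single stratum (no correction possible)
    gc_stratum <- if (length(br) >= 2)
      cut(gc, breaks = br, include.lowest = TRUE)
    else factor(rep("all", n_bins))
  }
  out <- matrix(NA_real_, n_bins, ncol(counts), dimnames = dimnames(counts))
  for (ci in seq_len(ncol(counts))) {
    v <- counts[, ci] / mapp
    v[mask] <- NA_real_
    if (!is.null(gc_stratum)) {
      med <- tapply(v, gc_stratum, median, na.rm = TRUE)
      denom <- as.numeric(med[gc_stratum])
      v <- ifelse(denom > 0, v / denom, NA_real_)
    }
    g_med <- median(v, na.rm = TRUE)
    if (is.na(g_med) || g_med == 0) stop("zero genome-wide median corrected count")
    out[, ci] <- v / g_med
  }
  out
}

#' Segment corrected ratios into gain/loss calls
#'
#' Candidate runs are maximal consecutive stretches of bins (within one
#' chromosome) whose ratio exceeds `gain_cut` (or falls below `loss_cut`);
#' missing bins break runs. A run is called iff its length is strictly
#' greater than `min_run` and the median ratio of the run passes the same
#' cut. The cuts are strict inequalities: ratios exactly at 1.36 / 0.67
#' never trigger.
#'
#' @param ratios matrix bins x cells from [correct_bin_counts()].
#' @param bins interval data.frame matching the rows (genome order).
#' @param gain_cut,loss_cut thresholds (defaults 1.36 / 0.67).
#' @param min_run strict minimum run length in bins (default 10: runs must
#'   exceed 10 bins).
#' @return data.frame `cell_id, chrom, start, end, call, n_bins,
#'   median_ratio`.
#' @export
segment_and_call <- function(ratios, bins, gain_cut = 1.36, loss_cut = 0.67,
                             min_run = 10L) {
  stopifnot(nrow(ratios) == nrow(bins))
  cells <- colnames(ratios) %||% sprintf("cell%d", seq_len(ncol(ratios)))
  rows <- list()
  for (ci in seq_len(ncol(ratios))) {
    for (ch in unique(bins$chrom)) {
      sel <- which(bins$chrom == ch)
      r <- ratios[sel, ci]
      state <- ifelse(is.na(r), "na",
                      ifelse(r > gain_cut, "gain",
                             ifelse(r < loss_cut, "loss", "neutral")))
      rl <- rle(state)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      for (seg in which(rl$values %in% c("gain", "loss") &
                        rl$lengths > min_run)) {
        run <- seq.int(starts[seg], ends[seg])
        med <- median(r[run])
        pass <- if (rl$values[seg] == "gain") med > gain_cut else med < loss_cut
        if (!pass) next
        rows[[length(rows) + 1L]] <- data.frame(
          cell_id = cells[ci], chrom = ch,
          start = bins$start[sel[starts[seg]]],
          end = bins$end[sel[ends[seg]]],
          call = rl$values[seg], n_bins = rl$lengths[seg],
          median_ratio = med, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(cell_id = character(), chrom = character(),
                      start = integer(), end = integer(), call = character(),
                      n_bins = integer(), median_ratio = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
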