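## Nucleosome-depleted region (NDR) detection.
##
## GCH calls of all cells in a group are pooled; 120-bp windows at 20-bp
## spacing are tested against the genomic background with a 2x2 chi-square
## (1 df, no continuity correction); windows with significantly elevated
## GCH methylation (p <= 1e-15) are merged, and merged regions must be at
## least 140 bp long, contain at least 5 distinct GCH sites and avoid the
## blacklist.

#' Pool GCH calls across cells
#'
#' @param calls list of GCH-only [CytosineCallSet()] (one per cell of a
#'   group, e.g. a developmental stage).
#' @return data.table `chrom,pos,strand,n_meth,n_unmeth` with per-site sums,
#'   keyed by position.
#' @export
aggregate_gch <- function(calls) {
  calls <- as_call_list(calls)
  recs <- rbindlist(lapply(calls, `[[`, "records"))
  if (!nrow(recs)) return(data.table(chrom = character(), pos = integer(),
                                     strand = character(), n_meth = integer(),
                                     n_unmeth = integer()))
  if (any(recs$context != "GCH"))
    stop("aggregate_gch expects GCH-context records only")
  pooled <- recs[, .(n_meth = sum(n_meth), n_unmeth = sum(n_unmeth)),
                 by = .(chrom, pos, strand)]
  setkeyv(pooled, c("chrom", "pos"))
  pooled[]
}

#' Sliding-window chi-square scan of pooled GCH counts
#'
#' Windows tile each chromosome from offset 0. Each window with at least one
#' covered site is tested with a 2x2 chi-square of its (C, T) counts against
#' the remaining genome-wide counts, 1 df, no Yates correction; `p` is the
#' upper tail.
#'
#' @param pooled output of [aggregate_gch()].
#' @param chrom_sizes named vector of chromosome lengths.
#' @param window,step window width and spacing in bases.
#' @return data.table of window statistics (`chrom,start,end,n_meth,
#'   n_unmeth,n_sites,chi2,p`) with attributes `genome_rate`, `genome_c`,
#'   `genome_t`.
#' @export
scan_windows <- function(pooled, chrom_sizes, window = 120L, step = 20L) {
  stopifnot(window > 0L, step > 0L)
  empty <- data.table(chrom = character(), start = integer(), end = integer(),
                      n_meth = numeric(), n_unmeth = numeric(),
                      n_sites = integer(), chi2 = numeric(), p = numeric())
  if (!nrow(pooled)) return(empty)
  g_c <- sum(pooled$n_meth)
  g_t <- sum(pooled$n_unmeth)
  out <- vector("list", length(chrom_sizes))
  for (i in seq_along(chrom_sizes)) {
    ch <- names(chrom_sizes)[i]
    sub <- pooled[chrom == ch]
    if (!nrow(sub)) next
    o <- order(sub$pos)
    pos <- sub$pos[o]
    cum_c <- c(0, cumsum(sub$n_meth[o]))
    cum_t <- c(0, cumsum(sub$n_unmeth[o]))
    starts <- seq.int(0L, max(0L, as.integer(chrom_sizes[[i]]) - 1L), by = step)
    # window [s, s+window) covers 1-based positions s+1 .. s+window
    hi <- findInterval(pmin(starts + window, as.integer(chrom_sizes[[i]])), pos)
    lo <- findInterval(starts, pos)
    ns <- hi - lo
    keep <- ns >= 1L
    if (!any(keep)) next
    out[[i]] <- data.table(chrom = ch, start = starts[keep],
                           end = as.integer(pmin(starts[keep] + window,
                                                 chrom_sizes[[i]])),
                           n_meth = cum_c[hi + 1L][keep] - cum_c[lo + 1L][keep],
                           n_unmeth = cum_t[hi + 1L][keep] - cum_t[lo + 1L][keep],
                           n_sites = ns[keep])
  }
  stats <- rbindlist(out)
  if (!nrow(stats)) return(empty)
  a <- stats$n_meth; b <- stats$n_unmeth
  cc <- g_c - a; dd <- g_t - b
  n <- g_c + g_t
  num <- n * (a * dd - b * cc)^2
  den <- (a + b) * (cc + dd) * (a + cc) * (b + dd)
  stats[, chi2 := ifelse(den > 0, num / den, 0)]
  stats[, p := pchisq(chi2, df = 1, lower.tail = FALSE)]
  setattr(stats, "genome_rate", g_c / (g_c + g_t))
  setattr(stats, "genome_c", g_c)
  setattr(stats, "genome_t", g_t)
  stats[]
}

#' Merge significant windows into NDRs
#'
#' Keeps windows with `p <= p_cut` and a GCH rate above the genomic
#' background ("significantly elevated"), merges overlapping or book-ended
#' windows, recomputes distinct-site counts and the pooled accessibility of
#' each merged region, applies the length and site filters, and removes
#' regions overlapping the blacklist by >= 1 bp.
#'
#' @param stats window table from [scan_windows()].
#' @param pooled pooled count table from [aggregate_gch()].
#' @param p_cut significance cutoff (default 1e-15).
#' @param min_len minimum merged length in bp (default 140).
#' @param min_sites minimum distinct GCH sites (default 5).
#' @param blacklist optional interval data.frame of regions to exclude.
#' @param gap maximum gap (bp) between kept windows that still merges
#'   (default 0 = overlap or book-ended only).
#' @return data.frame of NDRs: `chrom,start,end,name,p_min,n_sites,mean_acc`.
#' @export
merge_significant_windows <- function(stats, pooled, p_cut = 1e-15,
                                      min_len = 140L, min_sites = 5L,
                                      blacklist = NULL, gap = 0L) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), p_min = numeric(),
                      n_sites = integer(), mean_acc = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(stats)) return(empty)
  g_rate <- attr(stats, "genome_rate")
  sig <- stats[stats$p <= p_cut &
                 stats$n_meth / (stats$n_meth + stats$n_unmeth) > g_rate, ]
  if (!nrow(sig)) return(empty)
  gr <- GenomicRanges::reduce(gi_to_gr(sig), min.gapwidth = gap + 1L)
  ndrs <- gr_to_gi(gr)
  # min constituent-window p per merged region
  hits <- GenomicRanges::findOverlaps(gi_to_gr(sig), gr)
  pmin_by <- tapply(sig$p[S4Vectors::queryHits(hits)],
                    S4Vectors::subjectHits(hits), min)
  ndrs$p_min <- as.numeric(pmin_by[as.character(seq_len(nrow(ndrs)))])
  # distinct sites + pooled counts over the merged interval
  gr_sites <- GenomicRanges::GRanges(pooled$chrom,
                                     IRanges::IRanges(pooled$pos, pooled$pos))
  sh <- GenomicRanges::findOverlaps(gr_sites, gr)
  qi <- S4Vectors::queryHits(sh); si <- S4Vectors::subjectHits(sh)
  agg <- data.table(si = si, c = pooled$n_meth[qi], t = pooled$n_unmeth[qi])[
    , .(n_sites = .N, c = sum(c), t = sum(t)), by = si]
  ndrs$n_sites <- 0L; ndrs$mean_acc <- NA_real_
  ndrs$n_sites[agg$si] <- agg$n_sites
  ndrs$mean_acc[agg$si] <- agg$c / (agg$c + agg$t)
  keep <- (ndrs$end - ndrs$start) >= min_len & ndrs$n_sites >= min_sites
  ndrs <- ndrs[keep, , drop = FALSE]
  if (!is.null(blacklist) && nrow(ndrs) && nrow(blacklist)) {
    ov <- GenomicRanges::findOverlaps(gi_to_gr(ndrs), gi_to_gr(blacklist))
    if (length(ov))
      ndrs <- ndrs[-unique(S4Vectors::queryHits(ov)), , drop = FALSE]
  }
  if (nrow(ndrs)) {
    ndrs$name <- sprintf("ndr%05d", seq_len(nrow(ndrs)))
    ndrs <- ndrs[, c("chrom", "start", "end", "name", "p_min", "n_sites",
                     "mean_acc")]
    rownames(ndrs) <- NULL
  } else ndrs <- empty
  ndrs
}

#' Classify NDRs relative to gene TSSs
#'
#' An NDR overlapping any TSS point is a `TSS_NDR`; otherwise an NDR whose
#' distance to the nearest TSS is below `proximal_dist` is a `Proximal_NDR`;
#' all others are `Distal_NDR` (at least `proximal_dist` away).
#'
#' @param ndrs NDR data.frame.
#' @param genes gene model data.frame (needs `chrom`, `tss`).
#' @param proximal_dist promoter distance cutoff in bp (default 2000).
#' @return `ndrs` with a `klass` column.
#' @export
classify_ndrs <- function(ndrs, genes, proximal_dist = 2000L) {
  if (!nrow(ndrs)) { ndrs$klass <- character(0); return(ndrs) }
  if (is.null(genes) || !nrow(genes)) {
    warning("no gene models supplied; all NDRs classified Distal_NDR")
    ndrs$klass <- "Distal_NDR"
    return(ndrs)
  }
  gr_n <- gi_to_gr(ndrs)
  gr_t <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$tss, genes$tss))
  klass <- rep("Distal_NDR", nrow(ndrs))
  ov <- GenomicRanges::findOverlaps(gr_n, gr_t)
  klass[unique(S4Vectors::queryHits(ov))] <- "TSS_NDR"
  dn <- GenomicRanges::distanceToNearest(gr_n, gr_t)
  qh <- S4Vectors::queryHits(dn)
  near <- qh[S4Vectors::mcols(dn)$distance < proximal_dist]
  klass[setdiff(near, unique(S4Vectors::queryHits(ov)))] <- "Proximal_NDR"
  ndrs$klass <- klass
  ndrs
}

#' Call NDRs from per-cell GCH data
#'
#' Convenience wrapper: pool, scan, merge, classify.
#'
#' @param calls list of GCH [CytosineCallSet()].
#' @param chrom_sizes named chromosome lengths.
#' @param genes optional gene models for classification.
#' @param blacklist optional blacklist intervals.
#' @param window,step,p_cut,min_len,min_sites,gap see
#'   [scan_windows()]/[merge_significant_windows()].
#' @return classified NDR data.frame.
#' @export
call_ndrs <- function(calls, chrom_sizes, genes = NULL, blacklist = NULL,
                      window = 120L, step = 20L, p_cut = 1e-15,
                      min_len = 140L, min_sites = 5L, gap = 0L) {
  pooled <- aggregate_gch(calls)
  stats <- scan_windows(pooled, chrom_sizes, window = window, step = step)
  ndrs <- merge_significant_windows(stats, pooled, p_cut = p_cut,
                                    min_len = min_len, min_sites = min_sites,
                                    blacklist = blacklist, gap = gap)
  if (!is.null(genes)) ndrs <- classify_ndrs(ndrs, genes) else
    ndrs$klass <- rep("Distal_NDR", nrow(ndrs))
  ndrs
}
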