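## Allele-specific methylation/accessibility on 500-bp tiles.

#' Per-tile allelic counts
#'
#' Sums methylated (C) and unmethylated (T) read counts over all cells and
#' sites of each 0-anchored `tile_size`-bp tile, separately per allele and
#' per stage. Tiles covered by fewer than `min_cells` cells on either
#' allele are excluded.
#'
#' @param mat_calls,pat_calls per-cell allele-tagged [CytosineCallSet()]
#'   lists (maternal / paternal).
#' @param stage_of optional named vector mapping cell id to stage; NULL
#'   treats all cells as one group `"all"`.
#' @param context `"WCG"` or `"GCH"`.
#' @param tile_size tile width in bp (fixed grid anchored at 0).
#' @param min_cells minimum covering cells per allele (default 3).
#' @return data.frame `stage, chrom, start, end, context, mat_c, mat_t,
#'   pat_c, pat_t, n_cells_mat, n_cells_pat`.
#' @export
allelic_tile_counts <- function(mat_calls, pat_calls, stage_of = NULL,
                                context = c("WCG", "GCH"), tile_size = 500L,
                                min_cells = 3L) {
  context <- match.arg(context)
  tally <- function(calls) {
    calls <- as_call_list(calls)
    recs <- rbindlist(lapply(calls, function(cs)
      cbind(cs$records[context, on = "context", nomatch = NULL],
            cell_id = cs$cell_id)))
    if (!nrow(recs)) return(recs)
    recs[, stage := if (is.null(stage_of)) "all" else stage_of[cell_id]]
    recs[, start := as.integer((pos - 1L) %/% tile_size) * tile_size]
    recs[, .(c = sum(n_meth), t = sum(n_unmeth),
             n_cells = length(unique(cell_id))),
         by = .(stage, chrom, start)]
  }
  m <- tally(mat_calls)
  p <- tally(pat_calls)
  if (!nrow(m) || !nrow(p))
    return(data.frame(stage = character(), chrom = character(),
                      start = integer(), end = integer(),
                      context = character(), mat_c = numeric(),
                      mat_t = numeric(), pat_c = numeric(), pat_t = numeric(),
                      n_cells_mat = integer(), n_cells_pat = integer()))
  setnames(m, c("c", "t", "n_cells"), c("mat_c", "mat_t", "n_cells_mat"))
  setnames(p, c("c", "t", "n_cells"), c("pat_c", "pat_t", "n_cells_pat"))
  j <- merge(m, p, by = c("stage", "chrom", "start"))
  j <- j[n_cells_mat >= min_cells & n_cells_pat >= min_cells]
  out <- as.data.frame(j)
  out$end <- out$start + tile_size
  out$context <- rep(context, nrow(out))
  out[order(out$stage, out$chrom, out$start),
      c("stage", "chrom", "start", "end", "context", "mat_c", "mat_t",
        "pat_c", "pat_t", "n_cells_mat", "n_cells_pat")]
}

#' Fisher exact test of allelic differences per tile
#'
#' Two-sided Fisher exact test on `[[mat_c, mat_t], [pat_c, pat_t]]` per
#' tile, BH-adjusted within each stage x context family; a tile is
#' significant iff `fdr < fdr_cut`. Tables with a zero margin are defined
#' (p = 1).
#'
#' @param counts output of [allelic_tile_counts()].
#' @param fdr_cut significance cutoff (default 0.01).
#' @return `counts` with `odds_ratio` (sample odds ratio), `p`, `fdr`,
#'   `significant` columns.
#' @export
allelic_difference_test <- function(counts, fdr_cut = 0.01) {
  n <- nrow(counts)
  p <- numeric(n); or <- numeric(n)
  for (i in seq_len(n)) {
    tab <- matrix(c(counts$mat_c[i], counts$mat_t[i],
                    counts$pat_c[i], counts$pat_t[i]), 2, byrow = TRUE)
    p[i] <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1 else
      fisher.test(tab)$p.value
    or[i] <- (counts$mat_c[i] * counts$pat_t[i]) /
      (counts$mat_t[i] * counts$pat_c[i])
  }
  out <- counts
  out$odds_ratio <- or
  out$p <- p
  out$fdr <- NA_real_
  for (grp in unique(paste(counts$stage, counts$context))) {
    sel <- paste(counts$stage, counts$context) == grp
    out$fdr[sel] <- p.adjust(p[sel], "BH")
  }
  out$significant <- out$fdr < fdr_cut
  out
}

#' Allele-resolved genic profiles
#'
#' Same running-window machinery as [genic_profile()] with the allelic
#' geometry: 500-bp windows at 100-bp steps over the 2.5-kb flanks (21
#' windows per flank) and a 10-fraction window at 2-fraction steps over the
#' 100-fraction gene body (46 windows); one track per allele per cell.
#'
#' @param mat_calls,pat_calls per-cell allele-tagged call lists.
#' @param genes gene model data.frame.
#' @param context `"WCG"` or `"GCH"`.
#' @return list with `maternal` and `paternal`: lists of `ProfileTrack`, one
#'   per cell.
#' @export
allelic_genic_profile <- function(mat_calls, pat_calls, genes,
                                  context = c("WCG", "GCH")) {
  context <- match.arg(context)
  run <- function(calls) lapply(as_call_list(calls), genic_profile,
                                genes = genes, context = context,
                                flank = 2500L, window = 500L, step = 100L,
                                fractions = 100L, body_window = 10L,
                                body_step = 2L)
  list(maternal = run(mat_calls), paternal = run(pat_calls))
}
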